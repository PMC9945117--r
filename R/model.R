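# Classifier layer. The random forest is the primary model; linear
# discriminant, RBF support vector machine, and decision tree are the
# classical baselines, each used with its host package's standard
# defaults (recorded in the model/run config).

classifierKinds <- c("rf", "ld", "svm", "dt")

#' Train a virion-protein classifier
#'
#' Fits one of four classifiers to a feature matrix:
#' \describe{
#'   \item{\code{"rf"}}{random forest (\pkg{randomForest}), default 500
#'     trees; the prediction score is the fraction of trees voting
#'     positive.}
#'   \item{\code{"ld"}}{linear discriminant (\code{MASS::lda}); score is
#'     the posterior probability of the positive class.}
#'   \item{\code{"svm"}}{RBF support vector machine (\code{e1071::svm})
#'     with probability estimates.}
#'   \item{\code{"dt"}}{CART decision tree (\code{rpart}), default
#'     complexity settings.}
#' }
#' Training is deterministic given \code{seed}. Constant (zero-variance)
#' columns are dropped for \code{"ld"} and \code{"svm"}, which cannot use
#' them; the dropped names are recorded in the model config.
#'
#' @param features A \linkS4class{VirionFeatures} with labels, or a
#'   numeric matrix (then \code{labels} is required).
#' @param labels Optional label factor/character when \code{features} is a
#'   bare matrix.
#' @param kind One of \code{"rf"}, \code{"ld"}, \code{"svm"}, \code{"dt"}.
#' @param nTrees Forest size for \code{kind = "rf"}.
#' @param seed Integer seed controlling all training randomness.
#' @param ... Further arguments passed to the underlying fitting function.
#' @return A \linkS4class{VirionModel}.
#' @seealso [predictScores()], [crossValidate()]
#' @export
trainClassifier <- function(features, labels = NULL,
                            kind = c("rf", "ld", "svm", "dt"),
                            nTrees = 500L, seed = 1L, ...) {
  kind <- match.arg(kind)
  if (is(features, "VirionFeatures")) {
    if (is.null(labels)) labels <- classLabels(features)
    features <- featureMatrix(features)
  }
  stopifnot(is.matrix(features), !is.null(colnames(features)))
  if (!all(is.finite(features))) stop("feature matrix contains NA/NaN/Inf")
  y <- factor(as.character(labels), levels = c("negative", "positive"))
  if (anyNA(y)) stop("labels must be 'positive'/'negative'")
  if (length(y) != nrow(features))
    stop("labels must match the number of rows")
  if (nlevels(droplevels(y)) < 2L || min(table(y)) < 2L)
    stop("need at least 2 samples in each class")
  dropped <- character()
  fullNames <- colnames(features)
  if (kind %in% c("ld", "svm")) {
    const <- apply(features, 2L, function(v) length(unique(v)) == 1L)
    dropped <- colnames(features)[const]
    features <- features[, !const, drop = FALSE]
  }
  set.seed(as.integer(seed))
  fit <- switch(kind,
    rf = randomForest::randomForest(features, y, ntree = as.integer(nTrees),
                                    ...),
    ld = suppressWarnings(MASS::lda(features, grouping = y, ...)),
    svm = e1071::svm(features, y, kernel = "radial", probability = TRUE,
                     ...),
    dt = rpart::rpart(y ~ ., data = data.frame(features, check.names = FALSE,
                                               y = y),
                      method = "class", ...))
  cfg <- list(seed = as.integer(seed), droppedConstant = dropped,
              fullFeatureNames = fullNames)
  if (kind == "rf") cfg$nTrees <- as.integer(nTrees)
  new("VirionModel", kind = kind, fit = fit,
      featureNames = colnames(features), config = cfg)
}

#' Positive-class scores from a trained model
#'
#' Scores in [0, 1]: the fraction of forest trees voting positive, or the
#' model's posterior/probability analogue for the baselines. The matrix
#' columns must match the model's \code{featureNames} exactly (same names,
#' same order) — a mismatch is an error, never a silent reorder.
#' Thresholding at 0.5 (ties toward negative) gives hard labels.
#'
#' @param model A \linkS4class{VirionModel}.
#' @param features A \linkS4class{VirionFeatures} or numeric matrix. For
#'   models that dropped constant columns at training, the full original
#'   column set is also accepted.
#' @return Numeric vector of scores, one per row.
#' @export
predictScores <- function(model, features) {
  stopifnot(is(model, "VirionModel"))
  if (is(features, "VirionFeatures")) features <- featureMatrix(features)
  stopifnot(is.matrix(features))
  want <- model@featureNames
  if (!identical(colnames(features), want)) {
    # exact original training layout (incl. columns dropped as constant)
    # is also accepted; anything else — including a permutation — is not
    full <- model@config$fullFeatureNames
    if (length(model@config$droppedConstant) &&
        identical(colnames(features), full))
      features <- features[, want, drop = FALSE]
    else
      stop("feature columns do not match the model's featureNames")
  }
  switch(model@kind,
    rf = stats::predict(model@fit, features, type = "prob")[, "positive"],
    ld = stats::predict(model@fit, features)$posterior[, "positive"],
    svm = attr(stats::predict(model@fit, features, probability = TRUE),
               "probabilities")[, "positive"],
    dt = stats::predict(model@fit,
                        data.frame(features, check.names = FALSE),
                        type = "prob")[, "positive"])
}

# hard labels at the 0.5 vote-fraction threshold; ties go negative
hardLabels <- function(scores) {
  factor(ifelse(scores > 0.5, "positive", "negative"),
         levels = c("negative", "positive"))
}

#' Persist / restore a trained model
#'
#' Writes a versioned bundle (config, feature names, fitted state) via
#' \code{saveRDS}. \code{readVirionModel} refuses bundles with an unknown
#' format version, and [predictScores()] enforces feature-name identity at
#' prediction time.
#'
#' @param model A \linkS4class{VirionModel}.
#' @param path File path for the bundle.
#' @return \code{writeVirionModel}: \code{path}, invisibly;
#'   \code{readVirionModel}: the \linkS4class{VirionModel}.
#' @export
writeVirionModel <- function(model, path) {
  stopifnot(is(model, "VirionModel"))
  saveRDS(list(format = "virionRF-model", version = model@version,
               kind = model@kind, featureNames = model@featureNames,
               config = model@config, fit = model@fit), path)
  invisible(path)
}

#' @rdname writeVirionModel
#' @param path File path for the bundle.
#' @export
readVirionModel <- function(path) {
  b <- readRDS(path)
  if (!identical(b$format, "virionRF-model") || !identical(b$version, "1"))
    stop("not a recognized model bundle (format/version mismatch)")
  new("VirionModel", kind = b$kind, fit = b$fit,
      featureNames = b$featureNames, config = b$config, version = b$version)
}

# stratified fold assignment: per-class round-robin of a shuffled index,
# keeping per-fold class ratios within one sample of the global ratio
stratifiedFolds <- function(labels, folds, seed, stratified = TRUE) {
  n <- length(labels)
  assign <- integer(n)
  set.seed(as.integer(seed))
  if (stratified) {
    for (cl in levels(labels)) {
      i <- which(labels == cl)
      if (length(i) < folds)
        stop("class '", cl, "' has fewer samples than folds")
      assign[i] <- sample(rep_len(seq_len(folds), length(i)))
    }
  } else {
    if (n < folds) stop("fewer samples than folds")
    assign <- sample(rep_len(seq_len(folds), n))
  }
  assign
}

#' Stratified k-fold cross-validation of an encoding + classifier
#'
#' Encodes the dataset once, splits it into stratified folds, trains on
#' each training split and scores the held-out fold. All out-of-fold
#' predictions are pooled into a single confusion table from which the
#' five metrics are computed once (pooled protocol); per-fold metrics and
#' the pooled ROC curve are also returned. The whole procedure is
#' deterministic given \code{seed}.
#'
#' @param data A \linkS4class{VirionSet}.
#' @param spec An \linkS4class{EncodingSpec}, or a single encoding name
#'   (\code{"aac"}, \code{"cksaap"}, \code{"dpc"}, \code{"dde"},
#'   \code{"combined"}).
#' @param classifier Classifier kind, see [trainClassifier()].
#' @param folds Number of folds (default 5); each class must have at
#'   least \code{folds} samples.
#' @param stratified Keep class ratios across folds (default TRUE).
#' @param seed Integer seed for fold assignment and per-fold training.
#' @param nTrees Forest size for the random forest.
#' @param ... Passed to [trainClassifier()].
#' @return A \linkS4class{VirionEvaluation}.
#' @export
crossValidate <- function(data, spec = encodingSpec(),
                          classifier = c("rf", "ld", "svm", "dt"),
                          folds = 5L, stratified = TRUE, seed = 1L,
                          nTrees = 500L, ...) {
  classifier <- match.arg(classifier)
  encodingName <- if (is.character(spec)) tolower(spec) else "custom"
  if (is.character(spec)) spec <- specForEncoding(spec)
  stopifnot(is(data, "VirionSet"), is(spec, "EncodingSpec"))
  if (identical(encodingName, "custom") &&
      spec@useAAC && spec@useCKSAAP && spec@useDPC && spec@useDDE)
    encodingName <- "combined"
  feats <- encodeFeatures(data, spec)
  m <- featureMatrix(feats)
  y <- classLabels(data)
  folds <- as.integer(folds)
  stopifnot(folds >= 2L)
  assign <- stratifiedFolds(y, folds, seed, stratified)
  scores <- rep(NA_real_, length(y))
  perFold <- vector("list", folds)
  for (k in seq_len(folds)) {
    test <- assign == k
    model <- trainClassifier(m[!test, , drop = FALSE], y[!test],
                             kind = classifier, nTrees = nTrees,
                             seed = childSeed(seed, k), ...)
    scores[test] <- predictScores(model, m[test, , drop = FALSE])
    # per-fold metrics are undefined when a fold misses a class
    # (e.g. leave-one-out); the pooled metrics below are always defined
    foldMetrics <- tryCatch(
      computeMetrics(confusionCounts(y[test], hardLabels(scores[test]))),
      error = function(e) list(sn = NA_real_, sp = NA_real_, acc = NA_real_,
                               f1 = NA_real_, mcc = NA_real_))
    perFold[[k]] <- data.frame(fold = k,
                               sn = foldMetrics$sn, sp = foldMetrics$sp,
                               acc = foldMetrics$acc, f1 = foldMetrics$f1,
                               mcc = foldMetrics$mcc)
  }
  counts <- confusionCounts(y, hardLabels(scores))
  roc <- rocPoints(scores, y)
  new("VirionEvaluation", classifier = classifier, encoding = encodingName,
      counts = counts, metrics = computeMetrics(counts),
      perFold = do.call(rbind, perFold), roc = roc, auc = rocAUC(roc),
      scores = scores, folds = assign,
      config = list(classifier = classifier, folds = folds,
                    stratified = stratified, seed = as.integer(seed),
                    nTrees = as.integer(nTrees),
                    foldSeeds = vapply(seq_len(folds),
                                       function(k) childSeed(seed, k), 1L),
                    encoding = encodingName))
}

#' Cross-validated comparison of classifiers and encodings
#'
#' Runs [crossValidate()] for every (classifier, encoding) combination and
#' stacks the pooled metrics into one table — one row per combination,
#' mirroring a per-feature performance comparison.
#'
#' @param data A \linkS4class{VirionSet}.
#' @param classifiers Subset of \code{c("rf", "ld", "svm", "dt")}.
#' @param encodings Subset of \code{c("aac", "cksaap", "dpc", "dde",
#'   "combined")}.
#' @param folds,seed,nTrees See [crossValidate()].
#' @return List with \code{table} (data frame from [metricsTable()]) and
#'   \code{evaluations} (named list of \linkS4class{VirionEvaluation}).
#' @export
evaluationReport <- function(data, classifiers = c("rf", "ld", "svm", "dt"),
                             encodings = c("aac", "cksaap", "dpc", "dde",
                                           "combined"),
                             folds = 5L, seed = 1L, nTrees = 500L) {
  classifiers <- match.arg(classifiers, several.ok = TRUE)
  encodings <- match.arg(tolower(encodings),
                         c("aac", "cksaap", "dpc", "dde", "combined"),
                         several.ok = TRUE)
  evs <- list()
  for (enc in encodings)
    for (clf in classifiers)
      evs[[paste(clf, enc, sep = ".")]] <-
        crossValidate(data, enc, classifier = clf, folds = folds,
                      seed = seed, nTrees = nTrees)
  list(table = metricsTable(evs), evaluations = evs)
}
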
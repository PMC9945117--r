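#' @import methods
#' @importFrom Biostrings AAStringSet readAAStringSet writeXStringSet
NULL

#' The 20 standard amino-acid residues
#'
#' One-letter codes of the standard proteinogenic amino acids, in the fixed
#' alphabetical order used for every feature block in this package.
#'
#' @format Character vector of length 20.
#' @export
AA_ALPHABET20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                   "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Genetic-code codon multiplicities
#'
#' Number of sense codons encoding each standard residue (61 in total),
#' used as the theoretical background of the DDE descriptor: under this
#' null the expected frequency of a dipeptide ab is
#' (codons(a)/61) * (codons(b)/61).
#'
#' @format Named integer vector of length 20 summing to 61.
#' @export
CODON_COUNTS <- c(A = 4L, C = 2L, D = 2L, E = 2L, F = 2L, G = 4L, H = 2L,
                  I = 3L, K = 2L, L = 6L, M = 1L, N = 2L, P = 4L, Q = 2L,
                  R = 6L, S = 6L, T = 4L, V = 4L, W = 1L, Y = 2L)

# 400 dipeptides, first position major: AA, AC, ..., AY, CA, ..., YY
dipeptideNames <- function() {
  paste0(rep(AA_ALPHABET20, each = 20L), rep(AA_ALPHABET20, 20L))
}

#' Labeled two-class protein sequence set
#'
#' Container for a binary phage virion-protein benchmark: an
#' \link[Biostrings]{AAStringSet} of validated sequences plus a parallel
#' label factor with levels \code{negative} (non-virion) and
#' \code{positive} (virion). Positives conventionally precede negatives.
#'
#' @slot sequences An \code{AAStringSet}; every sequence is non-empty and
#'   contains only the 20 standard residues.
#' @slot labels Factor with levels \code{c("negative", "positive")},
#'   one per sequence.
#' @slot provenance Single string describing where the set came from.
#'
#' @seealso [loadLabeledSet()], [generateVirionSet()]
#' @export
setClass("VirionSet",
  representation(sequences = "AAStringSet",
                 labels = "factor",
                 provenance = "character"),
  prototype(provenance = NA_character_))

setValidity("VirionSet", function(object) {
  msg <- character()
  if (length(object@sequences) != length(object@labels))
    msg <- c(msg, "sequences and labels must have equal length")
  if (!identical(levels(object@labels), c("negative", "positive")))
    msg <- c(msg, "labels must be a factor with levels c('negative','positive')")
  if (anyNA(object@labels))
    msg <- c(msg, "labels must not contain NA")
  w <- Biostrings::width(object@sequences)
  if (length(w) && any(w < 1L))
    msg <- c(msg, "all sequences must have length >= 1")
  bad <- invalidResidueIds(object@sequences)
  if (length(bad))
    msg <- c(msg, paste0("non-standard residues in: ",
                         paste(utils::head(bad, 5L), collapse = ", ")))
  if (length(object@provenance) != 1L)
    msg <- c(msg, "provenance must be a single string")
  if (length(msg)) msg else TRUE
})

#' Encoding specification
#'
#' Which of the four sequence descriptors to compute and their parameters.
#' With all four enabled and \code{cksaapMaxGap = 3} the combined vector has
#' 20 + 1600 + 400 + 400 = 2420 dimensions.
#'
#' @slot useAAC,useCKSAAP,useDPC,useDDE Logical flags; at least one must
#'   be \code{TRUE}.
#' @slot cksaapMaxGap Integer >= 0, the largest gap k (number of residues
#'   separating a pair); gap blocks 0..k are concatenated. Default 3.
#' @slot ddeSqrtVariance Logical; if \code{TRUE} (default) DDE standardizes
#'   by the standard deviation sqrt(Tv), if \code{FALSE} by the variance Tv.
#'
#' @seealso [encodingSpec()], [encodeFeatures()]
#' @export
setClass("EncodingSpec",
  representation(useAAC = "logical", useCKSAAP = "logical",
                 useDPC = "logical", useDDE = "logical",
                 cksaapMaxGap = "integer", ddeSqrtVariance = "logical"),
  prototype(useAAC = TRUE, useCKSAAP = TRUE, useDPC = TRUE, useDDE = TRUE,
            cksaapMaxGap = 3L, ddeSqrtVariance = TRUE))

setValidity("EncodingSpec", function(object) {
  msg <- character()
  flags <- c(object@useAAC, object@useCKSAAP, object@useDPC, object@useDDE)
  if (length(flags) != 4L || anyNA(flags))
    msg <- c(msg, "the four use* flags must be single non-NA logicals")
  else if (!any(flags))
    msg <- c(msg, "at least one encoding must be enabled")
  if (length(object@cksaapMaxGap) != 1L || is.na(object@cksaapMaxGap) ||
      object@cksaapMaxGap < 0L)
    msg <- c(msg, "cksaapMaxGap must be a single integer >= 0")
  if (length(object@ddeSqrtVariance) != 1L || is.na(object@ddeSqrtVariance))
    msg <- c(msg, "ddeSqrtVariance must be a single logical")
  if (length(msg)) msg else TRUE
})

#' Feature matrix with per-column encoding provenance
#'
#' Dense numeric matrix of one feature vector per sequence (rows follow the
#' originating \linkS4class{VirionSet} order), with column names following
#' the feature-name grammar \code{AAC.<a>}, \code{CKSAAP.<ab>.gap<k>},
#' \code{DPC.<ab>}, \code{DDE.<ab>} and a parallel vector recording which
#' encoding block each column belongs to.
#'
#' @slot matrix Numeric matrix, samples x features, finite, with row names
#'   (sequence ids) and column names (feature names).
#' @slot blocks Character vector, one of \code{"AAC"}, \code{"CKSAAP"},
#'   \code{"DPC"}, \code{"DDE"} per column.
#' @slot labels Factor as in \linkS4class{VirionSet} (may be length 0 for
#'   unlabeled input).
#' @slot spec The \linkS4class{EncodingSpec} that produced the matrix.
#'
#' @seealso [encodeFeatures()], [featureMatrix()], [writeFeatureCSV()]
#' @export
setClass("VirionFeatures",
  representation(matrix = "matrix", blocks = "character",
                 labels = "factor", spec = "EncodingSpec"))

setValidity("VirionFeatures", function(object) {
  msg <- character()
  m <- object@matrix
  if (!is.numeric(m)) msg <- c(msg, "matrix must be numeric")
  if (is.null(colnames(m))) msg <- c(msg, "matrix must have column names")
  if (anyDuplicated(colnames(m))) msg <- c(msg, "feature names must be unique")
  if (length(object@blocks) != ncol(m))
    msg <- c(msg, "blocks must have one entry per column")
  if (!all(object@blocks %in% c("AAC", "CKSAAP", "DPC", "DDE")))
    msg <- c(msg, "blocks must be AAC/CKSAAP/DPC/DDE")
  if (length(object@labels) && length(object@labels) != nrow(m))
    msg <- c(msg, "labels must be empty or one per row")
  if (length(m) && !all(is.finite(m)))
    msg <- c(msg, "matrix must be finite (no NA/NaN/Inf)")
  if (length(msg)) msg else TRUE
})

#' A trained virion-protein classifier
#'
#' Bundle of a fitted classifier, its configuration, and the exact feature
#' columns it was trained on. Prediction refuses matrices whose columns
#' differ from \code{featureNames} (no silent reordering).
#'
#' @slot kind One of \code{"rf"}, \code{"ld"}, \code{"svm"}, \code{"dt"}.
#' @slot fit The underlying fitted object (opaque).
#' @slot featureNames Column names the model expects, in order.
#' @slot config Named list of hyperparameters and the training seed.
#' @slot version Serialization format version.
#'
#' @seealso [trainClassifier()], [predictScores()], [writeVirionModel()]
#' @export
setClass("VirionModel",
  representation(kind = "character", fit = "ANY", featureNames = "character",
                 config = "list", version = "character"),
  prototype(version = "1"))

setValidity("VirionModel", function(object) {
  msg <- character()
  if (!object@kind %in% c("rf", "ld", "svm", "dt"))
    msg <- c(msg, "kind must be one of rf, ld, svm, dt")
  if (anyDuplicated(object@featureNames))
    msg <- c(msg, "featureNames must be unique")
  if (length(msg)) msg else TRUE
})

#' Cross-validation evaluation result
#'
#' Out-of-fold predictions from stratified k-fold cross-validation, pooled
#' into one confusion table from which the five headline metrics
#' (Sn, Sp, Acc, MCC, F1) are computed once, plus per-fold metrics and the
#' pooled ROC curve.
#'
#' @slot classifier Classifier kind (\code{"rf"}, \code{"ld"}, \code{"svm"},
#'   \code{"dt"}).
#' @slot encoding Short label of the encoding used (e.g. \code{"aac"},
#'   \code{"combined"}).
#' @slot counts Named numeric vector \code{c(tp, fp, tn, fn)} pooled over
#'   all test folds.
#' @slot metrics Named list with \code{sn}, \code{sp}, \code{acc},
#'   \code{f1}, \code{mcc}, \code{mccDegenerate}.
#' @slot perFold Data frame of the same metrics computed per fold.
#' @slot roc Data frame with columns \code{fpr}, \code{tpr} from the pooled
#'   out-of-fold scores.
#' @slot auc Trapezoidal area under the pooled ROC curve.
#' @slot scores Pooled out-of-fold scores, one per sample, dataset order.
#' @slot folds Integer fold assignment, one per sample.
#' @slot config Named list recording all seeds and hyperparameters
#'   (the run log).
#'
#' @seealso [crossValidate()], [evaluationReport()]
#' @export
setClass("VirionEvaluation",
  representation(classifier = "character", encoding = "character",
                 counts = "numeric", metrics = "list",
                 perFold = "data.frame", roc = "data.frame",
                 auc = "numeric", scores = "numeric", folds = "integer",
                 config = "list"))
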
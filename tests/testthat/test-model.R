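test_that("training on separable composition clusters is perfect in-sample", {
  ds <- toyBenchmark(20)
  f <- encodeFeatures(ds, encodingSpec(useCKSAAP = FALSE, useDPC = FALSE,
                                       useDDE = FALSE))
  for (kind in c("rf", "ld", "svm", "dt")) {
    model <- trainClassifier(f, kind = kind, nTrees = 100, seed = 2)
    sc <- predictScores(model, f)
    expect_true(all(sc >= 0 & sc <= 1))
    acc <- mean((sc > 0.5) == (classLabels(ds) == "positive"))
    expect_gte(acc, 0.95)
  }
})

test_that("training is reproducible run-to-run under a fixed seed", {
  ds <- toyBenchmark(15)
  f <- encodeFeatures(ds, encodingSpec(useCKSAAP = FALSE, useDDE = FALSE))
  held <- encodeFeatures(toyBenchmark(10, seed = 99),
                         encodingSpec(useCKSAAP = FALSE, useDDE = FALSE))
  m1 <- trainClassifier(f, kind = "rf", nTrees = 150, seed = 7)
  m2 <- trainClassifier(f, kind = "rf", nTrees = 150, seed = 7)
  expect_identical(predictScores(m1, held), predictScores(m2, held))
})

test_that("degenerate training inputs are rejected", {
  m <- matrix(runif(40), 10, 4, dimnames = list(NULL, paste0("AAC.", 1:4)))
  expect_error(trainClassifier(m, rep("positive", 10), kind = "rf"),
               "each class")
  m2 <- m; m2[1, 1] <- NA
  expect_error(trainClassifier(m2, rep(c("positive", "negative"), 5),
                               kind = "rf"), "NA")
})

test_that("prediction enforces exact feature-column identity", {
  ds <- toyBenchmark(10)
  spec <- encodingSpec(useCKSAAP = FALSE, useDPC = FALSE, useDDE = FALSE)
  f <- encodeFeatures(ds, spec)
  model <- trainClassifier(f, kind = "rf", nTrees = 50, seed = 1)
  m <- featureMatrix(f)
  perm <- m[, rev(colnames(m))]
  expect_error(predictScores(model, perm), "do not match")
  expect_error(predictScores(model, m[, -1]), "do not match")
  # row permutation permutes scores correspondingly (row independence)
  sc <- predictScores(model, m)
  expect_equal(predictScores(model, m[c(3, 1, 2), ]), sc[c(3, 1, 2)],
               ignore_attr = TRUE)
  # single-row matrix gives a single score
  expect_length(predictScores(model, m[1, , drop = FALSE]), 1L)
})

test_that("model persistence round-trips and refuses foreign bundles", {
  ds <- toyBenchmark(10)
  f <- encodeFeatures(ds, encodingSpec(useCKSAAP = FALSE, useDPC = FALSE,
                                       useDDE = FALSE))
  model <- trainClassifier(f, kind = "rf", nTrees = 50, seed = 3)
  p <- tempfile(fileext = ".rds")
  writeVirionModel(model, p)
  back <- readVirionModel(p)
  expect_equal(back@featureNames, model@featureNames)
  expect_identical(predictScores(back, f), predictScores(model, f))
  saveRDS(list(format = "something-else"), p)
  expect_error(readVirionModel(p), "version mismatch|not a recognized")
})

test_that("stratified folds partition the data and balance classes", {
  ds <- generateVirionSet(33, c(20, 40), "none", 0, seed = 6)
  ev <- crossValidate(ds, "aac", classifier = "dt", folds = 5, seed = 2)
  folds <- ev@folds
  expect_length(folds, 66L)
  expect_setequal(unique(folds), 1:5)
  y <- classLabels(ds)
  for (k in 1:5) {
    tab <- table(y[folds == k])
    # per-fold class ratio within one sample of the global 50/50
    expect_lte(abs(tab[["positive"]] - tab[["negative"]]), 1L)
  }
})

test_that("leave-one-out tests every sample exactly once", {
  ds <- generateVirionSet(5, c(20, 30), "composition", 1, seed = 8)
  ev <- crossValidate(ds, "aac", classifier = "rf", folds = 10,
                      stratified = FALSE, seed = 3, nTrees = 50)
  expect_equal(sort(tabulate(ev@folds, 10)), rep(1L, 10))
  expect_true(all(is.finite(ev@scores)))
})

test_that("cross-validation output is bit-stable for fixed seeds", {
  ds <- toyBenchmark(12)
  ev1 <- crossValidate(ds, "aac", classifier = "rf", folds = 3, seed = 5,
                       nTrees = 80)
  ev2 <- crossValidate(ds, "aac", classifier = "rf", folds = 3, seed = 5,
                       nTrees = 80)
  expect_identical(ev1@scores, ev2@scores)
  expect_identical(ev1@folds, ev2@folds)
  expect_identical(ev1@metrics, ev2@metrics)
})

test_that("cross-validation rejects classes smaller than the fold count", {
  ds <- generateVirionSet(3, c(20, 30), "none", 0, seed = 1)
  expect_error(crossValidate(ds, "aac", folds = 5), "fewer samples")
})

test_that("pooled metrics come from one pooled confusion table", {
  ds <- toyBenchmark(15)
  ev <- crossValidate(ds, "aac", classifier = "rf", folds = 5, seed = 9,
                      nTrees = 80)
  expect_equal(sum(ev@counts), 30)
  expect_equal(ev@metrics, computeMetrics(ev@counts))
  expect_equal(ev@auc, rocAUC(ev@roc))
  # run log captures the protocol
  expect_equal(ev@config$folds, 5L)
  expect_length(ev@config$foldSeeds, 5L)
})

test_that("evaluation report has one row per classifier/encoding pair", {
  ds <- toyBenchmark(12)
  rep <- evaluationReport(ds, classifiers = c("rf", "dt"),
                          encodings = c("aac", "dpc"), folds = 3,
                          seed = 2, nTrees = 60)
  expect_equal(nrow(rep$table), 4L)
  expect_setequal(rep$table$classifier, c("rf", "dt"))
  expect_true(all(is.finite(as.matrix(rep$table[, 3:8]))))
})
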
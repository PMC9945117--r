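test_that("AAC counts residues by hand-checkable fractions", {
  v <- encodeAAC("AAAA")[1, ]
  expect_equal(unname(v["AAC.A"]), 1)
  expect_equal(sum(v), 1)
  v2 <- encodeAAC("ACCD")[1, ]
  expect_equal(unname(v2[c("AAC.A", "AAC.C", "AAC.D")]), c(0.25, 0.5, 0.25))
  expect_equal(sum(v2 != 0), 3L)
  expect_error(encodeAAC(""), "empty sequence")
})

test_that("DPC counts adjacent pairs over length - 1", {
  v <- encodeDPC("ACAC")[1, ]
  expect_equal(unname(v[c("DPC.AC", "DPC.CA")]), c(2 / 3, 1 / 3))
  expect_equal(sum(v), 1)
  v2 <- encodeDPC("AA")[1, ]
  expect_equal(unname(v2["DPC.AA"]), 1)
  expect_error(encodeDPC("A"), "length >= 2")
})

test_that("CKSAAP counts gapped pairs per sub-block", {
  v <- encodeCKSAAP("AAAA", maxGap = 0)[1, ]
  expect_length(v, 400L)
  expect_equal(unname(v["CKSAAP.AA.gap0"]), 1)
  v2 <- encodeCKSAAP("ACDE", maxGap = 2)[1, ]
  expect_length(v2, 1200L)
  gap2 <- v2[endsWith(names(v2), ".gap2")]
  expect_equal(unname(gap2["CKSAAP.AE.gap2"]), 1)
  expect_equal(sum(gap2 != 0), 1L)
  expect_error(encodeCKSAAP("ACD", maxGap = 2), "length >= 4")
})

test_that("DDE matches closed-form arithmetic on a single dipeptide", {
  tm <- (4 / 61) * (2 / 61)              # codons(A)/61 * codons(C)/61
  tv <- tm * (1 - tm) / 1                # N = 1 dipeptide
  expect_equal(encodeDDE("AC")[1, "DDE.AC"], (1 - tm) / sqrt(tv))
  expect_equal(encodeDDE("AC", sqrtVariance = FALSE)[1, "DDE.AC"],
               (1 - tm) / tv)
})

test_that("absent dipeptides always score strictly negative in DDE", {
  v <- encodeDDE("ACACACAC")[1, ]
  absent <- setdiff(names(v), c("DDE.AC", "DDE.CA"))
  expect_true(all(v[absent] < 0))
})

test_that("all four encoders match brute-force oracles on random sequences", {
  set.seed(101)
  lens <- sample(5:500, 100, replace = TRUE)
  for (len in lens) {
    s <- randomSequence(len)
    expect_equal(unname(encodeAAC(s)[1, ]), oracleAAC(s))
    expect_equal(unname(encodeDPC(s)[1, ]), oracleDPC(s))
    expect_equal(unname(encodeCKSAAP(s, 3)[1, ]), oracleCKSAAP(s, 3))
    expect_equal(unname(encodeDDE(s)[1, ]), oracleDDE(s))
  }
  # literal-variance variant, spot-checked on a subset
  for (len in lens[1:10]) {
    s <- randomSequence(len)
    expect_equal(unname(encodeDDE(s, sqrtVariance = FALSE)[1, ]),
                 oracleDDE(s, sqrtVariance = FALSE))
  }
})

test_that("AAC/DPC and every CKSAAP gap block are unit-normalized", {
  set.seed(7)
  for (i in 1:25) {
    s <- randomSequence(sample(6:300, 1))
    expect_equal(sum(encodeAAC(s)), 1, tolerance = 1e-9)
    expect_equal(sum(encodeDPC(s)), 1, tolerance = 1e-9)
    ck <- encodeCKSAAP(s, 3)[1, ]
    for (k in 0:3)
      expect_equal(sum(ck[endsWith(names(ck), paste0(".gap", k))]), 1,
                   tolerance = 1e-9)
  }
})

test_that("AAC is permutation-invariant; pair encoders are not", {
  set.seed(13)
  s <- randomSequence(120)
  sh <- paste(sample(strsplit(s, "")[[1]]), collapse = "")
  expect_equal(encodeAAC(s)[1, ], encodeAAC(sh)[1, ])
  expect_false(isTRUE(all.equal(encodeDPC(s)[1, ], encodeDPC(sh)[1, ])))
  expect_false(isTRUE(all.equal(encodeCKSAAP(s, 3)[1, ],
                                encodeCKSAAP(sh, 3)[1, ])))
  expect_false(isTRUE(all.equal(encodeDDE(s)[1, ], encodeDDE(sh)[1, ])))
})

test_that("DDE entries average to zero under the codon-background null", {
  # residues i.i.d. proportional to codon multiplicities => E[Dc] = Tm,
  # so every DDE entry has expectation 0
  ds <- generateVirionSet(150, c(250, 350), "none", 0, seed = 5,
                          background = "codon")
  m <- encodeDDE(ds)
  mu <- colMeans(m)
  expect_lt(max(abs(mu)), 0.25)
  expect_lt(abs(mean(mu)), 0.05)
})

test_that("DDE theoretical variance is strictly positive for any pair", {
  tm <- as.vector(outer(CODONS / 61, CODONS / 61))
  expect_true(all(tm > 0 & tm < 1))  # hence Tv = Tm(1-Tm)/N > 0 for N >= 1
})

test_that("combined vector concatenates blocks in fixed order with 2420 dims", {
  set.seed(3)
  s <- randomSequence(50)
  v <- encodeCombined(s)
  expect_equal(ncol(v), 2420L)
  expect_false(anyDuplicated(colnames(v)) > 0)
  blocks <- sub("\\..*$", "", colnames(v))
  expect_equal(rle(blocks)$values, c("AAC", "CKSAAP", "DPC", "DDE"))
  expect_equal(rle(blocks)$lengths, c(20L, 1600L, 400L, 400L))
  # each named block equals the standalone encoder
  expect_equal(v[, blocks == "AAC"], encodeAAC(s)[1, ])
  expect_equal(v[, blocks == "CKSAAP"], encodeCKSAAP(s, 3)[1, ])
  expect_equal(v[, blocks == "DPC"], encodeDPC(s)[1, ])
  expect_equal(v[, blocks == "DDE"], encodeDDE(s)[1, ])
  # single-block spec is the identity on that encoder
  aacOnly <- encodeCombined(s, encodingSpec(useCKSAAP = FALSE,
                                            useDPC = FALSE, useDDE = FALSE))
  expect_equal(aacOnly, encodeAAC(s))
})

test_that("dataset encoding preserves order, shape, and determinism", {
  ds <- toyBenchmark(5)
  aac <- encodingSpec(useCKSAAP = FALSE, useDPC = FALSE, useDDE = FALSE)
  f <- encodeFeatures(ds, aac)
  expect_equal(dim(f), c(10L, 20L))
  expect_equal(rownames(featureMatrix(f)), names(sequences(ds)))
  expect_true(all(is.finite(featureMatrix(f))))
  # identical records give identical rows
  dup <- virionSet(c(a = "ACDEFGHIKL", b = "ACDEFGHIKL"),
                   c("positive", "negative"))
  fd <- encodeFeatures(dup)
  expect_equal(featureMatrix(fd)[1, ], featureMatrix(fd)[2, ])
  # a too-short record aborts with its id
  short <- virionSet(c(ok = "ACDEFGHIKL", tiny = "ACD"),
                     c("positive", "negative"))
  expect_error(encodeFeatures(short), "tiny")
})

test_that("encoding spec validity enforces its invariants", {
  expect_error(encodingSpec(useAAC = FALSE, useCKSAAP = FALSE,
                            useDPC = FALSE, useDDE = FALSE),
               "at least one")
  expect_error(encodingSpec(cksaapMaxGap = -1), "cksaapMaxGap")
})
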
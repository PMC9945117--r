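# Independent brute-force oracles, deliberately written as plain loops
# over characters/index pairs so they share no code with the package's
# vectorized encoders.

ALPHA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
PAIRS <- as.vector(t(outer(ALPHA, ALPHA, paste0)))  # AA, AC, ..., YY
CODONS <- c(A = 4, C = 2, D = 2, E = 2, F = 2, G = 4, H = 2, I = 3, K = 2,
            L = 6, M = 1, N = 2, P = 4, Q = 2, R = 6, S = 6, T = 4, V = 4,
            W = 1, Y = 2)

oracleAAC <- function(s) {
  ch <- strsplit(s, "")[[1]]
  v <- sapply(ALPHA, function(a) sum(ch == a)) / length(ch)
  unname(v)
}

oracleDPC <- function(s) {
  ch <- strsplit(s, "")[[1]]
  n <- length(ch)
  counts <- setNames(numeric(400), PAIRS)
  for (i in seq_len(n - 1))
    counts[paste0(ch[i], ch[i + 1])] <- counts[paste0(ch[i], ch[i + 1])] + 1
  unname(counts / (n - 1))
}

# all (i, i + k + 1) index pairs for one gap k
oracleCKSAAPgap <- function(s, k) {
  ch <- strsplit(s, "")[[1]]
  n <- length(ch)
  counts <- setNames(numeric(400), PAIRS)
  for (i in seq_len(n)) {
    j <- i + k + 1
    if (j <= n)
      counts[paste0(ch[i], ch[j])] <- counts[paste0(ch[i], ch[j])] + 1
  }
  unname(counts / (n - k - 1))
}

oracleCKSAAP <- function(s, maxGap)
  unlist(lapply(0:maxGap, function(k) oracleCKSAAPgap(s, k)))

oracleDDE <- function(s, sqrtVariance = TRUE) {
  ch <- strsplit(s, "")[[1]]
  n <- length(ch)
  N <- n - 1
  out <- numeric(400)
  for (p in seq_along(PAIRS)) {
    a <- substr(PAIRS[p], 1, 1); b <- substr(PAIRS[p], 2, 2)
    ni <- 0
    for (i in seq_len(N))
      if (ch[i] == a && ch[i + 1] == b) ni <- ni + 1
    dc <- ni / N
    tm <- (CODONS[[a]] / 61) * (CODONS[[b]] / 61)
    tv <- tm * (1 - tm) / N
    out[p] <- if (sqrtVariance) (dc - tm) / sqrt(tv) else (dc - tm) / tv
  }
  out
}

# direct-arithmetic metric oracle from the printed formulas
oracleMetrics <- function(tp, fp, tn, fn) {
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  list(sn = tp / (tp + fn),
       sp = tn / (tn + fp),
       acc = (tp + tn) / (tp + tn + fp + fn),
       f1 = 2 * tp / (2 * tp + fn + fp),
       mcc = if (den == 0) 0 else (tp * tn - fp * fn) / sqrt(den))
}

# AUC as the fraction of positive-negative pairs correctly ordered,
# ties counted 1/2
oracleConcordanceAUC <- function(scores, labels) {
  sp <- scores[labels == "positive"]
  sn <- scores[labels == "negative"]
  tot <- 0
  for (a in sp) for (b in sn)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

randomSequence <- function(len) paste(sample(ALPHA, len, replace = TRUE),
                                      collapse = "")

writeFastaFile <- function(lines, path = tempfile(fileext = ".fasta")) {
  writeLines(lines, path)
  path
}

# tiny separable benchmark used by several model tests
toyBenchmark <- function(nPerClass = 20, seed = 11) {
  generateVirionSet(nPerClass, c(30, 60), "composition", effectSize = 0.9,
                    seed = seed)
}
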
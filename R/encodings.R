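# The four composition descriptors. Each encoder takes a VirionSet,
# AAStringSet, or character vector and returns a samples x features
# numeric matrix with stable column names:
#   AAC.<a>   CKSAAP.<ab>.gap<k>   DPC.<ab>   DDE.<ab>
# Residue and pair order is strict alphabetical, first position major.

#' Amino acid composition (AAC)
#'
#' Frequency of each of the 20 standard residues: entry i is
#' count(residue i) / length. Entries sum to 1 for every non-empty
#' sequence, and the descriptor is invariant under any permutation of the
#' residues.
#'
#' @param x A \linkS4class{VirionSet}, \code{AAStringSet}, or character
#'   vector of sequences over the 20-letter alphabet.
#' @return Numeric matrix, one row per sequence, 20 columns
#'   \code{AAC.A} ... \code{AAC.Y}.
#' @examples
#' encodeAAC("ACCD")   # A 0.25, C 0.50, D 0.25
#' @export
encodeAAC <- function(x) {
  chars <- asSequenceCharacters(x)
  out <- t(vapply(chars, function(s) {
    idx <- residueIndex(s)
    if (length(idx) < 1L) stop("empty sequence")
    tabulate(idx, 20L) / length(idx)
  }, numeric(20L)))
  dimnames(out) <- list(names(chars), paste0("AAC.", AA_ALPHABET20))
  out
}

#' Dipeptide composition (DPC)
#'
#' Frequency of each of the 400 ordered adjacent residue pairs: the entry
#' for pair ab is (number of positions i with residue a at i and b at i+1)
#' divided by (length - 1). Entries sum to 1 for every sequence of
#' length >= 2.
#'
#' @inheritParams encodeAAC
#' @return Numeric matrix, one row per sequence, 400 columns
#'   \code{DPC.AA} ... \code{DPC.YY} (first residue major).
#' @examples
#' v <- encodeDPC("ACAC")  # AC = 2/3, CA = 1/3
#' v[, c("DPC.AC", "DPC.CA")]
#' @export
encodeDPC <- function(x) {
  chars <- asSequenceCharacters(x)
  out <- t(vapply(chars, function(s) {
    idx <- residueIndex(s)
    n <- length(idx)
    if (n < 2L) stop("DPC requires sequence length >= 2")
    pair <- (idx[-n] - 1L) * 20L + idx[-1L]
    tabulate(pair, 400L) / (n - 1L)
  }, numeric(400L)))
  dimnames(out) <- list(names(chars), paste0("DPC.", dipeptideNames()))
  out
}

#' Composition of k-spaced amino acid pairs (CKSAAP)
#'
#' For each gap k in 0..\code{maxGap}, the 400-vector of frequencies of
#' ordered residue pairs separated by exactly k intervening residues: the
#' gap-k entry for pair ab is the number of index pairs (i, i + k + 1)
#' carrying a then b, divided by the number of such index pairs,
#' length - k - 1. Gap 0 recovers adjacent pairs (DPC counts). Sub-blocks
#' are concatenated in ascending k, so the default \code{maxGap = 3} gives
#' 4 x 400 = 1600 features, and each gap sub-block sums to 1.
#'
#' @inheritParams encodeAAC
#' @param maxGap Largest gap (>= 0); sequences must have
#'   length >= maxGap + 2.
#' @return Numeric matrix, one row per sequence,
#'   \code{400 * (maxGap + 1)} columns \code{CKSAAP.AA.gap0} ...
#'   \code{CKSAAP.YY.gap<maxGap>}.
#' @examples
#' v <- encodeCKSAAP("ACDE", maxGap = 2)
#' v[, "CKSAAP.AE.gap2"]   # the single gap-2 pair A..E
#' @export
encodeCKSAAP <- function(x, maxGap = 3L) {
  maxGap <- as.integer(maxGap)
  stopifnot(length(maxGap) == 1L, maxGap >= 0L)
  chars <- asSequenceCharacters(x)
  p <- 400L * (maxGap + 1L)
  out <- t(vapply(chars, function(s) {
    idx <- residueIndex(s)
    n <- length(idx)
    if (n < maxGap + 2L)
      stop("CKSAAP with maxGap ", maxGap, " requires sequence length >= ",
           maxGap + 2L)
    unlist(lapply(0L:maxGap, function(k) {
      nPairs <- n - k - 1L
      pair <- (idx[seq_len(nPairs)] - 1L) * 20L + idx[seq_len(nPairs) + k + 1L]
      tabulate(pair, 400L) / nPairs
    }), use.names = FALSE)
  }, numeric(p)))
  cn <- unlist(lapply(0L:maxGap, function(k)
    paste0("CKSAAP.", dipeptideNames(), ".gap", k)), use.names = FALSE)
  dimnames(out) <- list(names(chars), cn)
  out
}

#' Dipeptide deviation from expected mean (DDE)
#'
#' Standardizes each observed dipeptide frequency against a theoretical
#' mean and variance derived from genetic-code codon multiplicities.
#' With N = length - 1 dipeptides and, for pair i = ab,
#' \deqn{Dc(i) = n_i / N}
#' \deqn{Tm(i) = (codons(a)/61) (codons(b)/61)}
#' \deqn{Tv(i) = Tm(i)(1 - Tm(i)) / N}
#' the feature is \code{(Dc - Tm)/sqrt(Tv)} (default), or the unscaled
#' \code{(Dc - Tm)/Tv} when \code{sqrtVariance = FALSE}. Entries are
#' unbounded in sign; a dipeptide absent from the sequence always scores
#' strictly negative. Tv is always positive for finite sequences
#' (0 < Tm < 1, N >= 1).
#'
#' @inheritParams encodeAAC
#' @param sqrtVariance Standardize by the standard deviation (default) or
#'   by the variance itself.
#' @return Numeric matrix, one row per sequence, 400 columns
#'   \code{DDE.AA} ... \code{DDE.YY}.
#' @examples
#' encodeDDE("AC")[, "DDE.AC"]  # (1 - Tm)/sqrt(Tm(1 - Tm)), Tm = (4/61)(2/61)
#' @export
encodeDDE <- function(x, sqrtVariance = TRUE) {
  chars <- asSequenceCharacters(x)
  codonFreq <- CODON_COUNTS / 61
  tm <- rep(codonFreq, each = 20L) * rep(codonFreq, 20L)
  out <- t(vapply(chars, function(s) {
    idx <- residueIndex(s)
    n <- length(idx)
    if (n < 2L) stop("DDE requires sequence length >= 2")
    N <- n - 1L
    dc <- tabulate((idx[-n] - 1L) * 20L + idx[-1L], 400L) / N
    tv <- tm * (1 - tm) / N
    if (sqrtVariance) (dc - tm) / sqrt(tv) else (dc - tm) / tv
  }, numeric(400L)))
  dimnames(out) <- list(names(chars), paste0("DDE.", dipeptideNames()))
  out
}

#' Construct an EncodingSpec
#'
#' @param useAAC,useCKSAAP,useDPC,useDDE Enable the corresponding block.
#' @param cksaapMaxGap Largest CKSAAP gap (default 3, giving 1600 CKSAAP
#'   features).
#' @param ddeSqrtVariance Standardize DDE by sqrt(Tv) (default) or Tv.
#' @return An \linkS4class{EncodingSpec}.
#' @export
encodingSpec <- function(useAAC = TRUE, useCKSAAP = TRUE, useDPC = TRUE,
                         useDDE = TRUE, cksaapMaxGap = 3L,
                         ddeSqrtVariance = TRUE) {
  new("EncodingSpec", useAAC = useAAC, useCKSAAP = useCKSAAP,
      useDPC = useDPC, useDDE = useDDE,
      cksaapMaxGap = as.integer(cksaapMaxGap),
      ddeSqrtVariance = ddeSqrtVariance)
}

# spec for a single named block, or "combined"/"all" for all four
specForEncoding <- function(encoding, cksaapMaxGap = 3L) {
  encoding <- match.arg(tolower(encoding),
                        c("aac", "cksaap", "dpc", "dde", "combined", "all"))
  if (encoding %in% c("combined", "all"))
    return(encodingSpec(cksaapMaxGap = cksaapMaxGap))
  encodingSpec(useAAC = encoding == "aac", useCKSAAP = encoding == "cksaap",
               useDPC = encoding == "dpc", useDDE = encoding == "dde",
               cksaapMaxGap = cksaapMaxGap)
}

#' Combined feature encoding of one or more sequences
#'
#' Concatenates the enabled blocks in the fixed order
#' AAC, CKSAAP, DPC, DDE. With all four enabled and the default
#' \code{cksaapMaxGap = 3}, the combined vector has
#' 20 + 1600 + 400 + 400 = 2420 dimensions.
#'
#' @inheritParams encodeAAC
#' @param spec An \linkS4class{EncodingSpec}.
#' @return Numeric matrix, one row per sequence, with globally unique
#'   column names.
#' @examples
#' ncol(encodeCombined(paste(rep("ACDEFGHIKL", 5), collapse = "")))  # 2420
#' @export
encodeCombined <- function(x, spec = encodingSpec()) {
  stopifnot(is(spec, "EncodingSpec"))
  validObject(spec)
  chars <- asSequenceCharacters(x)
  parts <- list()
  if (spec@useAAC) parts$AAC <- encodeAAC(chars)
  if (spec@useCKSAAP) parts$CKSAAP <- encodeCKSAAP(chars, spec@cksaapMaxGap)
  if (spec@useDPC) parts$DPC <- encodeDPC(chars)
  if (spec@useDDE) parts$DDE <- encodeDDE(chars, spec@ddeSqrtVariance)
  do.call(cbind, unname(parts))
}

#' Encode a labeled dataset into a feature matrix
#'
#' Applies [encodeCombined()] to every record of a
#' \linkS4class{VirionSet}; row order matches the set, column order is
#' fixed by the spec. A record violating a length precondition (e.g. a
#' 3-mer with \code{cksaapMaxGap = 3}) aborts with the record id.
#'
#' @param data A \linkS4class{VirionSet} (or unlabeled sequences).
#' @param spec An \linkS4class{EncodingSpec}.
#' @return A \linkS4class{VirionFeatures}.
#' @export
encodeFeatures <- function(data, spec = encodingSpec()) {
  stopifnot(is(spec, "EncodingSpec"))
  validObject(spec)
  chars <- asSequenceCharacters(data)
  m <- tryCatch(encodeCombined(chars, spec), error = function(e) e)
  if (inherits(m, "error")) {
    # re-run record by record so the error names the offender
    for (id in names(chars)) {
      bad <- tryCatch({encodeCombined(chars[id], spec); NULL},
                      error = function(e) conditionMessage(e))
      if (!is.null(bad)) stop("record '", id, "': ", bad)
    }
    stop(conditionMessage(m))
  }
  blocks <- sub("\\..*$", "", colnames(m))
  labels <- if (is(data, "VirionSet")) classLabels(data)
            else factor(character(), levels = c("negative", "positive"))
  new("VirionFeatures", matrix = m, blocks = blocks, labels = labels,
      spec = spec)
}
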
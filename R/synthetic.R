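# Synthetic two-class benchmark generator. Emulates the shape of a
# balanced virion / non-virion benchmark (500 sequences per class) with
# controllable class signal, so every pipeline stage is testable without
# external data. It does not attempt to mimic real phage protein
# statistics (domain architecture, signal peptides).

# residues whose enrichment defines the positive class in composition mode
SIGNATURE_RESIDUES <- c("A", "G", "T", "V")

#' Generate a labeled two-class synthetic sequence set
#'
#' Draws residues i.i.d. per position from a background distribution
#' (uniform over the 20 residues by default, or proportional to
#' genetic-code codon counts with \code{background = "codon"}) and plants
#' a class signal in the positive class:
#' \describe{
#'   \item{\code{"none"}}{both classes identical — the null benchmark.}
#'   \item{\code{"composition"}}{positive-class residue distribution is
#'     the mixture \code{(1 - effectSize) * background + effectSize *
#'     signature}, where the signature distribution is uniform over the
#'     residues A, G, T, V; at \code{effectSize = 1} positives contain
#'     only signature residues. The signal lives chiefly in the AAC
#'     block.}
#'   \item{\code{"dipeptide_motif"}}{each positive sequence independently
#'     receives the 3-mer "WWH" spliced in at a random position with
#'     probability \code{effectSize}; W and H are rare, so the signal
#'     lives in the dipeptide/k-spaced pair blocks rather than AAC.}
#'   \item{\code{"mixed"}}{both of the above.}
#' }
#' \code{effectSize = 0} always makes the two classes identically
#' distributed. Output is fully reproducible given \code{seed}.
#'
#' @param nPerClass Sequences per class (default 500, the shape of a
#'   balanced virion benchmark).
#' @param lengthRange Integer (min, max), each >= 5; lengths are drawn
#'   uniformly. Default 50--400, a typical span for phage structural
#'   proteins.
#' @param signalMode One of \code{"none"}, \code{"composition"},
#'   \code{"dipeptide_motif"}, \code{"mixed"}.
#' @param effectSize Signal strength in [0, 1].
#' @param seed Integer seed.
#' @param background \code{"uniform"} (default; keeps DDE entries
#'   non-degenerate in both signs) or \code{"codon"} (codon-multiplicity
#'   weighted, the DDE null).
#' @return A \linkS4class{VirionSet} with ids \code{pos_1..n} then
#'   \code{neg_1..n}, positives first.
#' @examples
#' generateVirionSet(5, c(30, 60), "composition", 0.8, seed = 1)
#' @export
generateVirionSet <- function(nPerClass = 500L, lengthRange = c(50L, 400L),
                              signalMode = c("none", "composition",
                                             "dipeptide_motif", "mixed"),
                              effectSize = 0.5, seed = 1L,
                              background = c("uniform", "codon")) {
  signalMode <- match.arg(signalMode)
  background <- match.arg(background)
  nPerClass <- as.integer(nPerClass)
  stopifnot(nPerClass >= 1L, effectSize >= 0, effectSize <= 1)
  lengthRange <- as.integer(lengthRange)
  if (length(lengthRange) != 2L || any(lengthRange < 5L) ||
      lengthRange[1L] > lengthRange[2L])
    stop("lengthRange must be (min, max) with 5 <= min <= max")
  bg <- if (background == "uniform") rep(1 / 20, 20L)
        else as.numeric(CODON_COUNTS) / 61
  names(bg) <- AA_ALPHABET20
  sig <- bg
  if (signalMode %in% c("composition", "mixed")) {
    signature <- stats::setNames(rep(0, 20L), AA_ALPHABET20)
    signature[SIGNATURE_RESIDUES] <- 1 / length(SIGNATURE_RESIDUES)
    sig <- (1 - effectSize) * bg + effectSize * signature
  }
  motif <- signalMode %in% c("dipeptide_motif", "mixed")
  set.seed(as.integer(seed))
  drawClass <- function(prob, n, planted) {
    len <- sample(lengthRange[1L]:lengthRange[2L], n, replace = TRUE)
    vapply(seq_len(n), function(i) {
      s <- sample(AA_ALPHABET20, len[i], replace = TRUE, prob = prob)
      if (planted && stats::runif(1) < effectSize) {
        at <- sample.int(len[i] + 1L, 1L) - 1L  # insertion point 0..len
        s <- append(s, c("W", "W", "H"), after = at)
      }
      paste(s, collapse = "")
    }, "")
  }
  pos <- drawClass(sig, nPerClass, planted = motif)
  neg <- drawClass(bg, nPerClass, planted = FALSE)
  names(pos) <- paste0("pos_", seq_len(nPerClass))
  names(neg) <- paste0("neg_", seq_len(nPerClass))
  virionSet(c(pos, neg),
            rep(c("positive", "negative"), each = nPerClass),
            provenance = sprintf(
              "synthetic(mode=%s, effect=%g, n=%d/class, len=%d-%d, bg=%s, seed=%d)",
              signalMode, effectSize, nPerClass, lengthRange[1L],
              lengthRange[2L], background, as.integer(seed)))
}

#' Write a two-file FASTA benchmark
#'
#' Writes \code{positives.fasta} and \code{negatives.fasta} into a
#' directory, the layout [loadLabeledSet()] reads back with an exact
#' id/sequence round-trip.
#'
#' @param dataset A \linkS4class{VirionSet} with both classes non-empty.
#' @param dir Output directory (created if needed).
#' @return Named character vector with the two file paths, invisibly.
#' @export
writeBenchmark <- function(dataset, dir) {
  stopifnot(is(dataset, "VirionSet"))
  y <- classLabels(dataset)
  if (!all(c("positive", "negative") %in% y))
    stop("dataset must contain both classes")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(positives = file.path(dir, "positives.fasta"),
             negatives = file.path(dir, "negatives.fasta"))
  writeProteinFasta(sequences(dataset)[y == "positive"], paths[["positives"]])
  writeProteinFasta(sequences(dataset)[y == "negative"], paths[["negatives"]])
  invisible(paths)
}
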
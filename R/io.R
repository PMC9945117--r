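#' Read and validate a protein FASTA file
#'
#' Reads a multi-record FASTA file (wrapped or unwrapped lines), normalizes
#' lowercase residues to uppercase, and enforces the 20-letter standard
#' alphabet. Under \code{policy = "reject"} any sequence carrying a
#' non-standard residue (B, J, O, U, X, Z, gaps, ...) raises an error that
#' names the offending record; under \code{policy = "strip"} those
#' characters are removed with a warning stating how many were dropped.
#'
#' @param path Path to a FASTA file.
#' @param policy Either \code{"reject"} (default) or \code{"strip"}.
#' @return An \link[Biostrings]{AAStringSet}, one entry per record, named
#'   by the first whitespace-delimited header token.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1 capsid", "ACDE", ">p2", "ggwwh"), fa)
#' readProteinFasta(fa)
#' @export
readProteinFasta <- function(path, policy = c("reject", "strip")) {
  policy <- match.arg(policy)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0L) stop("empty FASTA file: ", path)
  names(seqs) <- vapply(strsplit(names(seqs), "\\s+"), `[`, "", 1L)
  chars <- toupper(as.character(seqs))
  pat <- paste0("[^", paste(AA_ALPHABET20, collapse = ""), "]")
  nBad <- vapply(gregexpr(pat, chars),
                 function(g) if (g[1L] == -1L) 0L else length(g), 0L)
  if (policy == "reject") {
    if (any(nBad > 0L))
      stop("non-standard residues in record(s): ",
           paste(utils::head(names(seqs)[nBad > 0L], 10L), collapse = ", "),
           " (use policy = 'strip' to remove them)")
  } else if (any(nBad > 0L)) {
    chars <- gsub(pat, "", chars)
    warning(sum(nBad), " non-standard residue(s) stripped from ",
            sum(nBad > 0L), " record(s)")
  }
  if (any(nchar(chars) == 0L))
    stop("sequence empty after validation in record(s): ",
         paste(names(seqs)[nchar(chars) == 0L], collapse = ", "))
  Biostrings::AAStringSet(stats::setNames(chars, names(seqs)))
}

#' Construct a VirionSet
#'
#' @param sequences An \code{AAStringSet} or named character vector of
#'   validated sequences.
#' @param labels Character or factor of \code{"positive"} /
#'   \code{"negative"}, one per sequence.
#' @param provenance Free-text origin of the set.
#' @return A \linkS4class{VirionSet}.
#' @export
virionSet <- function(sequences, labels, provenance = NA_character_) {
  if (is.character(sequences)) sequences <- Biostrings::AAStringSet(sequences)
  labels <- factor(as.character(labels), levels = c("negative", "positive"))
  new("VirionSet", sequences = sequences, labels = labels,
      provenance = as.character(provenance))
}

#' Load a two-file labeled benchmark
#'
#' Reads one FASTA file per class and assembles a \linkS4class{VirionSet}
#' with positives (virion proteins) first, mirroring the usual layout of
#' two-class virion benchmarks. Duplicate record ids across the two files
#' are permitted (labels, not ids, carry class identity) but warned about.
#'
#' @param posPath FASTA of the positive class (virion proteins).
#' @param negPath FASTA of the negative class (non-virion proteins).
#' @param policy Residue policy passed to [readProteinFasta()].
#' @return A \linkS4class{VirionSet}.
#' @export
loadLabeledSet <- function(posPath, negPath, policy = c("reject", "strip")) {
  policy <- match.arg(policy)
  pos <- readProteinFasta(posPath, policy)
  neg <- readProteinFasta(negPath, policy)
  if (length(pos) == 0L || length(neg) == 0L) stop("empty class")
  if (any(names(pos) %in% names(neg)))
    warning("duplicate record ids across the two classes")
  virionSet(c(pos, neg),
            rep(c("positive", "negative"), c(length(pos), length(neg))),
            provenance = paste0(posPath, " + ", negPath))
}

#' Write sequences to FASTA
#'
#' @param x A \linkS4class{VirionSet} or \code{AAStringSet}.
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
writeProteinFasta <- function(x, path) {
  if (is(x, "VirionSet")) x <- sequences(x)
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}

#' Write a feature matrix to CSV
#'
#' One row per sequence: a leading \code{id} column, a \code{label} column
#' (empty string when the features are unlabeled), then one column per
#' feature named by the feature-name grammar (\code{AAC.A},
#' \code{CKSAAP.AC.gap0}, \code{DPC.AC}, \code{DDE.AC}, ...).
#'
#' @param features A \linkS4class{VirionFeatures}.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeFeatureCSV <- function(features, path) {
  stopifnot(is(features, "VirionFeatures"))
  m <- featureMatrix(features)
  lab <- if (length(features@labels)) as.character(features@labels)
         else rep("", nrow(m))
  df <- data.frame(id = rownames(m), label = lab, m,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
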
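# Residue validation helpers shared by I/O and the VirionSet validity method.

# ids (or indices) of sequences containing a character outside the
# 20-letter alphabet; input already uppercased
invalidResidueIds <- function(seqs) {
  chars <- as.character(seqs)
  bad <- grepl(paste0("[^", paste(AA_ALPHABET20, collapse = ""), "]"), chars)
  if (!any(bad)) return(character())
  ids <- names(seqs)
  if (is.null(ids)) ids <- as.character(seq_along(seqs))
  ids[bad]
}

# integer encoding 1..20 of a residue string; stops on invalid residues
residueIndex <- function(sequence) {
  idx <- match(strsplit(sequence, "", fixed = TRUE)[[1]], AA_ALPHABET20)
  if (anyNA(idx)) stop("sequence contains non-standard residues")
  idx
}

asSequenceCharacters <- function(x) {
  if (is(x, "VirionSet")) x <- sequences(x)
  if (is(x, "AAStringSet")) {
    chars <- as.character(x)
    if (is.null(names(chars))) names(chars) <- paste0("seq", seq_along(chars))
    return(chars)
  }
  if (is.character(x)) {
    if (is.null(names(x))) names(x) <- paste0("seq", seq_along(x))
    return(x)
  }
  stop("expected a VirionSet, AAStringSet, or character vector of sequences")
}

# deterministic child seed for the i-th stochastic sub-task, kept < 2^31
childSeed <- function(seed, i) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(i) * 104729) %% 2147483587)
}
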
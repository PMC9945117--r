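#' @rdname VirionSet-class
#' @param x,object A \linkS4class{VirionSet} (or, where documented, a
#'   \linkS4class{VirionFeatures}).
#' @export
setGeneric("sequences", function(x) standardGeneric("sequences"))

#' @rdname VirionSet-class
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))

#' @rdname VirionFeatures-class
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))

#' @rdname VirionFeatures-class
#' @export
setGeneric("featureBlocks", function(x) standardGeneric("featureBlocks"))

#' Accessors for VirionSet
#'
#' @describeIn VirionSet-class the underlying \code{AAStringSet}.
#' @export
setMethod("sequences", "VirionSet", function(x) x@sequences)

#' @describeIn VirionSet-class the label factor
#'   (levels \code{negative}, \code{positive}).
#' @export
setMethod("classLabels", "VirionSet", function(x) x@labels)

#' @describeIn VirionSet-class number of sequences.
#' @export
setMethod("length", "VirionSet", function(x) length(x@sequences))

#' @describeIn VirionSet-class subset records (and labels) by index.
#' @param i Index vector.
#' @param j,...,drop Ignored.
#' @export
setMethod("[", "VirionSet", function(x, i, j, ..., drop = FALSE) {
  new("VirionSet", sequences = x@sequences[i],
      labels = droplevels0(x@labels[i]), provenance = x@provenance)
})

# subsetting must keep both levels even if one class vanishes
droplevels0 <- function(f) factor(f, levels = c("negative", "positive"))

setMethod("show", "VirionSet", function(object) {
  tab <- table(object@labels)
  cat("VirionSet with", length(object), "sequences (",
      tab[["positive"]], "positive /", tab[["negative"]], "negative )\n")
  w <- Biostrings::width(object@sequences)
  if (length(w))
    cat("  lengths:", min(w), "-", max(w),
        " median", stats::median(w), "\n")
  if (!is.na(object@provenance))
    cat("  provenance:", object@provenance, "\n")
})

#' @describeIn VirionFeatures-class the samples x features numeric matrix.
#' @export
setMethod("featureMatrix", "VirionFeatures", function(x) x@matrix)

#' @describeIn VirionFeatures-class the encoding block of each column.
#' @export
setMethod("featureBlocks", "VirionFeatures", function(x) x@blocks)

#' @describeIn VirionFeatures-class the label factor (may be empty).
#' @export
setMethod("classLabels", "VirionFeatures", function(x) x@labels)

#' @describeIn VirionFeatures-class samples x features dimensions.
#' @export
setMethod("dim", "VirionFeatures", function(x) dim(x@matrix))

setMethod("show", "VirionFeatures", function(object) {
  cat("VirionFeatures:", nrow(object@matrix), "samples x",
      ncol(object@matrix), "features\n")
  cat("  blocks:", paste(sprintf("%s(%d)", names(table(object@blocks)),
                                 table(object@blocks)), collapse = " "), "\n")
  if (length(object@labels))
    cat("  labels:", sum(object@labels == "positive"), "positive /",
        sum(object@labels == "negative"), "negative\n")
})

setMethod("show", "VirionModel", function(object) {
  cat("VirionModel <", object@kind, "> on", length(object@featureNames),
      "features\n")
  cfg <- object@config
  if (length(cfg))
    cat("  config:", paste(names(cfg), unlist(lapply(cfg, format)),
                           sep = "=", collapse = " "), "\n")
})

setMethod("show", "VirionEvaluation", function(object) {
  m <- object@metrics
  cat(sprintf("VirionEvaluation [%s | %s] pooled over %d folds\n",
              object@classifier, object@encoding,
              length(unique(object@folds))))
  cat(sprintf("  Sp %.2f%%  Sn %.2f%%  Acc %.2f%%  MCC %.4f  F1 %.4f  AUC %.4f\n",
              100 * m$sp, 100 * m$sn, 100 * m$acc, m$mcc, m$f1, object@auc))
})
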
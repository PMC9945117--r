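#' Confusion counts from hard predictions
#'
#' @param truth,predicted Factors or characters over
#'   \code{"positive"} / \code{"negative"}; virion proteins are the
#'   positive class.
#' @return Named numeric vector \code{c(tp, fp, tn, fn)}.
#' @export
confusionCounts <- function(truth, predicted) {
  truth <- as.character(truth); predicted <- as.character(predicted)
  stopifnot(length(truth) == length(predicted),
            all(truth %in% c("positive", "negative")),
            all(predicted %in% c("positive", "negative")))
  c(tp = sum(truth == "positive" & predicted == "positive"),
    fp = sum(truth == "negative" & predicted == "positive"),
    tn = sum(truth == "negative" & predicted == "negative"),
    fn = sum(truth == "positive" & predicted == "negative"))
}

#' The five binary-classification metrics
#'
#' Computes sensitivity, specificity, accuracy, F1 and the Matthews
#' correlation coefficient from a confusion table:
#' \deqn{Sn = TP/(TP+FN), \quad Sp = TN/(TN+FP)}
#' \deqn{Acc = (TP+TN)/(TP+TN+FP+FN), \quad F1 = 2TP/(2TP+FN+FP)}
#' \deqn{MCC = (TP \cdot TN - FP \cdot FN) /
#'   \sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}
#' When any MCC denominator factor is zero (e.g. a degenerate classifier
#' that never predicts positive), MCC is defined as 0 by the standard
#' convention and \code{mccDegenerate} is set. Both classes must be
#' present in the truth (tp + fn >= 1 and tn + fp >= 1).
#'
#' @param counts Named vector with \code{tp}, \code{fp}, \code{tn},
#'   \code{fn} (as from [confusionCounts()]); alternatively pass the four
#'   counts via the named arguments.
#' @param tp,fp,tn,fn Individual counts, used when \code{counts} is
#'   missing.
#' @return Named list \code{sn}, \code{sp}, \code{acc}, \code{f1},
#'   \code{mcc}, \code{mccDegenerate}.
#' @examples
#' computeMetrics(tp = 45, fn = 5, tn = 47, fp = 3)
#' @export
computeMetrics <- function(counts, tp, fp, tn, fn) {
  if (!missing(counts)) {
    tp <- counts[["tp"]]; fp <- counts[["fp"]]
    tn <- counts[["tn"]]; fn <- counts[["fn"]]
  }
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  if (tp + fn < 1 || tn + fp < 1)
    stop("both classes must be present (tp + fn >= 1 and tn + fp >= 1)")
  f1 <- if (2 * tp + fn + fp == 0) 0 else 2 * tp / (2 * tp + fn + fp)
  den <- c(tp + fp, tp + fn, tn + fp, tn + fn)
  degenerate <- any(den == 0)
  mcc <- if (degenerate) 0
         else (tp * tn - fp * fn) / sqrt(prod(den))
  list(sn = tp / (tp + fn), sp = tn / (tn + fp),
       acc = (tp + tn) / (tp + tn + fp + fn), f1 = f1, mcc = mcc,
       mccDegenerate = degenerate)
}

#' ROC curve points from scores
#'
#' Sweeps the decision threshold over the distinct score values (higher
#' score = more positive), emitting one (FPR, TPR) point per threshold;
#' tied scores are grouped, so identical scores for all samples give just
#' the two endpoints (0,0) and (1,1). The curve is monotone non-decreasing
#' in both coordinates.
#'
#' @param scores Finite numeric scores.
#' @param labels \code{"positive"} / \code{"negative"} per score; both
#'   classes must be present.
#' @return Data frame with columns \code{fpr}, \code{tpr}, starting at
#'   (0,0) and ending at (1,1).
#' @seealso [rocAUC()]
#' @export
rocPoints <- function(scores, labels) {
  labels <- as.character(labels)
  stopifnot(length(scores) == length(labels), all(is.finite(scores)),
            all(labels %in% c("positive", "negative")))
  P <- sum(labels == "positive"); N <- sum(labels == "negative")
  if (P == 0L || N == 0L) stop("both classes must be present")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; pos <- labels[o] == "positive"
  # index of the last element of each tie group, descending score order
  grp <- which(!duplicated(s, fromLast = TRUE))
  tpr <- c(0, cumsum(pos)[grp] / P)
  fpr <- c(0, cumsum(!pos)[grp] / N)
  data.frame(fpr = fpr, tpr = tpr)
}

#' Trapezoidal area under an ROC curve
#'
#' @param roc Data frame from [rocPoints()], or a numeric score vector (in
#'   which case \code{labels} must be given and the curve is computed
#'   first).
#' @param labels Optional labels when \code{roc} is a score vector.
#' @return The AUC in [0, 1]; equals the probability that a random
#'   positive outscores a random negative, ties counted 1/2.
#' @export
rocAUC <- function(roc, labels = NULL) {
  if (is.numeric(roc) && !is.null(labels)) roc <- rocPoints(roc, labels)
  sum(diff(roc$fpr) * (utils::head(roc$tpr, -1L) + utils::tail(roc$tpr, -1L)) / 2)
}

#' Tabular evaluation report
#'
#' Flattens a list of \linkS4class{VirionEvaluation} objects into one row
#' per (classifier, encoding), with percentages for Sp/Sn/Acc and raw
#' MCC/F1/AUC — the layout of a per-feature performance table.
#'
#' @param evaluations A list of \linkS4class{VirionEvaluation} objects (a
#'   single one is accepted).
#' @return Data frame with columns \code{classifier}, \code{encoding},
#'   \code{sp_pct}, \code{sn_pct}, \code{acc_pct}, \code{mcc}, \code{f1},
#'   \code{auc}.
#' @export
metricsTable <- function(evaluations) {
  if (is(evaluations, "VirionEvaluation")) evaluations <- list(evaluations)
  do.call(rbind, lapply(evaluations, function(ev) {
    m <- ev@metrics
    data.frame(classifier = ev@classifier, encoding = ev@encoding,
               sp_pct = 100 * m$sp, sn_pct = 100 * m$sn,
               acc_pct = 100 * m$acc, mcc = m$mcc, f1 = m$f1, auc = ev@auc,
               stringsAsFactors = FALSE)
  }))
}
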
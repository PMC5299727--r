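# Selection-performance scoring.

#' Confusion counts of a selection against the truth
#'
#' @param selected,truth 0/1 matrices (or vectors) of the same shape.
#' @return named list with `TP`, `FP`, `TN`, `FN`, `N` (total indicators).
#' @export
confusionCounts <- function(selected, truth) {
  if (!identical(dim(selected), dim(truth)) ||
      length(selected) != length(truth))
    stop("'selected' and 'truth' must have the same shape")
  s <- as.integer(selected != 0)
  t <- as.integer(truth != 0)
  list(TP = sum(s == 1 & t == 1), FP = sum(s == 1 & t == 0),
       TN = sum(s == 0 & t == 0), FN = sum(s == 0 & t == 1),
       N = length(s))
}

#' Accuracy, error rates and Matthews correlation
#'
#' `accScore` is (TP + TN) / N over all indicators; `fprScore` is
#' FP / (FP + TN); `fnrScore` is FN / (FN + TP). `mccScore` uses the
#' normalized form MCC = (TP/N - S * Pr) / sqrt(Pr S (1 - S)(1 - Pr)) with
#' Pr = (TP + FP)/N the selected fraction and S = (TP + FN)/N the true
#' positive fraction — algebraically identical to the classic
#' (TP TN - FP FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)) wherever both are
#' defined, and set to 0 by convention when Pr or S is 0 or 1 (degenerate
#' denominator).
#'
#' @param counts list from [confusionCounts()].
#' @return a single number.
#' @name selection-scores
NULL

#' @rdname selection-scores
#' @export
accScore <- function(counts) (counts$TP + counts$TN) / counts$N

#' @rdname selection-scores
#' @export
fprScore <- function(counts) {
  d <- counts$FP + counts$TN
  if (d == 0) return(0)
  counts$FP / d
}

#' @rdname selection-scores
#' @export
fnrScore <- function(counts) {
  d <- counts$FN + counts$TP
  if (d == 0) return(0)
  counts$FN / d
}

#' @rdname selection-scores
#' @export
mccScore <- function(counts) {
  N <- counts$N
  Pr <- (counts$TP + counts$FP) / N
  S <- (counts$TP + counts$FN) / N
  if (Pr <= 0 || Pr >= 1 || S <= 0 || S >= 1)
    return(structure(0, degenerate = TRUE))
  (counts$TP / N - S * Pr) / sqrt(Pr * S * (1 - S) * (1 - Pr))
}

#' Collapse an indicator matrix to the taxon level
#'
#' A taxon is a taxa-wise positive if any of its covariate associations is
#' flagged.
#'
#' @param mat P x J 0/1 matrix (covariates x taxa).
#' @return length-J 0/1 vector.
#' @export
taxaWise <- function(mat) as.integer(colSums(as.matrix(mat) != 0) > 0)

#' ROC curve and AUC from PPI scores
#'
#' Sweeps the selection threshold over the sorted unique scores (ties enter
#' or leave the selection together), records (FPR, TPR) at each threshold,
#' and integrates by the trapezoid rule. The AUC is invariant under
#' strictly increasing transforms of the scores.
#'
#' @param ppi numeric matrix or vector of scores.
#' @param truth 0/1 matrix or vector of the same shape.
#' @return list with `curve` (data.frame `threshold`, `fpr`, `tpr`) and
#'   `auc`.
#' @export
rocAuc <- function(ppi, truth) {
  if (length(ppi) != length(truth))
    stop("'ppi' and 'truth' must have the same shape")
  t <- as.integer(as.numeric(truth) != 0)
  s <- as.numeric(ppi)
  nP <- sum(t == 1); nN <- sum(t == 0)
  if (nP == 0 || nN == 0)
    stop("AUC undefined: truth contains a single class")
  thr <- c(Inf, sort(unique(s), decreasing = TRUE))
  tpr <- vapply(thr, function(cc) sum(s >= cc & t == 1) / nP, numeric(1))
  fpr <- vapply(thr, function(cc) sum(s >= cc & t == 0) / nN, numeric(1))
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  list(curve = data.frame(threshold = thr, fpr = fpr, tpr = tpr), auc = auc)
}

#' Score a selection against a simulation truth
#'
#' Convenience wrapper producing the metrics table for one replicate at
#' both granularities.
#'
#' @param selected P x J 0/1 selection matrix.
#' @param truth P x J 0/1 truth matrix (e.g. `xiTrue` of a
#'   [DMSimTruth-class]).
#' @param ppi optional P x J PPI matrix; when given, overall AUC is added.
#' @return data.frame with rows `overall` and `taxa`.
#' @export
scoreSelection <- function(selected, truth, ppi = NULL) {
  ov <- confusionCounts(selected, truth)
  tw <- confusionCounts(taxaWise(selected), taxaWise(truth))
  auc <- if (is.null(ppi)) NA_real_ else rocAuc(ppi, truth)$auc
  data.frame(
    granularity = c("overall", "taxa"),
    ACC = c(accScore(ov), accScore(tw)),
    FPR = c(fprScore(ov), fprScore(tw)),
    FNR = c(fnrScore(ov), fnrScore(tw)),
    MCC = c(as.numeric(mccScore(ov)), as.numeric(mccScore(tw))),
    AUC = c(auc, NA_real_))
}
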
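# Evaluation suite: confusion counts, threshold metrics, ROC/PR areas,
# a stratified cross-validation harness and per-patient cumulative effect
# risk.

#' Confusion counts at a score threshold
#'
#' Positive class is `driver`; a score strictly above `threshold` predicts
#' driver.
#'
#' @param scores numeric scores in `[0,1]`.
#' @param labels vector with values `driver` / `passenger` (or 1/0 logical
#'   or numeric, where 1 = driver).
#' @param threshold decision threshold (default 0.5, strict).
#' @return list with `TP`, `FP`, `TN`, `FN`.
#' @export
confusion <- function(scores, labels, threshold = 0.5) {
  y <- as_binary_labels(labels)
  if (length(scores) != length(y)) stop("scores and labels differ in length")
  pred <- scores > threshold
  list(TP = sum(pred & y == 1), FP = sum(pred & y == 0),
       TN = sum(!pred & y == 0), FN = sum(!pred & y == 1))
}

as_binary_labels <- function(labels) {
  if (is.character(labels) || is.factor(labels)) {
    l <- as.character(labels)
    if (!all(l %in% c("driver", "passenger")))
      stop("labels must be 'driver'/'passenger' or binary")
    as.integer(l == "driver")
  } else as.integer(labels != 0)
}

safe_div <- function(num, den) if (den == 0) c(0, TRUE) else c(num / den, FALSE)

#' Threshold metrics from confusion counts
#'
#' Precision, sensitivity, specificity, balanced accuracy, F1, accuracy
#' and the Matthews correlation coefficient. Any metric whose denominator
#' is zero is reported as 0 and flagged in `degenerate`.
#'
#' @param counts list with `TP`, `FP`, `TN`, `FN` (see [confusion()]).
#' @return list of metrics plus `n` and a character vector `degenerate`.
#' @export
metrics <- function(counts) {
  TP <- counts$TP; FP <- counts$FP; TN <- counts$TN; FN <- counts$FN
  n <- TP + FP + TN + FN
  deg <- character(0)
  pre <- safe_div(TP, TP + FP); if (pre[2]) deg <- c(deg, "PRE")
  sen <- safe_div(TP, TP + FN); if (sen[2]) deg <- c(deg, "SEN")
  spe <- safe_div(TN, TN + FP); if (spe[2]) deg <- c(deg, "SPE")
  f1 <- safe_div(2 * TP, 2 * TP + FP + FN); if (f1[2]) deg <- c(deg, "F1")
  acc <- safe_div(TP + TN, n); if (acc[2]) deg <- c(deg, "ACC")
  mcc_den <- sqrt(as.numeric(TP + FN) * (TP + FP) * (TN + FP) * (TN + FN))
  mcc <- if (mcc_den == 0) {deg <- c(deg, "MCC"); 0} else
    (as.numeric(TP) * TN - as.numeric(FP) * FN) / mcc_den
  list(PRE = pre[1], SEN = sen[1], SPE = spe[1],
       BACC = (sen[1] + spe[1]) / 2, F1 = f1[1], ACC = acc[1], MCC = mcc,
       n = n, degenerate = deg)
}

#' Area under the ROC curve (rank statistic)
#'
#' Mann-Whitney formulation with average ranks for tied scores.
#'
#' @param scores numeric scores.
#' @param labels see [confusion()].
#' @return AUC in `[0,1]`; `NA` if a class is absent.
#' @export
roc_auc <- function(scores, labels) {
  y <- as_binary_labels(labels)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve (step integration)
#'
#' Precision-recall points are taken at every distinct score threshold
#' (descending); the area is the step integral
#' `sum (R_i - R_{i-1}) * P_i`.
#'
#' @inheritParams roc_auc
#' @return AUPR in `[0,1]`; `NA` if there is no positive.
#' @export
pr_auc <- function(scores, labels) {
  y <- as_binary_labels(labels)
  P <- sum(y == 1)
  if (P == 0) return(NA_real_)
  o <- order(scores, decreasing = TRUE)
  ys <- y[o]; ss <- scores[o]
  tp <- cumsum(ys); fp <- cumsum(1 - ys)
  last <- c(ss[-1] != ss[-length(ss)], TRUE)  # end of each tie block
  tp <- tp[last]; fp <- fp[last]
  prec <- tp / (tp + fp)
  rec <- tp / P
  sum(diff(c(0, rec)) * prec)
}

#' ROC and PR curve points
#'
#' @inheritParams roc_auc
#' @return list of two data.frames: `roc` (fpr, tpr) and `pr`
#'   (recall, precision), one point per distinct threshold.
#' @export
curve_points <- function(scores, labels) {
  y <- as_binary_labels(labels)
  o <- order(scores, decreasing = TRUE)
  ys <- y[o]; ss <- scores[o]
  tp <- cumsum(ys); fp <- cumsum(1 - ys)
  last <- c(ss[-1] != ss[-length(ss)], TRUE)
  tp <- tp[last]; fp <- fp[last]
  P <- sum(y == 1); N <- sum(y == 0)
  list(roc = data.frame(fpr = c(0, fp / max(N, 1)), tpr = c(0, tp / max(P, 1))),
       pr = data.frame(recall = tp / max(P, 1), precision = tp / (tp + fp)))
}

#' Full evaluation report for scored variants
#'
#' @inheritParams confusion
#' @return list with threshold metrics, `AUC`, `AUPR`, `threshold`, `n`.
#' @export
evaluation_report <- function(scores, labels, threshold = 0.5) {
  m <- metrics(confusion(scores, labels, threshold))
  m$AUC <- roc_auc(scores, labels)
  m$AUPR <- pr_auc(scores, labels)
  m$threshold <- threshold
  m
}

#' Stratified cross-validation of a fit/predict pipeline
#'
#' @param x feature matrix (plain numeric matrix).
#' @param y labels (see [confusion()]).
#' @param fit function `(x, y, seed) -> model`.
#' @param predict_fun function `(model, x) -> scores`.
#' @param folds number of folds (default 10).
#' @param seed seed for fold assignment and per-fold fits.
#' @param threshold decision threshold for fold metrics.
#' @return list with `oof` (out-of-fold scores), `fold` assignment,
#'   `per_fold` reports, `pooled` report over all out-of-fold scores, and
#'   `mean` (mean of per-fold AUC/ACC).
#' @export
cross_validate <- function(x, y, fit, predict_fun, folds = 10, seed = 1,
                           threshold = 0.5) {
  yb <- as_binary_labels(y)
  fold <- stratified_folds(yb, folds, seed)
  oof <- numeric(length(yb))
  per_fold <- vector("list", folds)
  for (k in seq_len(folds)) {
    tr <- fold != k
    model <- fit(x[tr, , drop = FALSE], yb[tr], child_seed(seed, paste0("fold", k)))
    oof[!tr] <- predict_fun(model, x[!tr, , drop = FALSE])
    per_fold[[k]] <- evaluation_report(oof[!tr], yb[!tr], threshold)
  }
  pooled <- evaluation_report(oof, yb, threshold)
  list(oof = oof, fold = fold, per_fold = per_fold, pooled = pooled,
       mean = list(AUC = mean(vapply(per_fold, `[[`, 0, "AUC")),
                   ACC = mean(vapply(per_fold, `[[`, 0, "ACC"))))
}

#' Per-patient cumulative effect risk
#'
#' CER is the per-patient sum of scores of variants predicted as drivers
#' (score strictly above `driver_threshold`); with `mode = "all"` every
#' variant's score is summed regardless of threshold.
#'
#' @param patient character/factor vector of patient ids, one per variant.
#' @param scores numeric scores aligned with `patient`.
#' @param driver_threshold threshold above which a variant contributes
#'   (default 0.5).
#' @param mode `"predicted"` (default) or `"all"`.
#' @return data.frame with `patient`, `CER`, `n_contributing`.
#' @export
cumulative_effect_risk <- function(patient, scores, driver_threshold = 0.5,
                                   mode = c("predicted", "all")) {
  mode <- match.arg(mode)
  if (length(patient) != length(scores)) stop("patient and scores differ in length")
  keep <- if (mode == "predicted") scores > driver_threshold else
    rep(TRUE, length(scores))
  ids <- unique(as.character(patient))
  cer <- vapply(ids, function(p) sum(scores[keep & patient == p]), 0)
  cnt <- vapply(ids, function(p) sum(keep & patient == p), 0L)
  data.frame(patient = ids, CER = unname(cer), n_contributing = unname(cnt),
             stringsAsFactors = FALSE)
}
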
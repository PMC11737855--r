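# End-to-end training pipeline: normalize -> screen groups -> rank ->
# forward subset search -> stacked ensemble.

#' Train the full stacked pipeline on a raw feature matrix
#'
#' Fits the min-max normalizer on the given (training) rows, screens the
#' feature groups at `screen_threshold`, ranks the surviving columns with
#' the four importance measures, picks each base learner's best
#' (ranking, prefix) subset by cross-validated forward search, and fits
#' the out-of-fold stacking ensemble with the chosen meta classifier.
#'
#' If no group passes the screen (e.g. label-shuffled data), the pipeline
#' declines feature selection: with no group showing discriminative power
#' there is no evidence base for AUC-driven subset optimization, and
#' running it anyway would let the search latch onto chance correlations
#' and report inflated cross-validated performance. Instead every base
#' learner is stacked on the full feature set (a fixed, non-adaptive
#' choice, so the reported CV AUC stays an honest null estimate) and a
#' warning is issued.
#'
#' @param fm a raw `feature_matrix` of training rows.
#' @param labels binary labels (driver/passenger or 1/0).
#' @param screen_threshold group screen threshold (default 0.60).
#' @param cv folds used throughout (default 10).
#' @param seed root seed; all stage seeds derive from it.
#' @param learners base learner ids (default all five).
#' @param meta meta classifier id (default `"lr"`).
#' @param ks optional SFS prefix grid override.
#' @return list of class `ssnv_pipeline` with the fitted `model`
#'   (`stacked_model`), `screen`, `selection`, `normalizer` and
#'   `cv_report` (pooled stack CV metrics).
#' @export
train_pipeline <- function(fm, labels, screen_threshold = 0.60, cv = 10,
                           seed = 1, learners = base_learner_ids(),
                           meta = "lr", ks = NULL) {
  y <- as_binary_labels(labels)
  log_msg("normalizing ", nrow(fm$x), " x ", ncol(fm$x))
  norm <- fit_normalizer(fm)
  fmn <- apply_normalizer(norm, fm)
  log_msg("screening ", nrow(fm_groups(fmn)), " feature groups")
  screen <- screen_groups(fmn, y, learners = learners,
                          threshold = screen_threshold, cv = cv,
                          seed = child_seed(seed, "screen"))
  retained <- screen$retained
  if (length(retained) == 0) {
    warning("no feature group passed the ", screen_threshold, " screen; ",
            "skipping subset optimization (no evidence to select on) and ",
            "stacking all learners on the full feature set")
    selection <- NULL
    subsets <- stats::setNames(
      rep(list(seq_len(ncol(fmn$x))), length(learners)), learners)
  } else {
    retained_cols <- which(fmn$info$group %in% retained)
    xr <- fmn$x[, retained_cols, drop = FALSE]
    log_msg(length(retained), " group(s) retained (", ncol(xr),
            " columns); ranking and forward search")
    selection <- select_per_learner(xr, y, learners = learners, cv = cv,
                                    seed = child_seed(seed, "select"), ks = ks)
    subsets <- lapply(selection$winners, function(w) retained_cols[w$subset])
  }
  log_msg("fitting stacked ensemble (meta = ", meta, ")")
  model <- fit_stack(fmn$x, y, subsets, meta = meta, cv = cv,
                     seed = child_seed(seed, "stack"),
                     normalizer = norm, feature_info = fmn$info)
  structure(list(model = model, screen = screen, selection = selection,
                 normalizer = norm, retained_groups = retained,
                 cv_report = model$cv_report, seed = seed, cv = cv),
            class = "ssnv_pipeline")
}

#' @export
print.ssnv_pipeline <- function(x, ...) {
  cat("ssnv_pipeline:", length(x$retained_groups), "retained group(s);",
      "stack CV AUC", round(x$cv_report$AUC, 3), "\n")
  invisible(x)
}

#' Selection report as a serializable list
#'
#' Per-group screen scores, per-learner chosen ranking/subset and SFS
#' trajectories, plus a reproducibility block.
#'
#' @param pipeline an `ssnv_pipeline`.
#' @return a list suitable for `jsonlite::write_json`.
#' @export
selection_report <- function(pipeline) {
  sel <- pipeline$selection
  list(
    screen = list(threshold = pipeline$screen$threshold,
                  aggregate = pipeline$screen$aggregate,
                  scores = pipeline$screen$scores,
                  retained = pipeline$retained_groups),
    winners = if (is.null(sel)) NULL else lapply(sel$winners, function(w)
      list(method = w$method, chosen_k = w$chosen_k, auc = w$auc,
           subset = w$subset)),
    trajectories = if (is.null(sel)) NULL else
      lapply(sel$searches, function(per_method)
        lapply(per_method, function(s) s$trajectory)),
    stack_cv = pipeline$cv_report[c("AUC", "AUPR", "ACC", "MCC")],
    reproducibility = list(seed = pipeline$seed, cv = pipeline$cv)
  )
}
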
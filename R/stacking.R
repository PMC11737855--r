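# Out-of-fold probability stacking: five base learners on their selected
# feature subsets, a logistic-regression meta-classifier on the 5-column
# OOF matrix, alternative combination strategies (majority voting, simple
# averaging, Bayesian model averaging) and the 9-candidate super-ensemble.

#' Out-of-fold probabilities of one learner
#'
#' Stratified `cv`-fold split: each row's probability comes from the fold
#' model whose training set excludes that row. The returned vector carries
#' the fold assignment (`attr "fold"`) and each fold model's training
#' index set (`attr "train_index"`) so the anti-leakage structure can be
#' audited.
#'
#' @param learner a base learner id.
#' @param subset column indices of the learner's selected features.
#' @param x numeric feature matrix.
#' @param labels binary labels.
#' @param cv number of folds (default 10).
#' @param seed integer seed.
#' @return numeric OOF probability vector with audit attributes.
#' @export
generate_oof_probs <- function(learner, subset, x, labels, cv = 10, seed = 1) {
  y <- as_binary_labels(labels)
  if (length(y) < cv) stop("fewer rows (", length(y), ") than folds (", cv, ")")
  if (any(subset < 1 | subset > ncol(x))) stop("subset indices out of range")
  xs <- x[, subset, drop = FALSE]
  fold <- stratified_folds(y, cv, seed)
  oof <- numeric(length(y))
  train_index <- vector("list", cv)
  for (k in seq_len(cv)) {
    tr <- which(fold != k)
    train_index[[k]] <- tr
    fit <- fit_learner(learner, xs[tr, , drop = FALSE], y[tr],
                       seed = child_seed(seed, paste0("oof", k)))
    oof[fold == k] <- predict_learner(fit, xs[fold == k, , drop = FALSE])
  }
  attr(oof, "fold") <- fold
  attr(oof, "train_index") <- train_index
  oof
}

#' Fit the stacked ensemble
#'
#' Generates the 5-dimensional out-of-fold probability features (one column
#' per base learner, each on its selected subset), trains the
#' meta-classifier on them, and refits every base learner on the full
#' training data for inference. The stack's cross-validated performance is
#' the pooled AUC of meta predictions under the same fold structure.
#'
#' @param x numeric training feature matrix (normalized).
#' @param labels binary labels.
#' @param subsets named list (per learner id) of column-index subsets.
#' @param meta meta classifier id (default `"lr"`).
#' @param cv folds for the OOF features (default 10).
#' @param seed integer seed.
#' @param normalizer optional fitted `normalizer` stored for inference.
#' @param feature_info optional column metadata stored for inference.
#' @return a `stacked_model`.
#' @export
fit_stack <- function(x, labels, subsets, meta = "lr", cv = 10, seed = 1,
                      normalizer = NULL, feature_info = NULL) {
  y <- as_binary_labels(labels)
  ids <- names(subsets)
  if (is.null(ids) || any(!nzchar(ids))) stop("subsets must be a named list (learner ids)")
  oof <- sapply(ids, function(id)
    generate_oof_probs(id, subsets[[id]], x, y, cv = cv,
                       seed = child_seed(seed, paste0("stack_", id))))
  colnames(oof) <- ids
  meta_fit <- fit_meta(meta, oof, y, seed = child_seed(seed, "meta"))
  base_fits <- lapply(ids, function(id)
    fit_learner(id, x[, subsets[[id]], drop = FALSE], y,
                seed = child_seed(seed, paste0("refit_", id))))
  names(base_fits) <- ids
  cv_meta <- cross_validate(
    oof, y,
    fit = function(xt, yt, s) fit_meta(meta, xt, yt, seed = s),
    predict_fun = predict_meta,
    folds = cv, seed = child_seed(seed, "stackcv"))
  structure(list(
    learner_ids = ids, subsets = subsets, base_fits = base_fits,
    meta_id = meta, meta_fit = meta_fit, oof = oof, labels = y,
    cv_report = cv_meta$pooled, cv = cv, seed = seed,
    normalizer = normalizer, feature_info = feature_info,
    format_version = 1L), class = "stacked_model")
}

#' Base-model probabilities for new data
#'
#' @param model a `stacked_model`.
#' @param x numeric matrix with the training column layout.
#' @return matrix (rows x learners) of base probabilities.
#' @export
base_probabilities <- function(model, x) {
  sapply(model$learner_ids, function(id)
    predict_learner(model$base_fits[[id]],
                    x[, model$subsets[[id]], drop = FALSE]))
}

#' Predict driver scores from a stacked model
#'
#' @param object a `stacked_model`.
#' @param x numeric matrix (same columns as training) or `feature_matrix`.
#' @param ... unused.
#' @return numeric scores in `[0,1]`.
#' @export
predict.stacked_model <- function(object, x, ...) {
  if (inherits(x, "feature_matrix")) {
    if (!x$normalized && !is.null(object$normalizer))
      x <- apply_normalizer(object$normalizer, x)
    x <- x$x
  }
  bp <- base_probabilities(object, x)
  if (is.null(dim(bp))) bp <- matrix(bp, nrow = 1)
  predict_meta(object$meta_fit, bp)
}

#' @export
print.stacked_model <- function(x, ...) {
  cat("stacked_model:", length(x$learner_ids), "base learners (",
      paste(x$learner_ids, collapse = ", "), ") ->", x$meta_id,
      "meta; CV AUC", round(x$cv_report$AUC, 3), "\n")
  invisible(x)
}

#' Bayesian-model-averaging weights from base performance
#'
#' Weights are proportional to `max(AUC_i - 0.5, eps)` and normalized to
#' sum to one: monotone in cross-validated performance, nonnegative, and
#' degenerating to equal weights (simple averaging) when all AUCs agree.
#'
#' @param aucs numeric vector of base-model CV AUCs.
#' @param eps floor on the shifted AUC (default 1e-6).
#' @return nonnegative weights summing to 1.
#' @export
bma_weights <- function(aucs, eps = 1e-6) {
  w <- pmax(aucs - 0.5, eps)
  w / sum(w)
}

#' Combine base probabilities with a non-stacking strategy
#'
#' * `MV` — majority vote of the five thresholded labels (no ties with an
#'   odd number of voters); returns 0/1 labels.
#' * `SA` — arithmetic mean of the probabilities.
#' * `BMA` — weighted mean with nonnegative weights summing to one
#'   (see [bma_weights()]).
#'
#' @param probs matrix (rows x base models) of probabilities.
#' @param strategy `"MV"`, `"SA"` or `"BMA"`.
#' @param weights BMA weights (required for `"BMA"`).
#' @param threshold vote threshold for `"MV"` (default 0.5).
#' @return numeric vector: scores (`SA`, `BMA`) or 0/1 labels (`MV`).
#' @export
predict_strategy <- function(probs, strategy = c("SA", "MV", "BMA"),
                             weights = NULL, threshold = 0.5) {
  strategy <- match.arg(strategy)
  probs <- as.matrix(probs)
  switch(strategy,
    SA = rowMeans(probs),
    MV = as.numeric(rowMeans(probs > threshold) > 0.5),
    BMA = {
      if (is.null(weights)) stop("BMA requires weights (see bma_weights)")
      if (abs(sum(weights) - 1) > 1e-9 || any(weights < 0))
        stop("BMA weights must be nonnegative and sum to 1")
      as.numeric(probs %*% weights)
    })
}

#' Super-ensemble: choose the best meta classifier
#'
#' Scores each candidate meta classifier by cross-validated AUC on the
#' out-of-fold probability matrix and retains the best (first in
#' `candidates` order on ties).
#'
#' @param oof matrix of base-model OOF probabilities.
#' @param labels binary labels.
#' @param candidates meta learner ids (default all nine).
#' @param cv folds.
#' @param seed integer seed.
#' @return list with `best_id`, `best_fit` (refit on all rows) and
#'   `table` (data.frame candidate, AUC, ACC).
#' @export
fit_super_ensemble <- function(oof, labels, candidates = meta_learner_ids(),
                               cv = 10, seed = 1) {
  y <- as_binary_labels(labels)
  rows <- lapply(candidates, function(id) {
    r <- cross_validate(
      as.matrix(oof), y,
      fit = function(xt, yt, s) fit_meta(id, xt, yt, seed = s),
      predict_fun = predict_meta,
      folds = cv, seed = child_seed(seed, paste0("se_", id)))
    data.frame(candidate = id, AUC = r$pooled$AUC, ACC = r$pooled$ACC,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  best_id <- tab$candidate[which.max(tab$AUC)]
  list(best_id = best_id,
       best_fit = fit_meta(best_id, as.matrix(oof), y,
                           seed = child_seed(seed, "se_refit")),
       table = tab)
}

#' Save a stacked model bundle
#'
#' Writes a directory with a JSON manifest (format version, learner ids,
#' subsets, seeds) and serialized components; [load_stacked_model()]
#' restores a model that predicts identically.
#'
#' @param model a `stacked_model`.
#' @param dir bundle directory (created if needed).
#' @export
save_stacked_model <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(format_version = model$format_version,
                   learner_ids = model$learner_ids,
                   meta_id = model$meta_id,
                   subsets = model$subsets,
                   cv = model$cv, seed = model$seed)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  saveRDS(model, file.path(dir, "model.rds"))
  invisible(dir)
}

#' Load a stacked model bundle
#'
#' @param dir bundle directory written by [save_stacked_model()].
#' @return a `stacked_model`.
#' @export
load_stacked_model <- function(dir) {
  f <- file.path(dir, "model.rds")
  if (!file.exists(f)) stop("not a model bundle (missing model.rds): ", dir)
  model <- readRDS(f)
  if (!inherits(model, "stacked_model")) stop("corrupt model bundle: ", dir)
  model
}
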
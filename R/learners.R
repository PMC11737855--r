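# Base and meta learner backends behind stable learner ids.
#
# The five base learner ids are "cat", "rf", "gbdt", "ada", "xgb". Backends
# are pluggable: "rf" is a probability forest (ranger); "xgb" is
# regularized extreme gradient boosting; "gbdt" is a plain (unregularized,
# shallow-tree, shrinkage 0.1) gradient-boosting configuration; "cat" is a
# stochastic gradient-boosting configuration (row/column subsampling,
# depth 6) standing in for ordered boosting; "ada" is discrete AdaBoost on
# decision stumps (compiled stump search). All fits are deterministic for
# a fixed seed and run single-threaded.

#' Base learner identifiers
#'
#' @return character vector of the five base learner ids.
#' @export
base_learner_ids <- function() c("cat", "rf", "gbdt", "ada", "xgb")

xgb_params <- function(id) {
  switch(id,
    xgb = list(objective = "binary:logistic", nrounds = 40, eta = 0.3,
               max_depth = 3, lambda = 1, tree_method = "hist"),
    gbdt = list(objective = "binary:logistic", nrounds = 50, eta = 0.1,
                max_depth = 3, lambda = 0, alpha = 0, tree_method = "hist"),
    cat = list(objective = "binary:logistic", nrounds = 50, eta = 0.15,
               max_depth = 4, lambda = 3, subsample = 0.8,
               colsample_bytree = 0.5, tree_method = "hist"),
    stop("no boosting config for learner ", id))
}

fit_xgb_config <- function(id, x, y, seed) {
  p <- xgb_params(id)
  nrounds <- p$nrounds
  p$nrounds <- NULL
  p$nthread <- 1
  colnames(x) <- NULL
  d <- xgboost::xgb.DMatrix(x, label = y)
  model <- with_seed(seed,
    xgboost::xgb.train(params = p, data = d, nrounds = nrounds, verbose = 0))
  structure(list(id = id, model = model, p = ncol(x)), class = "base_fit")
}

#' Fit a base learner
#'
#' @param id learner id, one of [base_learner_ids()].
#' @param x numeric feature matrix (rows = samples).
#' @param y binary labels (1 = driver).
#' @param seed integer seed.
#' @param importance for `"rf"`, also compute impurity importance.
#' @return a `base_fit` object.
#' @export
fit_learner <- function(id, x, y, seed = 1, importance = FALSE) {
  y <- as_binary_labels(y)
  if (length(unique(y)) < 2) stop("training labels must contain both classes")
  switch(id,
    rf = {
      model <- ranger::ranger(
        x = as.data.frame(x), y = factor(y, levels = c(0, 1)),
        probability = TRUE, num.trees = 300, seed = seed, num.threads = 1,
        importance = if (importance) "impurity" else "none")
      structure(list(id = id, model = model, p = ncol(x)), class = "base_fit")
    },
    ada = fit_adaboost(x, y, seed = seed),
    cat = , gbdt = , xgb = fit_xgb_config(id, x, y, seed),
    stop("unknown learner id: ", id))
}

#' Predict probabilities from a base learner fit
#'
#' @param fit a `base_fit`.
#' @param x numeric matrix with the same columns as at fit time.
#' @return numeric vector of driver probabilities in `[0,1]`.
#' @export
predict_learner <- function(fit, x) {
  if (ncol(x) != fit$p) stop("column count mismatch: ", ncol(x), " vs ", fit$p)
  switch(fit$id,
    rf = {
      pr <- stats::predict(fit$model, data = as.data.frame(x),
                           num.threads = 1)$predictions
      unname(pr[, "1"])
    },
    ada = predict_adaboost(fit, x),
    cat = , gbdt = , xgb = {
      colnames(x) <- NULL
      unname(stats::predict(fit$model, xgboost::xgb.DMatrix(x)))
    })
}

# ---- discrete AdaBoost on decision stumps -------------------------------

# Candidate features are subsampled (up to max_features per round, seeded)
# to bound the stump search on wide feature groups.
fit_adaboost <- function(x, y, n_rounds = 40, max_features = 100, seed = 1) {
  n <- nrow(x); p <- ncol(x)
  yy <- ifelse(y == 1, 1L, -1L)
  w <- rep(1 / n, n)
  stumps <- vector("list", n_rounds)
  with_seed(seed, {
    for (m in seq_len(n_rounds)) {
      cols <- if (p > max_features) sort(sample.int(p, max_features)) else seq_len(p)
      st <- .best_stump(x[, cols, drop = FALSE], w, yy)
      if (st$col < 1) break  # no valid split anywhere (constant features)
      j <- cols[st$col]
      err <- min(max(st$err, 1e-10), 1 - 1e-10)
      alpha <- 0.5 * log((1 - err) / err)
      h <- st$polarity * ifelse(x[, j] > st$threshold, 1L, -1L)
      w <- w * exp(-alpha * yy * h)
      w <- w / sum(w)
      stumps[[m]] <- list(col = j, threshold = st$threshold,
                          polarity = st$polarity, alpha = alpha)
      if (st$err < 1e-9) break  # perfect stump; further rounds add nothing
    }
  })
  stumps <- Filter(Negate(is.null), stumps)
  structure(list(id = "ada", stumps = stumps, p = p), class = "base_fit")
}

predict_adaboost <- function(fit, x) {
  f <- numeric(nrow(x))
  for (st in fit$stumps) {
    f <- f + st$alpha * st$polarity * ifelse(x[, st$col] > st$threshold, 1, -1)
  }
  1 / (1 + exp(-2 * f))
}

# ---- feature importance --------------------------------------------------

# impurity/gain importance over all columns (unused columns get 0)
learner_importance <- function(id, x, y, seed = 1) {
  y <- as_binary_labels(y)
  p <- ncol(x)
  if (id == "rf") {
    model <- ranger::ranger(
      x = as.data.frame(x), y = factor(y, levels = c(0, 1)),
      probability = TRUE, num.trees = 300, seed = seed, num.threads = 1,
      importance = "impurity")
    imp <- model$variable.importance
    out <- numeric(p)
    out[match(names(imp), colnames(as.data.frame(x)))] <- imp
    return(out)
  }
  fit <- fit_xgb_config(id, x, y, seed)
  tab <- xgboost::xgb.importance(model = fit$model)
  out <- numeric(p)
  if (!is.null(tab) && nrow(tab)) {
    idx <- as.integer(sub("^f", "", tab$Feature)) + 1L
    out[idx] <- tab$Gain
  }
  out
}

# ---- meta learners (super-ensemble candidates) --------------------------

#' Meta learner identifiers
#'
#' The nine candidate meta classifiers for the super-ensemble: logistic
#' regression, support-vector machine, random forest, decision tree,
#' extremely randomized trees, gradient-boosted trees, AdaBoost,
#' k-nearest neighbours and naive Bayes.
#'
#' @return character vector of meta learner ids.
#' @export
meta_learner_ids <- function() c("lr", "svm", "rf", "dt", "ert", "gbdt",
                                 "ada", "knn", "nb")

#' Fit a meta classifier on probability features
#'
#' @param id one of [meta_learner_ids()].
#' @param x numeric matrix of base-model probabilities.
#' @param y binary labels.
#' @param seed integer seed.
#' @return a `meta_fit` object.
#' @export
fit_meta <- function(id, x, y, seed = 1) {
  y <- as_binary_labels(y)
  df <- as.data.frame(x)
  names(df) <- paste0("p", seq_len(ncol(x)))
  fit <- switch(id,
    lr = suppressWarnings(stats::glm(y ~ ., data = cbind(y = y, df),
                                     family = stats::binomial())),
    svm = with_seed(seed, e1071::svm(x, factor(y, levels = c(0, 1)),
                                     probability = TRUE)),
    rf = ranger::ranger(x = df, y = factor(y, levels = c(0, 1)),
                        probability = TRUE, num.trees = 300, seed = seed,
                        num.threads = 1),
    dt = rpart::rpart(y ~ ., data = cbind(y = factor(y), df),
                      method = "class"),
    ert = ranger::ranger(x = df, y = factor(y, levels = c(0, 1)),
                         probability = TRUE, num.trees = 300, seed = seed,
                         num.threads = 1, splitrule = "extratrees",
                         replace = FALSE, sample.fraction = 1),
    gbdt = fit_xgb_config("gbdt", x, y, seed),
    ada = fit_adaboost(x, y, seed = seed),
    knn = list(train = x, cl = factor(y, levels = c(0, 1)), k = 5),
    nb = e1071::naiveBayes(df, factor(y, levels = c(0, 1))),
    stop("unknown meta learner id: ", id))
  structure(list(id = id, fit = fit, p = ncol(x)), class = "meta_fit")
}

#' Predict probabilities from a meta classifier
#'
#' @param meta a `meta_fit`.
#' @param x numeric matrix of base-model probabilities.
#' @return numeric vector of driver probabilities.
#' @export
predict_meta <- function(meta, x) {
  df <- as.data.frame(x)
  names(df) <- paste0("p", seq_len(ncol(x)))
  switch(meta$id,
    lr = unname(stats::predict(meta$fit, newdata = df, type = "response")),
    svm = {
      pr <- attr(stats::predict(meta$fit, x, probability = TRUE),
                 "probabilities")
      unname(pr[, "1"])
    },
    rf = , ert = unname(stats::predict(meta$fit, data = df,
                                       num.threads = 1)$predictions[, "1"]),
    dt = unname(stats::predict(meta$fit, newdata = df)[, "1"]),
    gbdt = predict_learner(meta$fit, x),
    ada = predict_adaboost(meta$fit, x),
    knn = {
      pr <- class::knn(meta$fit$train, x, meta$fit$cl, k = meta$fit$k,
                       prob = TRUE)
      win <- attr(pr, "prob")
      unname(ifelse(pr == "1", win, 1 - win))
    },
    nb = unname(stats::predict(meta$fit, df, type = "raw")[, "1"]))
}
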
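# Feature-group screening, importance rankings (RIS / XIS / mRIS / GIS)
# and importance-ranked forward subset search.

# Out-of-fold probabilities of one learner under stratified CV; AUC/ACC are
# computed on the pooled out-of-fold scores.
cv_learner <- function(id, x, y, folds = 10, seed = 1) {
  cv <- cross_validate(
    x, y,
    fit = function(xt, yt, s) fit_learner(id, xt, yt, seed = s),
    predict_fun = predict_learner,
    folds = folds, seed = seed)
  list(oof = cv$oof, AUC = cv$pooled$AUC, ACC = cv$pooled$ACC, fold = cv$fold)
}

#' Screen feature groups by per-group discriminative power
#'
#' Each group's columns are evaluated alone: for every learner, stratified
#' 10-fold cross-validated AUC and ACC (threshold 0.5). A group is
#' retained iff the aggregated AUC and ACC both strictly exceed
#' `threshold`. Aggregation over learners is `"mean"` by default: with
#' five learners screened per group, the mean damps the multiple-testing
#' inflation of the per-learner maximum, keeping label-independent groups
#' below the threshold (`"best"` is available for the permissive variant).
#'
#' @param fm a normalized `feature_matrix`.
#' @param labels binary labels.
#' @param learners learner ids (default all five).
#' @param threshold screen threshold (default 0.60).
#' @param cv number of folds (default 10).
#' @param seed integer seed (fold assignment and fits).
#' @param aggregate `"mean"` or `"best"` over learners.
#' @return list with `scores` (data.frame group x learner AUC/ACC),
#'   `retained` (character vector of retained groups), `threshold`,
#'   `aggregate`.
#' @export
screen_groups <- function(fm, labels, learners = base_learner_ids(),
                          threshold = 0.60, cv = 10, seed = 1,
                          aggregate = c("mean", "best")) {
  aggregate <- match.arg(aggregate)
  y <- as_binary_labels(labels)
  reg <- fm_groups(fm)
  rows <- list()
  for (g in reg$group) {
    cols <- which(fm$info$group == g)
    if (length(cols) == 0) stop("group has no columns: ", g)
    xg <- fm$x[, cols, drop = FALSE]
    for (id in learners) {
      r <- cv_learner(id, xg, y, folds = cv,
                      seed = child_seed(seed, paste0("screen_", g, "_", id)))
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, learner = id, AUC = r$AUC, ACC = r$ACC,
        stringsAsFactors = FALSE)
    }
  }
  scores <- do.call(rbind, rows)
  aggfun <- if (aggregate == "best") max else mean
  agg <- do.call(rbind, lapply(split(scores, scores$group), function(d)
    data.frame(group = d$group[1], AUC = aggfun(d$AUC), ACC = aggfun(d$ACC))))
  retained <- agg$group[agg$AUC > threshold & agg$ACC > threshold]
  list(scores = scores, aggregated = agg,
       retained = as.character(retained), threshold = threshold,
       aggregate = aggregate)
}

# equal-frequency discretization into at most `bins` bins
discretize_ef <- function(v, bins = 10) {
  br <- unique(stats::quantile(v, probs = seq(0, 1, length.out = bins + 1),
                               na.rm = TRUE, names = FALSE))
  if (length(br) <= 2) return(as.integer(v > br[1]) + 1L)
  findInterval(v, br[-c(1, length(br))]) + 1L
}

mi_disc <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  p <- tab / n
  pa <- rowSums(p); pb <- colSums(p)
  ex <- outer(pa, pb)
  nz <- p > 0
  sum(p[nz] * log(p[nz] / ex[nz]))
}

# MI of every column of the discretized matrix D against one discrete
# vector s, via one-hot crossproducts (BLAS), in nats.
mi_all_vs <- function(D, s, bins) {
  n <- nrow(D)
  sl <- sort(unique(s))
  S <- matrix(0, n, length(sl))
  S[cbind(seq_len(n), match(s, sl))] <- 1
  cs <- colSums(S) / n                       # P(s = b)
  mi <- numeric(ncol(D))
  for (a in seq_len(bins)) {
    Da <- D == a
    ca <- colSums(Da) / n                    # P(d_j = a)
    cnt <- crossprod(Da, S) / n              # P(d_j = a, s = b), p x |s|
    ex <- outer(ca, cs)
    term <- cnt * log(cnt / ex)
    term[cnt == 0] <- 0
    mi <- mi + rowSums(term)
  }
  mi
}

# Greedy mRMR ordering (difference form: relevance minus mean redundancy).
# The greedy order is computed exactly for the first `max_greedy` features;
# any remainder is appended in relevance order (prefix searches never look
# past the greedy depth).
mrmr_order <- function(x, y, bins = 10, max_greedy = 200) {
  p <- ncol(x)
  D <- vapply(seq_len(p), function(j) discretize_ef(x[, j], bins),
              integer(nrow(x)))
  rel <- mi_all_vs(D, y, bins)
  first <- order(-rel, seq_len(p))[1]
  sel <- first
  remaining <- setdiff(seq_len(p), first)
  redsum <- numeric(p)
  while (length(remaining) > 0 && length(sel) < min(p, max_greedy)) {
    last <- sel[length(sel)]
    redsum[remaining] <- redsum[remaining] +
      mi_all_vs(D[, remaining, drop = FALSE], D[, last], bins)
    obj <- rel[remaining] - redsum[remaining] / length(sel)
    pick <- remaining[order(-obj, remaining)[1]]
    sel <- c(sel, pick)
    remaining <- setdiff(remaining, pick)
  }
  if (length(remaining)) sel <- c(sel, remaining[order(-rel[remaining], remaining)])
  sel
}

#' Rank features by an importance measure
#'
#' * `RIS` — impurity-decrease importance from a probability random forest.
#' * `XIS` — gain importance from regularized extreme gradient boosting.
#' * `GIS` — gain importance from a plain gradient-boosted tree ensemble.
#' * `mRIS` — greedy mRMR ordering (maximize mutual information with the
#'   label minus mean mutual information with already-selected features;
#'   features discretized into 10 equal-frequency bins). Since greedy
#'   objective values are not comparable across steps, mRIS reports
#'   descending selection ranks as its scores.
#'
#' Ties are broken by column order.
#'
#' @param x numeric matrix (typically the retained-group columns).
#' @param labels binary labels.
#' @param method one of `"RIS"`, `"XIS"`, `"mRIS"`, `"GIS"`.
#' @param seed integer seed for the tree fits.
#' @return list with `method`, `order` (a permutation of column indices,
#'   most important first), `scores` (non-increasing), `feature_names`.
#' @export
rank_features <- function(x, labels, method = c("RIS", "XIS", "mRIS", "GIS"),
                          seed = 1) {
  method <- match.arg(method)
  y <- as_binary_labels(labels)
  p <- ncol(x)
  if (method == "mRIS") {
    ord <- mrmr_order(x, y)
    scores <- (p:1) / p
  } else {
    id <- switch(method, RIS = "rf", XIS = "xgb", GIS = "gbdt")
    imp <- learner_importance(id, x, y, seed = seed)
    ord <- order(-imp, seq_len(p))
    scores <- imp[ord]
  }
  list(method = method, order = ord, scores = scores,
       feature_names = colnames(x)[ord])
}

# default prefix grid: complete for small D, otherwise all k <= 8 plus a
# geometric ladder capped at min(D, cap)
default_prefix_grid <- function(D, cap = 150) {
  if (D <= 20) return(seq_len(D))
  top <- min(D, cap)
  ks <- c(1:8, round(exp(seq(log(10), log(top), length.out = 8))))
  sort(unique(pmin(ks, top)))
}

#' Forward subset search over importance-ranked prefixes
#'
#' Evaluates cross-validated AUC of one learner on the top-k features of a
#' ranking over a grid of prefix sizes, and picks the k maximizing AUC
#' (smallest k on ties). By default the grid is prefix-complete for up to
#' 20 features and otherwise covers all k <= 8 plus a geometric ladder
#' capped at 150 features; pass `ks = 1:ncol(x)` for a fully exhaustive
#' search.
#'
#' @param x numeric matrix (retained-group columns).
#' @param labels binary labels.
#' @param learner a base learner id.
#' @param ranking an importance ranking from [rank_features()].
#' @param cv folds (default 10).
#' @param seed integer seed.
#' @param ks prefix sizes to evaluate (default: see above).
#' @return list with `learner`, `method`, `trajectory` (data.frame k, AUC),
#'   `chosen_k`, `subset` (column indices into `x`), `auc`.
#' @export
sfs_prefix_search <- function(x, labels, learner, ranking, cv = 10, seed = 1,
                              ks = NULL) {
  y <- as_binary_labels(labels)
  D <- ncol(x)
  if (is.null(ks)) ks <- default_prefix_grid(D)
  ks <- sort(unique(as.integer(ks)))
  if (any(ks < 1 | ks > D)) stop("prefix sizes must lie in 1..", D)
  aucs <- vapply(ks, function(k) {
    cols <- ranking$order[seq_len(k)]
    cv_learner(learner, x[, cols, drop = FALSE], y, folds = cv,
               seed = child_seed(seed, paste0("sfs_", learner, "_",
                                              ranking$method)))$AUC
  }, 0)
  best <- which.max(aucs)  # first max = smallest k on ties
  list(learner = learner, method = ranking$method,
       trajectory = data.frame(k = ks, AUC = aucs),
       chosen_k = ks[best],
       subset = ranking$order[seq_len(ks[best])],
       auc = aucs[best])
}

#' Choose the best (ranking, prefix) pair for every learner
#'
#' Runs [sfs_prefix_search()] for each learner crossed with each ranking
#' method and keeps, per learner, the combination with the highest
#' cross-validated AUC (first method in `methods` order on ties).
#'
#' @param x numeric matrix (retained-group columns).
#' @param labels binary labels.
#' @param learners base learner ids.
#' @param methods ranking method names (default all four).
#' @param cv folds.
#' @param seed integer seed.
#' @param ks optional prefix grid forwarded to the search.
#' @return list with `winners` (per learner: method, subset, auc),
#'   `searches` (all learner x method results), `rankings`.
#' @export
select_per_learner <- function(x, labels, learners = base_learner_ids(),
                               methods = c("RIS", "XIS", "mRIS", "GIS"),
                               cv = 10, seed = 1, ks = NULL) {
  rankings <- lapply(methods, function(m)
    rank_features(x, labels, m, seed = child_seed(seed, paste0("rank_", m))))
  names(rankings) <- methods
  searches <- list()
  winners <- list()
  for (id in learners) {
    res <- lapply(methods, function(m)
      sfs_prefix_search(x, labels, id, rankings[[m]], cv = cv,
                        seed = child_seed(seed, paste0("sel_", id)), ks = ks))
    names(res) <- methods
    searches[[id]] <- res
    aucs <- vapply(res, `[[`, 0, "auc")
    best <- which.max(aucs)
    winners[[id]] <- res[[best]]
  }
  list(winners = winners, searches = searches, rankings = rankings)
}

#' Jaccard overlap of two feature subsets
#'
#' @param a,b integer vectors of column indices.
#' @return `|A intersect B| / |A union B|`.
#' @export
subset_overlap <- function(a, b) {
  length(intersect(a, b)) / length(union(a, b))
}
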
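# Metric suite: confusion counts, threshold metrics, ROC/PR areas, the CV
# harness and cumulative effect risk.

test_that("confusion counts classify strictly above the threshold", {
  cc <- confusion(c(0.9, 0.1), c("driver", "passenger"))
  expect_equal(cc, list(TP = 1L, FP = 0L, TN = 1L, FN = 0L))
  cc2 <- confusion(rep(0, 7), rep("driver", 7))
  expect_equal(cc2$FN, 7L)
  # exact-threshold scores fall on the negative side
  cc3 <- confusion(c(0.5, 0.5), c("driver", "passenger"))
  expect_equal(cc3$FN, 1L)
  expect_equal(cc3$TN, 1L)
  # conservation over random data
  set.seed(1)
  cc4 <- confusion(runif(1000), sample(c("driver", "passenger"), 1000, TRUE))
  expect_equal(cc4$TP + cc4$FP + cc4$TN + cc4$FN, 1000L)
})

test_that("threshold metrics agree with an independent hand computation", {
  # TP=40, FN=10, TN=30, FP=20, computed by hand from the definitions:
  # PRE = 40/60, SEN = 40/50, SPE = 30/50, BACC = (0.8 + 0.6)/2,
  # F1 = 80/110, ACC = 70/100,
  # MCC = (40*30 - 20*10) / sqrt(50 * 60 * 50 * 40) = 1000/2449.4897...
  m <- metrics(list(TP = 40, FP = 20, TN = 30, FN = 10))
  expect_equal(m$PRE, 2 / 3)
  expect_equal(m$SEN, 0.8)
  expect_equal(m$SPE, 0.6)
  expect_equal(m$BACC, 0.7)
  expect_equal(m$F1, 80 / 110)
  expect_equal(m$ACC, 0.7)
  expect_equal(m$MCC, 1000 / sqrt(50 * 60 * 50 * 40))
  expect_equal(m$MCC, 0.4082483, tolerance = 1e-6)
  expect_length(m$degenerate, 0)
})

test_that("perfect and chance classifiers hit the metric extremes", {
  perf <- metrics(list(TP = 50, FP = 0, TN = 50, FN = 0))
  for (k in c("PRE", "SEN", "SPE", "BACC", "F1", "ACC", "MCC"))
    expect_equal(perf[[k]], 1)
  chance <- metrics(list(TP = 25, FP = 25, TN = 25, FN = 25))
  expect_equal(chance$ACC, 0.5)
  expect_equal(chance$MCC, 0)
})

test_that("zero-denominator metrics report 0 with a degenerate flag", {
  m <- metrics(list(TP = 0, FP = 0, TN = 10, FN = 0))
  expect_equal(m$PRE, 0)
  expect_equal(m$SEN, 0)
  expect_true(all(c("PRE", "SEN", "MCC") %in% m$degenerate))
})

test_that("BACC identity and MCC bounds hold over random confusion counts", {
  set.seed(7)
  for (i in 1:1000) {
    cc <- as.list(stats::setNames(rmultinom(1, 200, runif(4))[, 1],
                                  c("TP", "FP", "TN", "FN")))
    m <- metrics(cc)
    expect_identical(m$BACC, (m$SEN + m$SPE) / 2)
    expect_gte(m$MCC, -1)
    expect_lte(m$MCC, 1)
    expect_equal(m$n, 200)
    # F1 is the harmonic mean of PRE and SEN when both are nonzero
    if (m$PRE > 0 && m$SEN > 0)
      expect_equal(m$F1, 2 * m$PRE * m$SEN / (m$PRE + m$SEN))
  }
})

test_that("rank-statistic AUC equals the concordant-pair oracle", {
  pair_auc <- function(s, y) {
    # O(n^2) enumeration: concordant pairs + half of ties
    pos <- s[y == 1]; neg <- s[y == 0]
    tot <- 0
    for (a in pos) for (b in neg) tot <- tot + (a > b) + 0.5 * (a == b)
    tot / (length(pos) * length(neg))
  }
  set.seed(11)
  for (i in 1:25) {
    y <- c(rep(1, 8), rep(0, 12))
    s <- round(runif(20), 2)            # rounding forces some ties
    expect_equal(roc_auc(s, y), pair_auc(s, y))
  }
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_true(is.na(roc_auc(c(0.1, 0.9), c(1, 1))))
})

test_that("rank AUC agrees with an established ROC implementation", {
  set.seed(17)
  for (i in 1:5) {
    s <- round(runif(100), 2)
    y <- rbinom(100, 1, plogis(4 * s - 2))
    if (length(unique(y)) < 2) next
    ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                          direction = "<")))
    expect_equal(roc_auc(s, y), ref)
  }
})

test_that("AUC is near 0.5 when labels are independent of scores", {
  set.seed(5)
  s <- runif(10000)
  y <- rbinom(10000, 1, 0.5)
  expect_equal(roc_auc(s, y), 0.5, tolerance = 0.03)
})

test_that("AUC is invariant under strictly monotone score transforms and
           label complementation swaps SEN and SPE", {
  set.seed(9)
  s <- runif(300)
  y <- rbinom(300, 1, plogis(3 * s - 1.5))
  a <- roc_auc(s, y)
  expect_equal(roc_auc(qlogis(pmin(pmax(s, 1e-9), 1 - 1e-9)), y), a)
  expect_equal(roc_auc(s^3, y), a)
  m1 <- metrics(confusion(s, y))
  m2 <- metrics(confusion(-s, 1 - y, threshold = -0.5))
  expect_equal(m1$SEN, m2$SPE)
  expect_equal(m1$SPE, m2$SEN)
})

test_that("PR area matches the average-precision oracle on tie-free data", {
  ap_oracle <- function(s, y) {
    # mean over positives of precision at that positive's threshold
    o <- order(s, decreasing = TRUE)
    ys <- y[o]
    mean((cumsum(ys) / seq_along(ys))[ys == 1])
  }
  set.seed(13)
  for (i in 1:20) {
    s <- sample(seq(0.01, 0.99, length.out = 40))  # distinct scores
    y <- rbinom(40, 1, s)
    if (sum(y) == 0) next
    expect_equal(pr_auc(s, y), ap_oracle(s, y))
  }
  expect_equal(pr_auc(c(0.9, 0.8, 0.2), c(1, 1, 0)), 1)
  pts <- curve_points(c(0.9, 0.4, 0.2), c(1, 0, 1))
  expect_equal(nrow(pts$roc), 4)
  expect_true(all(diff(pts$roc$fpr) >= 0))
})

test_that("the CV harness stratifies, is seeded and sums fold confusions", {
  pm <- planted_matrix(n = 95, seed = 2)
  fit <- function(x, y, s) {
    list(mu = colMeans(x[y == 1, , drop = FALSE]) -
           colMeans(x[y == 0, , drop = FALSE]))
  }
  prd <- function(m, x) plogis(as.numeric(x %*% m$mu))
  r1 <- cross_validate(pm$x, pm$y, fit, prd, folds = 10, seed = 3)
  r2 <- cross_validate(pm$x, pm$y, fit, prd, folds = 10, seed = 3)
  expect_identical(r1$fold, r2$fold)
  expect_identical(r1$oof, r2$oof)
  # fold sizes differ by at most one within each class
  for (cl in c(0, 1)) {
    sizes <- table(r1$fold[pm$y == cl])
    expect_lte(max(sizes) - min(sizes), 1)
  }
  pooled <- confusion(r1$oof, pm$y)
  fold_sum <- Reduce(function(a, b) Map(`+`, a, b),
                     lapply(1:10, function(k)
                       confusion(r1$oof[r1$fold == k], pm$y[r1$fold == k])))
  expect_equal(pooled, fold_sum)
  expect_error(stratified_folds(rep(1, 5), k = 10), "fewer observations")
})

test_that("cumulative effect risk sums predicted-driver scores per patient", {
  r <- cumulative_effect_risk(rep("P1", 3), c(0.9, 0.6, 0.2))
  expect_equal(r$CER, 1.5)
  expect_equal(r$n_contributing, 2L)
  r0 <- cumulative_effect_risk(c("P1", "P1"), c(0.3, 0.2))
  expect_equal(r0$CER, 0)
  rall <- cumulative_effect_risk(rep("P1", 3), c(0.9, 0.6, 0.2), mode = "all")
  expect_equal(rall$CER, 1.7)
  # monotone nondecreasing as variants are added
  set.seed(21)
  s <- runif(50)
  cer_k <- vapply(seq_along(s), function(k)
    cumulative_effect_risk(rep("P", k), s[seq_len(k)])$CER, 0)
  expect_true(all(diff(cer_k) >= 0))
  # multiple patients partition their variants
  pts <- c("A", "B", "A", "B")
  r2 <- cumulative_effect_risk(pts, c(0.9, 0.8, 0.7, 0.1))
  expect_equal(r2$CER[r2$patient == "A"], 1.6)
  expect_equal(r2$CER[r2$patient == "B"], 0.8)
})
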
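# Encoder families: exact dimension arithmetic, value semantics, missing
# propagation, and the alt-minus-ref difference restriction property.

block_len <- function(b) length(b$values)
blocks_len <- function(bl) sum(vapply(bl, block_len, 0L))

test_that("one-hot encoding has width 4L and basis-vector semantics", {
  w <- test_window(strrep("A", 101))
  b <- encode_onehot(w, "ref")
  expect_equal(block_len(b), 404)
  expect_equal(b$values, rep(c(1, 0, 0, 0), 101))  # A basis at every position
  # alt and ref one-hot differ in exactly the 4 centre entries
  w2 <- random_window(101, seed = 3)
  d <- encode_onehot(w2, "alt")$values - encode_onehot(w2, "ref")$values
  expect_equal(sum(d != 0), 2)  # two entries flip between distinct bases
  expect_true(all(which(d != 0) %in% (4 * w2$center + 1:4)))
})

test_that("physicochemical widths are 3L, 1L and 8L with table-row values", {
  w <- test_window(strrep("G", 101))
  bl <- encode_physchem(w, "ref")
  expect_equal(vapply(bl, block_len, 0L), c(303L, 101L, 808L))
  tb <- default_property_tables()
  expect_equal(bl[[1]]$values, rep(unname(tb$ncp[, "G"]), 101))
  expect_equal(bl[[2]]$values, rep(unname(tb$eiip[, "G"]), 101))
  expect_equal(bl[[3]]$values, rep(unname(tb$pcp[, "G"]), 101))
})

test_that("an N in the window propagates to missing feature values", {
  s <- strrep("A", 101)
  substr(s, 30, 30) <- "N"
  w <- test_window(s)
  eiip <- encode_physchem(w, "ref")[[2]]
  expect_equal(sum(is.na(eiip$values)), 1)
  expect_true(is.na(eiip$values[30]))
  oh <- encode_onehot(w, "ref")
  expect_equal(sum(is.na(oh$values)), 4)
  # shape: every pentamer covering position 30 is knocked out
  sh <- encode_shape(w, "ref", test_shape_table())
  mgw <- sh[[which(vapply(sh, function(b) b$group_name, "") == "shape_alt_MGW")]]
  expect_equal(which(is.na(mgw$values)), (28:32) - 2)  # centres 28..32
})

test_that("physicochemical difference features span 16 dims from table rows", {
  w <- random_window(101, seed = 7)
  w$ref <- "G"; w$alt <- "C"
  substr(w$ref_seq, w$center + 1, w$center + 1) <- "G"
  substr(w$alt_seq, w$center + 1, w$center + 1) <- "C"
  bl <- encode_physchem_diff(w)
  expect_equal(vapply(bl, block_len, 0L), c(4L, 3L, 1L, 8L))
  tb <- default_property_tables()
  expect_equal(bl[[3]]$values, unname(tb$eiip[, "C"] - tb$eiip[, "G"]))
  expect_equal(bl[[1]]$values, unname(tb$onehot[, "C"] - tb$onehot[, "G"]))
  # forced alt == ref: all 16 values vanish
  wi <- identical_allele_window(101, seed = 8)
  expect_true(all(unlist(lapply(encode_physchem_diff(wi),
                                function(b) b$values)) == 0))
})

test_that("shape encoding follows the pentamer-centre/step-average rule", {
  st <- test_shape_table()
  # constant-table limit: every value equals the constant
  ct <- st
  for (ty in names(ct$per_base)) ct$per_base[[ty]][] <- 2.5
  for (ty in names(ct$per_step)) ct$per_step[[ty]][] <- -1.5
  w <- random_window(21, seed = 2)
  bl <- encode_shape(w, "ref", ct)
  for (b in bl[1:8]) expect_true(all(b$values == 2.5))
  for (b in bl[9:14]) expect_true(all(b$values == -1.5))
  # brute-force recompute on a 9-mer: per-base value at pentamer centre;
  # step value = mean of the (1 or 2) covering pentamers' contributions
  w9 <- random_window(9, seed = 13)
  chars <- strsplit(w9$ref_seq, "")[[1]]
  penta <- vapply(3:7, function(c) paste(chars[(c - 2):(c + 2)], collapse = ""), "")
  bl9 <- encode_shape(w9, "ref", st)
  mgw <- bl9[[which(vapply(bl9, function(b) b$group_name, "") == "shape_alt_MGW")]]
  expect_equal(mgw$values, unname(st$per_base$MGW[penta]))
  roll <- bl9[[which(vapply(bl9, function(b) b$group_name, "") == "shape_alt_roll")]]
  m <- st$per_step$roll
  # steps s = 2..7; contributions: left entry of pentamer centred s+1,
  # right entry of pentamer centred s (centres valid in 3..7)
  expected <- vapply(2:7, function(s) {
    contrib <- c(if (s + 1 >= 3 && s + 1 <= 7) m[penta[s + 1 - 2], 1],
                 if (s >= 3 && s <= 7) m[penta[s - 2], 2])
    mean(contrib)
  }, 0)
  expect_equal(roll$values, expected)
})

test_that("shape dimension arithmetic holds for any odd window length", {
  st <- test_shape_table()
  for (L in c(9, 11, 21, 101)) {
    w <- random_window(L, seed = L)
    expect_equal(blocks_len(encode_shape(w, "alt", st)),
                 8 * (L - 4) + 6 * (L - 3))
    expect_equal(blocks_len(encode_shape_diff(w, st)), 76)
  }
  expect_error(encode_shape(test_window("ACGTN"), "ref",
                            structure(list(per_base = list(), per_step = list()))),
               "incomplete")
})

test_that("shape difference equals the full alt-ref vector masked to the
           variant-overlapping coordinates", {
  st <- test_shape_table()
  for (seed in 1:10) {
    w <- random_window(101, seed = seed)
    full_ref <- encode_shape(w, "ref", st)
    full_alt <- encode_shape(w, "alt", st)
    diff <- encode_shape_diff(w, st)
    m <- w$center + 1
    for (i in seq_along(full_ref)) {
      fullD <- full_alt[[i]]$values - full_ref[[i]]$values
      is_base <- grepl("shape_alt_", full_ref[[i]]$group_name) && i <= 8
      idx <- if (i <= 8) (m - 2):(m + 2) - 2 else (m - 3):(m + 2) - 1
      expect_equal(diff[[i]]$values, fullD[idx])
      expect_true(all(fullD[-idx] == 0))   # zero outside the retained coords
    }
  }
  wi <- identical_allele_window(101, seed = 99)
  expect_true(all(unlist(lapply(encode_shape_diff(wi, st),
                                function(b) b$values)) == 0))
})

test_that("embedding features have per-model width dims*L and a
           centre-restricted difference", {
  ad <- test_adapter()
  w <- random_window(101, seed = 21)
  bl <- encode_embedding(w, "alt", ad)
  expect_equal(length(bl), 3)
  expect_equal(vapply(bl, block_len, 0L), rep(1616L, 3))
  expect_equal(blocks_len(bl), 4848)
  # determinism
  bl2 <- encode_embedding(w, "alt", ad)
  expect_identical(lapply(bl, `[[`, "values"), lapply(bl2, `[[`, "values"))
  dl <- encode_embedding_diff(w, ad)
  expect_equal(blocks_len(dl), 48)
  # equals the full position-wise subtraction restricted to the centre
  for (i in seq_along(ad$model_ids)) {
    er <- ad$embed(ad$model_ids[i], w$ref_seq)
    ea <- ad$embed(ad$model_ids[i], w$alt_seq)
    fullD <- ea - er
    expect_equal(dl[[i]]$values, fullD[, w$center + 1])
    expect_true(all(fullD[, -(w$center + 1)] == 0))
  }
  wi <- identical_allele_window(101, seed = 22)
  expect_true(all(unlist(lapply(encode_embedding_diff(wi, ad),
                                function(b) b$values)) == 0))
  # adapter contract: wrong-length output is rejected
  bad <- ad
  bad$embed <- function(model_id, seq) matrix(0, 3, nchar(seq))
  expect_error(encode_embedding(w, "alt", bad), "contract")
})

test_that("annotation join respects configured group widths and missing keys", {
  v <- data.frame(chrom = c("chr1", "chr1", "chr2"), pos = c(10L, 20L, 99L),
                  ref = c("A", "C", "G"), alt = c("G", "T", "A"))
  tab <- cbind(v[1:2, ], as.data.frame(matrix(seq_len(2 * 39), 2, 39)))
  ann <- attach_annotations(v, tab)
  expect_equal(length(ann[[1]]), 4)
  expect_equal(vapply(ann[[1]], block_len, 0L), c(10L, 10L, 12L, 7L),
               ignore_attr = TRUE)
  expect_equal(blocks_len(ann[[1]]), 39)
  # absent key: all-missing row
  expect_true(all(is.na(unlist(lapply(ann[[3]], `[[`, "values")))))
  # custom widths repartition the same columns
  ann2 <- attach_annotations(v, tab, c(a = 5, b = 20, c = 10, d = 4))
  expect_equal(vapply(ann2[[1]], block_len, 0L), c(5L, 20L, 10L, 4L),
               ignore_attr = TRUE)
  expect_error(attach_annotations(v, tab, c(a = 1, b = 1, c = 1, d = 1)),
               "group widths")
})

test_that("assembly produces the documented totals and group registry", {
  st <- test_shape_table()
  ad <- test_adapter()
  v <- data.frame(chrom = "chrT", pos = 51L, ref = "A", alt = "C")
  w <- random_window(101, seed = 31)
  w$ref <- substr(w$ref_seq, 51, 51)
  v$ref <- w$ref
  ann_tab <- cbind(v, as.data.frame(matrix(rnorm(39), 1, 39)))
  blocks <- c(attach_annotations(v, ann_tab)[[1]],
              encode_shape(w, "alt", st),
              encode_shape_diff(w, st),
              list(encode_onehot(w, "alt")),
              encode_physchem(w, "alt"),
              encode_physchem_diff(w))
  blocks_full <- c(blocks, encode_embedding(w, "alt", ad),
                   encode_embedding_diff(w, ad))
  fm <- assemble_features(list(blocks_full))
  expect_equal(ncol(fm$x), 8007)
  expect_equal(nrow(fm_groups(fm)), 46)
  # dropping the embedding category removes 4848 + 48 columns
  fm2 <- assemble_features(list(blocks))
  expect_equal(ncol(fm2$x), 8007 - 4896)
  # single variant, single block
  fm3 <- assemble_features(list(list(encode_onehot(w, "alt"))))
  expect_equal(dim(fm3), c(1L, 404L))
  expect_equal(as.numeric(fm3$x[1, ]), encode_onehot(w, "alt")$values)
})

test_that("min-max normalization, clipping and mean imputation behave", {
  info <- data.frame(name = c("a.1", "a.2"), group = "a", category = "x",
                     index = 1:2)
  x <- matrix(c(2, 4, 6, 5, 5, 5), 3, 2)
  fm <- ssnvStack:::new_feature_matrix(x, info, paste0("v", 1:3))
  nz <- fit_normalizer(fm)
  out <- apply_normalizer(nz, fm)
  expect_equal(as.numeric(out$x[, 1]), c(0, 0.5, 1))
  expect_equal(as.numeric(out$x[, 2]), c(0, 0, 0))   # constant column rule
  # test-time values outside the training range are clipped into [0,1]
  xt <- matrix(c(8, 1, 5, 5), 2, 2)
  fmt <- ssnvStack:::new_feature_matrix(xt, info, paste0("t", 1:2))
  outt <- apply_normalizer(nz, fmt)
  expect_equal(as.numeric(outt$x[, 1]), c(1, 0))
  pre <- apply_normalizer(nz, fmt, clip = FALSE)
  expect_gt(pre$x[1, 1], 1)
  # missing values impute to the training mean of the normalized column
  xm <- matrix(c(NA, 4, NA, 5), 2, 2)
  fmm <- ssnvStack:::new_feature_matrix(xm, info, paste0("m", 1:2))
  outm <- apply_normalizer(nz, fmm)
  expect_false(anyNA(outm$x))
  expect_equal(unname(outm$x[1, 1]), 0.5)   # mean of {0, 0.5, 1}
  # idempotent on already-normalized training data
  nz2 <- fit_normalizer(out)
  out2 <- apply_normalizer(nz2, out)
  expect_equal(out2$x, out$x)
  expect_error(apply_normalizer(structure(list(fitted = FALSE),
                                          class = "normalizer"), fm),
               "not been fitted")
})
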
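# FeatureMatrix container: variants x features with per-column
# (group, category, index) metadata, min-max normalization and mean
# imputation fitted on training rows only.

new_feature_matrix <- function(x, info, keys) {
  stopifnot(ncol(x) == nrow(info))
  colnames(x) <- info$name
  structure(list(x = x, info = info, keys = keys, normalized = FALSE),
            class = "feature_matrix")
}

#' @export
dim.feature_matrix <- function(x) dim(x$x)

#' @export
print.feature_matrix <- function(x, ...) {
  cat("feature_matrix:", nrow(x$x), "variants x", ncol(x$x), "features in",
      length(unique(x$info$group)), "groups",
      if (x$normalized) "(normalized)" else "(raw)", "\n")
  invisible(x)
}

#' Assemble per-variant feature blocks into a feature matrix
#'
#' Every variant must carry the same ordered set of blocks (same group
#' names and widths). With all default encoders at L = 101 the result has
#' 8,007 columns partitioned into 46 groups.
#'
#' @param block_lists list over variants; each element a flat list of
#'   feature blocks (see the `encode_*` functions).
#' @param keys character vector of variant keys (row identifiers).
#' @return a `feature_matrix`.
#' @export
assemble_features <- function(block_lists, keys = NULL) {
  if (length(block_lists) == 0) stop("no variants to assemble")
  flat <- lapply(block_lists, function(bl) {
    if (inherits(bl, "feature_block")) bl <- list(bl)
    bl
  })
  first <- flat[[1]]
  groups <- vapply(first, function(b) b$group_name, "")
  if (anyDuplicated(groups)) stop("duplicate group names in blocks")
  widths <- vapply(first, function(b) length(b$values), 0L)
  cats <- vapply(first, function(b) b$category, "")
  info <- data.frame(
    name = unlist(lapply(seq_along(first), function(i)
      paste0(groups[i], ".", seq_len(widths[i])))),
    group = rep(groups, widths),
    category = rep(cats, widths),
    index = unlist(lapply(widths, seq_len)),
    stringsAsFactors = FALSE
  )
  x <- t(vapply(flat, function(bl) {
    g <- vapply(bl, function(b) b$group_name, "")
    if (!identical(g, groups)) stop("inconsistent block sets across variants")
    unlist(lapply(bl, function(b) b$values), use.names = FALSE)
  }, numeric(sum(widths))))
  if (is.null(keys)) keys <- paste0("v", seq_along(flat))
  new_feature_matrix(x, info, keys)
}

#' Restrict a feature matrix to a set of groups
#'
#' @param fm a `feature_matrix`.
#' @param groups character vector of group names to keep.
#' @return a `feature_matrix` with only those groups' columns.
#' @export
fm_subset_groups <- function(fm, groups) {
  missing_g <- setdiff(groups, unique(fm$info$group))
  if (length(missing_g)) stop("unknown group(s): ", paste(missing_g, collapse = ", "))
  keep <- fm$info$group %in% groups
  new_feature_matrix(fm$x[, keep, drop = FALSE],
                     fm$info[keep, , drop = FALSE], fm$keys) |>
    (\(f) {f$normalized <- fm$normalized; f})()
}

#' Group registry of a feature matrix
#'
#' @param fm a `feature_matrix`.
#' @return data.frame with `group`, `category`, `width`.
#' @export
fm_groups <- function(fm) {
  g <- unique(fm$info[, c("group", "category")])
  g$width <- as.integer(table(fm$info$group)[g$group])
  rownames(g) <- NULL
  g
}

#' Fit a min-max normalizer on training rows
#'
#' Records per-column training min, max and the mean of the normalized
#' non-missing training values (used for imputation). Constant columns
#' normalize to 0.
#'
#' @param train a raw `feature_matrix` of training rows.
#' @return a `normalizer` object.
#' @export
fit_normalizer <- function(train) {
  x <- train$x
  cmin <- apply(x, 2, function(c) if (all(is.na(c))) 0 else min(c, na.rm = TRUE))
  cmax <- apply(x, 2, function(c) if (all(is.na(c))) 0 else max(c, na.rm = TRUE))
  rng <- cmax - cmin
  xn <- sweep(x, 2, cmin)
  xn <- sweep(xn, 2, ifelse(rng > 0, rng, 1), "/")
  xn[, rng == 0] <- 0
  mu <- colMeans(xn, na.rm = TRUE)
  mu[!is.finite(mu)] <- 0
  structure(list(min = cmin, max = cmax, mean_norm = mu,
                 names = colnames(x), fitted = TRUE),
            class = "normalizer")
}

#' Apply a fitted normalizer
#'
#' Maps each column through `(x - min) / (max - min)` with the training
#' min/max, clips to `[0, 1]` (test values can fall outside the training
#' range) and imputes missing values with the training mean of the
#' normalized column. The result contains no missing values.
#'
#' @param state a `normalizer` from [fit_normalizer()].
#' @param fm a raw `feature_matrix`.
#' @param clip clip to `[0,1]` after scaling (default TRUE).
#' @return a normalized `feature_matrix`.
#' @export
apply_normalizer <- function(state, fm, clip = TRUE) {
  if (!inherits(state, "normalizer") || !isTRUE(state$fitted))
    stop("normalizer has not been fitted")
  if (!identical(state$names, colnames(fm$x)))
    stop("normalizer was fitted on a different column set")
  rng <- state$max - state$min
  xn <- sweep(fm$x, 2, state$min)
  xn <- sweep(xn, 2, ifelse(rng > 0, rng, 1), "/")
  xn[, rng == 0] <- 0
  if (clip) xn[] <- pmin(pmax(xn, 0), 1)
  nas <- which(is.na(xn), arr.ind = TRUE)
  if (nrow(nas)) xn[nas] <- state$mean_norm[nas[, 2]]
  out <- new_feature_matrix(xn, fm$info, fm$keys)
  out$normalized <- TRUE
  out
}

#' Encode a variant table end to end into a feature matrix
#'
#' Runs every encoder family over the variants' 101-nt windows and joins
#' the annotation table, producing the full raw feature matrix (8,007
#' columns in 46 groups at default settings). Normalization is a separate,
#' training-aware step ([fit_normalizer()] / [apply_normalizer()]).
#'
#' @param genome `DNAStringSet` or FASTA path.
#' @param variants data.frame from [read_variants()].
#' @param annotations annotation table (data.frame or TSV path), or NULL to
#'   skip the basic-annotation category.
#' @param shape_table pentamer shape table.
#' @param prop_tables per-nucleotide property tables.
#' @param adapter embedder adapter, or NULL to skip embedding categories.
#' @param flank window half-width (default 50).
#' @param annotation_group_widths passed to [attach_annotations()].
#' @return list with `fm` (raw `feature_matrix`), `variants` (rows encoded)
#'   and `windows`.
#' @export
encode_dataset <- function(genome, variants, annotations = NULL,
                           shape_table, prop_tables = default_property_tables(),
                           adapter = NULL, flank = 50L,
                           annotation_group_widths = c(annot_sequence = 10,
                                                       annot_conservation = 10,
                                                       annot_functional = 12,
                                                       annot_splicing = 7)) {
  ext <- extract_windows(genome, variants, flank = flank, on_error = "stop")
  windows <- ext$windows
  variants <- variants[ext$kept, , drop = FALSE]
  annot_blocks <- if (!is.null(annotations)) {
    attach_annotations(variants, annotations, annotation_group_widths)
  } else NULL
  block_lists <- lapply(seq_along(windows), function(i) {
    w <- windows[[i]]
    bl <- list()
    if (!is.null(annot_blocks)) bl <- c(bl, annot_blocks[[i]])
    bl <- c(bl,
            encode_shape(w, "alt", shape_table),
            encode_shape_diff(w, shape_table),
            list(encode_onehot(w, "alt")),
            encode_physchem(w, "alt", prop_tables),
            encode_physchem_diff(w, prop_tables))
    if (!is.null(adapter)) {
      bl <- c(bl, encode_embedding(w, "alt", adapter),
              encode_embedding_diff(w, adapter))
    }
    bl
  })
  keys <- paste(variants$chrom, variants$pos, variants$ref, variants$alt,
                sep = ":")
  list(fm = assemble_features(block_lists, keys), variants = variants,
       windows = windows)
}
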
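# Building labelled, redundancy-filtered, proximity-balanced datasets from
# recurrence-annotated variants.

#' Label variants by recurrence level
#'
#' Variants observed in at least `pos_threshold` independent cases are
#' putative drivers; variants observed exactly once are putative
#' passengers; intermediate recurrence levels are `unknown` and excluded
#' from training.
#'
#' @param variants data.frame with a `recurrence` column (no NAs).
#' @param pos_threshold minimum recurrence for the driver class (default 7).
#' @return the data.frame with its `label` column set to
#'   `driver` / `passenger` / `unknown`.
#' @export
label_by_recurrence <- function(variants, pos_threshold = 7L) {
  if (is.null(variants$recurrence) || anyNA(variants$recurrence))
    stop("all variants must carry a recurrence count")
  r <- variants$recurrence
  variants$label <- ifelse(r >= pos_threshold, "driver",
                           ifelse(r == 1L, "passenger", "unknown"))
  variants
}

window_identity <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  mean(ca == cb)
}

#' Greedy sequence-identity redundancy filter
#'
#' Clusters equal-length windows greedily in input order: a window joins
#' the first existing cluster whose representative shares at least
#' `identity_threshold` position-wise identity (ungapped); otherwise it
#' founds a new cluster. Cluster representatives are retained. This is an
#' internal stand-in for external redundancy-removal suites, with the same
#' threshold semantics.
#'
#' @param seqs character vector of equal-length window sequences.
#' @param identity_threshold fraction of identical positions (default 0.80).
#' @return list with `keep` (indices of retained representatives) and
#'   `cluster` (cluster id per input window).
#' @export
redundancy_filter <- function(seqs, identity_threshold = 0.80) {
  n <- length(seqs)
  if (n == 0) return(list(keep = integer(0), cluster = integer(0)))
  if (length(unique(nchar(seqs))) != 1) stop("windows must have equal length")
  mat <- do.call(rbind, strsplit(seqs, ""))
  reps <- integer(0)
  cluster <- integer(n)
  for (i in seq_len(n)) {
    assigned <- FALSE
    for (k in seq_along(reps)) {
      if (mean(mat[i, ] == mat[reps[k], ]) >= identity_threshold) {
        cluster[i] <- k
        assigned <- TRUE
        break
      }
    }
    if (!assigned) {
      reps <- c(reps, i)
      cluster[i] <- length(reps)
    }
  }
  list(keep = reps, cluster = cluster)
}

#' Pair drivers with nearby passengers into a balanced dataset
#'
#' Each driver (in chromosome, then position order) takes the nearest
#' still-unused passenger on the same chromosome by absolute position
#' distance; drivers on chromosomes without remaining passengers are
#' dropped with a warning. The output has equal class counts, and each
#' retained driver records its matched passenger via `pair_id`.
#'
#' @param variants labelled data.frame (see [label_by_recurrence()]).
#' @return data.frame of retained drivers and passengers with a `pair_id`
#'   column shared within a pair.
#' @export
pair_balance <- function(variants) {
  drv <- variants[variants$label == "driver", , drop = FALSE]
  pas <- variants[variants$label == "passenger", , drop = FALSE]
  drv <- drv[order(drv$chrom, drv$pos), , drop = FALSE]
  used <- rep(FALSE, nrow(pas))
  pairs <- list()
  dropped <- 0L
  pid <- 0L
  for (i in seq_len(nrow(drv))) {
    cand <- which(!used & pas$chrom == drv$chrom[i])
    if (length(cand) == 0) {
      dropped <- dropped + 1L
      next
    }
    j <- cand[which.min(abs(pas$pos[cand] - drv$pos[i]))]
    used[j] <- TRUE
    pid <- pid + 1L
    d <- drv[i, , drop = FALSE]; p <- pas[j, , drop = FALSE]
    d$pair_id <- pid; p$pair_id <- pid
    pairs[[length(pairs) + 1L]] <- rbind(d, p)
  }
  if (dropped > 0) warning(dropped, " driver(s) dropped: no same-chromosome passenger available")
  if (length(pairs) == 0) stop("no driver/passenger pairs could be formed")
  out <- do.call(rbind, pairs)
  rownames(out) <- NULL
  out
}

#' Split a paired dataset into training and test partitions
#'
#' Stratified by construction: matched pairs are kept together (both
#' members land in the same partition), so class balance is preserved and
#' near-duplicate leakage between partitions is avoided. Deterministic for
#' a fixed seed.
#'
#' @param dataset output of [pair_balance()] (needs `pair_id`).
#' @param train_fraction fraction of pairs assigned to training (default 0.8).
#' @param seed integer seed.
#' @return the data.frame with a `split` column in `{train, test}`.
#' @export
split_train_test <- function(dataset, train_fraction = 0.8, seed = 1) {
  if (is.null(dataset$pair_id)) stop("dataset must carry pair_id (see pair_balance)")
  ids <- unique(dataset$pair_id)
  n_train <- round(length(ids) * train_fraction)
  train_ids <- with_seed(seed, sample(ids, n_train))
  dataset$split <- ifelse(dataset$pair_id %in% train_ids, "train", "test")
  dataset
}

#' Write a dataset manifest TSV
#'
#' @param dataset labelled/split data.frame.
#' @param path output TSV path.
#' @export
write_manifest <- function(dataset, path) {
  cols <- intersect(c("chrom", "pos", "ref", "alt", "recurrence", "label",
                      "pair_id", "split"), names(dataset))
  utils::write.table(dataset[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
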
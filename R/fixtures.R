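# Deterministic synthetic fixtures: genome, pentamer shape table,
# per-nucleotide property tables, mock embedders and label-correlated
# variants + annotations. Every output is a pure function of the config.
#
# All tables here are synthetic stand-ins generated from a seed; the file
# formats are exactly the ones the real pipeline consumes, so a user can
# substitute measured shape/property/embedding tables without code
# changes.

# plausible per-type value ranges (Angstrom or degrees) for the synthetic
# pentamer shape table
SHAPE_RANGES <- list(
  shear = c(-0.5, 0.5), stretch = c(-0.3, 0.3), stagger = c(-0.5, 0.5),
  buckle = c(-15, 15), ProT = c(-16, -1), opening = c(-5, 5),
  MGW = c(2.8, 6.2), EP = c(-12, -2),
  shift = c(-0.6, 0.6), slide = c(-2, 0.5), rise = c(3, 3.6),
  tilt = c(-5, 5), roll = c(-8, 8), HelT = c(30, 40)
)

#' Default fixture configuration
#'
#' The synthetic study conditions: two 60-kb chromosomes, 200 drivers and
#' 200 passengers (pairable within 120-500 bp), driver-local GC enrichment
#' and driver-biased mutation spectrum of strength `delta`, and annotation
#' columns shifted between classes by `annotation_effect` standard
#' deviations. `delta = 0` with `annotation_effect = 0` is the null
#' regime (no class signal anywhere).
#'
#' @param seed root seed.
#' @param ... overrides for any config field.
#' @return a named list (class `fixture_config`).
#' @export
default_fixture_config <- function(seed = 1, ...) {
  cfg <- list(
    seed = seed,
    n_chromosomes = 2L,
    chromosome_length = 60000L,
    n_driver = 200L,
    n_passenger = 200L,
    delta = 0.6,
    annotation_effect = 0.8,
    annotation_group_widths = c(annot_sequence = 10, annot_conservation = 10,
                                annot_functional = 12, annot_splicing = 7),
    flank = 50L,
    pair_distance = c(120L, 500L),
    n_models = 3L,
    embed_dims = 16L
  )
  structure(utils::modifyList(cfg, list(...)), class = "fixture_config")
}

#' Generate a synthetic genome
#'
#' I.i.d. uniform ACGT chromosomes named `chr1`, `chr2`, ...
#'
#' @param config a [default_fixture_config()].
#' @return a `DNAStringSet`.
#' @export
make_genome <- function(config) {
  seqs <- vapply(seq_len(config$n_chromosomes), function(i) {
    with_seed(child_seed(config$seed, paste0("genome", i)),
              paste(sample(VALID_NT, config$chromosome_length, replace = TRUE),
                    collapse = ""))
  }, "")
  g <- Biostrings::DNAStringSet(seqs)
  names(g) <- paste0("chr", seq_len(config$n_chromosomes))
  g
}

#' Generate a synthetic pentamer shape table
#'
#' Seeded pseudo-random values covering all 1,024 pentamers for the 8
#' per-base and 6 per-step shape types, drawn uniformly within each type's
#' plausible physical range.
#'
#' @param seed integer seed.
#' @return a shape table: list with `per_base` (named vectors over
#'   pentamers) and `per_step` (1024 x 2 matrices: left/right central-step
#'   contributions).
#' @export
make_shape_table <- function(seed = 1) {
  per_base <- lapply(PER_BASE_SHAPES, function(ty) {
    r <- SHAPE_RANGES[[ty]]
    v <- with_seed(child_seed(seed, paste0("shape_", ty)),
                   runif(1024, r[1], r[2]))
    names(v) <- ALL_PENTAMERS
    v
  })
  names(per_base) <- PER_BASE_SHAPES
  per_step <- lapply(PER_STEP_SHAPES, function(ty) {
    r <- SHAPE_RANGES[[ty]]
    m <- with_seed(child_seed(seed, paste0("shape_", ty)),
                   matrix(runif(2048, r[1], r[2]), 1024, 2))
    rownames(m) <- ALL_PENTAMERS
    colnames(m) <- c("step_left", "step_right")
    m
  })
  names(per_step) <- PER_STEP_SHAPES
  list(per_base = per_base, per_step = per_step)
}

#' Write / read a pentamer shape table (long TSV)
#'
#' Columns: `pentamer`, `shape_type`, `value_1`, `value_2`; per-base types
#' use `value_1` only, per-step types carry the left/right central-step
#' contributions.
#'
#' @param table a shape table.
#' @param path TSV path.
#' @export
write_shape_table <- function(table, path) {
  rows <- list()
  for (ty in PER_BASE_SHAPES) {
    rows[[ty]] <- data.frame(pentamer = ALL_PENTAMERS, shape_type = ty,
                             value_1 = unname(table$per_base[[ty]]),
                             value_2 = NA_real_)
  }
  for (ty in PER_STEP_SHAPES) {
    rows[[ty]] <- data.frame(pentamer = ALL_PENTAMERS, shape_type = ty,
                             value_1 = unname(table$per_step[[ty]][, 1]),
                             value_2 = unname(table$per_step[[ty]][, 2]))
  }
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_shape_table
#' @export
read_shape_table <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  per_base <- lapply(PER_BASE_SHAPES, function(ty) {
    s <- d[d$shape_type == ty, ]
    v <- s$value_1[match(ALL_PENTAMERS, s$pentamer)]
    names(v) <- ALL_PENTAMERS
    v
  })
  names(per_base) <- PER_BASE_SHAPES
  per_step <- lapply(PER_STEP_SHAPES, function(ty) {
    s <- d[d$shape_type == ty, ]
    i <- match(ALL_PENTAMERS, s$pentamer)
    m <- cbind(step_left = s$value_1[i], step_right = s$value_2[i])
    rownames(m) <- ALL_PENTAMERS
    m
  })
  names(per_step) <- PER_STEP_SHAPES
  validate_shape_table(list(per_base = per_base, per_step = per_step))
}

#' Generate synthetic per-nucleotide property tables
#'
#' Seeded pseudo-random NCP (3 x 4), EIIP (1 x 4), PCP (8 x 4) and the
#' canonical one-hot table, complete over ACGT.
#'
#' @param seed integer seed.
#' @return list as in [default_property_tables()].
#' @export
make_property_tables <- function(seed = 1) {
  tpl <- default_property_tables()
  rnd <- function(tag, nr) {
    m <- with_seed(child_seed(seed, tag), matrix(runif(nr * 4), nr, 4))
    colnames(m) <- VALID_NT
    m
  }
  list(ncp = {m <- rnd("ncp", 3); rownames(m) <- rownames(tpl$ncp); m},
       eiip = {m <- rnd("eiip", 1); rownames(m) <- "eiip"; m},
       pcp = {m <- rnd("pcp", 8); rownames(m) <- rownames(tpl$pcp); m},
       onehot = tpl$onehot)
}

#' Build a deterministic mock embedder adapter
#'
#' Each (model, nucleotide) pair maps to a fixed seeded vector of length
#' `dims`; `embed(model_id, seq)` returns the `dims x nchar(seq)` matrix
#' of per-position vectors, with NA columns at non-ACGT positions.
#'
#' @param seed integer seed.
#' @param n_models number of models (default 3).
#' @param dims dimensions per model (default 16).
#' @return an embedder adapter (list with `model_ids`, `dims`, `embed`,
#'   and the lookup `tables`).
#' @export
make_mock_embedder <- function(seed = 1, n_models = 3, dims = 16) {
  model_ids <- paste0("m", seq_len(n_models))
  tables <- lapply(model_ids, function(mid) {
    m <- sapply(VALID_NT, function(nt)
      with_seed(child_seed(seed, paste0("embed_", mid, "_", nt)),
                runif(dims, -1, 1)))
    m  # dims x 4
  })
  names(tables) <- model_ids
  embedder_from_tables(tables, dims)
}

embedder_from_tables <- function(tables, dims) {
  model_ids <- names(tables)
  list(model_ids = model_ids, dims = dims, tables = tables,
       embed = function(model_id, seq) {
         tb <- tables[[model_id]]
         if (is.null(tb)) stop("unknown embedder model: ", model_id)
         idx <- nt_index(seq)
         out <- matrix(NA_real_, dims, length(idx))
         ok <- !is.na(idx)
         out[, ok] <- tb[, idx[ok]]
         out
       })
}

#' Write / read an embedder lookup table (TSV)
#'
#' Columns: `model`, `nucleotide`, `d1` ... `d<dims>`.
#'
#' @param adapter adapter from [make_mock_embedder()].
#' @param path TSV path.
#' @export
write_embedder_table <- function(adapter, path) {
  rows <- do.call(rbind, lapply(adapter$model_ids, function(mid) {
    d <- as.data.frame(t(adapter$tables[[mid]]))
    names(d) <- paste0("d", seq_len(adapter$dims))
    cbind(data.frame(model = mid, nucleotide = VALID_NT), d)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_embedder_table
#' @export
read_embedder_table <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  dims <- sum(grepl("^d[0-9]+$", names(d)))
  models <- unique(d$model)
  tables <- lapply(models, function(mid) {
    s <- d[d$model == mid, ]
    m <- t(as.matrix(s[match(VALID_NT, s$nucleotide),
                       paste0("d", seq_len(dims))]))
    colnames(m) <- VALID_NT
    rownames(m) <- NULL
    m
  })
  names(tables) <- models
  embedder_from_tables(tables, dims)
}

gc_fraction <- function(seq_chars) mean(seq_chars %in% c("G", "C"))

#' Balanced label shuffle for null-signal diagnostics
#'
#' Produces a random relabelling with the same class counts whose sample
#' correlation with the original labels is exactly zero: half of each
#' class (rounded) keeps its label, half swaps. A plain permutation has a
#' chance class-overlap correlation of order `1/sqrt(n)` with the true
#' labels, which strongly separable features amplify into spurious
#' held-out signal; forcing zero overlap-bias makes the shuffled labels a
#' clean null against every feature.
#'
#' @param labels binary labels (driver/passenger or 1/0).
#' @param seed integer seed.
#' @return shuffled labels, same encoding and class counts as the input.
#' @export
balanced_label_shuffle <- function(labels, seed = 1) {
  y <- as_binary_labels(labels)
  i1 <- which(y == 1); i0 <- which(y == 0)
  k1 <- round(length(i1) / 2)            # positives staying positive
  k0 <- length(i1) - k1                  # negatives becoming positive
  if (k0 > length(i0)) stop("classes too unbalanced for a balanced shuffle")
  out <- integer(length(y))
  with_seed(seed, {
    out[sample(i1, k1)] <- 1L
    out[sample(i0, k0)] <- 1L
  })
  if (is.character(labels) || is.factor(labels)) {
    ifelse(out == 1, "driver", "passenger")
  } else out
}

#' Generate label-correlated variants and their annotation table
#'
#' Drivers are placed (rejection sampling, up to 200 tries per site) at
#' positions whose 11-nt local context has GC fraction at least
#' `0.5 + delta/3`, and their alternate allele is biased toward C/G with
#' probability `0.5 + delta/2`; each driver gets a passenger on the same
#' chromosome at distance 120-500 bp with uniform placement and uniform
#' alternate allele. Recurrence is 1 for passengers and uniform on 7..20
#' for drivers. Annotation columns are label-shifted Gaussians: drivers at
#' `+effect/2`, passengers at `-effect/2`, unit variance. With
#' `delta = 0` and `annotation_effect = 0` every feature is class-independent.
#'
#' @param config a [default_fixture_config()].
#' @param genome `DNAStringSet` from [make_genome()].
#' @return list with `variants` (data.frame incl. recurrence and label)
#'   and `annotations` (data.frame keyed by chrom/pos/ref/alt).
#' @export
make_labelled_variants <- function(config, genome) {
  flank <- config$flank
  chrom_names <- names(genome)
  chars <- lapply(chrom_names, function(cn)
    strsplit(as.character(genome[[cn]]), "")[[1]])
  names(chars) <- chrom_names
  gc_min <- 0.5 + config$delta / 3
  cg_prob <- 0.5 + config$delta / 2
  used <- new.env()
  res <- with_seed(child_seed(config$seed, "variants"), {
    rows <- list()
    for (i in seq_len(config$n_driver)) {
      cn <- chrom_names[(i - 1) %% length(chrom_names) + 1]
      cc <- chars[[cn]]
      L <- length(cc)
      lo <- flank + 1L
      hi <- L - flank - max(config$pair_distance)
      # driver site: local GC enrichment by rejection sampling
      best_pos <- NA; best_gc <- -1
      for (try in 1:200) {
        pos <- sample(lo:hi, 1)
        key <- paste0(cn, ":", pos)
        if (!is.null(used[[key]])) next
        gc <- gc_fraction(cc[(pos - 5):(pos + 5)])
        if (gc > best_gc) {best_gc <- gc; best_pos <- pos}
        if (gc >= gc_min || config$delta == 0) break
      }
      pos <- if (config$delta == 0) best_pos else
        if (best_gc >= gc_min) best_pos else best_pos  # best effort
      used[[paste0(cn, ":", pos)]] <- TRUE
      ref <- cc[pos]
      alt <- if (runif(1) < cg_prob && config$delta > 0) {
        cand <- setdiff(c("C", "G"), ref)
        if (length(cand) == 0) cand <- setdiff(VALID_NT, ref)
        sample(cand, 1)
      } else sample(setdiff(VALID_NT, ref), 1)
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = cn, pos = pos, ref = ref, alt = alt,
        recurrence = sample(7:20, 1), label = "driver",
        stringsAsFactors = FALSE)
      # matched passenger nearby
      for (try in 1:200) {
        off <- sample(config$pair_distance[1]:config$pair_distance[2], 1) *
          sample(c(-1L, 1L), 1)
        ppos <- pos + off
        key <- paste0(cn, ":", ppos)
        if (ppos >= flank + 1L && ppos <= L - flank && is.null(used[[key]])) {
          used[[key]] <- TRUE
          pref <- cc[ppos]
          rows[[length(rows) + 1L]] <- data.frame(
            chrom = cn, pos = ppos, ref = pref,
            alt = sample(setdiff(VALID_NT, pref), 1),
            recurrence = 1L, label = "passenger", stringsAsFactors = FALSE)
          break
        }
      }
    }
    # extra unpaired passengers if requested
    n_pas <- sum(vapply(rows, function(r) r$label == "passenger", TRUE))
    extra <- config$n_passenger - n_pas
    k <- 0L
    while (k < extra) {
      cn <- sample(chrom_names, 1)
      cc <- chars[[cn]]
      ppos <- sample((flank + 1L):(length(cc) - flank), 1)
      key <- paste0(cn, ":", ppos)
      if (!is.null(used[[key]])) next
      used[[key]] <- TRUE
      pref <- cc[ppos]
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = cn, pos = ppos, ref = pref,
        alt = sample(setdiff(VALID_NT, pref), 1),
        recurrence = 1L, label = "passenger", stringsAsFactors = FALSE)
      k <- k + 1L
    }
    do.call(rbind, rows)
  })
  res$id <- paste0("v", seq_len(nrow(res)))
  widths <- config$annotation_group_widths
  ncols <- sum(widths)
  shift <- ifelse(res$label == "driver", config$annotation_effect / 2,
                  -config$annotation_effect / 2)
  ann <- with_seed(child_seed(config$seed, "annotations"), {
    m <- matrix(rnorm(nrow(res) * ncols), nrow(res), ncols) + shift
    colnames(m) <- unlist(lapply(seq_along(widths), function(g)
      paste0(names(widths)[g], "_", seq_len(widths[g]))))
    m
  })
  annotations <- cbind(res[, c("chrom", "pos", "ref", "alt")],
                       as.data.frame(ann))
  list(variants = res, annotations = annotations)
}

#' Write a complete fixture bundle to disk
#'
#' Emits exactly the formats the pipeline consumes: `genome.fa`,
#' `variants.tsv` (chrom, pos, ref, alt, recurrence, label),
#' `annotations.tsv`, `shape_table.tsv`, `embedder.tsv`, and a
#' `fixture_config.yaml` snapshot.
#'
#' @param config a [default_fixture_config()].
#' @param dir output directory.
#' @return named list of written paths (invisibly).
#' @export
make_fixture_bundle <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  genome <- make_genome(config)
  vs <- make_labelled_variants(config, genome)
  paths <- list(
    genome = file.path(dir, "genome.fa"),
    variants = file.path(dir, "variants.tsv"),
    annotations = file.path(dir, "annotations.tsv"),
    shape_table = file.path(dir, "shape_table.tsv"),
    embedder = file.path(dir, "embedder.tsv"),
    config = file.path(dir, "fixture_config.yaml")
  )
  Biostrings::writeXStringSet(genome, paths$genome)
  utils::write.table(
    vs$variants[, c("chrom", "pos", "ref", "alt", "recurrence", "label")],
    paths$variants, sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = FALSE)
  utils::write.table(vs$annotations, paths$annotations, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_shape_table(make_shape_table(config$seed), paths$shape_table)
  write_embedder_table(
    make_mock_embedder(config$seed, config$n_models, config$embed_dims),
    paths$embedder)
  cfg <- unclass(config)
  cfg$annotation_group_widths <- as.list(cfg$annotation_group_widths)
  cfg$pair_distance <- as.list(cfg$pair_distance)
  yaml::write_yaml(cfg, paths$config)
  invisible(paths)
}
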
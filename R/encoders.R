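# Sequence-window feature encoders.
#
# Seven feature categories are produced per variant: basic annotations (4
# groups, joined from a precomputed table), DNA shape of the alternative
# allele (14 groups, pentamer lookup), DNA shape allele differences (14
# groups), physicochemical/one-hot of the alternative allele (4 groups),
# their allele differences (4 groups), embedding-derived features (3 groups)
# and embedding allele differences (3 groups) — 46 groups, 8,007 columns at
# the default 101-nt window.
#
# Missing-value semantics: any value whose support (pentamer, position,
# embedding input) contains N is NA; NAs survive until normalization, where
# they are imputed with training means.

PER_BASE_SHAPES <- c("shear", "stretch", "stagger", "buckle", "ProT",
                     "opening", "MGW", "EP")
PER_STEP_SHAPES <- c("shift", "slide", "rise", "tilt", "roll", "HelT")
ALL_SHAPES <- c(PER_BASE_SHAPES, PER_STEP_SHAPES)

ALL_PENTAMERS <- local({
  nt <- c("A", "C", "G", "T")
  g <- expand.grid(p5 = nt, p4 = nt, p3 = nt, p2 = nt, p1 = nt,
                   stringsAsFactors = FALSE)
  paste0(g$p1, g$p2, g$p3, g$p4, g$p5)
})

# map a sequence string to nucleotide indices 1..4 (A,C,G,T), NA otherwise
nt_index <- function(seq) {
  m <- match(strsplit(seq, "")[[1]], VALID_NT)
  m
}

# pentamer ids (1..1024, base-4 big-endian) for centres 3..L-2; NA if the
# pentamer contains a non-ACGT base
pentamer_ids <- function(idx) {
  L <- length(idx)
  centers <- 3:(L - 2)
  id <- (idx[centers - 2] - 1L) * 256L + (idx[centers - 1] - 1L) * 64L +
    (idx[centers] - 1L) * 16L + (idx[centers + 1] - 1L) * 4L +
    (idx[centers + 2] - 1L) + 1L
  id
}

new_block <- function(group, category, values) {
  structure(list(group_name = group, category = category,
                 values = as.numeric(values)),
            class = "feature_block")
}

#' Default per-nucleotide property tables
#'
#' Bundles the four per-nucleotide encodings used by the physicochemical
#' encoders: `ncp` (3-bit chemical-property code: ring structure, hydrogen
#' bonding strength, chemical functionality), `eiip` (electron-ion
#' interaction pseudopotential scalar), `pcp` (8 physical properties per
#' base; the property set is configuration — these defaults are the
#' package's documented reference values) and `onehot` (canonical basis).
#' All tables are matrices with columns A, C, G, T.
#'
#' @return list with elements `ncp` (3x4), `eiip` (1x4), `pcp` (8x4),
#'   `onehot` (4x4).
#' @export
default_property_tables <- function() {
  list(
    ncp = matrix(c(1, 1, 1,   0, 1, 0,   1, 0, 0,   0, 0, 1), 3, 4,
                 dimnames = list(c("ring", "hbond", "functional"), VALID_NT)),
    eiip = matrix(c(0.1260, 0.1340, 0.0806, 0.1335), 1, 4,
                  dimnames = list("eiip", VALID_NT)),
    pcp = matrix(c(
      # A        C        G        T
      135.13, 111.10, 151.13, 126.11,   # molar mass (g/mol)
      360.00, 320.00, 360.00, 335.00,   # melting point (K)
      0.30,   0.79,   1.27,   0.55,     # water solubility (g/100 mL)
      4.15,   4.45,   3.30,   9.90,     # pKa
      1,      2,      2,      1,        # H-bond donor count
      3,      3,      4,      2,        # H-bond acceptor count
      10,     6,      11,     6,        # ring atoms
      -0.09, -1.73,  -0.96,  -0.62      # logP
    ), 8, 4, byrow = TRUE,
    dimnames = list(c("mass", "melting", "solubility", "pKa", "hb_donor",
                      "hb_acceptor", "ring_atoms", "logP"), VALID_NT)),
    onehot = diag(4)[, , drop = FALSE] |>
      (\(m) {dimnames(m) <- list(VALID_NT, VALID_NT); m})()
  )
}

validate_property_tables <- function(tables) {
  for (nm in c("ncp", "eiip", "pcp", "onehot")) {
    tb <- tables[[nm]]
    if (is.null(tb) || !all(VALID_NT %in% colnames(tb)))
      stop("property table '", nm, "' must cover nucleotides A, C, G, T")
  }
  if (nrow(tables$pcp) != 8) stop("pcp table must have 8 properties")
  if (nrow(tables$ncp) != 3) stop("ncp table must have 3 properties")
  invisible(tables)
}

window_seq <- function(window, allele = c("alt", "ref")) {
  allele <- match.arg(allele)
  if (allele == "alt") window$alt_seq else window$ref_seq
}

# encode a sequence with a per-nucleotide table (rows = properties), in
# position-major layout; non-ACGT positions become NA
encode_table_seq <- function(seq, table) {
  idx <- nt_index(seq)
  v <- table[, idx, drop = FALSE]          # properties x L, NA col for N
  v[, is.na(idx)] <- NA_real_
  as.numeric(v)                            # column- (position-) major
}

#' One-hot encode a window sequence
#'
#' @param window a `seq_window`.
#' @param allele `"alt"` (default) or `"ref"`.
#' @return a feature block of length `4 * L` (position-major).
#' @export
encode_onehot <- function(window, allele = c("alt", "ref")) {
  seq <- window_seq(window, match.arg(allele))
  new_block("onehot_alt", "physchem-alt",
            encode_table_seq(seq, default_property_tables()$onehot))
}

#' Physicochemical encodings of a window sequence
#'
#' NCP (3 values/position), EIIP (1/position) and PCP (8/position), each a
#' separate feature group; 303 + 101 + 808 values at L = 101.
#'
#' @param window a `seq_window`.
#' @param allele `"alt"` or `"ref"`.
#' @param tables property tables, see [default_property_tables()].
#' @return list of three feature blocks (`ncp_alt`, `eiip_alt`, `pcp_alt`).
#' @export
encode_physchem <- function(window, allele = c("alt", "ref"),
                            tables = default_property_tables()) {
  validate_property_tables(tables)
  seq <- window_seq(window, match.arg(allele))
  list(new_block("ncp_alt", "physchem-alt", encode_table_seq(seq, tables$ncp)),
       new_block("eiip_alt", "physchem-alt", encode_table_seq(seq, tables$eiip)),
       new_block("pcp_alt", "physchem-alt", encode_table_seq(seq, tables$pcp)))
}

#' Allele-difference physicochemical features
#'
#' Only the variant position differs between alleles, so the difference
#' reduces to alt-row minus ref-row of each table at the centre base:
#' widths 4 (one-hot) + 3 (NCP) + 1 (EIIP) + 8 (PCP) = 16.
#'
#' @inheritParams encode_physchem
#' @return list of four feature blocks.
#' @export
encode_physchem_diff <- function(window, tables = default_property_tables()) {
  validate_property_tables(tables)
  ref <- window$ref
  alt <- window$alt
  diff_of <- function(tb) tb[, alt] - tb[, ref]
  list(new_block("onehot_diff", "physchem-diff", diff_of(tables$onehot)),
       new_block("ncp_diff", "physchem-diff", diff_of(tables$ncp)),
       new_block("eiip_diff", "physchem-diff", diff_of(tables$eiip)),
       new_block("pcp_diff", "physchem-diff", diff_of(tables$pcp)))
}

validate_shape_table <- function(table) {
  for (ty in PER_BASE_SHAPES) {
    if (is.null(table$per_base[[ty]]) || length(table$per_base[[ty]]) != 1024)
      stop("shape table incomplete for per-base type ", ty)
  }
  for (ty in PER_STEP_SHAPES) {
    if (is.null(table$per_step[[ty]]) || nrow(table$per_step[[ty]]) != 1024)
      stop("shape table incomplete for per-step type ", ty)
  }
  invisible(table)
}

# core pentamer-lookup encoder for one sequence: returns list of named
# numeric vectors, one per shape type
shape_encode_seq <- function(seq, table) {
  idx <- nt_index(seq)
  L <- length(idx)
  if (L < 5) stop("window too short for pentamer encoding (need >= 5)")
  pid <- pentamer_ids(idx)              # centres 3..L-2
  out <- list()
  for (ty in PER_BASE_SHAPES) {
    out[[ty]] <- unname(table$per_base[[ty]][pid])
  }
  # step s (joining positions s, s+1), s = 2..L-2:
  #   left contribution from pentamer centred at s+1 (its left central step)
  #   right contribution from pentamer centred at s (its right central step)
  n_steps <- L - 3
  centers <- 3:(L - 2)
  for (ty in PER_STEP_SHAPES) {
    m <- table$per_step[[ty]]
    left <- rep(NA_real_, n_steps)      # indexed by s - 1, s in 2..L-2
    right <- rep(NA_real_, n_steps)
    # pentamer centred at c: left step c-1 -> slot c-2; right step c -> slot c-1
    left[centers - 2] <- m[pid, 1]
    right_slots <- centers - 1
    keep <- right_slots <= n_steps
    right[right_slots[keep]] <- m[pid[keep], 2]
    both <- !is.na(left) & !is.na(right)
    vals <- ifelse(both, (left + right) / 2,
                   ifelse(is.na(left), right, left))
    out[[ty]] <- vals
  }
  out
}

#' DNA shape features of a window sequence
#'
#' Pentamer-lookup shape encoding: for the 8 per-base shape types one value
#' per position 3..L-2 (L-4 values each); for the 6 per-step types one value
#' per base step 2..L-2 (L-3 values each), averaging the contributions of
#' the one or two pentamers whose central steps cover that step. At L = 101
#' this yields 8*97 + 6*98 = 1,364 values across 14 groups. Pentamers
#' containing N contribute missing values.
#'
#' @param window a `seq_window`.
#' @param allele `"alt"` or `"ref"`.
#' @param table a pentamer shape table, see [make_shape_table()].
#' @return list of 14 feature blocks (one per shape type).
#' @export
encode_shape <- function(window, allele = c("alt", "ref"), table) {
  validate_shape_table(table)
  seq <- window_seq(window, match.arg(allele))
  enc <- shape_encode_seq(seq, table)
  lapply(ALL_SHAPES, function(ty)
    new_block(paste0("shape_alt_", ty), "shape-alt", enc[[ty]]))
}

#' Allele-difference DNA shape features
#'
#' The alt-minus-ref shape difference restricted to the coordinates whose
#' pentamer support overlaps the variant: per-base positions centre +/- 2
#' (5 per type) and steps centre-3 .. centre+2 (6 per type), 8*5 + 6*6 = 76
#' values across 14 groups. Outside these coordinates the full-vector
#' difference is identically zero.
#'
#' @inheritParams encode_shape
#' @return list of 14 feature blocks.
#' @export
encode_shape_diff <- function(window, table) {
  validate_shape_table(table)
  enc_ref <- shape_encode_seq(window$ref_seq, table)
  enc_alt <- shape_encode_seq(window$alt_seq, table)
  m <- window$center + 1L               # 1-based variant position
  L <- nchar(window$ref_seq)
  pb_pos <- (m - 2):(m + 2)             # per-base positions touched
  pb_idx <- pb_pos - 2                  # vector slot of position c is c - 2
  st_pos <- (m - 3):(m + 2)             # steps touched
  st_idx <- st_pos - 1                  # vector slot of step s is s - 1
  if (any(pb_idx < 1) || any(pb_idx > L - 4) ||
      any(st_idx < 1) || any(st_idx > L - 3)) {
    stop("window too short to hold all variant-overlapping pentamers (need L >= 9, centred variant)")
  }
  out <- list()
  for (ty in PER_BASE_SHAPES) {
    out <- c(out, list(new_block(paste0("shape_diff_", ty), "shape-diff",
                                 enc_alt[[ty]][pb_idx] - enc_ref[[ty]][pb_idx])))
  }
  for (ty in PER_STEP_SHAPES) {
    out <- c(out, list(new_block(paste0("shape_diff_", ty), "shape-diff",
                                 enc_alt[[ty]][st_idx] - enc_ref[[ty]][st_idx])))
  }
  out
}

validate_adapter <- function(adapter) {
  stopifnot(is.list(adapter), !is.null(adapter$model_ids),
            !is.null(adapter$dims), is.function(adapter$embed))
  invisible(adapter)
}

#' Per-position embedding of an adapter at one position
#'
#' Convenience accessor: the `dims`-long embedding vector of `model_id` for
#' the given window sequence at a 1-based position.
#'
#' @param adapter an embedder adapter (see [make_mock_embedder()]).
#' @param model_id one of `adapter$model_ids`.
#' @param seq sequence string.
#' @param position 1-based position.
#' @export
embed_at <- function(adapter, model_id, seq, position) {
  adapter$embed(model_id, seq)[, position]
}

#' Embedding-derived features of a window sequence
#'
#' One feature group per embedding model: the model's per-position vectors
#' concatenated position-major (`dims * L` values; 16 * 101 = 1,616 per
#' model, 4,848 over the default three models).
#'
#' @param window a `seq_window`.
#' @param allele `"alt"` or `"ref"`.
#' @param adapter embedder adapter with `model_ids`, `dims` and
#'   `embed(model_id, seq)` returning a `dims x L` matrix (NA columns for N).
#' @return list of feature blocks, one per model.
#' @export
encode_embedding <- function(window, allele = c("alt", "ref"), adapter) {
  validate_adapter(adapter)
  seq <- window_seq(window, match.arg(allele))
  L <- nchar(seq)
  lapply(adapter$model_ids, function(mid) {
    e <- adapter$embed(mid, seq)
    if (!is.matrix(e) || nrow(e) != adapter$dims || ncol(e) != L)
      stop("embedder contract violated for model ", mid,
           ": expected ", adapter$dims, " x ", L, " matrix")
    new_block(paste0("embed_alt_", mid), "embed-alt", as.numeric(e))
  })
}

#' Allele-difference embedding features
#'
#' Alt-embedding minus ref-embedding at the variant position only: `dims`
#' values per model (48 over three 16-dim models).
#'
#' @inheritParams encode_embedding
#' @return list of feature blocks, one per model.
#' @export
encode_embedding_diff <- function(window, adapter) {
  validate_adapter(adapter)
  pos <- window$center + 1L
  lapply(adapter$model_ids, function(mid) {
    er <- adapter$embed(mid, window$ref_seq)
    ea <- adapter$embed(mid, window$alt_seq)
    if (!is.matrix(ea) || nrow(ea) != adapter$dims)
      stop("embedder contract violated for model ", mid)
    new_block(paste0("embed_diff_", mid), "embed-diff", ea[, pos] - er[, pos])
  })
}

#' Join precomputed annotation features to variants
#'
#' The annotation table stands in for upstream per-variant scores (sequence
#' context, conservation, functional predictors, splicing). It is keyed by
#' `chrom`, `pos`, `ref`, `alt`; remaining numeric columns are partitioned
#' in order into four groups by `group_widths`. Variants absent from the
#' table receive an all-missing row (mean-imputed at normalization).
#'
#' @param variants data.frame with the key columns.
#' @param table annotation data.frame (or TSV path) with key + value columns.
#' @param group_widths named integer vector partitioning the value columns;
#'   must sum to the number of value columns.
#' @return list (one element per variant) of lists of 4 feature blocks.
#' @export
attach_annotations <- function(variants, table,
                               group_widths = c(annot_sequence = 10,
                                                annot_conservation = 10,
                                                annot_functional = 12,
                                                annot_splicing = 7)) {
  if (is.character(table)) {
    table <- utils::read.delim(table, stringsAsFactors = FALSE)
  }
  keycols <- c("chrom", "pos", "ref", "alt")
  if (!all(keycols %in% names(table))) stop("annotation table must have columns chrom, pos, ref, alt")
  valcols <- setdiff(names(table), keycols)
  if (sum(group_widths) != length(valcols)) {
    stop("group widths sum to ", sum(group_widths), " but table has ",
         length(valcols), " value columns")
  }
  key <- function(df) paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")
  ridx <- match(key(variants), key(table))
  ends <- cumsum(group_widths)
  starts <- ends - group_widths + 1
  lapply(seq_len(nrow(variants)), function(i) {
    row <- if (is.na(ridx[i])) rep(NA_real_, length(valcols)) else
      as.numeric(table[ridx[i], valcols])
    lapply(seq_along(group_widths), function(g) {
      new_block(names(group_widths)[g], "basic-annotation",
                row[starts[g]:ends[g]])
    })
  })
}
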
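# Reading variants (VCF / TSV), genome access, allele-specific window
# extraction and scored output. Coordinates are 1-based inclusive (VCF
# convention); window-internal indices are 0-based.

VALID_NT <- c("A", "C", "G", "T")

#' Read single-nucleotide variants from a VCF or TSV file
#'
#' Accepts a minimal VCF (CHROM/POS/ID/REF/ALT columns) or a headerless
#' 4-6 column TSV: chromosome, position, reference allele, alternate allele,
#' optional recurrence count, optional label. Rows whose REF or ALT is not a
#' single canonical nucleotide (indels, MNVs, ambiguity codes) are skipped
#' with a warning; the number skipped is recorded in the `n_skipped`
#' attribute of the result.
#'
#' @param path path to the variant file.
#' @param format `"vcf"`, `"tsv"`, or `"auto"` (by file extension).
#' @return a `data.frame` with columns `chrom`, `pos`, `ref`, `alt`, `id`,
#'   `recurrence`, `label`; attribute `n_skipped` counts excluded rows.
#' @export
read_variants <- function(path, format = c("auto", "vcf", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read variant file: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "tsv"
  }
  if (format == "vcf") {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(v)
    if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
    df <- data.frame(
      chrom = as.character(fix[, "CHROM"]),
      pos = as.integer(fix[, "POS"]),
      ref = toupper(as.character(fix[, "REF"])),
      alt = toupper(as.character(fix[, "ALT"])),
      id = as.character(fix[, "ID"]),
      recurrence = NA_integer_,
      label = NA_character_,
      stringsAsFactors = FALSE
    )
  } else {
    raw <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                             colClasses = "character", comment.char = "#")
    if (nrow(raw) > 0 && is.na(suppressWarnings(as.integer(raw[1, 2])))) {
      raw <- raw[-1, , drop = FALSE]   # tolerate a header line
    }
    if (ncol(raw) < 4) stop("TSV variant file needs at least 4 columns")
    df <- data.frame(
      chrom = raw[, 1],
      pos = suppressWarnings(as.integer(raw[, 2])),
      ref = toupper(raw[, 3]),
      alt = toupper(raw[, 4]),
      id = if (ncol(raw) >= 7) raw[, 7] else NA_character_,
      recurrence = if (ncol(raw) >= 5) suppressWarnings(as.integer(raw[, 5])) else NA_integer_,
      label = if (ncol(raw) >= 6) raw[, 6] else NA_character_,
      stringsAsFactors = FALSE
    )
  }
  ok <- df$ref %in% VALID_NT & df$alt %in% VALID_NT & df$ref != df$alt &
    !is.na(df$pos) & df$pos >= 1
  n_skipped <- sum(!ok)
  if (n_skipped > 0) {
    warning(n_skipped, " non-SNV or malformed row(s) skipped")
  }
  df <- df[ok, , drop = FALSE]
  if (nrow(df) == 0) stop("no parsable SNV rows in ", path)
  rownames(df) <- NULL
  attr(df, "n_skipped") <- n_skipped
  df
}

#' Load a genome from FASTA
#'
#' Reads a FASTA file into a [Biostrings::DNAStringSet], truncating record
#' names at the first whitespace so they match VCF-style chromosome names.
#'
#' @param path FASTA file path.
#' @return a `DNAStringSet` keyed by chromosome name.
#' @export
read_genome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Extract an allele-specific sequence window around a variant
#'
#' Takes the reference sequence `pos - flank ... pos + flank` (1-based,
#' inclusive) and builds the alternative-allele sequence by substituting the
#' centre base. The genome base at `pos` must equal the variant's reference
#' allele; windows running past a chromosome end are an error (no padding).
#'
#' @param genome a `DNAStringSet` (see [read_genome()]) or FASTA path.
#' @param variant one-row data.frame (or list) with `chrom`, `pos`, `ref`, `alt`.
#' @param flank half-width of the window (default 50, i.e. 101-nt windows).
#' @return an object of class `seq_window`: list with `chrom`, `pos`, `ref`,
#'   `alt`, `flank`, `ref_seq`, `alt_seq` and the 0-based `center` index.
#' @export
extract_window <- function(genome, variant, flank = 50L) {
  if (is.character(genome)) genome <- read_genome(genome)
  chrom <- as.character(variant$chrom)
  pos <- as.integer(variant$pos)
  ref <- toupper(as.character(variant$ref))
  alt <- toupper(as.character(variant$alt))
  if (!chrom %in% names(genome)) stop("chromosome not in genome: ", chrom)
  clen <- Biostrings::width(genome[chrom])
  if (pos - flank < 1L || pos + flank > clen) {
    stop("window [", pos - flank, ", ", pos + flank, "] overruns chromosome ",
         chrom, " (length ", clen, ")")
  }
  ref_seq <- toupper(as.character(Biostrings::subseq(genome[[chrom]],
                                                     start = pos - flank,
                                                     end = pos + flank)))
  center <- flank  # 0-based index of the variant base
  genome_base <- substr(ref_seq, center + 1L, center + 1L)
  if (genome_base != ref) {
    stop("reference mismatch at ", chrom, ":", pos, ": genome has ",
         genome_base, ", variant says ", ref)
  }
  alt_seq <- ref_seq
  substr(alt_seq, center + 1L, center + 1L) <- alt
  structure(list(chrom = chrom, pos = pos, ref = ref, alt = alt,
                 flank = as.integer(flank), ref_seq = ref_seq,
                 alt_seq = alt_seq, center = center),
            class = "seq_window")
}

#' Extract windows for a variant table
#'
#' Vectorised convenience over [extract_window()]. Variants whose window
#' cannot be extracted are dropped with a warning when `on_error = "drop"`,
#' or raise the underlying error when `on_error = "stop"`.
#'
#' @param genome `DNAStringSet` or FASTA path.
#' @param variants data.frame from [read_variants()].
#' @param flank window half-width.
#' @param on_error `"stop"` or `"drop"`.
#' @return list with `windows` (list of `seq_window`) and `kept` (row indices).
#' @export
extract_windows <- function(genome, variants, flank = 50L,
                            on_error = c("stop", "drop")) {
  on_error <- match.arg(on_error)
  if (is.character(genome)) genome <- read_genome(genome)
  windows <- vector("list", nrow(variants))
  kept <- logical(nrow(variants))
  for (i in seq_len(nrow(variants))) {
    w <- tryCatch(extract_window(genome, variants[i, ], flank),
                  error = function(e) e)
    if (inherits(w, "error")) {
      if (on_error == "stop") stop(w)
      kept[i] <- FALSE
    } else {
      windows[[i]] <- w
      kept[i] <- TRUE
    }
  }
  if (any(!kept)) warning(sum(!kept), " window(s) dropped during extraction")
  list(windows = windows[kept], kept = which(kept))
}

#' Write variant scores as a TSV
#'
#' Emits one row per variant with its score in `[0, 1]` and the thresholded
#' label: `driver` iff score strictly exceeds 0.5, else `passenger`.
#'
#' @param variants data.frame with `chrom`, `pos`, `ref`, `alt`.
#' @param scores numeric vector in `[0,1]`, same length as `nrow(variants)`.
#' @param path output path.
#' @param threshold decision threshold (default 0.5, strict inequality).
#' @return invisibly, the written data.frame.
#' @export
write_scores <- function(variants, scores, path, threshold = 0.5) {
  if (nrow(variants) != length(scores)) {
    stop("length mismatch: ", nrow(variants), " variants vs ",
         length(scores), " scores")
  }
  out <- data.frame(
    chrom = variants$chrom, pos = variants$pos,
    ref = variants$ref, alt = variants$alt,
    score = sprintf("%.6f", scores),
    predicted_label = ifelse(scores > threshold, "driver", "passenger"),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
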
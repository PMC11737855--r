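# Shared in-code fixtures for the test suite. Everything is generated
# programmatically; nothing is read from disk except files the tests
# themselves write to tempdir().

# construct a seq_window directly from a reference sequence string
test_window <- function(ref_seq, alt = NULL, center = (nchar(ref_seq) - 1) %/% 2,
                        chrom = "chrT", pos = center + 1L) {
  ref <- substr(ref_seq, center + 1, center + 1)
  if (is.null(alt)) alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
  alt_seq <- ref_seq
  substr(alt_seq, center + 1, center + 1) <- alt
  structure(list(chrom = chrom, pos = pos, ref = ref, alt = alt,
                 flank = as.integer(center), ref_seq = ref_seq,
                 alt_seq = alt_seq, center = as.integer(center)),
            class = "seq_window")
}

# deterministic random window of odd length L over ACGT
random_window <- function(L = 101, seed = 1, alt = NULL) {
  s <- ssnvStack:::with_seed(seed, paste(sample(c("A", "C", "G", "T"), L,
                                                replace = TRUE),
                                         collapse = ""))
  test_window(s, alt = alt)
}

# a window whose "alt" equals "ref" (forced degenerate case for the
# difference encoders; bypasses the variant invariant on purpose)
identical_allele_window <- function(L = 101, seed = 1) {
  w <- random_window(L, seed)
  w$alt <- w$ref
  w$alt_seq <- w$ref_seq
  w
}

test_shape_table <- function(seed = 42) make_shape_table(seed)
test_adapter <- function(seed = 42) make_mock_embedder(seed)

# small labelled feature matrix with a planted signal, for selection and
# stacking tests: `p_signal` informative columns (class shift `delta`),
# `p_noise` uniform-noise columns
planted_matrix <- function(n = 120, p_signal = 3, p_noise = 7, delta = 1.2,
                           seed = 1) {
  ssnvStack:::with_seed(seed, {
    y <- rep(c(1, 0), length.out = n)
    xs <- matrix(stats::rnorm(n * p_signal), n, p_signal) +
      delta * (y - 0.5)
    xn <- matrix(stats::runif(n * p_noise), n, p_noise)
    x <- cbind(xs, xn)
    colnames(x) <- c(paste0("sig", seq_len(p_signal)),
                     paste0("noise", seq_len(p_noise)))
    list(x = x, y = y)
  })
}

# tiny genome + matching variants written to tempfiles for the IO tests
write_tiny_genome <- function(seqs, path = tempfile(fileext = ".fa")) {
  g <- Biostrings::DNAStringSet(seqs)
  names(g) <- names(seqs)
  Biostrings::writeXStringSet(g, path)
  path
}
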
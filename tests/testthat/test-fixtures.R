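# Deterministic synthetic fixtures: genome, tables, embedders, variants.

test_that("genome generation is deterministic with uniform composition", {
  cfg <- default_fixture_config(seed = 3, n_chromosomes = 3,
                                chromosome_length = 100000L)
  g1 <- make_genome(cfg)
  g2 <- make_genome(cfg)
  expect_equal(length(g1), 3)
  expect_identical(as.character(g1), as.character(g2))
  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  Biostrings::writeXStringSet(g1, f1)
  Biostrings::writeXStringSet(g2, f2)
  expect_identical(readLines(f1), readLines(f2))   # byte-identical FASTA
  freq <- Biostrings::alphabetFrequency(g1[[1]], as.prob = TRUE)
  expect_true(all(abs(freq[c("A", "C", "G", "T")] - 0.25) < 0.01))
  # different seeds give different genomes
  g3 <- make_genome(default_fixture_config(seed = 4, n_chromosomes = 3,
                                           chromosome_length = 100000L))
  expect_false(identical(as.character(g1), as.character(g3)))
})

test_that("shape tables are complete, seed-sensitive and file-stable", {
  t1 <- make_shape_table(1)
  for (ty in names(t1$per_base)) expect_length(t1$per_base[[ty]], 1024)
  for (ty in names(t1$per_step)) expect_equal(dim(t1$per_step[[ty]]),
                                              c(1024L, 2L))
  t2 <- make_shape_table(2)
  expect_false(identical(t1$per_base$MGW, t2$per_base$MGW))
  path <- tempfile(fileext = ".tsv")
  write_shape_table(t1, path)
  rt <- read_shape_table(path)
  for (ty in names(t1$per_base)) expect_equal(rt$per_base[[ty]],
                                              t1$per_base[[ty]])
  for (ty in names(t1$per_step)) expect_equal(unname(rt$per_step[[ty]]),
                                              unname(t1$per_step[[ty]]))
})

test_that("property tables cover ACGT with the forced PCP width", {
  tb <- make_property_tables(5)
  expect_equal(colnames(tb$pcp), c("A", "C", "G", "T"))
  expect_equal(nrow(tb$pcp), 8)
  expect_equal(nrow(tb$ncp), 3)
  expect_equal(dim(tb$onehot), c(4L, 4L))
  expect_false(identical(make_property_tables(6)$pcp, tb$pcp))
})

test_that("the mock embedder is deterministic with distinct nucleotide
           vectors", {
  ad <- make_mock_embedder(9)
  expect_equal(ad$dims, 16)
  expect_length(ad$model_ids, 3)
  e1 <- ad$embed("m1", "ACGT")
  e2 <- ad$embed("m1", "ACGT")
  expect_identical(e1, e2)
  expect_equal(dim(e1), c(16L, 4L))
  # all four nucleotide vectors distinct (per model)
  expect_equal(ncol(unique(t(e1))), 16)
  expect_length(unique(apply(e1, 2, paste, collapse = ",")), 4)
  # per-position accessor agrees with the matrix form
  expect_equal(embed_at(ad, "m1", "ACGT", 3), e1[, 3])
  # N positions are missing
  eN <- ad$embed("m2", "ANG")
  expect_true(all(is.na(eN[, 2])))
  expect_false(anyNA(eN[, c(1, 3)]))
  # table round-trip preserves the embedding exactly
  path <- tempfile(fileext = ".tsv")
  write_embedder_table(ad, path)
  rt <- read_embedder_table(path)
  expect_equal(rt$embed("m1", "ACGT"), e1)
})

test_that("labelled variants match the configured class structure", {
  cfg <- default_fixture_config(seed = 17, n_driver = 40, n_passenger = 40,
                                chromosome_length = 30000L)
  g <- make_genome(cfg)
  vs <- make_labelled_variants(cfg, g)
  v <- vs$variants
  expect_equal(sum(v$label == "driver"), 40)
  expect_equal(sum(v$label == "passenger"), 40)
  expect_true(all(v$recurrence[v$label == "driver"] >= 7))
  expect_true(all(v$recurrence[v$label == "passenger"] == 1))
  # reference alleles agree with the genome
  for (i in sample(nrow(v), 10)) {
    expect_equal(substr(as.character(g[[v$chrom[i]]]), v$pos[i], v$pos[i]),
                 v$ref[i])
  }
  # planted compositional signal: driver contexts are GC-enriched
  gcloc <- function(chrom, pos) {
    s <- substr(as.character(g[[chrom]]), pos - 5, pos + 5)
    mean(strsplit(s, "")[[1]] %in% c("G", "C"))
  }
  gc_d <- mapply(gcloc, v$chrom[v$label == "driver"], v$pos[v$label == "driver"])
  gc_p <- mapply(gcloc, v$chrom[v$label == "passenger"],
                 v$pos[v$label == "passenger"])
  expect_gt(mean(gc_d), mean(gc_p) + 0.1)
  # annotation table is keyed to the variants with 39 value columns
  expect_equal(nrow(vs$annotations), nrow(v))
  expect_equal(ncol(vs$annotations), 4 + 39)
  # full determinism
  vs2 <- make_labelled_variants(cfg, g)
  expect_identical(vs$variants, vs2$variants)
  expect_identical(vs$annotations, vs2$annotations)
})

test_that("the null configuration removes every planted signal", {
  cfg <- default_fixture_config(seed = 19, n_driver = 30, n_passenger = 30,
                                chromosome_length = 30000L, delta = 0,
                                annotation_effect = 0)
  g <- make_genome(cfg)
  vs <- make_labelled_variants(cfg, g)
  ann <- as.matrix(vs$annotations[, -(1:4)])
  d <- vs$variants$label == "driver"
  # no annotation shift between classes
  expect_lt(abs(mean(ann[d, ]) - mean(ann[!d, ])), 0.15)
})

test_that("balanced label shuffles preserve counts with exactly half overlap", {
  y <- rep(c("driver", "passenger"), each = 100)
  s <- balanced_label_shuffle(y, seed = 5)
  expect_equal(sum(s == "driver"), 100)
  expect_equal(mean(s == y), 0.5)
  s2 <- balanced_label_shuffle(y, seed = 6)
  expect_false(identical(s, s2))
  yb <- rep(c(1, 0), each = 50)
  sb <- balanced_label_shuffle(yb, seed = 7)
  expect_equal(sum(sb), 50)
  expect_equal(mean(sb == yb), 0.5)
})

test_that("fixture bundles write every pipeline input format", {
  dir <- tempfile("bundle")
  cfg <- default_fixture_config(seed = 23, n_driver = 5, n_passenger = 5,
                                chromosome_length = 5000L)
  paths <- make_fixture_bundle(cfg, dir)
  for (p in paths) expect_true(file.exists(p))
  g <- read_genome(paths$genome)
  expect_equal(length(g), cfg$n_chromosomes)
  expect_warning(v <- read_variants(paths$variants, "tsv"), NA)
  expect_equal(nrow(v), 10)
  expect_true(all(v$label %in% c("driver", "passenger")))
  st <- read_shape_table(paths$shape_table)
  expect_length(st$per_base$MGW, 1024)
  cfg2 <- yaml::read_yaml(paths$config)
  expect_equal(cfg2$seed, 23)
})
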
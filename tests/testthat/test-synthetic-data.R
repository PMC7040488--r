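test_that("identical configurations give identical bundles", {
  a <- generate_dataset(tiny_config(rng_seed = 7))
  b <- generate_dataset(tiny_config(rng_seed = 7))
  expect_identical(a$mrna$values, b$mrna$values)
  expect_identical(a$mirna$values, b$mirna$values)
  expect_identical(a$sequences, b$sequences)
  expect_identical(a$truth, b$truth)
  expect_identical(a$reads, b$reads)
  c <- generate_dataset(tiny_config(rng_seed = 8))
  expect_false(identical(a$mrna$values, c$mrna$values))
})

test_that("matrix dimensions follow the configured design", {
  d <- generate_dataset(simulation_config(n_mrna = 200, n_lncrna = 20,
                                          n_mirna = 12, n_triplets = 5,
                                          rng_seed = 2),
                        include_reads = FALSE)
  expect_equal(dim(d$mrna$values), c(200, 9))
  expect_equal(dim(d$lncrna$values), c(20, 9))
  expect_equal(dim(d$mirna$values), c(12, 9))
  expect_equal(unique(d$mrna$samples$group), c("30d", "60d", "90d"))
  expect_equal(length(d$sequences$mrna), 200)
})

test_that("invalid configurations fail naming the violated field", {
  expect_error(simulation_config(n_triplets = 50, n_mirna = 10),
               "n_triplets")
  expect_error(simulation_config(repression_r = 0.5), "repression_r")
  expect_error(simulation_config(n_mrna = 0), "n_mrna")
  expect_error(simulation_config(dispersion = 0), "dispersion")
  expect_error(simulation_config(frac_bad_reads = 2), "frac_bad_reads")
})

test_that("planted targets carry the partner seed site and background is seed-free", {
  d <- generate_dataset(tiny_config(), include_reads = FALSE)
  tr <- d$truth$planted_triplets
  tx <- c(d$sequences$mrna, d$sequences$lncrna)
  for (i in seq_len(nrow(tr))) {
    mseq <- d$sequences$mirna[[tr$mirna_id[i]]]
    for (tid in c(tr$mrna_id[i], tr$lncrna_id[i])) {
      hits <- oracle_seed_sites(mseq, tx[[tid]])
      expect_gt(nrow(hits), 0)
      expect_true("8mer" %in% hits$site_type)
    }
  }
  planted_tx <- c(tr$mrna_id, tr$lncrna_id)
  planted_mir <- unique(d$truth$planted_de$feature_id[
    d$truth$planted_de$feature_class == "miRNA"])
  for (tid in setdiff(names(tx), planted_tx)) {
    for (mid in planted_mir) {
      expect_equal(nrow(oracle_seed_sites(d$sequences$mirna[[mid]],
                                          tx[[tid]])), 0)
    }
  }
})

test_that("recorded planted site coordinates classify as 8mers", {
  d <- generate_dataset(tiny_config(), include_reads = FALSE)
  ps <- d$truth$planted_sites
  tx <- c(d$sequences$mrna, d$sequences$lncrna)
  for (i in seq_len(nrow(ps))) {
    found <- find_seed_sites(d$sequences$mirna[[ps$mirna_id[i]]],
                             tx[[ps$transcript_id[i]]])
    expect_true(any(found$start == ps$start[i] &
                      found$end == ps$end[i] &
                      found$site_type == "8mer"))
  }
})

test_that("planted pairs are negatively coupled on the normalized scale", {
  rs <- c()
  for (s in 1:20) {
    d <- generate_dataset(simulation_config(rng_seed = s),
                          include_reads = FALSE)
    mir <- log2(as.matrix(tpm_matrix(d$mirna)) + 1)
    mr <- log2(as.matrix(fpkm_matrix(d$mrna)) + 1)
    tr <- d$truth$planted_triplets
    rs <- c(rs, vapply(seq_len(nrow(tr)), function(i)
      stats::cor(mir[tr$mirna_id[i], ], mr[tr$mrna_id[i], ]), 0))
  }
  expect_lte(mean(rs), -0.6)
  expect_gte(mean(rs < -0.7), 0.8)
})

test_that("small-RNA truth records each planted violation", {
  fq <- generate_smallrna_fastq(tiny_config(n_reads = 100,
                                            frac_bad_reads = 0))
  expect_equal(fq$truth$expected_clean_reads, 100)
  expect_true(all(fq$truth$read_status$keep))

  fq2 <- generate_smallrna_fastq(tiny_config(n_reads = 200,
                                             frac_bad_reads = 0.5))
  st <- fq2$truth$read_status
  expect_equal(sum(!st$keep), 100)
  expect_equal(unname(fq2$truth$rule_counts),
               c(20L, 20L, 20L, 20L, 20L))
  expect_equal(fq2$truth$expected_clean_reads, 100)
  # spot-check the planted violation structure
  cfg <- tiny_config(n_reads = 200, frac_bad_reads = 0.5)
  reads <- fq2$reads
  short <- reads[st$reason == "too_short", ]
  ins_len <- nchar(short$seq) - nchar(cfg$adapter5) - nchar(cfg$adapter3)
  expect_true(all(ins_len == 17))
  nb <- reads[st$reason == "n_base", ]
  expect_true(all(grepl("N", nb$seq, fixed = TRUE)))
})

test_that("a written bundle round-trips through the plain-text formats", {
  d <- generate_dataset(tiny_config())
  dir <- withr::local_tempdir()
  manifest <- write_dataset(d, dir)
  expect_true(all(file.exists(manifest$path)))
  back <- read_dataset(dir)
  expect_equal(back$mrna$values, d$mrna$values)
  expect_equal(back$mirna$lengths, d$mirna$lengths)
  expect_identical(back$sequences$mrna, d$sequences$mrna)
  expect_identical(lapply(back$genesets, `[[`, "members"),
                   lapply(d$genesets, `[[`, "members"))
  expect_identical(back$reads$seq, d$reads$seq)
  expect_identical(back$reads$qual, d$reads$qual)
  expect_equal(back$truth$planted_triplets, d$truth$planted_triplets)
  expect_equal(back$truth$expected_clean_reads,
               d$truth$expected_clean_reads)
})
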
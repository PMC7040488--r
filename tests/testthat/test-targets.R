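let7 <- "UGAGGUAGUAGGUUGUAUAGUU"

test_that("seed-site classes follow the canonical definitions", {
  # rc(seed7 GAGGUAG) = CTACCTC with a downstream A -> 8mer at [3, 11)
  s <- find_seed_sites(let7, "GGGCTACCTCAGGG")
  expect_equal(s, data.frame(start = 3L, end = 11L, site_type = "8mer"))
  # same anchor without the A -> 7mer-m8
  s <- find_seed_sites(let7, "GGGCTACCTCGGGG")
  expect_equal(s$site_type, "7mer-m8")
  expect_equal(c(s$start, s$end), c(3L, 10L))
  # seed6-only match followed by A -> 7mer-A1 (rc(seed6 GAGGUA) = TACCTC)
  s <- find_seed_sites(let7, "GGGTACCTCAGGG")
  expect_equal(s$site_type, "7mer-A1")
  expect_equal(c(s$start, s$end), c(3L, 10L))
  # seed6-only match, no A, not extendable -> 6mer at the sequence start
  s <- find_seed_sites(let7, "TACCTCG")
  expect_equal(s, data.frame(start = 0L, end = 6L, site_type = "6mer"))
  # no complement anywhere -> empty
  expect_equal(nrow(find_seed_sites(let7, "AAAAAAAAAAAA")), 0)
  # T/U insensitive on both inputs
  expect_equal(find_seed_sites(chartr("U", "T", let7), "GGGCUACCUCAGGG"),
               find_seed_sites(let7, "GGGCTACCTCAGGG"))
  expect_error(find_seed_sites("UGAGGUA", "ACGT"), "8 nt")
})

test_that("find_seed_sites equals the naive per-offset classifier", {
  set.seed(8)
  for (k in 1:150) {
    m <- random_nt(22)
    tx <- random_nt(sample(20:150, 1))
    expect_identical(find_seed_sites(m, tx), oracle_seed_sites(m, tx))
  }
  # enriched in true sites: transcripts seeded with the reverse complement
  for (k in 1:80) {
    m <- random_nt(22)
    rc7 <- oracle_revcomp(substr(chartr("U", "T", m), 2, 8))
    tx <- paste0(random_nt(10), rc7, sample(c("A", "C", ""), 1),
                 random_nt(10), substr(rc7, 2, 7), random_nt(5))
    got <- find_seed_sites(m, tx)
    expect_identical(got, oracle_seed_sites(m, tx))
    expect_gte(nrow(got), 1)
    expect_true(all(got$end <= nchar(tx)))
    expect_true(all(got$end - got$start ==
                      c(`6mer` = 6, `7mer-A1` = 7, `7mer-m8` = 7,
                        `8mer` = 8)[got$site_type]))
  }
})

test_that("overlapping and repeated anchors are reported separately", {
  m <- "UAAAAAAAGCGCGCGCGCGCGC"  # seed 2-7 = AAAAAA, rc = TTTTTT
  tx <- "GGTTTTTTTTGG"
  got <- find_seed_sites(m, tx)
  expect_identical(got, oracle_seed_sites(m, tx))
  expect_gt(nrow(got), 1)
})

test_that("predict_targets applies the class threshold over whole collections", {
  mirnas <- c(mir1 = let7)
  tx <- c(t8 = "GGGCTACCTCAGGG",   # 8mer
          t7 = "GGGCTACCTCGGGG",   # 7mer-m8
          t0 = "AAAAAAAAAAAAAA")   # nothing
  all_pairs <- predict_targets(mirnas, tx)
  expect_setequal(all_pairs$pairs$transcript_id, c("t8", "t7"))
  only8 <- predict_targets(mirnas, tx, min_site_type = "8mer")
  expect_equal(only8$pairs$transcript_id, "t8")
  expect_equal(only8$pairs$best_site_type, "8mer")
  expect_equal(nrow(predict_targets(mirnas, tx["t0"])$pairs), 0)
  expect_error(predict_targets(c(a = let7, a = let7), tx), "duplicate")
})

test_that("every planted pair of the synthetic bundle is predicted", {
  d <- generate_dataset(tiny_config(), include_reads = FALSE)
  pred <- predict_targets(d$sequences$mirna,
                          c(d$sequences$mrna, d$sequences$lncrna))
  keys <- paste(pred$pairs$mirna_id, pred$pairs$transcript_id)
  tr <- d$truth$planted_triplets
  expect_true(all(paste(tr$mirna_id, tr$mrna_id) %in% keys))
  expect_true(all(paste(tr$mirna_id, tr$lncrna_id) %in% keys))
})

test_that("the consensus rule keeps exactly the pairs shared by all predictors", {
  mk <- function(pairs, label) {
    sites <- data.frame(mirna_id = pairs$mirna_id,
                        transcript_id = pairs$transcript_id,
                        start = 0L, end = 8L, site_type = "8mer",
                        stringsAsFactors = FALSE)
    cernetr:::target_prediction(sites, transcript_class = "mRNA",
                                label = label)
  }
  p1 <- mk(data.frame(mirna_id = c("m1", "m1", "m2"),
                      transcript_id = c("g1", "g2", "g1")), "engineA")
  p2 <- mk(data.frame(mirna_id = c("m1", "m1"),
                      transcript_id = c("g1", "g2")), "engineB")
  p3 <- mk(data.frame(mirna_id = c("m1", "m2"),
                      transcript_id = c("g1", "g1")), "engineC")
  consensus <- intersect_predictions(list(p1, p2, p3))
  expect_equal(nrow(consensus$pairs), 1)  # only (m1, g1) is in 3/3
  expect_equal(consensus$pairs$mirna_id, "m1")
  expect_equal(consensus$pairs$support, "engineA+engineB+engineC")
  # a pair present in 2/3 collections is dropped
  expect_false("g2" %in% consensus$pairs$transcript_id)
  # single collection: identity
  solo <- intersect_predictions(list(p1))
  expect_equal(solo$pairs$transcript_id, p1$pairs$transcript_id)
})

test_that("site tables round-trip through TSV import", {
  d <- generate_dataset(tiny_config(), include_reads = FALSE)
  pred <- predict_targets(d$sequences$mirna, d$sequences$mrna,
                          transcript_class = "mRNA")
  path <- file.path(withr::local_tempdir(), "sites.tsv")
  write_sites_tsv(pred, path)
  back <- read_prediction_tsv(path, label = "seedmatch")
  expect_equal(back$sites[order(back$sites$mirna_id, back$sites$start), ],
               pred$sites[order(pred$sites$mirna_id, pred$sites$start), ],
               ignore_attr = TRUE)
  expect_setequal(paste(back$pairs$mirna_id, back$pairs$transcript_id),
                  paste(pred$pairs$mirna_id, pred$pairs$transcript_id))
})
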
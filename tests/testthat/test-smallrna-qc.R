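a5 <- "GTTCAG"
a3 <- "TGGAAT"
params <- qc_params(adapter5 = a5, adapter3 = a3)

qchar <- function(q) intToUtf8(q + 33L)
qual_of <- function(seq, q = 35) {
  paste(rep(qchar(q), nchar(seq)), collapse = "")
}
mk_read <- function(id, seq, qual = qual_of(seq)) {
  data.frame(id = id, seq = seq, qual = qual, stringsAsFactors = FALSE)
}
good_insert <- "ACGTACGTACGTACGTACGTAC"  # 22 nt

test_that("each filtering rule rejects with the right reason, in order", {
  seq_ok <- paste0(a5, good_insert, a3)
  q_two_low <- qual_of(seq_ok)
  substr(q_two_low, 3, 3) <- qchar(20)
  substr(q_two_low, 9, 9) <- qchar(20)
  q_one_low <- qual_of(seq_ok)
  substr(q_one_low, 3, 3) <- qchar(20)
  seq_n <- paste0(a5, sub("^A", "N", good_insert), a3)
  q_both <- q_two_low  # low quality AND (below) an N in the sequence

  reads <- rbind(
    mk_read("ok", seq_ok),
    mk_read("two_low_q", seq_ok, q_two_low),
    mk_read("one_low_q_ok", seq_ok, q_one_low),
    mk_read("has_n", seq_n),
    mk_read("no_a3", paste0(a5, good_insert)),
    mk_read("no_a5", paste0(good_insert, a3)),
    mk_read("empty_insert", paste0(a5, a3)),
    mk_read("short_insert", paste0(a5, substr(good_insert, 1, 17), a3)),
    mk_read("low_q_and_n", seq_n, q_both))
  res <- clean_reads(reads, params)

  expect_setequal(res$clean$id, c("ok", "one_low_q_ok"))
  expect_equal(res$clean$insert[res$clean$id == "ok"], good_insert)
  reason <- stats::setNames(res$per_read$reason, res$per_read$id)
  expect_equal(unname(reason["two_low_q"]), "low_quality")
  expect_equal(unname(reason["has_n"]), "n_base")
  expect_equal(unname(reason["no_a3"]), "no_adapter")
  expect_equal(unname(reason["no_a5"]), "no_adapter")
  expect_equal(unname(reason["empty_insert"]), "no_insert")
  expect_equal(unname(reason["short_insert"]), "too_short")
  # rule order: quality is checked before the N rule
  expect_equal(unname(reason["low_q_and_n"]), "low_quality")
  # conservation: kept + per-rule rejections = total
  expect_equal(sum(res$report$n), nrow(reads))
})

test_that("a boundary-quality base counts as low quality (inclusive threshold)", {
  seq <- paste0(a5, good_insert, a3)
  q <- qual_of(seq)
  substr(q, 1, 1) <- qchar(20)
  substr(q, 2, 2) <- qchar(20)
  res <- clean_reads(mk_read("r", seq, q), params)
  expect_equal(res$per_read$reason, "low_quality")
  q21 <- qual_of(seq)
  substr(q21, 1, 1) <- qchar(21)
  substr(q21, 2, 2) <- qchar(21)
  expect_true(clean_reads(mk_read("r", seq, q21), params)$per_read$keep)
})

test_that("malformed reads are rejected with the offending id", {
  bad <- mk_read("broken", "ACGT", "II")
  expect_error(clean_reads(bad, params), "broken")
})

test_that("the QC count on the synthetic FASTQ matches the planted truth exactly", {
  cfg <- tiny_config(n_reads = 250, frac_bad_reads = 0.2)
  d <- generate_dataset(cfg)
  res <- clean_reads(d$reads, qc_params(adapter5 = cfg$adapter5,
                                        adapter3 = cfg$adapter3))
  expect_equal(nrow(res$clean), d$truth$expected_clean_reads)
  expect_identical(res$per_read$keep, d$truth$read_status$keep)
  got <- stats::setNames(res$report$n, res$report$rule)
  for (rule in names(d$truth$rule_counts)) {
    expect_equal(unname(got[rule]), unname(d$truth$rule_counts[rule]))
  }
})

test_that("clean_reads reads FASTQ from disk", {
  cfg <- tiny_config(n_reads = 60, frac_bad_reads = 0.1)
  d <- generate_dataset(cfg)
  path <- file.path(withr::local_tempdir(), "reads.fastq")
  write_fastq(d$reads, path)
  res <- clean_reads(path, qc_params(adapter5 = cfg$adapter5,
                                     adapter3 = cfg$adapter3))
  expect_equal(nrow(res$clean), d$truth$expected_clean_reads)
})

test_that("collapse_tags counts, sorts and conserves totals", {
  expect_equal(collapse_tags(c("AAA", "AAA", "CCC")),
               data.frame(tag = c("AAA", "CCC"), count = c(2L, 1L)))
  expect_equal(nrow(collapse_tags(character(0))), 0)
  ten <- replicate(10, random_nt(20))
  tab <- collapse_tags(ten)
  expect_equal(nrow(tab), 10)
  expect_true(all(tab$count == 1))
  # descending count, ties broken lexicographically
  tab2 <- collapse_tags(c("TTT", "GGG", "TTT", "AAA", "GGG"))
  expect_equal(tab2$tag, c("GGG", "TTT", "AAA"))
  expect_equal(sum(tab2$count), 5)
  expect_error(collapse_tags(c("AAA", "")), "non-empty")
})
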
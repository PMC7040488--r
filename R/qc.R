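#' Quality-control parameters for small-RNA clean-tag filtering
#'
#' @param q_threshold Phred score at or below which a base counts as
#'   low-quality (default 20, inclusive).
#' @param max_low_quality Maximum tolerated number of low-quality bases per
#'   read; one more rejects the read (default 1, i.e. reject at >= 2).
#' @param min_insert_len Minimum insert length in nt after adapter removal
#'   (default 18; adapters do not count).
#' @param adapter5,adapter3 Adapter sequences; the read must start with the
#'   5' adapter and contain the 3' adapter downstream of it.
#' @param require_adapters Reject reads missing either adapter (default
#'   TRUE).
#' @return A list of class `qc_params`.
#' @export
qc_params <- function(q_threshold = 20, max_low_quality = 1,
                      min_insert_len = 18,
                      adapter5 = "GTTCAGAGTTCTACAGTCCGACGATC",
                      adapter3 = "TGGAATTCTCGGGTGCCAAGG",
                      require_adapters = TRUE) {
  if (min_insert_len < 1) stop("'min_insert_len' must be >= 1")
  if (q_threshold < 0) stop("'q_threshold' must be >= 0")
  if (max_low_quality < 0) stop("'max_low_quality' must be >= 0")
  structure(list(q_threshold = q_threshold, max_low_quality = max_low_quality,
                 min_insert_len = min_insert_len,
                 adapter5 = toupper(adapter5), adapter3 = toupper(adapter3),
                 require_adapters = isTRUE(require_adapters)),
            class = "qc_params")
}

#' Filter raw small-RNA reads into clean inserts
#'
#' Applies, in order: (1) reject reads with more than `max_low_quality`
#' bases at or below the quality threshold; (2) reject reads containing an
#' unknown nucleotide (N); (3) strip the 5' adapter prefix and the first
#' occurrence of the 3' adapter downstream of it, rejecting reads missing a
#' required adapter or whose insert is empty (adapters back to back);
#' (4) reject inserts shorter than `min_insert_len` (adapters excluded).
#' A read violating several rules is counted against the first violated
#' rule in this order.
#'
#' @param reads Data frame with columns `id`, `seq`, `qual` (Phred+33), as
#'   returned by [read_fastq()] or [generate_smallrna_fastq()], or a path
#'   to a FASTQ file.
#' @param params A [qc_params()].
#' @return List of class `qc_result`: `clean` (data frame `id`, `insert`),
#'   `report` (data frame `rule`, `n` — kept reads plus one row per
#'   rejection rule; the column sums to the input read count), and
#'   `per_read` (data frame `id`, `keep`, `reason`).
#' @export
clean_reads <- function(reads, params = qc_params()) {
  stopifnot(inherits(params, "qc_params"))
  if (is.character(reads) && length(reads) == 1) reads <- read_fastq(reads)
  stopifnot(all(c("id", "seq", "qual") %in% names(reads)))
  if (any(nchar(reads$seq) != nchar(reads$qual))) {
    bad <- which(nchar(reads$seq) != nchar(reads$qual))[1]
    stop("malformed read (seq/qual length mismatch): ", reads$id[bad])
  }
  n <- nrow(reads)
  reason <- character(n)
  insert <- rep(NA_character_, n)
  a5 <- params$adapter5
  a3 <- params$adapter3

  for (i in seq_len(n)) {
    seq <- toupper(reads$seq[i])
    phred <- utf8ToInt(reads$qual[i]) - 33L
    if (sum(phred <= params$q_threshold) > params$max_low_quality) {
      reason[i] <- "low_quality"
      next
    }
    if (grepl("N", seq, fixed = TRUE)) {
      reason[i] <- "n_base"
      next
    }
    ins <- seq
    if (params$require_adapters) {
      if (!startsWith(seq, a5)) {
        reason[i] <- "no_adapter"
        next
      }
      rest <- substr(seq, nchar(a5) + 1L, nchar(seq))
      hit <- regexpr(a3, rest, fixed = TRUE)
      if (hit < 0) {
        reason[i] <- "no_adapter"
        next
      }
      ins <- substr(rest, 1L, hit - 1L)
      if (nchar(ins) == 0) {
        reason[i] <- "no_insert"
        next
      }
    }
    if (nchar(ins) < params$min_insert_len) {
      reason[i] <- "too_short"
      next
    }
    reason[i] <- "keep"
    insert[i] <- ins
  }

  keep <- reason == "keep"
  rules <- c("keep", "low_quality", "n_base", "no_adapter", "no_insert",
             "too_short")
  report <- data.frame(rule = rules,
                       n = vapply(rules, function(r) sum(reason == r), 0L),
                       stringsAsFactors = FALSE)
  structure(list(
    clean = data.frame(id = reads$id[keep], insert = insert[keep],
                       stringsAsFactors = FALSE),
    report = report,
    per_read = data.frame(id = reads$id, keep = keep,
                          reason = ifelse(keep, "", reason),
                          stringsAsFactors = FALSE)
  ), class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  total <- sum(x$report$n)
  kept <- x$report$n[x$report$rule == "keep"]
  cat(sprintf("<qc_result> %d / %d reads kept (%.1f%%)\n", kept, total,
              100 * kept / max(total, 1)))
  rej <- x$report[x$report$rule != "keep" & x$report$n > 0, ]
  if (nrow(rej)) {
    cat("rejections:", paste(sprintf("%s=%d", rej$rule, rej$n),
                             collapse = ", "), "\n")
  }
  invisible(x)
}

#' Collapse clean inserts into a unique-tag count table
#'
#' @param inserts Character vector of clean insert sequences, or the
#'   `clean` component of a [clean_reads()] result.
#' @return Data frame with columns `tag` and `count`, sorted by descending
#'   count then lexicographic tag; counts sum to `length(inserts)`.
#' @export
collapse_tags <- function(inserts) {
  if (is.data.frame(inserts)) inserts <- inserts$insert
  if (length(inserts) == 0) {
    return(data.frame(tag = character(0), count = integer(0),
                      stringsAsFactors = FALSE))
  }
  if (any(!nzchar(inserts))) stop("inserts must be non-empty strings")
  tab <- table(inserts)
  df <- data.frame(tag = names(tab), count = as.integer(tab),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$count, df$tag), , drop = FALSE]
  rownames(df) <- NULL
  df
}
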
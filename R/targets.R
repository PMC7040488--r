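# Canonical seed-match site classes, weakest to strongest. A site is
# anchored by a match of the transcript to the reverse complement of miRNA
# seed positions 2-7 (seed6); extension to position 8 and/or an A opposite
# miRNA position 1 upgrades the class.
SITE_CLASSES <- c("6mer", "7mer-A1", "7mer-m8", "8mer")

normalize_nt <- function(x) chartr("U", "T", toupper(x))

complement1 <- function(base) chartr("ACGT", "TGCA", base)

#' Locate canonical miRNA seed-match sites on a transcript
#'
#' Scans the transcript (5'->3') for the reverse complement of the miRNA
#' seed (positions 2-7) and classifies each hit: `8mer` when the match
#' extends to miRNA position 8 and the next transcript base (opposite
#' miRNA position 1) is an A; `7mer-m8` when it extends to position 8
#' without the A; `7mer-A1` when the seed6 match is followed by an A but
#' does not extend to position 8; `6mer` otherwise. Overlapping hits are
#' reported separately; each seed6 anchor yields exactly one class.
#'
#' @param mirna_seq Mature miRNA sequence, 5'->3' (U or T alphabet),
#'   length >= 8.
#' @param transcript_seq Transcript sequence, 5'->3'.
#' @return Data frame with columns `start`, `end` (0-based half-open on
#'   the transcript) and `site_type`, sorted by `start`. The span equals
#'   6, 7 or 8 nt according to the class.
#' @export
find_seed_sites <- function(mirna_seq, transcript_seq) {
  m <- normalize_nt(mirna_seq)
  tx <- normalize_nt(transcript_seq)
  if (nchar(m) < 8) stop("miRNA sequence must be at least 8 nt")
  empty <- data.frame(start = integer(0), end = integer(0),
                      site_type = character(0), stringsAsFactors = FALSE)
  if (nchar(tx) < 6) return(empty)
  rc6 <- revcomp(substr(m, 2, 7))
  hits <- Biostrings::start(
    Biostrings::matchPattern(rc6, Biostrings::DNAString(tx)))
  if (length(hits) == 0) return(empty)
  comp_m8 <- complement1(substr(m, 8, 8))
  sites <- lapply(hits, function(p1) classify_seed_hit(tx, p1, comp_m8))
  df <- do.call(rbind, sites)
  df <- df[order(df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# p1: 1-based start of the seed6 reverse-complement match on the transcript.
classify_seed_hit <- function(tx, p1, comp_m8) {
  len <- nchar(tx)
  p0 <- p1 - 1L  # 0-based
  extends_m8 <- p0 >= 1L && substr(tx, p0, p0) == comp_m8
  if (extends_m8) {
    q0 <- p0 - 1L  # 0-based start of the seed7 match
    has_a1 <- (q0 + 7L) < len && substr(tx, q0 + 8L, q0 + 8L) == "A"
    if (has_a1) {
      data.frame(start = q0, end = q0 + 8L, site_type = "8mer",
                 stringsAsFactors = FALSE)
    } else {
      data.frame(start = q0, end = q0 + 7L, site_type = "7mer-m8",
                 stringsAsFactors = FALSE)
    }
  } else {
    has_a1 <- (p0 + 6L) < len && substr(tx, p0 + 7L, p0 + 7L) == "A"
    if (has_a1) {
      data.frame(start = p0, end = p0 + 7L, site_type = "7mer-A1",
                 stringsAsFactors = FALSE)
    } else {
      data.frame(start = p0, end = p0 + 6L, site_type = "6mer",
                 stringsAsFactors = FALSE)
    }
  }
}

empty_sites_df <- function() {
  data.frame(mirna_id = character(0), transcript_id = character(0),
             start = integer(0), end = integer(0), site_type = character(0),
             stringsAsFactors = FALSE)
}

#' Predict miRNA targets across a transcript collection by seed matching
#'
#' Every (miRNA, transcript) pair with at least one seed site of class at
#' or above `min_site_type` (ordering 6mer < 7mer-A1 < 7mer-m8 < 8mer)
#' becomes a predicted target pair.
#'
#' @param mirnas Named character vector of mature miRNA sequences, or a
#'   FASTA path.
#' @param transcripts Named character vector of transcript sequences, or a
#'   FASTA path.
#' @param min_site_type Weakest site class accepted (default `"6mer"`).
#' @param transcript_class Optional class label (`"mRNA"`/`"lncRNA"`)
#'   recorded on the pairs.
#' @param label Predictor label recorded as support (default
#'   `"seedmatch"`).
#' @return Object of class `target_prediction`: `pairs` (data frame
#'   `mirna_id`, `transcript_id`, `transcript_class`, `best_site_type`,
#'   `n_sites`, `support`) and `sites` (per-site data frame).
#' @export
predict_targets <- function(mirnas, transcripts, min_site_type = "6mer",
                            transcript_class = NA_character_,
                            label = "seedmatch") {
  if (is.character(mirnas) && length(mirnas) == 1 && file.exists(mirnas)) {
    mirnas <- read_fasta(mirnas)
  }
  if (is.character(transcripts) && length(transcripts) == 1 &&
      file.exists(transcripts)) {
    transcripts <- read_fasta(transcripts)
  }
  min_site_type <- match.arg(min_site_type, SITE_CLASSES)
  if (anyDuplicated(names(mirnas))) stop("duplicate miRNA ids")
  if (anyDuplicated(names(transcripts))) stop("duplicate transcript ids")
  if ((length(mirnas) && is.null(names(mirnas))) ||
      (length(transcripts) && is.null(names(transcripts)))) {
    stop("sequences must be named")
  }
  if (length(mirnas) == 0 || length(transcripts) == 0) {
    return(target_prediction(empty_sites_df(),
                             transcript_class = transcript_class,
                             label = label))
  }
  tx_norm <- normalize_nt(transcripts)
  subj <- Biostrings::DNAStringSet(tx_norm)
  all_sites <- list()
  for (mid in names(mirnas)) {
    m <- normalize_nt(mirnas[[mid]])
    if (nchar(m) < 8) stop("miRNA sequence must be at least 8 nt: ", mid)
    rc6 <- revcomp(substr(m, 2, 7))
    comp_m8 <- complement1(substr(m, 8, 8))
    hits <- Biostrings::vmatchPattern(rc6, subj)
    for (ti in which(lengths(Biostrings::startIndex(hits)) > 0)) {
      tx <- tx_norm[[ti]]
      starts <- Biostrings::startIndex(hits)[[ti]]
      rows <- do.call(rbind, lapply(starts, function(p1)
        classify_seed_hit(tx, p1, comp_m8)))
      rows$mirna_id <- mid
      rows$transcript_id <- names(transcripts)[ti]
      all_sites[[length(all_sites) + 1L]] <- rows
    }
  }
  sites <- if (length(all_sites)) do.call(rbind, all_sites) else empty_sites_df()
  sites <- sites[c("mirna_id", "transcript_id", "start", "end", "site_type")]
  min_rank <- match(min_site_type, SITE_CLASSES)
  sites <- sites[match(sites$site_type, SITE_CLASSES) >= min_rank, ,
                 drop = FALSE]
  target_prediction(sites, transcript_class = transcript_class, label = label)
}

# Aggregate a site table into a target_prediction object.
target_prediction <- function(sites, transcript_class = NA_character_,
                              label = "seedmatch") {
  if (nrow(sites)) {
    sites <- sites[order(sites$mirna_id, sites$transcript_id, sites$start), ,
                   drop = FALSE]
    rownames(sites) <- NULL
    key <- paste(sites$mirna_id, sites$transcript_id, sep = "\r")
    rank <- match(sites$site_type, SITE_CLASSES)
    best <- tapply(rank, key, max)
    nsite <- tapply(rank, key, length)
    first <- !duplicated(key)
    pairs <- data.frame(
      mirna_id = sites$mirna_id[first],
      transcript_id = sites$transcript_id[first],
      transcript_class = transcript_class,
      best_site_type = SITE_CLASSES[as.integer(best[key[first]])],
      n_sites = as.integer(nsite[key[first]]),
      support = label,
      stringsAsFactors = FALSE, row.names = NULL)
  } else {
    pairs <- data.frame(mirna_id = character(0), transcript_id = character(0),
                        transcript_class = character(0),
                        best_site_type = character(0), n_sites = integer(0),
                        support = character(0), stringsAsFactors = FALSE)
  }
  structure(list(pairs = pairs, sites = sites, label = label),
            class = "target_prediction")
}

#' @export
print.target_prediction <- function(x, ...) {
  cat(sprintf("<target_prediction> %s: %d pairs, %d sites\n",
              paste(unique(x$pairs$support), collapse = "+"),
              nrow(x$pairs), nrow(x$sites)))
  invisible(x)
}

#' Intersect target predictions from several predictors
#'
#' Implements the consensus rule: a (miRNA, transcript) pair is kept only
#' when every predictor reports it. Support labels are unioned and site
#' coordinates deduplicated.
#'
#' @param prediction_sets List of `target_prediction` objects (e.g. the
#'   seed-match engine plus [read_prediction_tsv()] imports).
#' @return A consensus `target_prediction`.
#' @export
intersect_predictions <- function(prediction_sets) {
  stopifnot(length(prediction_sets) >= 1)
  keys <- lapply(prediction_sets, function(p)
    paste(p$pairs$mirna_id, p$pairs$transcript_id, sep = "\r"))
  common <- Reduce(intersect, keys)
  all_sites <- do.call(rbind, lapply(prediction_sets, `[[`, "sites"))
  all_sites <- all_sites[paste(all_sites$mirna_id, all_sites$transcript_id,
                               sep = "\r") %in% common, , drop = FALSE]
  all_sites <- unique(all_sites)
  pairs_list <- lapply(seq_along(prediction_sets), function(i) {
    p <- prediction_sets[[i]]$pairs
    p[keys[[i]] %in% common, , drop = FALSE]
  })
  merged <- pairs_list[[1]]
  key1 <- paste(merged$mirna_id, merged$transcript_id, sep = "\r")
  support <- stats::setNames(as.list(merged$support), key1)
  best <- stats::setNames(match(merged$best_site_type, SITE_CLASSES), key1)
  cls <- stats::setNames(merged$transcript_class, key1)
  for (p in pairs_list[-1]) {
    k <- paste(p$mirna_id, p$transcript_id, sep = "\r")
    for (j in seq_along(k)) {
      support[[k[j]]] <- union(support[[k[j]]], p$support[j])
      r <- match(p$best_site_type[j], SITE_CLASSES)
      if (!is.na(r) && (is.na(best[[k[j]]]) || r > best[[k[j]]])) {
        best[[k[j]]] <- r
      }
      if (is.na(cls[[k[j]]])) cls[[k[j]]] <- p$transcript_class[j]
    }
  }
  merged$support <- vapply(key1, function(k)
    paste(sort(support[[k]]), collapse = "+"), "")
  merged$best_site_type <- ifelse(is.na(best[key1]), NA_character_,
                                  SITE_CLASSES[best[key1]])
  merged$transcript_class <- unname(cls[key1])
  site_key <- paste(all_sites$mirna_id, all_sites$transcript_id, sep = "\r")
  merged$n_sites <- vapply(key1, function(k) sum(site_key == k), 0L)
  rownames(merged) <- NULL
  structure(list(pairs = merged, sites = all_sites,
                 label = paste(sort(unique(unlist(support))), collapse = "+")),
            class = "target_prediction")
}

#' Import an externally produced target prediction from TSV
#'
#' @param path TSV with at least `mirna_id` and `transcript_id`; `start`,
#'   `end`, `site_type` and `transcript_class` are used when present.
#' @param label Predictor label for the support evidence.
#' @return A `target_prediction`.
#' @export
read_prediction_tsv <- function(path, label) {
  df <- read_tsv(path)
  if (!all(c("mirna_id", "transcript_id") %in% names(df))) {
    stop("prediction TSV needs columns mirna_id and transcript_id")
  }
  has_sites <- all(c("start", "end", "site_type") %in% names(df))
  sites <- if (has_sites) {
    df[c("mirna_id", "transcript_id", "start", "end", "site_type")]
  } else empty_sites_df()
  cls <- if ("transcript_class" %in% names(df) && nrow(df)) {
    df$transcript_class[1]
  } else NA_character_
  if (has_sites) {
    target_prediction(sites, transcript_class = cls, label = label)
  } else {
    pairs <- unique(df[c("mirna_id", "transcript_id")])
    pairs$transcript_class <- cls
    pairs$best_site_type <- NA_character_
    pairs$n_sites <- 0L
    pairs$support <- label
    structure(list(pairs = pairs, sites = empty_sites_df(), label = label),
              class = "target_prediction")
  }
}

#' Write the per-site table of a prediction to TSV
#'
#' @param prediction A `target_prediction`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_sites_tsv <- function(prediction, path) {
  write_tsv(prediction$sites, path)
}
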
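# Plain-text I/O helpers shared across modules. All tables are tab-separated
# with a header row and no quoting; sequences go through Biostrings.

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Read sequences from a FASTA file
#'
#' @param path FASTA path.
#' @return Named character vector of sequences (uppercase, as stored).
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  stats::setNames(as.character(ss), names(ss))
}

#' Write a named set of sequences to FASTA
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (is.null(names(seqs)) || any(names(seqs) == "")) {
    stop("sequences must be named")
  }
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path, width = 80L)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' One set per line: term id, description, then tab-separated member ids.
#'
#' @param path GMT path.
#' @return A named list (names = term ids); each element has `term_id`,
#'   `term_name` and `members`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(ln) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) stop("malformed GMT line: ", substr(ln, 1, 60))
    list(term_id = parts[1], term_name = parts[2], members = unique(parts[-(1:2)]))
  })
  names(sets) <- vapply(sets, `[[`, "", "term_id")
  if (anyDuplicated(names(sets))) stop("duplicate term_id in GMT")
  sets
}

#' Write gene sets to a GMT file
#'
#' @param genesets Gene-set list as returned by [read_gmt()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(genesets, path) {
  lines <- vapply(genesets, function(gs) {
    paste(c(gs$term_id, gs$term_name, gs$members), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read small-RNA reads from a FASTQ file
#'
#' @param path FASTQ path (plain or gzipped).
#' @return Data frame with columns `id`, `seq`, `qual` (Phred+33 string).
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  # Biostrings warns about dropping (empty) mcols on the qualities; benign.
  qs <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  data.frame(id = names(qs),
             seq = as.character(qs),
             qual = as.character(Biostrings::quality(qs)),
             stringsAsFactors = FALSE)
}

#' Write small-RNA reads to a FASTQ file
#'
#' @param reads Data frame with columns `id`, `seq`, `qual`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("id", "seq", "qual") %in% names(reads)))
  if (any(nchar(reads$seq) != nchar(reads$qual))) {
    stop("seq and qual lengths differ")
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", reads$id, "\n", reads$seq, "\n+\n", reads$qual), con)
  invisible(path)
}
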
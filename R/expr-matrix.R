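#' Expression matrix container
#'
#' A light container for a features x samples expression table together with
#' the metadata every downstream stage needs: the feature class (mRNA, lncRNA
#' or miRNA), optional transcript lengths (required for FPKM and
#' length-normalized TPM), a sample table with group and replicate labels,
#' and the unit of the stored values.
#'
#' @param values Numeric matrix, features in rows, samples in columns.
#'   Row names are feature ids, column names are sample labels.
#' @param feature_class One of `"mRNA"`, `"lncRNA"`, `"miRNA"`.
#' @param samples Data frame with columns `sample`, `group`, `replicate`;
#'   `sample` must match `colnames(values)` in order.
#' @param lengths Optional numeric vector of transcript lengths (nt), named
#'   by feature id or in row order.
#' @param unit One of `"count"`, `"FPKM"`, `"TPM"`.
#' @return An object of class `expr_matrix`.
#' @export
expr_matrix <- function(values, feature_class = c("mRNA", "lncRNA", "miRNA"),
                        samples, lengths = NULL, unit = c("count", "FPKM", "TPM")) {
  feature_class <- match.arg(feature_class)
  unit <- match.arg(unit)
  values <- as.matrix(values)
  if (is.null(rownames(values))) stop("'values' must have feature ids as row names")
  if (is.null(colnames(values))) stop("'values' must have sample labels as column names")
  if (any(values < 0)) stop("expression values must be non-negative")
  if (anyDuplicated(colnames(values))) stop("sample labels must be unique")
  if (anyDuplicated(rownames(values))) stop("feature ids must be unique")
  samples <- as.data.frame(samples)
  need <- c("sample", "group", "replicate")
  if (!all(need %in% names(samples))) {
    stop("'samples' needs columns: ", paste(need, collapse = ", "))
  }
  if (!identical(as.character(samples$sample), colnames(values))) {
    stop("samples$sample must match colnames(values) in order")
  }
  if (!is.null(lengths)) {
    if (is.null(names(lengths))) {
      if (length(lengths) != nrow(values)) stop("unnamed 'lengths' must match row count")
      names(lengths) <- rownames(values)
    }
    missing <- setdiff(rownames(values), names(lengths))
    if (length(missing)) stop("missing length for feature: ", missing[1])
    lengths <- lengths[rownames(values)]
    if (any(lengths <= 0)) stop("lengths must be > 0")
  }
  structure(
    list(values = values, feature_class = feature_class,
         samples = samples, lengths = lengths, unit = unit),
    class = "expr_matrix"
  )
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %s [%s]: %d features x %d samples\n",
              x$feature_class, x$unit, nrow(x$values), ncol(x$values)))
  cat("groups:", paste(unique(x$samples$group), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' @export
as.matrix.expr_matrix <- function(x, ...) x$values

#' Write an expression matrix to TSV
#'
#' The dialect is: header row of sample labels, first column `feature_id`,
#' then (when lengths are stored) a `length` column, then one column per
#' sample. A companion `<stem>.samples.tsv` carries the group/replicate map.
#'
#' @param x An [expr_matrix].
#' @param path Output TSV path; the sample table is written next to it.
#' @return `path`, invisibly.
#' @export
write_expr_tsv <- function(x, path) {
  stopifnot(inherits(x, "expr_matrix"))
  df <- data.frame(feature_id = rownames(x$values), check.names = FALSE)
  if (!is.null(x$lengths)) df$length <- unname(x$lengths)
  df <- cbind(df, as.data.frame(x$values, check.names = FALSE))
  write_tsv(df, path)
  meta <- x$samples
  meta$feature_class <- x$feature_class
  meta$unit <- x$unit
  write_tsv(meta, samples_path(path))
  invisible(path)
}

#' Read an expression matrix written by [write_expr_tsv()]
#'
#' @param path TSV path; `<stem>.samples.tsv` must sit next to it.
#' @return An [expr_matrix].
#' @export
read_expr_tsv <- function(path) {
  df <- read_tsv(path)
  meta <- read_tsv(samples_path(path))
  lengths <- NULL
  mat_cols <- setdiff(names(df), c("feature_id", "length"))
  if ("length" %in% names(df)) lengths <- stats::setNames(df$length, df$feature_id)
  values <- as.matrix(df[mat_cols])
  rownames(values) <- df$feature_id
  expr_matrix(values, feature_class = meta$feature_class[1],
              samples = meta[c("sample", "group", "replicate")],
              lengths = lengths, unit = meta$unit[1])
}

samples_path <- function(path) sub("\\.tsv$", ".samples.tsv", path)

#' Restrict an expression matrix to a set of samples
#'
#' @param x An [expr_matrix].
#' @param sample_ids Sample labels to keep (order preserved from `x`).
#' @return An [expr_matrix] over the selected samples.
#' @export
subset_samples <- function(x, sample_ids) {
  stopifnot(inherits(x, "expr_matrix"))
  keep <- colnames(x$values) %in% sample_ids
  if (!any(keep)) stop("no matching samples")
  expr_matrix(x$values[, keep, drop = FALSE], x$feature_class,
              x$samples[keep, , drop = FALSE], x$lengths, x$unit)
}

group_samples <- function(x, group) {
  as.character(x$samples$sample[x$samples$group == group])
}
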
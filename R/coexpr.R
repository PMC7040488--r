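#' Pearson correlation with a two-sided p-value
#'
#' `r` is the sample Pearson correlation; the p-value is the two-sided
#' tail of `t = r * sqrt((n-2)/(1-r^2))` on `n-2` degrees of freedom.
#' Perfect correlation (`|r| = 1`) gives `p = 0`.
#'
#' @param x,y Numeric vectors of equal length `n >= 3`, neither constant.
#' @return List with `r`, `p` and `n`.
#' @export
correlation_with_p <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 3) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  r <- unname(ct$estimate)
  p <- if (abs(r) >= 1) 0 else ct$p.value
  list(r = r, p = p, n = n)
}

#' Screen candidate miRNA-target pairs for negative co-expression
#'
#' For every candidate (miRNA, target) pair, computes the Pearson
#' correlation of the two expression profiles across the shared samples
#' (optionally a subset, e.g. the two groups of one comparison) and flags
#' pairs passing `r < r_thr` and `p < p_thr`, both strict.
#'
#' @param mirna_expr [expr_matrix] of normalized miRNA expression.
#' @param target_expr [expr_matrix] of normalized target expression (mRNA
#'   or lncRNA).
#' @param candidates Data frame with columns `mirna_id` and
#'   `transcript_id` (e.g. the `pairs` of a `target_prediction`), or a
#'   `target_prediction` object.
#' @param r_thr,p_thr Retention thresholds (defaults -0.7 and 0.05).
#' @param sample_scope Optional character vector of sample labels to
#'   restrict the correlation to; default all shared samples.
#' @param log2_transform Correlate `log2(value + 1)` (default) rather than
#'   raw normalized values.
#' @return Data frame with one row per candidate: `mirna_id`, `target_id`,
#'   `target_class`, `r`, `p`, `n`, `retained`.
#' @export
screen_negative_pairs <- function(mirna_expr, target_expr, candidates,
                                  r_thr = -0.7, p_thr = 0.05,
                                  sample_scope = NULL,
                                  log2_transform = TRUE) {
  stopifnot(inherits(mirna_expr, "expr_matrix"),
            inherits(target_expr, "expr_matrix"))
  if (inherits(candidates, "target_prediction")) candidates <- candidates$pairs
  stopifnot(all(c("mirna_id", "transcript_id") %in% names(candidates)))
  shared <- intersect(colnames(mirna_expr$values), colnames(target_expr$values))
  if (!is.null(sample_scope)) shared <- intersect(shared, sample_scope)
  if (length(shared) < 3) stop("fewer than 3 shared samples in scope")
  m <- mirna_expr$values[, shared, drop = FALSE]
  t_ <- target_expr$values[, shared, drop = FALSE]
  if (log2_transform) {
    m <- log2(m + 1)
    t_ <- log2(t_ + 1)
  }
  out <- candidates[c("mirna_id", "transcript_id")]
  names(out)[2] <- "target_id"
  out$target_class <- target_expr$feature_class
  out$r <- NA_real_
  out$p <- NA_real_
  out$n <- length(shared)
  for (i in seq_len(nrow(out))) {
    mid <- out$mirna_id[i]
    tid <- out$target_id[i]
    if (!mid %in% rownames(m)) stop("unknown miRNA in candidates: ", mid)
    if (!tid %in% rownames(t_)) stop("unknown target in candidates: ", tid)
    cp <- correlation_with_p(m[mid, ], t_[tid, ])
    out$r[i] <- cp$r
    out$p[i] <- cp$p
  }
  out$retained <- out$r < r_thr & out$p < p_thr
  rownames(out) <- NULL
  out
}
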
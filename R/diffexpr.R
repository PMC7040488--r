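#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment: `q_(i) = min_{j >= i} (m * p_(j) / j)`, capped
#' at 1 and mapped back to input order.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return Adjusted q-values in input order.
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric(0))
  if (any(is.na(pvalues)) || any(pvalues < 0) || any(pvalues > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

# Welch two-sample p-value with a deterministic degenerate-case rule:
# when both groups have (numerically) zero variance the test statistic is
# undefined, so equal means give p = 1 and unequal means p = 0.
welch_p <- function(a, b) {
  se2 <- stats::var(a) / length(a) + stats::var(b) / length(b)
  d <- mean(b) - mean(a)
  scale <- max(abs(c(a, b)), 1)
  if (se2 <= (1e-12 * scale)^2) {
    return(if (abs(d) <= 1e-12 * scale) 1 else 0)
  }
  stats::t.test(b, a, var.equal = FALSE)$p.value
}

#' Differential-expression screen between two groups
#'
#' Per feature: the log2 fold-change is computed from the group means of
#' the normalized values with a pseudocount,
#' `log2(mean_B + pc) - log2(mean_A + pc)`; the p-value is a Welch
#' two-sample t-test on `log2(value + pc)`; q-values are BH-adjusted over
#' all features of the matrix. A feature is flagged significant when
#' `p < p_thr` and `|log2fc| > lfc_thr` (both strict).
#'
#' @param expr An [expr_matrix] of normalized values (FPKM or TPM).
#' @param groupA,groupB Group labels; fold-changes are B relative to A.
#' @param p_thr,lfc_thr Significance thresholds (defaults 0.05 and 1).
#' @param pseudocount Added before log transform (default 1).
#' @return Data frame with one row per feature: `feature_id`,
#'   `feature_class`, `comparison`, `log2fc`, `p`, `q`, `direction`,
#'   `significant`.
#' @export
de_screen <- function(expr, groupA, groupB, p_thr = 0.05, lfc_thr = 1,
                      pseudocount = 1) {
  stopifnot(inherits(expr, "expr_matrix"))
  if (!expr$unit %in% c("FPKM", "TPM")) {
    stop("de_screen expects normalized values (FPKM/TPM), got ", expr$unit)
  }
  for (g in c(groupA, groupB)) {
    n <- sum(expr$samples$group == g)
    if (n == 0) stop("group label not found: ", g)
    if (n < 2) stop("group '", g, "' has fewer than 2 replicates")
  }
  vA <- expr$values[, group_samples(expr, groupA), drop = FALSE]
  vB <- expr$values[, group_samples(expr, groupB), drop = FALSE]
  lA <- log2(vA + pseudocount)
  lB <- log2(vB + pseudocount)
  log2fc <- log2(rowMeans(vB) + pseudocount) - log2(rowMeans(vA) + pseudocount)
  p <- vapply(seq_len(nrow(lA)), function(i) welch_p(lA[i, ], lB[i, ]),
              numeric(1))
  q <- bh_adjust(p)
  data.frame(
    feature_id = rownames(expr$values),
    feature_class = expr$feature_class,
    comparison = paste0(groupA, "_vs_", groupB),
    log2fc = log2fc, p = p, q = q,
    direction = ifelse(log2fc >= 0, "up", "down"),
    significant = p < p_thr & abs(log2fc) > lfc_thr,
    stringsAsFactors = FALSE, row.names = NULL)
}
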
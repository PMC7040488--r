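#' FPKM normalization
#'
#' Fragments per kilobase of transcript per million mapped fragments,
#' computed within the matrix: for sample j with library size
#' `C_j = sum_i c_ij`, `FPKM_ij = c_ij * 1e9 / (L_i * C_j)`.
#'
#' @param x An [expr_matrix] of counts with feature lengths.
#' @return An [expr_matrix] with unit `"FPKM"`.
#' @export
fpkm_matrix <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  if (x$unit != "count") stop("FPKM requires a count matrix, got ", x$unit)
  if (is.null(x$lengths)) stop("FPKM requires feature lengths")
  libsize <- colSums(x$values)
  if (any(libsize == 0)) {
    stop("empty library: ", colnames(x$values)[which(libsize == 0)[1]])
  }
  fpkm <- sweep(x$values, 1, x$lengths, "/")
  fpkm <- sweep(fpkm, 2, libsize, "/") * 1e9
  expr_matrix(fpkm, x$feature_class, x$samples, x$lengths, unit = "FPKM")
}

#' TPM normalization
#'
#' Two conventions: `"per_million_tags"` (the small-RNA default) scales
#' each column to a million without length correction,
#' `TPM_ij = c_ij * 1e6 / sum_i c_ij`; `"length_normalized"` first divides
#' by transcript length, `r_ij = c_ij / L_i`, then scales,
#' `TPM_ij = r_ij * 1e6 / sum_i r_ij`. Either way every sample column sums
#' to 1e6.
#'
#' @param x An [expr_matrix] of counts.
#' @param mode Normalization convention (see above).
#' @return An [expr_matrix] with unit `"TPM"`.
#' @export
tpm_matrix <- function(x, mode = c("per_million_tags", "length_normalized")) {
  stopifnot(inherits(x, "expr_matrix"))
  mode <- match.arg(mode)
  if (x$unit != "count") stop("TPM requires a count matrix, got ", x$unit)
  rate <- x$values
  if (mode == "length_normalized") {
    if (is.null(x$lengths)) stop("length-normalized TPM requires feature lengths")
    rate <- sweep(rate, 1, x$lengths, "/")
  }
  denom <- colSums(rate)
  if (any(denom == 0)) {
    stop("empty library: ", colnames(x$values)[which(denom == 0)[1]])
  }
  tpm <- sweep(rate, 2, denom, "/") * 1e6
  expr_matrix(tpm, x$feature_class, x$samples, x$lengths, unit = "TPM")
}

#' Relative quantification by the 2^-ddCt method
#'
#' For each sample s, `dCt_s = Ct_target,s - Ct_reference,s`;
#' `ddCt_s = dCt_s - mean(dCt over calibrator samples)`; the returned
#' relative expression is `2^(-ddCt_s)`. By construction the geometric mean
#' of the calibrator group's values is 1.
#'
#' @param ct Data frame with columns `sample`, `group`, `gene`, `ct`.
#' @param target_gene,reference_gene Gene labels in `ct`.
#' @param calibrator_group Group whose mean dCt anchors the scale.
#' @return Data frame with columns `sample`, `group`, `rel_expr`.
#' @export
ddct <- function(ct, target_gene, reference_gene, calibrator_group) {
  stopifnot(all(c("sample", "group", "gene", "ct") %in% names(ct)))
  samples <- unique(ct[c("sample", "group")])
  pick <- function(gene) {
    v <- numeric(nrow(samples))
    for (i in seq_len(nrow(samples))) {
      row <- ct$ct[ct$sample == samples$sample[i] & ct$gene == gene]
      if (length(row) != 1) {
        stop("missing Ct for sample '", samples$sample[i], "', gene '",
             gene, "'")
      }
      v[i] <- row
    }
    v
  }
  dct <- pick(target_gene) - pick(reference_gene)
  cal <- samples$group == calibrator_group
  if (!any(cal)) stop("calibrator group '", calibrator_group, "' is empty")
  dd <- dct - mean(dct[cal])
  data.frame(sample = samples$sample, group = samples$group,
             rel_expr = 2^(-dd), stringsAsFactors = FALSE)
}
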
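#' Hypergeometric upper-tail p-value
#'
#' Probability of drawing at least `x` annotated genes when `n` genes are
#' drawn without replacement from a background of `N` genes of which `K`
#' are annotated: `p = sum_{k=x}^{min(n,K)} C(K,k) C(N-K,n-k) / C(N,n)`
#' (inclusive upper tail).
#'
#' @param x Overlap count.
#' @param K Annotated genes in the background.
#' @param n Drawn genes (e.g. DE genes).
#' @param N Background size.
#' @return The upper-tail p-value.
#' @export
hypergeom_pvalue <- function(x, K, n, N) {
  if (K > N || n > N) stop("K and n must not exceed N")
  if (x < 0 || x > min(n, K)) stop("x must lie in [0, min(n, K)]")
  stats::phyper(x - 1, K, N - K, n, lower.tail = FALSE)
}

#' Hypergeometric gene-set enrichment with BH q-values
#'
#' Scores each gene set by the hypergeometric upper-tail probability of
#' its overlap with the DE genes against the background, BH-adjusts across
#' all sets in the collection, and reports the rich factor `x / K` (DE
#' genes in the set over background genes in the set).
#'
#' @param de_genes Character vector of differentially expressed gene ids;
#'   must be a subset of `background`.
#' @param background Character vector: the tested universe.
#' @param genesets Gene-set list as from [read_gmt()].
#' @param q_thr Significance threshold on q (default 0.05).
#' @return Data frame sorted by ascending q (ties: descending rich factor,
#'   then term id) with columns `term_id`, `term_name`, `x`, `K`, `n`,
#'   `N`, `p`, `q`, `rich_factor`, `significant`.
#' @export
enrich_genesets <- function(de_genes, background, genesets, q_thr = 0.05) {
  de_genes <- unique(de_genes)
  background <- unique(background)
  outside <- setdiff(de_genes, background)
  if (length(outside)) {
    stop("DE gene absent from background: ", outside[1])
  }
  N <- length(background)
  n <- length(de_genes)
  rows <- lapply(genesets, function(gs) {
    members <- intersect(gs$members, background)
    K <- length(members)
    x <- length(intersect(members, de_genes))
    data.frame(term_id = gs$term_id, term_name = gs$term_name,
               x = x, K = K, n = n, N = N,
               p = if (K == 0) 1 else hypergeom_pvalue(x, K, n, N),
               rich_factor = if (K == 0) 0 else x / K,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  df$q <- bh_adjust(df$p)
  df$significant <- df$q < q_thr
  df <- df[order(df$q, -df$rich_factor, df$term_id), ,
           drop = FALSE]
  rownames(df) <- NULL
  df[c("term_id", "term_name", "x", "K", "n", "N", "p", "q",
       "rich_factor", "significant")]
}

#' Top-ranked enrichment records
#'
#' @param records Output of [enrich_genesets()] (already sorted).
#' @param n_top Number of records to keep (default 20).
#' @return The leading `n_top` rows.
#' @export
top_terms <- function(records, n_top = 20) {
  utils::head(records, n_top)
}

#' Select DE genes annotated to development terms
#'
#' Returns the union of the members of every gene set whose name contains
#' any of the patterns (case-insensitive substring match), intersected
#' with the DE genes.
#'
#' @param de_genes Character vector of DE gene ids.
#' @param genesets Gene-set list as from [read_gmt()].
#' @param name_patterns Substrings to match against term names (default
#'   `"development"`).
#' @return Character vector of selected gene ids (possibly empty).
#' @export
select_development_genes <- function(de_genes, genesets,
                                     name_patterns = "development") {
  if (length(name_patterns) == 0) stop("'name_patterns' must be non-empty")
  hits <- vapply(genesets, function(gs) {
    any(vapply(name_patterns, function(p)
      grepl(tolower(p), tolower(gs$term_name), fixed = TRUE), TRUE))
  }, TRUE)
  members <- as.character(unique(unlist(lapply(genesets[hits], `[[`,
                                               "members"))))
  intersect(as.character(de_genes), members)
}
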
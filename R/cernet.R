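#' Assemble a ceRNA network from screened negative co-expression pairs
#'
#' Keeps miRNA-mRNA edges whose mRNA belongs to the development gene set
#' and whose pair is supported by consensus target prediction, and
#' miRNA-lncRNA edges supported by consensus target prediction (the
#' development gate applies to mRNAs only). The network is the union of
#' the kept typed edges; a ceRNA triplet is every (miRNA m, mRNA g,
#' lncRNA l) for which both the (m, g) and (m, l) edges were kept — the
#' shared miRNA recognition element is m's seed. Edges lacking target
#' evidence are dropped with a warning, not an error.
#'
#' @param mrna_pairs,lncrna_pairs Data frames from
#'   [screen_negative_pairs()]; only rows with `retained == TRUE` are
#'   used.
#' @param consensus_targets A `target_prediction` (e.g. from
#'   [intersect_predictions()]) supplying the MRE evidence.
#' @param dev_genes Character vector of development-annotated DE gene ids
#'   gating the mRNA side.
#' @param require_lnc_target Also require target evidence for
#'   miRNA-lncRNA edges (default TRUE).
#' @param comparison Optional comparison label stored on the network.
#' @return Object of class `cernet`: `nodes` (data frame `id`,
#'   `node_type`), `edges` (data frame `source`, `target`, `edge_type`,
#'   `r`, `p`), `triplets` (data frame `mirna_id`, `mrna_id`, `lncrna_id`
#'   plus both edges' statistics) and `comparison`.
#' @export
build_cernet <- function(mrna_pairs, lncrna_pairs, consensus_targets,
                         dev_genes, require_lnc_target = TRUE,
                         comparison = NA_character_) {
  if (inherits(consensus_targets, "target_prediction")) {
    target_keys <- paste(consensus_targets$pairs$mirna_id,
                         consensus_targets$pairs$transcript_id, sep = "\r")
  } else {
    target_keys <- paste(consensus_targets$mirna_id,
                         consensus_targets$transcript_id, sep = "\r")
  }
  keep_retained <- function(pairs) {
    if (is.null(pairs)) {
      pairs <- data.frame(mirna_id = character(0), target_id = character(0),
                          r = numeric(0), p = numeric(0),
                          retained = logical(0), stringsAsFactors = FALSE)
    }
    pairs[which(pairs$retained), , drop = FALSE]
  }
  mp <- keep_retained(mrna_pairs)
  lp <- keep_retained(lncrna_pairs)

  in_targets <- function(pairs) {
    paste(pairs$mirna_id, pairs$target_id, sep = "\r") %in% target_keys
  }
  if (nrow(mp)) {
    ok <- in_targets(mp)
    if (any(!ok)) {
      warning(sum(!ok), " miRNA-mRNA pair(s) lacked target evidence and were dropped")
    }
    mp <- mp[ok & mp$target_id %in% dev_genes, , drop = FALSE]
  }
  if (nrow(lp) && require_lnc_target) {
    ok <- in_targets(lp)
    if (any(!ok)) {
      warning(sum(!ok), " miRNA-lncRNA pair(s) lacked target evidence and were dropped")
    }
    lp <- lp[ok, , drop = FALSE]
  }

  edge_df <- function(pairs, type) {
    if (is.null(pairs) || nrow(pairs) == 0) {
      return(data.frame(source = character(0), target = character(0),
                        edge_type = character(0), r = numeric(0),
                        p = numeric(0), stringsAsFactors = FALSE))
    }
    data.frame(source = pairs$mirna_id, target = pairs$target_id,
               edge_type = type, r = pairs$r, p = pairs$p,
               stringsAsFactors = FALSE)
  }
  edges <- rbind(edge_df(mp, "miRNA-mRNA"), edge_df(lp, "miRNA-lncRNA"))
  edges <- edges[!duplicated(edges[c("source", "target")]), , drop = FALSE]
  rownames(edges) <- NULL

  node_type <- c(
    stats::setNames(rep("miRNA", length(unique(edges$source))),
                    unique(edges$source)),
    stats::setNames(ifelse(unique(edges$target) %in% mp$target_id,
                           "mRNA", "lncRNA"),
                    unique(edges$target)))
  nodes <- data.frame(id = names(node_type), node_type = unname(node_type),
                      stringsAsFactors = FALSE)
  rownames(nodes) <- NULL

  triplets <- if (nrow(mp) && nrow(lp)) {
    tr <- merge(
      data.frame(mirna_id = mp$mirna_id, mrna_id = mp$target_id,
                 mrna_r = mp$r, mrna_p = mp$p, stringsAsFactors = FALSE),
      data.frame(mirna_id = lp$mirna_id, lncrna_id = lp$target_id,
                 lncrna_r = lp$r, lncrna_p = lp$p, stringsAsFactors = FALSE),
      by = "mirna_id")
    tr[order(tr$mirna_id, tr$mrna_id, tr$lncrna_id), , drop = FALSE]
  } else {
    data.frame(mirna_id = character(0), mrna_id = character(0),
               mrna_r = numeric(0), mrna_p = numeric(0),
               lncrna_id = character(0), lncrna_r = numeric(0),
               lncrna_p = numeric(0), stringsAsFactors = FALSE)
  }
  rownames(triplets) <- NULL
  structure(list(nodes = nodes, edges = edges, triplets = triplets,
                 comparison = comparison),
            class = "cernet")
}

#' @export
print.cernet <- function(x, ...) {
  cat(sprintf("<cernet>%s %d nodes, %d edges, %d triplets\n",
              if (is.na(x$comparison)) "" else paste0(" [", x$comparison, "]"),
              nrow(x$nodes), nrow(x$edges), nrow(x$triplets)))
  invisible(x)
}

#' @export
summary.cernet <- function(object, ...) {
  tab <- table(object$nodes$node_type)
  cat("ceRNA network", if (!is.na(object$comparison))
    paste0("(", object$comparison, ")"), "\n")
  cat(sprintf("  nodes: %d (%s)\n", nrow(object$nodes),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  etab <- table(object$edges$edge_type)
  cat(sprintf("  edges: %d (%s)\n", nrow(object$edges),
              paste(sprintf("%s=%d", names(etab), etab), collapse = ", ")))
  cat(sprintf("  ceRNA triplets: %d\n", nrow(object$triplets)))
  invisible(object)
}

cernet_igraph <- function(net) {
  igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                vertices = net$nodes)
}

#' @export
plot.cernet <- function(x, ...) {
  if (nrow(x$edges) == 0) {
    plot.new()
    title("empty ceRNA network")
    return(invisible(x))
  }
  g <- cernet_igraph(x)
  shapes <- c(miRNA = "rectangle", mRNA = "circle", lncRNA = "circle")
  cols <- c(miRNA = "tomato", mRNA = "skyblue", lncRNA = "palegreen")
  igraph::plot.igraph(
    g,
    vertex.shape = shapes[igraph::V(g)$node_type],
    vertex.color = cols[igraph::V(g)$node_type],
    vertex.label.cex = 0.7, ...)
  invisible(x)
}

#' Export a ceRNA network to Cytoscape-compatible files
#'
#' @param net A `cernet`.
#' @param dir Output directory (created if needed).
#' @param formats Subset of `"sif"`, `"edge_table"`, `"node_table"`,
#'   `"graphml"`.
#' @param prefix File-name prefix (default `"cernet"`).
#' @return Named character vector of written paths.
#' @export
export_network <- function(net, dir,
                           formats = c("sif", "edge_table", "node_table",
                                       "graphml"),
                           prefix = "cernet") {
  stopifnot(inherits(net, "cernet"))
  known <- c("sif", "edge_table", "node_table", "graphml")
  bad <- setdiff(formats, known)
  if (length(bad)) stop("unknown export format: ", bad[1])
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  out <- character(0)
  if ("sif" %in% formats) {
    path <- file.path(dir, paste0(prefix, ".sif"))
    writeLines(sprintf("%s\tinteracts\t%s", net$edges$source,
                       net$edges$target), path)
    out["sif"] <- path
  }
  if ("edge_table" %in% formats) {
    path <- file.path(dir, paste0(prefix, "_edges.tsv"))
    write_tsv(net$edges, path)
    out["edge_table"] <- path
  }
  if ("node_table" %in% formats) {
    path <- file.path(dir, paste0(prefix, "_nodes.tsv"))
    write_tsv(net$nodes, path)
    out["node_table"] <- path
  }
  if ("graphml" %in% formats) {
    path <- file.path(dir, paste0(prefix, ".graphml"))
    if (nrow(net$edges)) {
      igraph::write_graph(cernet_igraph(net), path, format = "graphml")
    } else {
      igraph::write_graph(igraph::make_empty_graph(), path,
                          format = "graphml")
    }
    out["graphml"] <- path
  }
  out
}

#' Rebuild a ceRNA network from exported edge and node tables
#'
#' @param edge_path,node_path Paths written by [export_network()].
#' @return A `cernet` (without triplets, which are derivable from the
#'   edges).
#' @export
import_network <- function(edge_path, node_path) {
  edges <- read_tsv(edge_path)
  nodes <- read_tsv(node_path)
  mp <- edges[edges$edge_type == "miRNA-mRNA", , drop = FALSE]
  lp <- edges[edges$edge_type == "miRNA-lncRNA", , drop = FALSE]
  triplets <- if (nrow(mp) && nrow(lp)) {
    tr <- merge(
      data.frame(mirna_id = mp$source, mrna_id = mp$target,
                 mrna_r = mp$r, mrna_p = mp$p, stringsAsFactors = FALSE),
      data.frame(mirna_id = lp$source, lncrna_id = lp$target,
                 lncrna_r = lp$r, lncrna_p = lp$p, stringsAsFactors = FALSE),
      by = "mirna_id")
    tr[order(tr$mirna_id, tr$mrna_id, tr$lncrna_id), , drop = FALSE]
  } else NULL
  structure(list(nodes = nodes, edges = edges,
                 triplets = triplets, comparison = NA_character_),
            class = "cernet")
}

#' Score predicted ceRNA triplets against planted truth
#'
#' Matches on exact (miRNA, mRNA, lncRNA) identity. Precision is TP over
#' predicted (0 when nothing is predicted), recall TP over planted, F1
#' their harmonic mean (0 when undefined).
#'
#' @param predicted Data frame with columns `mirna_id`, `mrna_id`,
#'   `lncrna_id` (e.g. a `cernet`'s `triplets`), or a `cernet`.
#' @param truth A truth list with `planted_triplets` (from
#'   [generate_dataset()]), or the triplet data frame itself.
#' @return List with `tp`, `n_predicted`, `n_planted`, `precision`,
#'   `recall`, `f1`.
#' @export
evaluate_recovery <- function(predicted, truth) {
  if (inherits(predicted, "cernet")) predicted <- predicted$triplets
  planted <- if (is.data.frame(truth)) truth else truth$planted_triplets
  key <- function(df) unique(paste(df$mirna_id, df$mrna_id, df$lncrna_id,
                                   sep = "\r"))
  pk <- if (nrow(predicted)) key(predicted) else character(0)
  tk <- key(planted)
  tp <- length(intersect(pk, tk))
  precision <- if (length(pk) == 0) 0 else tp / length(pk)
  recall <- if (length(tk) == 0) 0 else tp / length(tk)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  list(tp = tp, n_predicted = length(pk), n_planted = length(tk),
       precision = precision, recall = recall, f1 = f1)
}
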
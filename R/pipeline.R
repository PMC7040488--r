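#' Pipeline configuration
#'
#' Bundles every stage threshold (defaulting to the printed screening
#' thresholds: DE p < 0.05 with |log2 fold-change| > 1, co-expression
#' r < -0.7 with p < 0.05, enrichment q < 0.05), the comparison list, the
#' input source (a synthetic bundle or a directory of files) and the seed.
#'
#' @param synthetic Generate the input bundle with [generate_dataset()]
#'   (default TRUE).
#' @param sim A [simulation_config()] used in synthetic mode.
#' @param input_dir Directory of a written bundle (see [write_dataset()])
#'   used when `synthetic = FALSE`.
#' @param comparisons List of 2-vectors of group labels; default all
#'   pairwise comparisons in group order (for the default design:
#'   30d-60d, 30d-90d, 60d-90d).
#' @param p_thr,lfc_thr DE thresholds.
#' @param r_thr,coexpr_p_thr Negative co-expression thresholds.
#' @param q_thr Enrichment significance threshold.
#' @param min_site_type Weakest accepted seed-site class.
#' @param sample_scope `"all"` correlates over all samples; `"comparison"`
#'   restricts to the two compared groups.
#' @param dev_patterns Term-name substrings defining the development gate.
#' @param require_lnc_target Require target evidence on miRNA-lncRNA
#'   edges.
#' @param out_dir Optional output directory; when set, every stage writes
#'   its TSV outputs there.
#' @param rng_seed Seed forwarded to the generator in synthetic mode.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = TRUE, sim = simulation_config(),
                            input_dir = NULL, comparisons = NULL,
                            p_thr = 0.05, lfc_thr = 1,
                            r_thr = -0.7, coexpr_p_thr = 0.05,
                            q_thr = 0.05, min_site_type = "6mer",
                            sample_scope = c("all", "comparison"),
                            dev_patterns = "development",
                            require_lnc_target = TRUE,
                            out_dir = NULL, rng_seed = 1) {
  sample_scope <- match.arg(sample_scope)
  min_site_type <- match.arg(min_site_type, SITE_CLASSES)
  stopifnot(p_thr > 0, p_thr <= 1, coexpr_p_thr > 0, coexpr_p_thr <= 1,
            q_thr > 0, q_thr <= 1, lfc_thr >= 0, r_thr > -1, r_thr <= 0)
  if (!synthetic && is.null(input_dir)) {
    stop("non-synthetic mode needs 'input_dir'")
  }
  if (synthetic) {
    sim$rng_seed <- rng_seed
  }
  structure(list(synthetic = synthetic, sim = sim, input_dir = input_dir,
                 comparisons = comparisons, p_thr = p_thr,
                 lfc_thr = lfc_thr, r_thr = r_thr,
                 coexpr_p_thr = coexpr_p_thr, q_thr = q_thr,
                 min_site_type = min_site_type, sample_scope = sample_scope,
                 dev_patterns = dev_patterns,
                 require_lnc_target = require_lnc_target,
                 out_dir = out_dir, rng_seed = rng_seed),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; the `sim`
#' key holds [simulation_config()] arguments.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  sim_args <- raw$sim
  raw$sim <- NULL
  if (!is.null(raw$comparisons)) {
    raw$comparisons <- lapply(raw$comparisons, unlist)
  }
  args <- raw
  args$sim <- if (is.null(sim_args)) simulation_config()
              else do.call(simulation_config, sim_args)
  do.call(pipeline_config, args)
}

#' Run the full ceRNA-network inference pipeline
#'
#' Stages: input (synthetic generation or bundle read), small-RNA QC and
#' tag collapsing (when reads are present), FPKM/TPM normalization, a DE
#' screen per feature class and comparison, seed-match target prediction,
#' gene-set enrichment with the development gate, negative co-expression
#' screening of DE candidate pairs, network assembly with triplet
#' enumeration and Cytoscape-compatible export, and (with planted truth)
#' recovery scoring. Identical configurations give identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `cerna_pipeline` with `dataset`, `qc`, `tags`,
#'   `normalized`, `targets`, per-comparison results under `comparisons`,
#'   `recovery` (synthetic mode) and a `manifest` of written files (when
#'   `out_dir` is set).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dataset <- if (config$synthetic) generate_dataset(config$sim)
             else read_dataset(config$input_dir)

  out_dir <- config$out_dir
  manifest <- list()
  note <- function(name, path) manifest[[length(manifest) + 1L]] <<-
    data.frame(name = name, path = path, stringsAsFactors = FALSE)
  emit <- function(df, name) {
    if (!is.null(out_dir)) {
      path <- file.path(out_dir, paste0(name, ".tsv"))
      dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
      write_tsv(df, path)
      note(name, path)
    }
  }

  # --- small-RNA QC ------------------------------------------------------
  qc <- NULL
  tags <- NULL
  if (!is.null(dataset$reads)) {
    adapters <- if (!is.null(dataset$config)) {
      list(a5 = dataset$config$adapter5, a3 = dataset$config$adapter3)
    } else {
      list(a5 = qc_params()$adapter5, a3 = qc_params()$adapter3)
    }
    qc <- clean_reads(dataset$reads,
                      qc_params(adapter5 = adapters$a5,
                                adapter3 = adapters$a3))
    tags <- collapse_tags(qc$clean)
    emit(qc$report, "qc_report")
    emit(tags, "clean_tags")
  }

  # --- normalization -----------------------------------------------------
  normalized <- list(
    mrna = fpkm_matrix(dataset$mrna),
    lncrna = fpkm_matrix(dataset$lncrna),
    mirna = tpm_matrix(dataset$mirna, mode = "per_million_tags"))

  # --- target prediction (comparison-independent) ------------------------
  pred_mrna <- predict_targets(dataset$sequences$mirna,
                               dataset$sequences$mrna,
                               min_site_type = config$min_site_type,
                               transcript_class = "mRNA")
  pred_lnc <- predict_targets(dataset$sequences$mirna,
                              dataset$sequences$lncrna,
                              min_site_type = config$min_site_type,
                              transcript_class = "lncRNA")
  targets <- list(mrna = intersect_predictions(list(pred_mrna)),
                  lncrna = intersect_predictions(list(pred_lnc)))
  emit(targets$mrna$pairs, "targets_mrna")
  emit(targets$lncrna$pairs, "targets_lncrna")

  # --- comparisons -------------------------------------------------------
  groups <- unique(dataset$mrna$samples$group)
  comparisons <- config$comparisons
  if (is.null(comparisons)) {
    comparisons <- utils::combn(groups, 2, simplify = FALSE)
  }
  for (cmp in comparisons) {
    if (!all(cmp %in% groups)) {
      stop("comparison references unknown group: ",
           paste(setdiff(cmp, groups), collapse = ", "))
    }
  }

  results <- list()
  for (cmp in comparisons) {
    label <- paste0(cmp[1], "_vs_", cmp[2])
    de <- lapply(normalized, de_screen, groupA = cmp[1], groupB = cmp[2],
                 p_thr = config$p_thr, lfc_thr = config$lfc_thr)
    sig <- lapply(de, function(d) d$feature_id[d$significant])

    enrichment <- enrich_genesets(sig$mrna,
                                  rownames(dataset$mrna$values),
                                  dataset$genesets, q_thr = config$q_thr)
    dev_genes <- select_development_genes(sig$mrna, dataset$genesets,
                                          config$dev_patterns)

    scope <- if (config$sample_scope == "comparison") {
      s <- dataset$mrna$samples
      as.character(s$sample[s$group %in% cmp])
    } else NULL

    cand <- function(pred, sig_targets) {
      p <- pred$pairs
      p[p$mirna_id %in% sig$mirna & p$transcript_id %in% sig_targets, ,
        drop = FALSE]
    }
    mrna_pairs <- screen_negative_pairs(
      normalized$mirna, normalized$mrna, cand(targets$mrna, sig$mrna),
      r_thr = config$r_thr, p_thr = config$coexpr_p_thr,
      sample_scope = scope)
    lnc_pairs <- screen_negative_pairs(
      normalized$mirna, normalized$lncrna, cand(targets$lncrna, sig$lncrna),
      r_thr = config$r_thr, p_thr = config$coexpr_p_thr,
      sample_scope = scope)

    net <- build_cernet(mrna_pairs, lnc_pairs, targets_union(targets),
                        dev_genes,
                        require_lnc_target = config$require_lnc_target,
                        comparison = label)

    for (nm in names(de)) emit(de[[nm]], file.path(label, paste0("de_", nm)))
    emit(enrichment, file.path(label, "enrichment"))
    emit(mrna_pairs, file.path(label, "pairs_mrna"))
    emit(lnc_pairs, file.path(label, "pairs_lncrna"))
    emit(net$triplets, file.path(label, "triplets"))
    if (!is.null(out_dir)) {
      paths <- export_network(net, file.path(out_dir, label))
      for (nm in names(paths)) note(file.path(label, nm), paths[nm])
      writeLines(dev_genes, file.path(out_dir, label, "dev_genes.txt"))
      note(file.path(label, "dev_genes"),
           file.path(out_dir, label, "dev_genes.txt"))
    }

    results[[label]] <- list(comparison = cmp, de = de,
                             enrichment = enrichment, dev_genes = dev_genes,
                             mrna_pairs = mrna_pairs, lnc_pairs = lnc_pairs,
                             network = net)
  }

  # --- recovery against planted truth ------------------------------------
  recovery <- NULL
  all_triplets <- unique(do.call(rbind, lapply(results, function(r)
    r$network$triplets[c("mirna_id", "mrna_id", "lncrna_id")])))
  if (!is.null(dataset$truth) && nrow(dataset$truth$planted_triplets)) {
    recovery <- evaluate_recovery(
      if (is.null(all_triplets)) {
        data.frame(mirna_id = character(0), mrna_id = character(0),
                   lncrna_id = character(0))
      } else all_triplets,
      dataset$truth)
  }

  if (!is.null(out_dir)) {
    log_path <- file.path(out_dir, "run_log.txt")
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    writeLines(c(
      "cernetr pipeline run",
      sprintf("seed: %d", config$rng_seed),
      sprintf("comparisons: %s", paste(names(results), collapse = ", ")),
      sprintf("p_thr: %g  lfc_thr: %g  r_thr: %g  coexpr_p_thr: %g  q_thr: %g",
              config$p_thr, config$lfc_thr, config$r_thr,
              config$coexpr_p_thr, config$q_thr),
      sprintf("min_site_type: %s  sample_scope: %s  dev_patterns: %s",
              config$min_site_type, config$sample_scope,
              paste(config$dev_patterns, collapse = ",")),
      sprintf("require_lnc_target: %s", config$require_lnc_target)),
      log_path)
    note("run_log", log_path)
  }

  structure(list(dataset = dataset, qc = qc, tags = tags,
                 normalized = normalized, targets = targets,
                 comparisons = results, triplets = all_triplets,
                 recovery = recovery,
                 manifest = if (length(manifest)) do.call(rbind, manifest)
                            else NULL,
                 config = config),
            class = "cerna_pipeline")
}

# Union of the mRNA- and lncRNA-side consensus predictions, for the
# network's target-evidence lookup.
targets_union <- function(targets) {
  pairs <- rbind(targets$mrna$pairs, targets$lncrna$pairs)
  sites <- rbind(targets$mrna$sites, targets$lncrna$sites)
  structure(list(pairs = pairs, sites = sites, label = "seedmatch"),
            class = "target_prediction")
}

#' @export
print.cerna_pipeline <- function(x, ...) {
  cat("<cerna_pipeline>\n")
  for (nm in names(x$comparisons)) {
    r <- x$comparisons[[nm]]
    nsig <- vapply(r$de, function(d) sum(d$significant), 0L)
    cat(sprintf("  %s: DE %d mRNA / %d lncRNA / %d miRNA; %d + %d kept pairs; %d triplets\n",
                nm, nsig[["mrna"]], nsig[["lncrna"]], nsig[["mirna"]],
                sum(r$mrna_pairs$retained), sum(r$lnc_pairs$retained),
                nrow(r$network$triplets)))
  }
  if (!is.null(x$recovery)) {
    cat(sprintf("  recovery: precision %.2f, recall %.2f, F1 %.2f\n",
                x$recovery$precision, x$recovery$recall, x$recovery$f1))
  }
  invisible(x)
}
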
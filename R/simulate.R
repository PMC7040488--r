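#' Simulation configuration for a planted-truth transcriptome bundle
#'
#' Describes a bulk time-course design (by default 3 developmental stages x
#' 3 biological replicates, labelled 30d/60d/90d) with log-normal baseline
#' expression, negative-binomial counts, planted differentially expressed
#' features, and planted ceRNA triplets in which one mRNA and one lncRNA
#' carry an 8mer seed site for the same miRNA and are anti-correlated with
#' it at a configurable strength.
#'
#' @param n_mrna,n_lncrna,n_mirna Feature counts per class.
#' @param n_groups Number of stages (default 3, labelled 30d/60d/90d).
#' @param n_reps Biological replicates per stage.
#' @param group_labels Optional stage labels, length `n_groups`.
#' @param n_triplets Number of planted (miRNA, mRNA, lncRNA) ceRNA triplets.
#' @param repression_r Target Pearson correlation between a planted miRNA
#'   and each of its targets, in \[-1, 0).
#' @param de_lfc Planted log2 effect size between adjacent stages.
#' @param n_de_extra Additional planted DE features per class, outside the
#'   triplets.
#' @param dispersion Negative-binomial dispersion (1/size).
#' @param base_log2_mean,base_log2_sd Log2-scale baseline expression
#'   distribution across features.
#' @param latent_sd SD (log2 units) of the shared per-sample latent factor
#'   that couples each triplet's members beyond the stage trend.
#' @param mirna_bg_log2_boost Extra log2 baseline abundance of background
#'   (non-planted) miRNAs, emulating the dominance of abundant
#'   constitutive miRNAs in small-RNA libraries; keeps per-sample library
#'   composition stable so TPM normalization does not distort the planted
#'   couplings.
#' @param utr_len Transcript (3'UTR / lncRNA) sequence length in nt.
#' @param mirna_len Mature miRNA length in nt.
#' @param adapter5,adapter3 Small-RNA library adapter sequences (defaults:
#'   Illumina TruSeq small-RNA RA5/RA3).
#' @param n_reads Total small-RNA reads to emit.
#' @param frac_bad_reads Fraction of reads planted to fail exactly one QC
#'   rule each.
#' @param rng_seed Integer seed; identical configurations give identical
#'   bundles.
#' @return A validated list of class `sim_config`.
#' @export
simulation_config <- function(n_mrna = 200, n_lncrna = 50, n_mirna = 30,
                              n_groups = 3, n_reps = 3, group_labels = NULL,
                              n_triplets = 10, repression_r = -0.9,
                              de_lfc = 3, n_de_extra = 10,
                              dispersion = 0.1,
                              base_log2_mean = 8, base_log2_sd = 1.5,
                              latent_sd = 0.75, mirna_bg_log2_boost = 3,
                              utr_len = 500, mirna_len = 22,
                              adapter5 = "GTTCAGAGTTCTACAGTCCGACGATC",
                              adapter3 = "TGGAATTCTCGGGTGCCAAGG",
                              n_reads = 2000, frac_bad_reads = 0.1,
                              rng_seed = 1) {
  cfg <- list(n_mrna = n_mrna, n_lncrna = n_lncrna, n_mirna = n_mirna,
              n_groups = n_groups, n_reps = n_reps,
              group_labels = group_labels,
              n_triplets = n_triplets, repression_r = repression_r,
              de_lfc = de_lfc, n_de_extra = n_de_extra,
              dispersion = dispersion,
              base_log2_mean = base_log2_mean, base_log2_sd = base_log2_sd,
              latent_sd = latent_sd, mirna_bg_log2_boost = mirna_bg_log2_boost,
              utr_len = utr_len, mirna_len = mirna_len,
              adapter5 = toupper(adapter5), adapter3 = toupper(adapter3),
              n_reads = n_reads, frac_bad_reads = frac_bad_reads,
              rng_seed = rng_seed)
  for (f in c("n_mrna", "n_lncrna", "n_mirna", "n_groups", "n_reps",
              "utr_len", "mirna_len", "n_reads")) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1 || cfg[[f]] < 1) {
      stop("invalid configuration: '", f, "' must be a positive count")
    }
  }
  for (f in c("n_triplets", "n_de_extra")) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 0) {
      stop("invalid configuration: '", f, "' must be a non-negative count")
    }
  }
  if (cfg$n_triplets > min(n_mrna, n_lncrna, n_mirna)) {
    stop("invalid configuration: 'n_triplets' exceeds the smallest feature class")
  }
  if (!(repression_r < 0 && repression_r >= -1)) {
    stop("invalid configuration: 'repression_r' must lie in [-1, 0)")
  }
  if (dispersion <= 0) stop("invalid configuration: 'dispersion' must be > 0")
  if (frac_bad_reads < 0 || frac_bad_reads > 1) {
    stop("invalid configuration: 'frac_bad_reads' must lie in [0, 1]")
  }
  if (!nzchar(cfg$adapter5) || !nzchar(cfg$adapter3)) {
    stop("invalid configuration: 'adapter5'/'adapter3' must be non-empty")
  }
  if (cfg$mirna_len < 8) stop("invalid configuration: 'mirna_len' must be >= 8")
  if (is.null(cfg$group_labels)) {
    cfg$group_labels <- if (n_groups == 3) c("30d", "60d", "90d")
                        else paste0("t", seq_len(n_groups))
  }
  if (length(cfg$group_labels) != n_groups) {
    stop("invalid configuration: 'group_labels' length must equal n_groups")
  }
  class(cfg) <- "sim_config"
  cfg
}

# Run expr with a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

rand_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTU", "TGCAA", toupper(s)), "")[[1]]),
          collapse = "")
  }, "", USE.NAMES = FALSE)
}

contains_any <- function(seq, patterns) {
  any(vapply(patterns, function(p) grepl(p, seq, fixed = TRUE), TRUE))
}

# Draw a background transcript guaranteed free of every listed seed match.
sample_seed_free <- function(len, forbidden_rc6, max_tries = 1000) {
  for (i in seq_len(max_tries)) {
    s <- rand_seq(len)
    if (!contains_any(s, forbidden_rc6)) return(s)
  }
  stop("rejection sampling exhausted: could not draw a seed-free sequence of ",
       len, " nt avoiding ", length(forbidden_rc6), " seeds")
}

# Draw a planted target: one 8mer site for the partner, no seed match for
# any other planted miRNA.
sample_planted_target <- function(len, partner_site8, other_rc6,
                                  max_tries = 1000) {
  if (len < nchar(partner_site8)) stop("'utr_len' shorter than a seed site")
  for (i in seq_len(max_tries)) {
    s <- rand_seq(len)
    pos <- sample.int(len - nchar(partner_site8) + 1L, 1L)
    substr(s, pos, pos + nchar(partner_site8) - 1L) <- partner_site8
    if (!contains_any(s, other_rc6)) {
      return(list(seq = s, start = pos - 1L))  # 0-based
    }
  }
  stop("rejection sampling exhausted: could not plant a target site without ",
       "cross-matching another planted seed")
}

#' Generate a complete synthetic transcriptome bundle with planted truth
#'
#' Draws count matrices for mRNA, lncRNA and miRNA over the configured
#' design, transcript and mature-miRNA sequences, gene-set annotations
#' including a "development" term holding every planted triplet mRNA, and
#' an adapter-flanked small-RNA read set. Background features are
#' independent negative-binomial draws around a log-normal baseline;
#' planted miRNAs follow a monotone stage trend of `de_lfc` log2 units per
#' stage plus a per-sample latent factor, and their planted mRNA and lncRNA
#' targets move oppositely, with independent dilution noise calibrated so
#' the expected empirical Pearson correlation approximates `repression_r`.
#' Planted target sequences carry one 8mer site for the partner miRNA;
#' all other transcript sequences are rejection-sampled to be free of any
#' planted miRNA's seed match.
#'
#' @param config A [simulation_config()].
#' @param include_reads Also generate the small-RNA FASTQ component
#'   (see [generate_smallrna_fastq()]).
#' @return A list of class `cerna_sim` with elements `mrna`, `lncrna`,
#'   `mirna` ([expr_matrix] counts), `sequences` (list `mirna`, `mrna`,
#'   `lncrna` of named character vectors; miRNAs in RNA alphabet),
#'   `genesets`, `reads` (data frame or NULL), `truth` and `config`.
#'   `truth` carries `planted_triplets`, `planted_de`, `planted_sites`,
#'   `development_term_members`, `read_status` and `expected_clean_reads`.
#' @export
generate_dataset <- function(config, include_reads = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  out <- with_seed(config$rng_seed, generate_dataset_impl(config))
  if (include_reads) {
    fq <- generate_smallrna_fastq(config, mirna_seqs = out$sequences$mirna)
    out$reads <- fq$reads
    out$truth$read_status <- fq$truth$read_status
    out$truth$expected_clean_reads <- fq$truth$expected_clean_reads
    out$truth$rule_counts <- fq$truth$rule_counts
  }
  out
}

generate_dataset_impl <- function(config) {
  cfg <- config
  groups <- rep(cfg$group_labels, each = cfg$n_reps)
  reps <- rep(seq_len(cfg$n_reps), times = cfg$n_groups)
  sample_ids <- paste0(groups, "_r", reps)
  samples <- data.frame(sample = sample_ids, group = groups, replicate = reps,
                        stringsAsFactors = FALSE)
  n_samp <- length(sample_ids)

  ids <- list(
    mrna = sprintf("MRNA_%04d", seq_len(cfg$n_mrna)),
    lncrna = sprintf("LNC_%03d", seq_len(cfg$n_lncrna)),
    mirna = sprintf("MIR_%03d", seq_len(cfg$n_mirna))
  )
  nt <- cfg$n_triplets
  nx <- cfg$n_de_extra
  tri_idx <- seq_len(nt)
  extra_idx <- function(n_class) {
    if (nx == 0) integer(0) else (nt + seq_len(min(nx, max(0, n_class - nt))))
  }

  # Stage trend (log2 units), centred so the middle stage sits at baseline.
  centred <- (match(groups, cfg$group_labels) - (cfg$n_groups + 1) / 2)
  trend <- cfg$de_lfc * centred
  v_signal <- cfg$de_lfc^2 * mean(centred^2) + cfg$latent_sd^2
  # First-order correction for attenuation by NB measurement noise on the
  # log scale, so the *empirical* correlation targets repression_r.
  v_noise <- (cfg$dispersion + 2^-cfg$base_log2_mean) / log(2)^2
  atten <- v_signal / (v_signal + v_noise)
  rho0 <- min(0.995, abs(cfg$repression_r) / atten)
  dilution_sd <- sqrt(v_signal * (1 / rho0^2 - 1))

  tri_dir <- rep_len(c(1, -1), nt)              # planted miRNA trend sign
  latent <- if (nt > 0) {
    matrix(stats::rnorm(nt * n_samp, 0, cfg$latent_sd), nt, n_samp)
  } else matrix(0, 0, n_samp)

  make_counts <- function(n_feat, feat_ids, planted_signal, bg_boost = 0) {
    base <- stats::rnorm(n_feat, cfg$base_log2_mean, cfg$base_log2_sd)
    planted_rows <- rowSums(planted_signal != 0) > 0
    base[!planted_rows] <- base[!planted_rows] + bg_boost
    log2mu <- matrix(base, n_feat, n_samp) + planted_signal
    mu <- 2^log2mu
    counts <- matrix(stats::rnbinom(n_feat * n_samp, mu = mu,
                                    size = 1 / cfg$dispersion),
                     n_feat, n_samp,
                     dimnames = list(feat_ids, sample_ids))
    counts
  }

  # Planted signal matrices (log2 offsets added to the baseline).
  sig_mirna <- matrix(0, cfg$n_mirna, n_samp)
  sig_mrna <- matrix(0, cfg$n_mrna, n_samp)
  sig_lncrna <- matrix(0, cfg$n_lncrna, n_samp)
  # The dilution noise that keeps the expected correlation at repression_r
  # is drawn per stage (constant within a stage), modelling repression
  # strength that varies with developmental stage rather than with the
  # individual animal; replicate-level dilution would inflate within-group
  # variance and is not what stage-coherent ceRNA competition looks like.
  grp_of <- match(groups, cfg$group_labels)
  for (t in tri_idx) {
    s_t <- tri_dir[t] * trend + latent[t, ]
    sig_mirna[t, ] <- s_t
    sig_mrna[t, ] <- -s_t +
      stats::rnorm(cfg$n_groups, 0, dilution_sd)[grp_of]
    sig_lncrna[t, ] <- -s_t +
      stats::rnorm(cfg$n_groups, 0, dilution_sd)[grp_of]
  }
  extra_sign <- function(i) if (i %% 2 == 0) 1 else -1
  for (i in extra_idx(cfg$n_mirna)) sig_mirna[i, ] <- extra_sign(i) * trend
  for (i in extra_idx(cfg$n_mrna)) sig_mrna[i, ] <- extra_sign(i) * trend
  for (i in extra_idx(cfg$n_lncrna)) sig_lncrna[i, ] <- extra_sign(i) * trend

  counts <- list(
    mrna = make_counts(cfg$n_mrna, ids$mrna, sig_mrna),
    lncrna = make_counts(cfg$n_lncrna, ids$lncrna, sig_lncrna),
    mirna = make_counts(cfg$n_mirna, ids$mirna, sig_mirna,
                        bg_boost = cfg$mirna_bg_log2_boost)
  )

  # --- sequences ---------------------------------------------------------
  # "Planted" miRNAs (triplet partners and extra DE miRNAs) need mutually
  # distinct seed6s, and every transcript except a miRNA's own planted
  # target must stay free of their seed matches, so that sequence evidence
  # alone separates planted from background interactions.
  planted_mir_idx <- union(tri_idx, extra_idx(cfg$n_mirna))
  mirna_seq <- character(cfg$n_mirna)
  seen_rc6 <- character(0)
  seen_site8 <- character(0)
  for (i in seq_len(cfg$n_mirna)) {
    repeat {
      s <- rand_seq(cfg$mirna_len)
      if (!(i %in% planted_mir_idx)) break
      rc6 <- revcomp(substr(s, 2, 7))
      site8 <- if (i %in% tri_idx) {
        paste0(revcomp(substr(s, 2, 8)), "A")
      } else NULL
      # Planted seeds must be mutually distinct and must not occur inside
      # another planted miRNA's fixed 8mer site, or the target rejection
      # sampling below could never terminate.
      clash <- rc6 %in% seen_rc6 ||
        contains_any(paste(seen_site8, collapse = " "), rc6) ||
        (!is.null(site8) && length(seen_rc6) > 0 &&
           contains_any(site8, seen_rc6))
      if (!clash) {
        seen_rc6 <- c(seen_rc6, rc6)
        seen_site8 <- c(seen_site8, site8)
        break
      }
    }
    mirna_seq[i] <- s
  }
  names(mirna_seq) <- ids$mirna
  planted_rc6 <- revcomp(substr(mirna_seq[planted_mir_idx], 2, 7))
  names(planted_rc6) <- ids$mirna[planted_mir_idx]
  planted_site8 <- paste0(revcomp(substr(mirna_seq[tri_idx], 2, 8)), "A")

  mrna_seq <- character(cfg$n_mrna)
  lncrna_seq <- character(cfg$n_lncrna)
  sites <- list()
  for (t in tri_idx) {
    others <- planted_rc6[names(planted_rc6) != ids$mirna[t]]
    for (cls in c("mrna", "lncrna")) {
      pt <- sample_planted_target(cfg$utr_len, planted_site8[t], others)
      tid <- ids[[cls]][t]
      if (cls == "mrna") mrna_seq[t] <- pt$seq else lncrna_seq[t] <- pt$seq
      sites[[length(sites) + 1L]] <- data.frame(
        mirna_id = ids$mirna[t], transcript_id = tid,
        start = pt$start, end = pt$start + 8L, site_type = "8mer",
        stringsAsFactors = FALSE)
    }
  }
  for (i in setdiff(seq_len(cfg$n_mrna), tri_idx)) {
    mrna_seq[i] <- sample_seed_free(cfg$utr_len, planted_rc6)
  }
  for (i in setdiff(seq_len(cfg$n_lncrna), tri_idx)) {
    lncrna_seq[i] <- sample_seed_free(cfg$utr_len, planted_rc6)
  }
  names(mrna_seq) <- ids$mrna
  names(lncrna_seq) <- ids$lncrna
  planted_sites <- if (length(sites)) do.call(rbind, sites) else
    data.frame(mirna_id = character(0), transcript_id = character(0),
               start = integer(0), end = integer(0),
               site_type = character(0), stringsAsFactors = FALSE)

  # --- gene sets ---------------------------------------------------------
  dev_members <- ids$mrna[tri_idx]
  n_decoys <- min(20L, cfg$n_mrna - nt)
  decoy_pool <- setdiff(ids$mrna, dev_members)
  decoys <- if (n_decoys > 0) sample(decoy_pool, n_decoys) else character(0)
  genesets <- list(list(term_id = "GO:0032502",
                        term_name = "anatomical structure development",
                        members = c(dev_members, decoys)))
  for (k in seq_len(10)) {
    sz <- sample(10:min(40, cfg$n_mrna), 1)
    genesets[[k + 1L]] <- list(
      term_id = sprintf("PW_%03d", k),
      term_name = sprintf("pathway module %02d", k),
      members = sample(ids$mrna, sz))
  }
  names(genesets) <- vapply(genesets, `[[`, "", "term_id")

  # --- truth -------------------------------------------------------------
  planted_triplets <- data.frame(
    mirna_id = ids$mirna[tri_idx], mrna_id = ids$mrna[tri_idx],
    lncrna_id = ids$lncrna[tri_idx], stringsAsFactors = FALSE)

  comparisons <- utils::combn(cfg$group_labels, 2, simplify = FALSE)
  de_rows <- list()
  add_de <- function(fid, cls, sgn) {
    for (cmp in comparisons) {
      cA <- match(cmp[1], cfg$group_labels) - (cfg$n_groups + 1) / 2
      cB <- match(cmp[2], cfg$group_labels) - (cfg$n_groups + 1) / 2
      lfc <- sgn * cfg$de_lfc * (cB - cA)
      de_rows[[length(de_rows) + 1L]] <<- data.frame(
        feature_id = fid, feature_class = cls,
        comparison = paste0(cmp[1], "_vs_", cmp[2]),
        expected_lfc = lfc,
        direction = if (lfc > 0) "up" else "down",
        stringsAsFactors = FALSE)
    }
  }
  for (t in tri_idx) {
    add_de(ids$mirna[t], "miRNA", tri_dir[t])
    add_de(ids$mrna[t], "mRNA", -tri_dir[t])
    add_de(ids$lncrna[t], "lncRNA", -tri_dir[t])
  }
  for (i in extra_idx(cfg$n_mirna)) add_de(ids$mirna[i], "miRNA", extra_sign(i))
  for (i in extra_idx(cfg$n_mrna)) add_de(ids$mrna[i], "mRNA", extra_sign(i))
  for (i in extra_idx(cfg$n_lncrna)) add_de(ids$lncrna[i], "lncRNA", extra_sign(i))
  planted_de <- if (length(de_rows)) do.call(rbind, de_rows) else
    data.frame(feature_id = character(0), feature_class = character(0),
               comparison = character(0), expected_lfc = numeric(0),
               direction = character(0), stringsAsFactors = FALSE)

  lengths_of <- function(seqs) stats::setNames(nchar(seqs), names(seqs))
  structure(list(
    mrna = expr_matrix(counts$mrna, "mRNA", samples,
                       lengths = lengths_of(mrna_seq), unit = "count"),
    lncrna = expr_matrix(counts$lncrna, "lncRNA", samples,
                         lengths = lengths_of(lncrna_seq), unit = "count"),
    mirna = expr_matrix(counts$mirna, "miRNA", samples,
                        lengths = lengths_of(mirna_seq), unit = "count"),
    sequences = list(mirna = chartr("T", "U", mirna_seq),
                     mrna = mrna_seq, lncrna = lncrna_seq),
    genesets = genesets,
    reads = NULL,
    truth = list(planted_triplets = planted_triplets,
                 planted_de = planted_de,
                 planted_sites = planted_sites,
                 development_term_members = genesets[[1]]$members,
                 read_status = NULL,
                 expected_clean_reads = NA_integer_,
                 rule_counts = NULL),
    config = cfg
  ), class = "cerna_sim")
}

#' @export
print.cerna_sim <- function(x, ...) {
  cat("<cerna_sim> synthetic transcriptome bundle\n")
  cat(sprintf("  %d mRNA, %d lncRNA, %d miRNA over %d samples (%d x %d)\n",
              nrow(x$mrna$values), nrow(x$lncrna$values),
              nrow(x$mirna$values), ncol(x$mrna$values),
              x$config$n_groups, x$config$n_reps))
  cat(sprintf("  planted: %d triplets, %d DE records, %d seed sites\n",
              nrow(x$truth$planted_triplets), nrow(x$truth$planted_de),
              nrow(x$truth$planted_sites)))
  if (!is.null(x$reads)) {
    cat(sprintf("  small-RNA reads: %d (%d expected clean)\n",
                nrow(x$reads), x$truth$expected_clean_reads))
  }
  invisible(x)
}

#' Generate adapter-flanked small-RNA reads with planted QC violations
#'
#' Each read is `adapter5 + insert + adapter3` with Phred+33 qualities.
#' Clean reads have every base above the Q20 threshold and inserts of
#' 21-23 nt drawn from mature miRNA sequences (when available) or random
#' tags. A `frac_bad_reads` subset is planted to violate exactly one QC
#' rule each, cycling through: two or more low-quality (Q <= 20) bases, an
#' N base in the insert, a missing 3' adapter, an empty insert, and an
#' insert shorter than 18 nt.
#'
#' @param config A [simulation_config()].
#' @param mirna_seqs Optional named miRNA sequences to draw inserts from
#'   (U or T alphabet).
#' @return List with `reads` (data frame `id`, `seq`, `qual`) and `truth`
#'   (`read_status` data frame with `id`, `keep`, `reason`;
#'   `expected_clean_reads`; `rule_counts` named vector of planted
#'   violations per rule).
#' @export
generate_smallrna_fastq <- function(config, mirna_seqs = NULL) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$rng_seed + 1L, {
    n <- config$n_reads
    n_bad <- round(config$frac_bad_reads * n)
    rules <- c("low_quality", "n_base", "no_adapter", "no_insert", "too_short")
    bad_rule <- if (n_bad > 0) rules[(seq_len(n_bad) - 1L) %% 5L + 1L] else character(0)

    insert_pool <- if (!is.null(mirna_seqs)) chartr("U", "T", toupper(mirna_seqs)) else NULL
    draw_insert <- function(len) {
      if (!is.null(insert_pool)) {
        s <- sample(insert_pool, 1)
        if (nchar(s) >= len) return(substr(s, 1, len))
      }
      rand_seq(len)
    }
    draw_len <- function() sample(21:23, 1, prob = c(0.25, 0.5, 0.25))
    good_qual <- function(len) {
      paste(intToUtf8(sample(28:40, len, replace = TRUE) + 33L,
                      multiple = TRUE), collapse = "")
    }

    ids <- sprintf("read_%05d", seq_len(n))
    status <- rep("keep", n)
    seqs <- character(n)
    quals <- character(n)
    bad_pos <- if (n_bad > 0) sample.int(n, n_bad) else integer(0)
    rule_of <- rep(NA_character_, n)
    rule_of[bad_pos] <- bad_rule

    for (i in seq_len(n)) {
      rule <- rule_of[i]
      insert <- draw_insert(draw_len())
      if (is.na(rule)) {
        seqs[i] <- paste0(config$adapter5, insert, config$adapter3)
      } else if (rule == "low_quality") {
        seqs[i] <- paste0(config$adapter5, insert, config$adapter3)
      } else if (rule == "n_base") {
        pos <- sample.int(nchar(insert), 1)
        substr(insert, pos, pos) <- "N"
        seqs[i] <- paste0(config$adapter5, insert, config$adapter3)
      } else if (rule == "no_adapter") {
        seqs[i] <- paste0(config$adapter5, insert)
      } else if (rule == "no_insert") {
        seqs[i] <- paste0(config$adapter5, config$adapter3)
      } else if (rule == "too_short") {
        seqs[i] <- paste0(config$adapter5, substr(insert, 1, 17), config$adapter3)
      }
      quals[i] <- good_qual(nchar(seqs[i]))
      if (!is.na(rule)) {
        status[i] <- rule
        if (rule == "low_quality") {
          # exactly two bases at Q20 (inclusive threshold)
          lows <- sample.int(nchar(seqs[i]), 2)
          for (p in lows) substr(quals[i], p, p) <- intToUtf8(20L + 33L)
        }
      }
    }

    reads <- data.frame(id = ids, seq = seqs, qual = quals,
                        stringsAsFactors = FALSE)
    read_status <- data.frame(id = ids, keep = status == "keep",
                              reason = ifelse(status == "keep", "", status),
                              stringsAsFactors = FALSE)
    rule_counts <- vapply(rules, function(r) sum(status == r), 0L)
    list(reads = reads,
         truth = list(read_status = read_status,
                      expected_clean_reads = sum(status == "keep"),
                      rule_counts = rule_counts))
  })
}

#' Write a synthetic bundle to a directory of plain-text files
#'
#' Emits TSV count matrices, FASTA sequences, a GMT gene-set file, a FASTQ
#' read file (when present) and the planted-truth tables, and returns a
#' manifest. [read_dataset()] round-trips the result.
#'
#' @param dataset A `cerna_sim` bundle from [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Data frame manifest with columns `name` and `path`.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "cerna_sim"))
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(dir)) stop("cannot create directory: ", dir)
  }
  p <- function(name) file.path(dir, name)
  manifest <- list()
  add <- function(name, path) manifest[[length(manifest) + 1L]] <<-
    data.frame(name = name, path = path, stringsAsFactors = FALSE)

  for (cls in c("mrna", "lncrna", "mirna")) {
    path <- p(paste0(cls, "_counts.tsv"))
    write_expr_tsv(dataset[[cls]], path)
    add(paste0(cls, "_counts"), path)
    add(paste0(cls, "_samples"), samples_path(path))
    fa <- p(paste0(cls, ".fa"))
    write_fasta(dataset$sequences[[cls]], fa)
    add(paste0(cls, "_fasta"), fa)
  }
  write_gmt(dataset$genesets, p("genesets.gmt"))
  add("genesets", p("genesets.gmt"))
  if (!is.null(dataset$reads)) {
    write_fastq(dataset$reads, p("reads.fastq"))
    add("reads", p("reads.fastq"))
    write_tsv(dataset$truth$read_status, p("truth_reads.tsv"))
    add("truth_reads", p("truth_reads.tsv"))
  }
  write_tsv(dataset$truth$planted_triplets, p("truth_triplets.tsv"))
  add("truth_triplets", p("truth_triplets.tsv"))
  write_tsv(dataset$truth$planted_de, p("truth_de.tsv"))
  add("truth_de", p("truth_de.tsv"))
  write_tsv(dataset$truth$planted_sites, p("truth_sites.tsv"))
  add("truth_sites", p("truth_sites.tsv"))
  writeLines(dataset$truth$development_term_members, p("truth_dev_members.txt"))
  add("truth_dev_members", p("truth_dev_members.txt"))
  do.call(rbind, manifest)
}

#' Read a bundle written by [write_dataset()]
#'
#' @param dir Directory containing the bundle files.
#' @return A list shaped like the output of [generate_dataset()] (without
#'   `config`).
#' @export
read_dataset <- function(dir) {
  p <- function(name) file.path(dir, name)
  out <- list(
    mrna = read_expr_tsv(p("mrna_counts.tsv")),
    lncrna = read_expr_tsv(p("lncrna_counts.tsv")),
    mirna = read_expr_tsv(p("mirna_counts.tsv")),
    sequences = list(mirna = read_fasta(p("mirna.fa")),
                     mrna = read_fasta(p("mrna.fa")),
                     lncrna = read_fasta(p("lncrna.fa"))),
    genesets = read_gmt(p("genesets.gmt")),
    reads = if (file.exists(p("reads.fastq"))) read_fastq(p("reads.fastq")),
    truth = list(
      planted_triplets = read_tsv(p("truth_triplets.tsv")),
      planted_de = read_tsv(p("truth_de.tsv")),
      planted_sites = read_tsv(p("truth_sites.tsv")),
      development_term_members = readLines(p("truth_dev_members.txt")),
      read_status = if (file.exists(p("truth_reads.tsv")))
        read_tsv(p("truth_reads.tsv"))),
    config = NULL
  )
  if (!is.null(out$truth$read_status)) {
    out$truth$expected_clean_reads <- sum(out$truth$read_status$keep)
  }
  class(out) <- "cerna_sim"
  out
}
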
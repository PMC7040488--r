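# Independent from-definition oracles used to cross-check the package's
# statistics, plus small shared fixtures. Each oracle is written straight
# from the defining formula and shares no code with the implementation.

# Pearson r and two-sided p from the t transform, by hand.
oracle_pearson <- function(x, y) {
  n <- length(x)
  xc <- x - mean(x)
  yc <- y - mean(y)
  r <- sum(xc * yc) / sqrt(sum(xc^2) * sum(yc^2))
  if (abs(r) >= 1) return(list(r = sign(r), p = 0))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(t), df = n - 2))
}

# Brute-force BH step-up: q_(i) = min_{j >= i} m p_(j) / j, capped at 1.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(1, min(m * ps[i:m] / (i:m)))
  }
  out <- numeric(m)
  out[ord] <- q
  out
}

# Hypergeometric upper tail by direct summation of the mass function.
oracle_hyper <- function(x, K, n, N) {
  ks <- x:min(n, K)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

oracle_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

# Naive per-offset seed-site classifier: tests every transcript offset
# against the seed7 and seed6 reverse complements directly.
oracle_seed_sites <- function(mirna, transcript) {
  m <- chartr("U", "T", toupper(mirna))
  tx <- chartr("U", "T", toupper(transcript))
  len <- nchar(tx)
  rc7 <- oracle_revcomp(substr(m, 2, 8))
  rc6 <- oracle_revcomp(substr(m, 2, 7))
  out <- list()
  # seed7-anchored classes
  if (len >= 7) {
    for (q in 0:(len - 7)) {
      if (substr(tx, q + 1, q + 7) == rc7) {
        if (q + 8 <= len && substr(tx, q + 8, q + 8) == "A") {
          out[[length(out) + 1]] <- data.frame(start = q, end = q + 8L,
                                               site_type = "8mer")
        } else {
          out[[length(out) + 1]] <- data.frame(start = q, end = q + 7L,
                                               site_type = "7mer-m8")
        }
      }
    }
  }
  # seed6-only classes (anchor not extendable to the seed7 match)
  if (len >= 6) {
    for (p in 0:(len - 6)) {
      if (substr(tx, p + 1, p + 6) == rc6) {
        part_of_seed7 <- p >= 1 && substr(tx, p, p + 6) == rc7
        if (!part_of_seed7) {
          if (p + 7 <= len && substr(tx, p + 7, p + 7) == "A") {
            out[[length(out) + 1]] <- data.frame(start = p, end = p + 7L,
                                                 site_type = "7mer-A1")
          } else {
            out[[length(out) + 1]] <- data.frame(start = p, end = p + 6L,
                                                 site_type = "6mer")
          }
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(0), end = integer(0),
                      site_type = character(0), stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, out)
  df <- df[order(df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  df$site_type <- as.character(df$site_type)
  df
}

random_nt <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# A vector pair with an exact preset Pearson correlation, built by
# orthogonalization.
vectors_with_r <- function(r, n, seed = 1) {
  set.seed(seed)
  x <- scale(seq_len(n))[, 1]
  e <- stats::rnorm(n)
  e <- stats::residuals(stats::lm(e ~ x))
  e <- e / sqrt(sum(e^2) / (n - 1))
  x <- x / sqrt(sum(x^2) / (n - 1))
  list(x = x, y = r * x + sqrt(1 - r^2) * e)
}

# Small fast bundle shared across tests.
tiny_config <- function(...) {
  args <- list(n_mrna = 40, n_lncrna = 15, n_mirna = 10, n_triplets = 3,
               n_de_extra = 3, n_reads = 200, rng_seed = 11)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(simulation_config, args)
}

# A hand-made expression matrix over a 2-group design.
toy_expr <- function(values, feature_class = "mRNA", lengths = NULL,
                     unit = "count", n_reps = 3) {
  n <- ncol(values)
  groups <- rep(c("30d", "60d", "90d"), each = n_reps, length.out = n)
  samples <- data.frame(sample = colnames(values), group = groups,
                        replicate = rep(seq_len(n_reps), length.out = n))
  expr_matrix(values, feature_class, samples, lengths, unit)
}
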
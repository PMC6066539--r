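# Shared fixture builders. All fixtures are generated in code; nothing is
# read from disk except in explicit round-trip tests (which write to
# tempfiles first).

# A small expression study: `profiles` is a genes x stages matrix of
# log2(FPKM + 1) means; each stage gets `n_rep` replicates with Gaussian
# noise `sd` on the log scale.
toy_study <- function(profiles, n_rep = 2, sd = 0, seed = 1,
                      stages = colnames(profiles)) {
  set.seed(seed)
  design <- stage_design(transcriptome_stages = stages,
                         physiology_stages = c("W", "S1", "R1", "S2"),
                         equivalence = c())
  samples <- data.frame(
    sample = paste0(rep(stages, each = n_rep), "_r", seq_len(n_rep)),
    stage = rep(stages, each = n_rep),
    replicate = rep(seq_len(n_rep), times = length(stages)))
  logm <- profiles[, samples$stage, drop = FALSE] +
    matrix(rnorm(nrow(profiles) * nrow(samples), sd = sd),
           nrow(profiles), nrow(samples))
  fpkm <- pmax(2^logm - 1, 0)
  colnames(fpkm) <- samples$sample
  rownames(fpkm) <- rownames(profiles)
  expression_study(fpkm, samples, design)
}

# Long physiology table from a named list stage -> mean, replicated over
# plants with optional noise.
toy_physiology <- function(param_means, n_plants = 4, sd = 0, seed = 1) {
  set.seed(seed)
  rows <- list()
  for (p in names(param_means)) {
    means <- param_means[[p]]
    for (s in names(means)) {
      rows[[length(rows) + 1L]] <- data.frame(
        plant_id = sprintf("p%02d", seq_len(n_plants)), stage = s,
        parameter = p, value = means[[s]] + rnorm(n_plants, sd = sd))
    }
  }
  physiology_table(do.call(rbind, rows))
}

# Independent Pearson correlation (textbook formula, no stats::cor).
manual_pearson <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Independent Benjamini-Hochberg step-up (sort, scale, cumulative min).
manual_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# Brute-force hypergeometric upper tail P(X >= k) by direct summation of
# binomial-coefficient terms.
manual_hyper_tail <- function(k, K, N, n) {
  ks <- max(k, max(0, n - (N - K))):min(n, K)
  if (k > min(n, K)) return(0)
  sum(exp(lchoose(K, ks) + lchoose(N - K, n - ks) - lchoose(N, n)))
}

# Minimal average-linkage agglomeration oracle: returns the groups obtained
# by merging while the closest average distance is <= cut.
manual_average_linkage_groups <- function(d, cut) {
  groups <- as.list(seq_len(nrow(d)))
  repeat {
    if (length(groups) == 1L) break
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(groups)) for (j in seq_along(groups)) {
      if (i >= j) next
      avg <- mean(d[groups[[i]], groups[[j]]])
      if (avg < best_d) { best_d <- avg; best <- c(i, j) }
    }
    if (best_d > cut) break
    groups[[best[1]]] <- c(groups[[best[1]]], groups[[best[2]]])
    groups[[best[2]]] <- NULL
  }
  labels <- integer(nrow(d))
  for (g in seq_along(groups)) labels[groups[[g]]] <- g
  labels
}
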
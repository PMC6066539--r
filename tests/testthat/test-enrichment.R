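# Build an annotation table realizing exact 2x2 counts: k of the first n
# genes (the module) and K - k of the remaining genes carry the term.
annotation_for <- function(term, k, K, n, N) {
  genes <- sprintf("g%04d", seq_len(N))
  data.frame(gene = c(genes[seq_len(k)], genes[n + seq_len(K - k)]),
             term = term, stringsAsFactors = FALSE)
}

test_that("terms below the mapping floor are not tested", {
  N <- 100; n <- 20
  genes <- sprintf("g%04d", seq_len(N))
  ann <- rbind(annotation_for("GO:small", 4, 4, n, N),
               annotation_for("GO:big", 5, 10, n, N))
  res <- fisher_enrichment(genes[seq_len(n)], ann, genes)
  expect_equal(res$term, "GO:big")
  res2 <- fisher_enrichment(genes[seq_len(n)], ann, genes,
                            run_config(min_mapped_entries = 4))
  expect_setequal(res2$term, c("GO:small", "GO:big"))
})

test_that("an unannotated module scores p = 1 and counts are consistent", {
  N <- 50; n <- 10
  genes <- sprintf("g%04d", seq_len(N))
  ann <- annotation_for("GO:a", 0, 8, n, N)
  res <- fisher_enrichment(genes[seq_len(n)], ann, genes)
  expect_equal(res$k, 0L)
  expect_equal(res$p, 1)
  expect_equal(res$K, 8L)
  expect_error(fisher_enrichment(genes[1:10], ann, character(0)), "empty reference")
  expect_error(fisher_enrichment(c(genes[1:3], "alien"), ann, genes),
               "not in reference")
})

test_that("the worked hypergeometric example matches direct summation", {
  N <- 1000; n <- 50; K <- 100; k <- 5
  genes <- sprintf("g%04d", seq_len(N))
  ann <- annotation_for("GO:a", k, K, n, N)
  res <- fisher_enrichment(genes[seq_len(n)], ann, genes)
  expect_equal(res$p, manual_hyper_tail(k, K, N, n), tolerance = 1e-12)
})

test_that("Fisher p equals the brute-force tail over a dense small-table sweep", {
  cfg <- run_config(min_mapped_entries = 1)
  for (N in c(12, 25)) {
    genes <- sprintf("g%04d", seq_len(N))
    for (n in seq(1, N - 1, by = 3)) {
      # one call tests every feasible (K, k) pair as its own term
      combos <- expand.grid(K = seq_len(N), k = 0:n)
      combos <- combos[combos$k <= combos$K &
                         combos$K - combos$k <= N - n, , drop = FALSE]
      ann <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
        annotation_for(sprintf("GO:%d_%d", combos$K[i], combos$k[i]),
                       combos$k[i], combos$K[i], n, N)
      }))
      res <- fisher_enrichment(genes[seq_len(n)], ann, genes, cfg)
      idx <- match(res$term, sprintf("GO:%d_%d", combos$K, combos$k))
      oracle <- vapply(idx, function(i) {
        manual_hyper_tail(combos$k[i], combos$K[i], N, n)
      }, numeric(1))
      expect_equal(res$p, oracle, tolerance = 1e-11)
      expect_equal(res$k, combos$k[idx])
    }
  }
})

test_that("within-module FDR equals the independent step-up oracle", {
  set.seed(81)
  N <- 300; n <- 40
  genes <- sprintf("g%04d", seq_len(N))
  ann <- do.call(rbind, lapply(1:25, function(t) {
    K <- sample(5:60, 1)
    k <- sample(0:min(n, K), 1)
    if (K - k > N - n) k <- K - (N - n)
    annotation_for(sprintf("GO:%02d", t), k, K, n, N)
  }))
  res <- fisher_enrichment(genes[seq_len(n)], ann, genes)
  expect_equal(res$fdr, manual_bh(res$p), tolerance = 1e-12)
  expect_true(all(res$fdr >= res$p - 1e-12))
  expect_true(all(diff(res$fdr) >= -1e-12))  # sorted by fdr
})

test_that("planted enrichments win their module at module size 50", {
  spec <- simulation_spec(n_genes = 1000, modules = default_modules(50),
                          enrichment_plan = default_enrichment_plan(5, odds = 8),
                          seed = 91)
  sim <- simulate_expression(spec)
  ann <- simulate_annotations(spec, sim$truth)
  ref <- names(sim$truth$module)
  for (m in 1:5) {
    res <- fisher_enrichment(ref[sim$truth$module == m], ann$annotations, ref)
    planted <- ann$truth$enriched$term[ann$truth$enriched$module == m]
    expect_equal(res$term[1], planted)
    expect_lt(res$fdr[1], 0.05)
  }
})

test_that("slim rollup takes the group minimum and routes unmapped terms to other", {
  res <- structure(data.frame(
    module = c("M1", "M1", "M1", "M2"),
    term = c("GO:1", "GO:2", "GO:3", "GO:1"),
    k = 1L, n = 10L, K = 5L, N = 100L, odds_ratio = 1,
    p = c(0.001, 0.15, 0.3, 0.02),
    fdr = c(0.001, 0.2, 0.3, 0.02)),
    class = c("enrichment_result", "data.frame"))
  slim <- data.frame(term = c("GO:1", "GO:2"), slim = c("metabolism", "metabolism"))
  roll <- slim_rollup(res, slim)
  expect_equal(roll$min_fdr[roll$module == "M1" & roll$slim == "metabolism"], 0.001)
  expect_equal(roll$min_fdr[roll$module == "M1" & roll$slim == "other"], 0.3)
  expect_equal(roll$min_fdr[roll$module == "M2" & roll$slim == "metabolism"], 0.02)
  expect_equal(roll$neg_log10_fdr, -log10(roll$min_fdr))

  # brute-force group-min oracle on random groupings
  set.seed(92)
  terms <- sprintf("GO:%02d", 1:30)
  res2 <- structure(data.frame(
    module = "M1", term = terms, k = 1L, n = 10L, K = 5L, N = 100L,
    odds_ratio = 1, p = runif(30), fdr = runif(30)),
    class = c("enrichment_result", "data.frame"))
  slim2 <- data.frame(term = terms,
                      slim = sample(c("s1", "s2", "s3"), 30, replace = TRUE))
  roll2 <- slim_rollup(res2, slim2)
  for (s in unique(slim2$slim)) {
    expect_equal(roll2$min_fdr[roll2$slim == s],
                 min(res2$fdr[slim2$slim[match(res2$term, slim2$term)] == s]))
  }
})
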
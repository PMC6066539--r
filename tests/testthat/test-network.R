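test_that("variation filter uses a strict range threshold", {
  fpkm <- rbind(const = rep(2, 4),
                barely = c(2, 2, 2, 2.05),
                kept = c(2, 2, 2, 2.06))
  colnames(fpkm) <- paste0("s", 1:4)
  samples <- data.frame(sample = colnames(fpkm),
                        stage = c("W", "W", "S1", "S1"), replicate = c(1, 2, 1, 2))
  design <- stage_design(transcriptome_stages = c("W", "S1"), equivalence = c())
  study <- expression_study(fpkm, samples, design)
  flt <- variation_filter(study, 0.05)
  expect_equal(rownames(flt$fpkm), "kept")

  # filter count on a random matrix equals a brute-force scan
  set.seed(5)
  rnd <- matrix(runif(200, 0, 0.2), 50, 4,
                dimnames = list(paste0("g", 1:50), colnames(fpkm)))
  rstudy <- expression_study(rnd, samples, design)
  brute <- sum(apply(rnd, 1, function(v) diff(range(v)) > 0.05))
  expect_equal(nrow(variation_filter(rstudy, 0.05)$fpkm), brute)
})

test_that("correlation dissimilarity is a proper unsigned dissimilarity", {
  set.seed(8)
  prof <- matrix(runif(30, 1, 8), 10, 3,
                 dimnames = list(paste0("g", 1:10), c("W", "S1", "S3")))
  prof[2, ] <- prof[1, ]  # duplicated gene
  study <- toy_study(prof, sd = 0, seed = 8)
  d <- gene_dissimilarity(study, "cor")
  expect_equal(d[1, 2], 0)
  expect_true(all(abs(d - t(d)) < 1e-12))
  expect_true(all(diag(d) == 0))
  expect_true(all(d >= 0 & d <= 1))

  # anti-correlated profiles are close in an unsigned network
  prof2 <- rbind(up = c(1, 4, 7), down = c(7, 4, 1))
  colnames(prof2) <- c("W", "S1", "S3")
  study2 <- toy_study(prof2)
  expect_equal(gene_dissimilarity(study2, "cor")[1, 2], 0)

  const <- prof; const[3, ] <- 5
  study3 <- toy_study(const)
  expect_error(gene_dissimilarity(study3), "zero-variance")
})

test_that("TOM dissimilarity equals a direct triple-sum oracle on a toy matrix", {
  set.seed(13)
  prof <- matrix(runif(24, 1, 8), 4, 6,
                 dimnames = list(paste0("g", 1:4), paste0("t", 1:6)))
  study <- toy_study(prof, n_rep = 1, stages = colnames(prof))
  power <- 3
  d <- gene_dissimilarity(study, "tom", power = power)
  a <- abs(cor(t(log2(study$fpkm + 1))))^power
  diag(a) <- 0
  n <- nrow(a)
  oracle <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    if (i == j) next
    num <- sum(sapply(seq_len(n)[-c(i, j)], function(u) a[i, u] * a[u, j])) + a[i, j]
    ki <- sum(a[i, -i]); kj <- sum(a[j, -j])
    oracle[i, j] <- 1 - num / (min(ki, kj) + 1 - a[i, j])
  }
  expect_equal(unname(d), oracle, tolerance = 1e-12)
})

test_that("white-noise gene pairs match the sample-correlation oracle and sit near 1", {
  set.seed(21)
  stages <- paste0("t", 1:30)
  prof <- matrix(rnorm(60, 5, 1), 2, 30,
                 dimnames = list(c("g1", "g2"), stages))
  study <- toy_study(prof, n_rep = 1, stages = stages)
  d <- gene_dissimilarity(study, "tom", power = 1)
  # with two genes TOM reduces to 1 - a_ij = 1 - |r|
  x <- log2(study$fpkm + 1)
  expect_equal(d[1, 2], 1 - abs(manual_pearson(x[1, ], x[2, ])),
               tolerance = 1e-12)
  expect_gt(d[1, 2], 0.6)
})

test_that("two clean blocks are cut into exactly two exact modules", {
  profiles <- rbind(
    matrix(rep(c(2, 6, 4), each = 40), 40, 3),
    matrix(rep(c(6, 2, 7), each = 40), 40, 3))
  dimnames(profiles) <- list(sprintf("g%03d", 1:80), c("W", "S1", "S3"))
  study <- toy_study(profiles, sd = 1e-4, seed = 3)
  d <- gene_dissimilarity(study)
  part <- cluster_and_cut(d, min_module_size = 30)
  expect_length(part$sizes, 2L)
  expect_equal(unname(part$sizes), c(40L, 40L))
  expect_equal(adjusted_rand_index(part$module, rep(1:2, each = 40)), 1)
})

test_that("fewer genes than the module floor leaves everything unassigned", {
  set.seed(17)
  prof <- matrix(runif(60, 1, 8), 20, 3,
                 dimnames = list(paste0("g", 1:20), c("W", "S1", "S3")))
  study <- toy_study(prof, sd = 0.01, seed = 17)
  part <- cluster_and_cut(gene_dissimilarity(study), min_module_size = 30)
  expect_length(part$sizes, 0L)
  expect_true(all(part$module == 0))
})

test_that("a low-noise planted 5-module simulation is recovered exactly", {
  spec <- simulation_spec(n_genes = 250, modules = default_modules(50),
                          replicate_sd = 0.02, seed = 99)
  sim <- simulate_expression(spec)
  part <- cluster_and_cut(gene_dissimilarity(sim$study), 30)
  expect_equal(adjusted_rand_index(part$module, sim$truth$module), 1)
})

test_that("partitioning is deterministic for identical input", {
  spec <- simulation_spec(n_genes = 400, modules = default_modules(40),
                          seed = 7)
  sim <- simulate_expression(spec)
  d <- gene_dissimilarity(sim$study)
  p1 <- cluster_and_cut(d, 30)
  p2 <- cluster_and_cut(d, 30)
  expect_identical(p1$module, p2$module)
})

test_that("eigengenes match an independent eigendecomposition oracle", {
  set.seed(31)
  for (rep in 1:10) {
    prof <- matrix(runif(60, 1, 9), 10, 6,
                   dimnames = list(paste0("g", 1:10), paste0("t", 1:6)))
    study <- toy_study(prof, n_rep = 1, sd = 0.3, seed = rep,
                       stages = colnames(prof))
    part <- structure(list(module = setNames(rep(1L, 10), rownames(prof)),
                           sizes = c(`1` = 10L)), class = "module_partition")
    eig <- compute_eigengenes(study, part)
    z <- t(scale(t(log2(study$fpkm + 1))))
    ed <- eigen(crossprod(z), symmetric = TRUE)
    v <- ed$vectors[, 1]
    if (manual_pearson(v, colMeans(z)) < 0) v <- -v
    expect_equal(unname(eig$eigengenes[, 1]), unname(v), tolerance = 1e-9)
    expect_equal(unname(eig$var_explained[1]),
                 ed$values[1] / sum(ed$values), tolerance = 1e-9)
  }
})

test_that("eigengene orientation and degenerate modules behave as documented", {
  prof <- matrix(rep(c(2, 5, 8), each = 4), 4, 3,
                 dimnames = list(paste0("g", 1:4), c("W", "S1", "S3")))
  study <- toy_study(prof, sd = 0, seed = 1)
  part <- structure(list(module = setNames(rep(1L, 4), rownames(prof)),
                         sizes = c(`1` = 4L)), class = "module_partition")
  eig <- compute_eigengenes(study, part)
  # identical genes: all variance on the first component
  expect_equal(unname(eig$var_explained[1]), 1)
  expect_equal(sum(eig$eigengenes[, 1]^2), 1)
  # orientation contract: non-negative correlation with the mean profile
  z <- colMeans(t(scale(t(log2(study$fpkm + 1)))))
  expect_gte(manual_pearson(eig$eigengenes[, 1], z), 0)

  solo <- structure(list(module = setNames(c(1L, 0L, 0L, 0L), rownames(prof)),
                         sizes = c(`1` = 1L)), class = "module_partition")
  eig1 <- compute_eigengenes(study, solo)
  expect_equal(unname(eig1$var_explained[1]), 1)
})

test_that("meta-module grouping matches a manual average-linkage oracle", {
  set.seed(41)
  base <- scale(rnorm(6))[, 1]
  noise <- scale(residuals(lm(rnorm(6) ~ base)))[, 1]
  me <- cbind(M1 = base,
              M2 = sqrt(0.97) * base + sqrt(0.03) * noise,  # r ~ 0.985
              M3 = noise,                                    # r ~ 0 with M1
              M4 = -base)                                    # r = -1 with M1
  eigs <- structure(list(eigengenes = me,
                         var_explained = setNames(rep(1, 4), colnames(me)),
                         samples = data.frame(sample = paste0("s", 1:6))),
                    class = "eigengene_set")
  grouping <- group_metamodules(eigs, cut = 0.2)
  d <- 1 - cor(me)
  oracle <- manual_average_linkage_groups(d, 0.2)
  expect_equal(adjusted_rand_index(grouping$meta, oracle), 1)
  # M1/M2 together; the anti-correlated module stays solo at cut 0.2
  expect_equal(grouping$meta[["M1"]], grouping$meta[["M2"]])
  expect_length(unique(grouping$meta[c("M3", "M4")]), 2L)
  expect_false(grouping$meta[["M4"]] %in% grouping$meta[c("M1", "M2", "M3")])

  # perfectly correlated eigengenes are at distance zero and always merge
  two <- structure(list(eigengenes = cbind(M1 = base, M2 = base),
                        var_explained = c(M1 = 1, M2 = 1),
                        samples = data.frame(sample = paste0("s", 1:6))),
                   class = "eigengene_set")
  g2 <- group_metamodules(two, cut = 0.2)
  expect_equal(unname(g2$meta), c("A", "A"))
})

test_that("in-package adjusted Rand index agrees with mclust", {
  skip_if_not_installed("mclust")
  set.seed(51)
  for (i in 1:20) {
    a <- sample(0:4, 60, replace = TRUE)
    b <- sample(0:3, 60, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b),
                 unname(mclust::adjustedRandIndex(a, b)), tolerance = 1e-12)
  }
})
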
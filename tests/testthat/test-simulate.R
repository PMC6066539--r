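test_that("the generator is bit-identical under a fixed seed", {
  spec <- simulation_spec(n_genes = 200, modules = default_modules(30),
                          seed = 77)
  a <- simulate_expression(spec)
  b <- simulate_expression(spec)
  expect_identical(a$study$fpkm, b$study$fpkm)
  expect_identical(a$truth, b$truth)
  pa <- simulate_physiology(spec)
  pb <- simulate_physiology(spec)
  expect_identical(pa$table$value, pb$table$value)
  aa <- simulate_annotations(spec, a$truth)
  ab <- simulate_annotations(spec, a$truth)
  expect_identical(aa$annotations, ab$annotations)
  # different seed, different draws
  spec2 <- simulation_spec(n_genes = 200, modules = default_modules(30),
                           seed = 78)
  expect_false(identical(simulate_expression(spec2)$study$fpkm, a$study$fpkm))
})

test_that("the generator does not disturb the caller's RNG stream", {
  set.seed(123); before <- rnorm(1)
  set.seed(123)
  invisible(simulate_expression(simulation_spec(n_genes = 60,
                                                modules = default_modules(10),
                                                seed = 5)))
  expect_identical(rnorm(1), before)
})

test_that("zero noise and unit loading make within-module replicates identical", {
  mods <- list(list(size = 10, profile = c(W = 4, S1 = 6, S3 = 8),
                    pattern = "[+/+]"))
  spec <- simulation_spec(n_genes = 10, modules = mods, replicate_sd = 0,
                          loading_sd = 0, seed = 1)
  sim <- simulate_expression(spec)
  fpkm <- sim$study$fpkm
  stage <- sim$study$samples$stage
  for (s in unique(stage)) {
    cols <- which(stage == s)
    expect_equal(fpkm[, cols[1]], fpkm[, cols[2]])
  }
  # all module genes share the exact profile
  expect_equal(unname(fpkm[1, ]), unname(fpkm[10, ]))
  expect_equal(unname(log2(fpkm[1, stage == "S1"][1] + 1)), 6)
})

test_that("profiles that contradict the declared pattern are rejected before sampling", {
  bad <- list(list(size = 10, profile = c(W = 4, S1 = 4.5, S3 = 8),
                   pattern = "[+/+]"))
  expect_error(simulation_spec(n_genes = 20, modules = bad), "contradicts")
  bad2 <- list(list(size = 10, profile = c(W = 4, S1 = 6, S3 = 8),
                    pattern = "[=/+]"))
  expect_error(simulation_spec(n_genes = 20, modules = bad2), "contradicts")
  expect_error(simulation_spec(n_genes = 5, modules = default_modules(10)),
               "exceed")
  expect_error(simulation_spec(replicate_sd = -0.1), "non-negative")
})

test_that("within-module correlation exceeds background correlation", {
  spec <- simulation_spec(n_genes = 150, modules = default_modules(50)[1],
                          replicate_sd = 0.1, seed = 33)
  sim <- simulate_expression(spec)
  x <- log2(sim$study$fpkm + 1)
  mod <- names(sim$truth$module)[sim$truth$module == 1]
  bg <- names(sim$truth$module)[sim$truth$module == 0]
  pair_r <- function(genes) {
    pairs <- combn(genes[1:20], 2)
    mean(apply(pairs, 2, function(p) abs(manual_pearson(x[p[1], ], x[p[2], ]))))
  }
  expect_gt(pair_r(mod), 0.95)
  expect_gt(pair_r(mod), pair_r(bg) + 0.3)
})

test_that("zero-sd physiology reproduces stage means exactly", {
  plan <- default_physiology_plan()
  plan$sd <- 0
  spec <- simulation_spec(physiology_plan = plan, n_plants = 3, seed = 9)
  phys <- simulate_physiology(spec)
  gs <- phys$table[phys$table$parameter == "g_s", ]
  expect_true(all(gs$value[gs$stage == "W"] == 150))
  expect_true(all(gs$value[gs$stage == "S2"] == 30))
  expect_error({
    p2 <- plan; p2$sd[1] <- -1
    simulation_spec(physiology_plan = p2)
  }, "non-negative")
  expect_error(simulation_spec(n_plants = 1), "at least 2 plants")
})

test_that("the zero-noise stomatal-conductance plan classifies as [-/-] memory", {
  plan <- default_physiology_plan()
  plan$sd <- 0
  spec <- simulation_spec(physiology_plan = plan, n_plants = 4, seed = 10)
  phys <- simulate_physiology(spec)
  call <- classify_physiology_memory(phys$table, "g_s")
  expect_equal(call$pattern, "[-/-]")
  expect_equal(call$category, "memory")
})

test_that("raw-fluorescence mode carries the planted Genty yield exactly", {
  plan <- default_physiology_plan()
  plan$sd <- 0
  spec <- simulation_spec(physiology_plan = plan, n_plants = 3, seed = 11)
  raw <- simulate_physiology(spec, mode = "raw_fluorescence")
  derived <- derive_physiology(raw$table)
  phi <- derived[derived$parameter == "phiPSII", ]
  for (s in c("W", "S1", "R1", "S2")) {
    expect_equal(unique(phi$value[phi$stage == s]),
                 plan[plan$parameter == "phiPSII", s], tolerance = 1e-9)
  }
})

test_that("planted annotation odds are realized in the 2x2 table", {
  mods <- list(list(size = 250, profile = c(W = 6, S1 = 8, S3 = 8),
                    pattern = "[+/=]"))
  plan <- data.frame(module = 1, term = "GO:X", odds = 4)
  spec <- simulation_spec(n_genes = 500, modules = mods,
                          enrichment_plan = plan, annotation_baseline = 0.2,
                          n_background_terms = 2, seed = 55)
  sim <- simulate_expression(spec)
  ann <- simulate_annotations(spec, sim$truth)$annotations
  hit <- names(sim$truth$module) %in% ann$gene[ann$term == "GO:X"]
  inside <- sim$truth$module == 1
  tab <- table(inside, hit)
  or <- (tab["TRUE", "TRUE"] * tab["FALSE", "FALSE"]) /
    (tab["TRUE", "FALSE"] * tab["FALSE", "TRUE"])
  # planned odds 4, allow binomial error at n = 500
  expect_gt(or, 2)
  expect_lt(or, 8)

  # odds = 1 is the null: inside frequency close to the baseline outside
  plan1 <- data.frame(module = 1, term = "GO:Y", odds = 1)
  spec1 <- simulation_spec(n_genes = 500, modules = mods,
                           enrichment_plan = plan1, annotation_baseline = 0.2,
                           n_background_terms = 0, seed = 56)
  ann1 <- simulate_annotations(spec1, sim$truth)$annotations
  hit1 <- names(sim$truth$module) %in% ann1$gene[ann1$term == "GO:Y"]
  expect_lt(abs(mean(hit1[inside]) - mean(hit1[!inside])), 0.12)

  # infinite odds saturate the module
  planI <- data.frame(module = 1, term = "GO:Z", odds = Inf)
  specI <- simulation_spec(n_genes = 500, modules = mods,
                           enrichment_plan = planI, annotation_baseline = 0.2,
                           n_background_terms = 0, seed = 57)
  annI <- simulate_annotations(specI, sim$truth)$annotations
  expect_true(all(names(sim$truth$module)[inside] %in%
                    annI$gene[annI$term == "GO:Z"]))
  expect_error(simulation_spec(enrichment_plan = data.frame(
    module = 1, term = "GO:B", odds = 0)), "positive")
})
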
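# Synthetic expression, physiology and annotation data with planted ground
# truth. The generator emulates the statistical structure the analysis
# assumes: block-correlated modules following stage profiles on the
# log2(FPKM + 1) scale with Gaussian replicate noise (lognormal on the FPKM
# scale), planted term enrichments, and stage-structured physiology with
# Gaussian plant-to-plant noise.

#' Default planted modules
#'
#' Five 50-gene modules over a baseline log2 expression of 6-8, with stage
#' profiles whose pairwise shape correlations stay at or below 0.87 in
#' magnitude (so an unsigned network can separate them) and whose stage
#' steps are either 0 (an `=` position) or 2 log2 units (twice the
#' fold-change threshold).
#'
#' @param size Genes per module.
#' @return List of module descriptors (`size`, `profile`, `pattern`).
#' @export
default_modules <- function(size = 50) {
  list(
    list(size = size, profile = c(W = 6, S1 = 8, S3 = 10), pattern = "[+/+]"),
    list(size = size, profile = c(W = 6, S1 = 8, S3 = 8),  pattern = "[+/=]"),
    list(size = size, profile = c(W = 6, S1 = 8, S3 = 6),  pattern = "[+/-]"),
    list(size = size, profile = c(W = 6, S1 = 6, S3 = 8),  pattern = "[=/+]"),
    list(size = size, profile = c(W = 8, S1 = 6, S3 = 10), pattern = "[-/+]")
  )
}

#' Default physiology plan
#'
#' Per-parameter stage means (W, S1, R1, S2) and plant-to-plant standard
#' deviations encoding the qualitative memory calls of the repeated-drought
#' literature for maize seedlings: stomatal conductance and transpiration
#' show `[-/-]` memory, relative water content and internal CO2 `[-/=]`,
#' abscisic acid `[+/=]`, photosynthetic rate and the PSII efficiency /
#' quenching parameters delayed `[=/-]`, the energy-dependent-quenching
#' parameters delayed `[=/+]`, chlorophyll `[-/-]`, and the composite ratios
#' `[=/+]`. Stage means are exactly equal wherever the planted pattern has an
#' `=` position, so a zero-noise simulation reproduces the planted pattern
#' under any test.
#'
#' @return Data frame with columns `parameter`, `W`, `S1`, `R1`, `S2`, `sd`,
#'   `pattern`.
#' @export
default_physiology_plan <- function() {
  plan <- rbind(
    data.frame(parameter = "RWC",      W = 95,     S1 = 75,     R1 = 93,    S2 = 75,     sd = 2,      pattern = "[-/=]"),
    data.frame(parameter = "ABA",      W = 50,     S1 = 420,    R1 = 120,   S2 = 420,    sd = 30,     pattern = "[+/=]"),
    data.frame(parameter = "g_s",      W = 150,    S1 = 60,     R1 = 80,    S2 = 30,     sd = 8,      pattern = "[-/-]"),
    data.frame(parameter = "E",        W = 2.5,    S1 = 1.0,    R1 = 1.4,   S2 = 0.5,    sd = 0.12,   pattern = "[-/-]"),
    data.frame(parameter = "P_N",      W = 25,     S1 = 25,     R1 = 23,    S2 = 12,     sd = 1.5,    pattern = "[=/-]"),
    data.frame(parameter = "C_i",      W = 150,    S1 = 100,    R1 = 110,   S2 = 100,    sd = 8,      pattern = "[-/=]"),
    data.frame(parameter = "phiPSII",  W = 0.60,   S1 = 0.60,   R1 = 0.55,  S2 = 0.30,   sd = 0.02,   pattern = "[=/-]"),
    data.frame(parameter = "ETR",      W = 382,    S1 = 382,    R1 = 350,   S2 = 191,    sd = 15,     pattern = "[=/-]"),
    data.frame(parameter = "FvpFmp",   W = 0.75,   S1 = 0.75,   R1 = 0.70,  S2 = 0.55,   sd = 0.02,   pattern = "[=/-]"),
    data.frame(parameter = "qP",       W = 0.80,   S1 = 0.80,   R1 = 0.78,  S2 = 0.55,   sd = 0.03,   pattern = "[=/-]"),
    data.frame(parameter = "phiCO2",   W = 0.020,  S1 = 0.020,  R1 = 0.018, S2 = 0.009,  sd = 0.001,  pattern = "[=/-]"),
    data.frame(parameter = "NPQ",      W = 0.8,    S1 = 0.8,    R1 = 0.9,   S2 = 2.2,    sd = 0.1,    pattern = "[=/+]"),
    data.frame(parameter = "qE",       W = 0.5,    S1 = 0.5,    R1 = 0.6,   S2 = 1.8,    sd = 0.08,   pattern = "[=/+]"),
    data.frame(parameter = "phiqE",    W = 0.10,   S1 = 0.10,   R1 = 0.12,  S2 = 0.30,   sd = 0.02,   pattern = "[=/+]"),
    data.frame(parameter = "qE_ETR",   W = 0.0013, S1 = 0.0013, R1 = 0.0017, S2 = 0.0094, sd = 5e-4,  pattern = "[=/+]"),
    data.frame(parameter = "chlorophyll", W = 9,   S1 = 7,      R1 = 6,     S2 = 4,      sd = 0.4,    pattern = "[-/-]"),
    data.frame(parameter = "phiPSII_phiCO2", W = 30, S1 = 30,   R1 = 30.5,  S2 = 33.3,   sd = 0.8,    pattern = "[=/+]"),
    data.frame(parameter = "ETR_AG",   W = 14,     S1 = 14,     R1 = 15,    S2 = 21,     sd = 0.8,    pattern = "[=/+]")
  )
  plan$parameter <- as.character(plan$parameter)
  plan$pattern <- as.character(plan$pattern)
  plan
}

#' Default planted enrichment plan
#'
#' One distinct term per planted module at an odds multiplier of 8 over the
#' annotation baseline.
#'
#' @param n_modules Number of planted modules.
#' @param odds Odds multiplier for planted terms.
#' @return Data frame with columns `module`, `term`, `odds`.
#' @export
default_enrichment_plan <- function(n_modules = 5, odds = 8) {
  data.frame(module = seq_len(n_modules),
             term = sprintf("GO:PLANT%02d", seq_len(n_modules)),
             odds = odds, stringsAsFactors = FALSE)
}

#' Simulation specification
#'
#' Validated description of a synthetic study. Module stage profiles are
#' checked against their declared memory pattern before any sampling: a `+`
#' (`-`) position requires the corresponding stage step to be at least
#' `effect_threshold` up (down) in log2 units, an `=` position requires the
#' step's magnitude to stay strictly below it.
#'
#' @param n_genes Total genes (modules plus background pool).
#' @param modules List of module descriptors: `size`, `profile` (named log2
#'   means at the transcriptome stages), `pattern`.
#' @param replicate_sd Replicate noise sd on the log2(FPKM + 1) scale.
#' @param loading_sd Spread of the per-gene loading on the module profile.
#' @param background_mean,background_gene_sd Baseline log2 level of the
#'   background pool and its gene-to-gene spread.
#' @param n_replicates Biological replicates per transcriptome stage.
#' @param effect_threshold Log2 step that separates `=` from `+`/`-` in the
#'   profile consistency check (the pipeline's fold-change threshold).
#' @param enrichment_plan Data frame `module`, `term`, `odds` of planted
#'   enrichments; `odds = Inf` annotates every module gene.
#' @param annotation_baseline Probability that a background term annotates
#'   any gene.
#' @param n_background_terms Number of unenriched terms.
#' @param physiology_plan See [default_physiology_plan()].
#' @param n_plants Plants per physiology stage.
#' @param seed Integer RNG seed; all `simulate_*` output is a deterministic
#'   function of the spec.
#' @param design A [stage_design()].
#' @return Object of class `simulation_spec`.
#' @export
simulation_spec <- function(n_genes = 2000,
                            modules = default_modules(),
                            replicate_sd = 0.1,
                            loading_sd = 0.1,
                            background_mean = 6,
                            background_gene_sd = 0.5,
                            n_replicates = 2,
                            effect_threshold = 1.0,
                            enrichment_plan = default_enrichment_plan(length(modules)),
                            annotation_baseline = 0.05,
                            n_background_terms = 20,
                            physiology_plan = default_physiology_plan(),
                            n_plants = 10,
                            seed = 20180724,
                            design = stage_design()) {
  if (replicate_sd < 0 || loading_sd < 0) stop("noise sd must be non-negative")
  sizes <- vapply(modules, `[[`, numeric(1), "size")
  if (any(sizes < 1)) stop("module sizes must be positive")
  if (sum(sizes) > n_genes) stop("module sizes exceed n_genes")
  stages <- design$transcriptome_stages
  for (i in seq_along(modules)) {
    m <- modules[[i]]
    if (!all(stages %in% names(m$profile))) {
      stop("module ", i, " profile must name stages ",
           paste(stages, collapse = ", "))
    }
    check_profile_pattern(m$profile[stages], m$pattern, effect_threshold, i)
  }
  if (!is.null(enrichment_plan) && nrow(enrichment_plan)) {
    if (any(enrichment_plan$odds <= 0)) stop("planted odds must be positive")
    if (any(enrichment_plan$module > length(modules))) {
      stop("enrichment plan refers to unknown module")
    }
    key <- paste(enrichment_plan$module, enrichment_plan$term)
    if (anyDuplicated(key)) stop("enrichment plan terms must be distinct per module")
  }
  if (n_plants < 2) stop("need at least 2 plants per stage")
  if (any(physiology_plan$sd < 0)) stop("physiology sd must be non-negative")
  structure(list(n_genes = as.integer(n_genes), modules = modules,
                 replicate_sd = replicate_sd, loading_sd = loading_sd,
                 background_mean = background_mean,
                 background_gene_sd = background_gene_sd,
                 n_replicates = as.integer(n_replicates),
                 effect_threshold = effect_threshold,
                 enrichment_plan = enrichment_plan,
                 annotation_baseline = annotation_baseline,
                 n_background_terms = as.integer(n_background_terms),
                 physiology_plan = physiology_plan,
                 n_plants = as.integer(n_plants),
                 seed = as.integer(seed), design = design),
            class = "simulation_spec")
}

check_profile_pattern <- function(profile, pattern, threshold, module_idx) {
  steps <- diff(profile)
  signs <- strsplit(gsub("\\[|\\]", "", pattern), "/")[[1]]
  if (length(signs) != length(steps)) {
    stop("module ", module_idx, ": pattern ", pattern,
         " does not match a ", length(profile), "-stage profile")
  }
  for (j in seq_along(steps)) {
    ok <- switch(signs[j],
                 "+" = steps[j] >= threshold,
                 "-" = steps[j] <= -threshold,
                 "=" = abs(steps[j]) < threshold,
                 stop("module ", module_idx, ": bad sign '", signs[j], "'"))
    if (!ok) {
      stop("module ", module_idx, ": profile step ", j, " (", steps[j],
           ") contradicts declared pattern ", pattern)
    }
  }
  invisible(TRUE)
}

#' @export
print.simulation_spec <- function(x, ...) {
  cat(sprintf("Simulation spec: %d genes (%d in %d modules), %d replicates/stage, seed %d\n",
              x$n_genes, sum(vapply(x$modules, `[[`, numeric(1), "size")),
              length(x$modules), x$n_replicates, x$seed))
  invisible(x)
}

#' Simulate an expression study with planted modules
#'
#' Genes in a module share a latent stage profile: on the log2(FPKM + 1)
#' scale, `value = loading * profile(stage) + N(0, replicate_sd)` with a
#' per-gene loading drawn once from `N(1, loading_sd)`. Background genes are
#' independent noise around a flat per-gene baseline. Values are
#' back-transformed to FPKM (truncated at zero). Output is a deterministic
#' function of the spec (including its seed).
#'
#' @param spec A [simulation_spec()].
#' @return List with elements `study` (an [expression_study()]) and `truth`
#'   (class `synthetic_truth`: `module` and `pattern` per gene).
#' @export
simulate_expression <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  with_preserved_seed(spec$seed, {
    stages <- spec$design$transcriptome_stages
    samples <- data.frame(
      sample = paste0(rep(stages, each = spec$n_replicates), "_r",
                      rep(seq_len(spec$n_replicates), times = length(stages))),
      stage = rep(stages, each = spec$n_replicates),
      replicate = rep(seq_len(spec$n_replicates), times = length(stages)),
      stringsAsFactors = FALSE)
    n_samp <- nrow(samples)
    genes <- sprintf("gene%04d", seq_len(spec$n_genes))
    log_mat <- matrix(0, spec$n_genes, n_samp,
                      dimnames = list(genes, samples$sample))
    module_of <- stats::setNames(rep(0L, spec$n_genes), genes)
    pattern_of <- stats::setNames(rep("[=/=]", spec$n_genes), genes)

    row <- 1L
    for (mi in seq_along(spec$modules)) {
      m <- spec$modules[[mi]]
      idx <- row:(row + m$size - 1L)
      row <- row + m$size
      loading <- stats::rnorm(m$size, mean = 1, sd = spec$loading_sd)
      base <- outer(loading, as.numeric(m$profile[samples$stage]))
      noise <- matrix(stats::rnorm(m$size * n_samp, sd = spec$replicate_sd),
                      m$size, n_samp)
      log_mat[idx, ] <- base + noise
      module_of[idx] <- mi
      pattern_of[idx] <- m$pattern
    }
    n_bg <- spec$n_genes - row + 1L
    if (n_bg > 0) {
      idx <- row:spec$n_genes
      baseline <- stats::rnorm(n_bg, spec$background_mean,
                               spec$background_gene_sd)
      noise <- matrix(stats::rnorm(n_bg * n_samp, sd = spec$replicate_sd),
                      n_bg, n_samp)
      log_mat[idx, ] <- baseline + noise
    }
    fpkm <- pmax(2^log_mat - 1, 0)
    study <- expression_study(fpkm, samples, spec$design)
    truth <- structure(list(module = module_of, pattern = pattern_of),
                       class = "synthetic_truth")
    list(study = study, truth = truth)
  })
}

#' Simulate per-plant physiology
#'
#' Each plant-by-stage value is the planned stage mean plus Gaussian
#' plant-to-plant noise. In `mode = "raw_fluorescence"` the fluorescence
#' parameters are not emitted directly; instead raw readings `Fs`, `Fmp`,
#' `Fo`, `Fop`, `Fm`, `PPFD` and `relaxed_Fmp` are constructed per plant, by
#' inverting the quenching identities, to carry the planted `phiPSII`, `qP`,
#' `NPQ` and `qE` targets, alongside raw gas-exchange readings and the
#' pass-through parameters; [derive_physiology()] then recovers the planted
#' values.
#'
#' @param spec A [simulation_spec()].
#' @param mode `"derived"` (default) or `"raw_fluorescence"`.
#' @param Fm Dark-adapted maximal fluorescence used in raw mode (arbitrary
#'   units).
#' @param PPFD Photon flux used in raw mode.
#' @return List with elements `table` (a [physiology_table()]) and `truth`
#'   (`phys_pattern`: planted pattern per parameter).
#' @export
simulate_physiology <- function(spec, mode = c("derived", "raw_fluorescence"),
                                Fm = 2000, PPFD = 1500) {
  stopifnot(inherits(spec, "simulation_spec"))
  mode <- match.arg(mode)
  plan <- spec$physiology_plan
  stages <- spec$design$physiology_stages
  with_preserved_seed(spec$seed + 1L, {
    plants <- sprintf("plant%02d", seq_len(spec$n_plants))
    grid <- expand.grid(plant_id = plants, stage = stages,
                        stringsAsFactors = FALSE)
    values <- matrix(NA_real_, nrow(grid), nrow(plan),
                     dimnames = list(NULL, plan$parameter))
    for (j in seq_len(nrow(plan))) {
      mu <- as.numeric(plan[j, stages])
      values[, j] <- mu[match(grid$stage, stages)] +
        stats::rnorm(nrow(grid), sd = plan$sd[j])
    }
    truth <- structure(
      list(phys_pattern = stats::setNames(plan$pattern, plan$parameter)),
      class = "synthetic_truth")

    if (mode == "derived") {
      long <- data.frame(plant_id = rep(grid$plant_id, times = ncol(values)),
                         stage = rep(grid$stage, times = ncol(values)),
                         parameter = rep(colnames(values), each = nrow(grid)),
                         value = as.vector(values),
                         stringsAsFactors = FALSE)
      return(list(table = physiology_table(long, spec$design), truth = truth))
    }

    fluor <- c("phiPSII", "qP", "NPQ", "qE")
    missing_fluor <- setdiff(fluor, colnames(values))
    if (length(missing_fluor)) {
      stop("raw-fluorescence mode needs planned parameter(s): ",
           paste(missing_fluor, collapse = ", "))
    }
    phiPSII <- values[, "phiPSII"]; qP <- values[, "qP"]
    NPQ <- values[, "NPQ"]
    # qE is a component of NPQ; clip rare noise draws that would violate that
    qE <- pmin(values[, "qE"], NPQ)
    if (any(qE < 0)) stop("planted qE must be non-negative")
    Fmp <- Fm / (1 + NPQ)
    Fs <- Fmp * (1 - phiPSII)
    Fop <- Fmp * (1 - phiPSII / qP)
    # the light-adapted minimal fluorescence is emitted as measured (Fo' is
    # an accepted reading); the dark minimal is set equal to it, which keeps
    # the reading ordering invariants valid at any planted quenching level
    relaxed_Fmp <- Fm / ((1 + NPQ) - qE)
    raw <- cbind(Fs = Fs, Fmp = Fmp, Fo = Fop, Fop = Fop, Fm = Fm,
                 PPFD = PPFD, relaxed_Fmp = relaxed_Fmp)
    gas_pass <- setdiff(colnames(values),
                        c(fluor, "FvpFmp", "phiqE", "qE_ETR", "ETR",
                          "phiCO2", "phiPSII_phiCO2", "ETR_AG", "A_G"))
    out_vals <- cbind(raw, values[, gas_pass, drop = FALSE])
    long <- data.frame(plant_id = rep(grid$plant_id, times = ncol(out_vals)),
                       stage = rep(grid$stage, times = ncol(out_vals)),
                       parameter = rep(colnames(out_vals), each = nrow(grid)),
                       value = as.vector(out_vals),
                       stringsAsFactors = FALSE)
    list(table = physiology_table(long, spec$design), truth = truth)
  })
}

#' Simulate a gene-annotation table with planted enrichments
#'
#' Every term annotates genes independently at the baseline probability; for
#' each planted `(module, term, odds)` triple the annotation odds inside the
#' module are multiplied by `odds` (so `odds = 1` is the null and
#' `odds = Inf` annotates every module gene).
#'
#' @param spec A [simulation_spec()].
#' @param truth The `truth` component of [simulate_expression()] (gene ->
#'   module labels); regenerated from the spec when omitted.
#' @return List with `annotations` (data frame `gene`, `term`) and `truth`
#'   (`enriched`: the planted plan).
#' @export
simulate_annotations <- function(spec, truth = NULL) {
  stopifnot(inherits(spec, "simulation_spec"))
  if (is.null(truth)) truth <- simulate_expression(spec)$truth
  module_of <- truth$module
  genes <- names(module_of)
  b <- spec$annotation_baseline
  base_odds <- b / (1 - b)
  with_preserved_seed(spec$seed + 2L, {
    rows <- list()
    plan <- spec$enrichment_plan
    planned_terms <- if (is.null(plan)) character(0) else plan$term
    for (t in seq_len(spec$n_background_terms)) {
      term <- sprintf("GO:BG%04d", t)
      hit <- stats::runif(length(genes)) < b
      if (any(hit)) rows[[length(rows) + 1L]] <-
          data.frame(gene = genes[hit], term = term, stringsAsFactors = FALSE)
    }
    if (!is.null(plan)) {
      for (r in seq_len(nrow(plan))) {
        inside <- module_of == plan$module[r]
        p_in <- if (is.infinite(plan$odds[r])) 1 else {
          o <- base_odds * plan$odds[r]
          o / (1 + o)
        }
        prob <- ifelse(inside, p_in, b)
        hit <- stats::runif(length(genes)) < prob
        if (any(hit)) rows[[length(rows) + 1L]] <-
            data.frame(gene = genes[hit], term = plan$term[r],
                       stringsAsFactors = FALSE)
      }
    }
    annotations <- do.call(rbind, rows)
    list(annotations = annotations,
         truth = structure(list(enriched = plan), class = "synthetic_truth"))
  })
}
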
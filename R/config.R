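# Run configuration and stage design.

#' Stage design for a repeated-dehydration experiment
#'
#' Describes the treatment stages at which transcriptome and physiology were
#' sampled and which stages are considered equivalent across the two assays.
#' In the default design the transcriptome is sampled at watered (W), first
#' stress (S1) and third stress (S3), while physiology is measured at W, S1,
#' first rehydration (R1) and second stress (S2); S2 and S3 responses are
#' treated as comparable, so the repeated-stress contrast of the transcriptome
#' (S3 vs S1) is reported as the S2 response.
#'
#' @param transcriptome_stages Ordered stage labels of the expression samples.
#' @param physiology_stages Ordered stage labels of the physiology records.
#' @param equivalence Named character vector mapping a stage to the stage it is
#'   considered equivalent to; must be symmetric.
#' @return An object of class `stage_design`.
#' @export
#' @examples
#' stage_design()
stage_design <- function(transcriptome_stages = c("W", "S1", "S3"),
                         physiology_stages = c("W", "S1", "R1", "S2"),
                         equivalence = c(S3 = "S2", S2 = "S3")) {
  transcriptome_stages <- as.character(transcriptome_stages)
  physiology_stages <- as.character(physiology_stages)
  if (anyDuplicated(transcriptome_stages) || anyDuplicated(physiology_stages)) {
    stop("stage labels must be unique")
  }
  if (length(equivalence)) {
    if (is.null(names(equivalence))) stop("equivalence must be a named vector")
    for (from in names(equivalence)) {
      to <- equivalence[[from]]
      back <- if (to %in% names(equivalence)) equivalence[[to]] else NA_character_
      if (!identical(back, from)) {
        stop("equivalence map must be symmetric: ", from, " -> ", to,
             " has no inverse entry")
      }
    }
  }
  structure(list(transcriptome_stages = transcriptome_stages,
                 physiology_stages = physiology_stages,
                 equivalence = equivalence),
            class = "stage_design")
}

#' @export
print.stage_design <- function(x, ...) {
  cat("Stage design\n")
  cat("  transcriptome:", paste(x$transcriptome_stages, collapse = " -> "), "\n")
  cat("  physiology:   ", paste(x$physiology_stages, collapse = " -> "), "\n")
  if (length(x$equivalence)) {
    cat("  equivalent:   ",
        paste(names(x$equivalence), x$equivalence, sep = " ~ ", collapse = ", "),
        "\n")
  }
  invisible(x)
}

# Map a stage label through the equivalence relation onto a target stage set;
# returns NA when no counterpart exists.
map_stage <- function(stage, design, onto) {
  vapply(stage, function(s) {
    if (s %in% onto) return(s)
    eq <- if (s %in% names(design$equivalence)) design$equivalence[[s]] else NA_character_
    if (!is.na(eq) && eq %in% onto) eq else NA_character_
  }, character(1), USE.NAMES = FALSE)
}

#' Pipeline run configuration
#'
#' Bundles every threshold used by the pipeline into one validated object so
#' that a whole analysis is reproducible from a single record.
#'
#' @param q_threshold FDR cutoff for a differential-expression call.
#' @param lfc_threshold Minimum absolute log2 fold change for a call.
#' @param expr_percentile Per-sample expression floor: at least one of the two
#'   contrasted stage profiles must exceed this percentile of all values in
#'   that profile (in percent, strictly between 0 and 100).
#' @param variation_min_range Minimum FPKM range across samples for a gene to
#'   enter network construction (strict inequality).
#' @param min_module_size Minimum number of genes in a co-expression module.
#' @param metamodule_cut Eigengene dissimilarity (1 - correlation) below which
#'   modules are grouped into a meta-module.
#' @param min_mapped_entries Minimum number of reference genes annotated to a
#'   term for the term to be tested for enrichment.
#' @param alpha_phys Significance level for physiology stage contrasts.
#' @param absorptance Leaf absorptance used in electron-transport-rate and
#'   CO2-quantum-yield calculations.
#' @param psii_fraction Fraction of absorbed photons allocated to photosystem
#'   II.
#' @param rng_seed Integer seed used by simulation helpers when a spec does
#'   not carry its own.
#' @return An object of class `run_config` (a validated list).
#' @export
#' @examples
#' cfg <- run_config()
#' cfg$q_threshold
run_config <- function(q_threshold = 0.05,
                       lfc_threshold = 1.0,
                       expr_percentile = 25,
                       variation_min_range = 0.05,
                       min_module_size = 30,
                       metamodule_cut = 0.2,
                       min_mapped_entries = 5,
                       alpha_phys = 0.05,
                       absorptance = 0.85,
                       psii_fraction = 0.5,
                       rng_seed = 1L) {
  cfg <- list(q_threshold = q_threshold, lfc_threshold = lfc_threshold,
              expr_percentile = expr_percentile,
              variation_min_range = variation_min_range,
              min_module_size = as.integer(min_module_size),
              metamodule_cut = metamodule_cut,
              min_mapped_entries = as.integer(min_mapped_entries),
              alpha_phys = alpha_phys, absorptance = absorptance,
              psii_fraction = psii_fraction, rng_seed = as.integer(rng_seed))
  nums <- unlist(cfg[setdiff(names(cfg), "rng_seed")])
  if (any(!is.finite(nums))) stop("all configuration thresholds must be finite")
  if (cfg$expr_percentile <= 0 || cfg$expr_percentile >= 100) {
    stop("expr_percentile must lie strictly between 0 and 100")
  }
  if (cfg$min_module_size < 2L) stop("min_module_size must be at least 2")
  if (cfg$q_threshold < 0 || cfg$q_threshold > 1) stop("q_threshold must be in [0, 1]")
  if (cfg$alpha_phys <= 0 || cfg$alpha_phys >= 1) stop("alpha_phys must be in (0, 1)")
  structure(cfg, class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("stressmem run configuration\n")
  for (key in names(x)) cat(sprintf("  %-20s %s\n", key, format(x[[key]])))
  invisible(x)
}

#' Write / read a run configuration
#'
#' The configuration is serialised as a flat `key<TAB>value` text file so that
#' every threshold of a run is stored in one human-readable place.
#'
#' @param config A [run_config()] object.
#' @param path File path.
#' @return `write_config()` returns `path` invisibly; `read_config()` returns
#'   a `run_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  lines <- vapply(names(config), function(k) {
    paste0(k, "\t", format(config[[k]], digits = 17))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad)) stop("malformed config line ", which(bad)[1], ": ", lines[bad][1])
  vals <- stats::setNames(lapply(parts, function(p) as.numeric(p[2])),
                          vapply(parts, `[[`, character(1), 1))
  if (any(is.na(unlist(vals)))) stop("non-numeric config value")
  do.call(run_config, vals)
}
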
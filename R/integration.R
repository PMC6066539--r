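# Correlation of module eigengenes with physiological parameters.

#' Pair eigengene samples with physiology stage means
#'
#' Transcriptome samples and physiology plants are different individuals, so
#' the two assays are paired at the stage level: for each parameter the mean
#' over plants is computed per stage, each transcriptome sample's stage is
#' mapped through the stage-equivalence relation (S3 ~ S2) onto the
#' physiology stages, and the stage mean is replicated to every transcriptome
#' sample of that stage. Physiology stages without a transcriptome counterpart
#' (R1) are dropped. With the default design this yields n = 6 paired points.
#' Set `collapse = TRUE` to pair stage means directly (n = 3) instead.
#'
#' @param eigs An [compute_eigengenes()] result.
#' @param phys A [physiology_table()].
#' @param design A [stage_design()].
#' @param collapse Pair per stage instead of per transcriptome sample.
#' @return An object of class `aligned_traits`: `eigengenes` (n x modules),
#'   `traits` (n x parameters), `stage` (length n), and `constant`
#'   (logical per parameter flagging zero-variance trait vectors).
#' @export
align_stages <- function(eigs, phys, design = stage_design(),
                         collapse = FALSE) {
  stopifnot(inherits(eigs, "eigengene_set"), inherits(phys, "physiology_table"))
  samp <- eigs$samples
  mapped <- map_stage(samp$stage, design, unique(phys$stage))
  keep <- !is.na(mapped)
  if (!any(keep)) stop("no overlapping stages between eigengenes and physiology")
  me <- eigs$eigengenes[keep, , drop = FALSE]
  stage_of_sample <- mapped[keep]

  params <- unique(phys$parameter)
  stage_means <- vapply(params, function(p) {
    vapply(stage_of_sample, function(s) {
      mean(phys$value[phys$parameter == p & phys$stage == s])
    }, numeric(1))
  }, numeric(length(stage_of_sample)))
  colnames(stage_means) <- params
  rownames(stage_means) <- rownames(me)

  if (collapse) {
    stages <- unique(stage_of_sample)
    idx <- match(stages, stage_of_sample)
    me <- vapply(stages, function(s) {
      colMeans(me[stage_of_sample == s, , drop = FALSE])
    }, numeric(ncol(me)))
    me <- t(me)
    rownames(me) <- stages
    stage_means <- stage_means[idx, , drop = FALSE]
    rownames(stage_means) <- stages
    stage_of_sample <- stages
  }

  constant <- apply(stage_means, 2L, function(v) stats::sd(v) == 0)
  if (any(constant)) {
    log_msg("warn", "align_stages: constant trait vector for ",
            paste(params[constant], collapse = ", "))
  }
  structure(list(eigengenes = me, traits = stage_means,
                 stage = stage_of_sample, constant = constant),
            class = "aligned_traits")
}

#' Module-trait correlation matrix
#'
#' Pearson correlation of every module eigengene with every physiological
#' parameter over the paired points from [align_stages()], with a two-sided
#' p-value from `t = r * sqrt((n - 2) / (1 - r^2))` on n - 2 degrees of
#' freedom. Constant trait vectors give undefined (NA) cells rather than
#' zero.
#'
#' @param aligned An [align_stages()] result.
#' @return An object of class `module_trait_matrix` with matrices `r` and
#'   `p` (modules x parameters) and the number of paired points `n`.
#' @export
module_trait_correlation <- function(aligned) {
  stopifnot(inherits(aligned, "aligned_traits"))
  n <- nrow(aligned$eigengenes)
  if (n < 3L) stop("need at least 3 paired points, got ", n)
  mods <- colnames(aligned$eigengenes)
  params <- colnames(aligned$traits)
  r <- matrix(NA_real_, length(mods), length(params),
              dimnames = list(mods, params))
  p <- r
  for (i in seq_along(mods)) {
    for (j in seq_along(params)) {
      if (aligned$constant[j]) next
      rij <- stats::cor(aligned$eigengenes[, i], aligned$traits[, j])
      rij <- max(min(rij, 1), -1)
      tij <- rij * sqrt((n - 2) / max(1 - rij^2, .Machine$double.eps))
      r[i, j] <- rij
      p[i, j] <- 2 * stats::pt(-abs(tij), n - 2)
    }
  }
  structure(list(r = r, p = p, n = n), class = "module_trait_matrix")
}

#' @export
print.module_trait_matrix <- function(x, digits = 2, ...) {
  cat(sprintf("Module-trait correlations (n = %d paired points)\n", x$n))
  print(round(x$r, digits))
  invisible(x)
}

#' Long-format view of a module-trait matrix
#'
#' @param x A [module_trait_correlation()] result.
#' @param adjust Optionally BH-adjust the p-values across the whole grid
#'   (off by default; the displayed convention is raw p-values).
#' @return Data frame with columns `module`, `parameter`, `r`, `p` (and
#'   `fdr` when `adjust = TRUE`).
#' @export
module_trait_table <- function(x, adjust = FALSE) {
  stopifnot(inherits(x, "module_trait_matrix"))
  out <- data.frame(module = rep(rownames(x$r), times = ncol(x$r)),
                    parameter = rep(colnames(x$r), each = nrow(x$r)),
                    r = as.vector(x$r), p = as.vector(x$p),
                    stringsAsFactors = FALSE)
  if (adjust) out$fdr <- stats::p.adjust(out$p, method = "BH")
  out
}
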
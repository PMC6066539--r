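# Differential-expression calls between treatment stages and classification of
# each gene into the eight memory / non-memory sign patterns.

MEMORY_PATTERNS <- c("[+/+]", "[+/-]", "[+/=]", "[=/+]",
                     "[-/-]", "[-/+]", "[-/=]", "[=/-]")

#' Category of a memory sign pattern
#'
#' Maps a two-position sign pattern to its response category: `memory`
#' (significant in both the first and the repeated stress, `[+/+] [+/-] [-/-]
#' [-/+]`), `delayed-memory` (significant only in the repeated stress, `[=/+]
#' [=/-]`), `non-memory` (significant only in the first stress, `[+/=]
#' [-/=]`), and `non-responsive` (`[=/=]`).
#'
#' @param pattern Character vector of patterns such as `"[=/-]"`.
#' @return Character vector of categories.
#' @export
#' @examples
#' pattern_category(c("[=/-]", "[+/=]", "[-/-]", "[=/=]"))
pattern_category <- function(pattern) {
  out <- rep(NA_character_, length(pattern))
  out[pattern %in% c("[+/+]", "[+/-]", "[-/-]", "[-/+]")] <- "memory"
  out[pattern %in% c("[=/+]", "[=/-]")] <- "delayed-memory"
  out[pattern %in% c("[+/=]", "[-/=]")] <- "non-memory"
  out[pattern == "[=/=]"] <- "non-responsive"
  if (anyNA(out)) stop("unknown pattern label: ", pattern[is.na(out)][1])
  out
}

make_pattern <- function(first_sign, second_sign) {
  paste0("[", first_sign, "/", second_sign, "]")
}

#' Expression floor criterion
#'
#' For a contrast between two stages, a gene passes the floor when its value
#' in at least one of the two compared stage profiles strictly exceeds that
#' profile's given percentile computed over all genes. Replicates are averaged
#' per stage first; percentiles use linear interpolation between order
#' statistics.
#'
#' @param study An [expression_study()].
#' @param contrast Character vector of two stage labels `c(reference, test)`.
#' @param percentile Floor percentile in percent (default 25).
#' @return Named logical vector over genes.
#' @export
expression_floor <- function(study, contrast, percentile = 25) {
  stopifnot(inherits(study, "expression_study"), length(contrast) == 2L)
  if (nrow(study$fpkm) == 0L) stop("empty expression matrix")
  prof <- stage_profiles(study, contrast)
  pass <- rep(FALSE, nrow(prof))
  for (j in seq_len(ncol(prof))) {
    floor_j <- stats::quantile(prof[, j], probs = percentile / 100,
                               names = FALSE, type = 7)
    pass <- pass | (prof[, j] > floor_j)
  }
  stats::setNames(pass, rownames(prof))
}

#' Differential expression between two stages
#'
#' Computes, per gene, the log2 fold change of stage-mean FPKM (with a
#' pseudocount of 1), a Benjamini-Hochberg adjusted q-value from a per-gene
#' two-sided t test on log2(FPKM + 1) replicate values, the expression-floor
#' flag, and the combined significance call. A gene is significant when all
#' three conditions hold: `q <= q_threshold`, `|log2FC| >= lfc_threshold`,
#' and the floor criterion.
#'
#' The internal test defaults to the pooled-variance (Student) t. With two
#' replicates per stage the Welch approximation assigns between 1 and 2
#' degrees of freedom depending on the sample variance ratio, and the df loss
#' inflates p-values so badly that even four-fold changes rarely survive FDR
#' control; the pooled test keeps 2 df throughout. Set `var_equal = FALSE`
#' for Welch when replication is richer. Either way this internal path is a
#' stand-in for a dedicated count-model DE tool, whose output can be supplied
#' via `external`.
#'
#' Externally computed statistics (for instance from a count-model DE tool)
#' can be supplied through `external`, in which case only the floor is
#' computed internally.
#'
#' @param study An [expression_study()].
#' @param contrast Two stage labels `c(reference, test)`; fold change is
#'   test over reference.
#' @param config A [run_config()].
#' @param external Optional data frame with columns `gene`, `log2fc`, `q`
#'   replacing the internal test.
#' @param var_equal Pooled-variance (Student) t when `TRUE` (default), Welch
#'   when `FALSE`.
#' @return A data frame of class `differential_calls` with columns `gene`,
#'   `log2_fc`, `p_value`, `q_value`, `passes_floor`, `significant` and
#'   attribute `contrast`.
#' @export
call_differential <- function(study, contrast, config = run_config(),
                              external = NULL, var_equal = TRUE) {
  stopifnot(inherits(study, "expression_study"), length(contrast) == 2L)
  genes <- rownames(study$fpkm)
  prof <- stage_profiles(study, contrast)
  lfc_all <- log2((prof[, 2] + 1) / (prof[, 1] + 1))
  floor_pass <- expression_floor(study, contrast, config$expr_percentile)

  if (is.null(external)) {
    reps <- function(stage) {
      cols <- study$samples$sample[study$samples$stage == stage]
      if (length(cols) < 2L) {
        stop("stage ", stage, " has fewer than 2 replicates and no external ",
             "statistics were supplied")
      }
      log2(study$fpkm[, cols, drop = FALSE] + 1)
    }
    a <- reps(contrast[1]); b <- reps(contrast[2])
    p <- vapply(seq_along(genes), function(i) {
      safe_t_test(a[i, ], b[i, ], var_equal = var_equal)$p
    }, numeric(1))
    q <- stats::p.adjust(p, method = "BH")
    lfc <- lfc_all
  } else {
    need <- c("gene", "log2fc", "q")
    if (!all(need %in% names(external))) {
      stop("external DE table must have columns gene, log2fc, q")
    }
    idx <- match(genes, external$gene)
    if (anyNA(idx)) {
      stop("external DE table lacks gene(s): ",
           paste(utils::head(genes[is.na(idx)], 3), collapse = ", "))
    }
    lfc <- external$log2fc[idx]
    q <- external$q[idx]
    p <- rep(NA_real_, length(genes))
  }

  sig <- (q <= config$q_threshold) & (abs(lfc) >= config$lfc_threshold) &
    floor_pass
  out <- data.frame(gene = genes, log2_fc = unname(lfc), p_value = unname(p),
                    q_value = unname(q), passes_floor = unname(floor_pass),
                    significant = unname(sig), stringsAsFactors = FALSE)
  attr(out, "contrast") <- contrast
  class(out) <- c("differential_calls", "data.frame")
  log_msg("info", "call_differential ", contrast[2], " vs ", contrast[1], ": ",
          sum(sig), "/", length(sig), " significant")
  out
}

# Sign of one position of the memory pattern from a differential call row.
contrast_sign <- function(significant, log2_fc) {
  ifelse(significant, ifelse(log2_fc > 0, "+", "-"), "=")
}

#' Classify genes into memory patterns
#'
#' Assembles the two-position sign pattern per gene from the first-stress
#' contrast (S1 vs W) and the repeated-stress contrast (S3 vs S1, reported as
#' the S2 response since S2 and S3 responses are treated as comparable). The
#' first sign is the fold-change sign if the first contrast is significant,
#' otherwise `=`; likewise for the second sign.
#'
#' @param call_s1 [call_differential()] result for the first-stress contrast.
#' @param call_s3 [call_differential()] result for the repeated-stress
#'   contrast.
#' @return A data frame of class `memory_calls` with per-gene signs, pattern
#'   and category plus the per-contrast statistics.
#' @export
classify_gene_memory <- function(call_s1, call_s3) {
  if (!identical(call_s1$gene, call_s3$gene)) {
    stop("the two contrasts must cover the same genes in the same order")
  }
  first <- contrast_sign(call_s1$significant, call_s1$log2_fc)
  second <- contrast_sign(call_s3$significant, call_s3$log2_fc)
  pattern <- make_pattern(first, second)
  out <- data.frame(gene = call_s1$gene,
                    first_sign = first, second_sign = second,
                    pattern = pattern, category = pattern_category(pattern),
                    log2_fc_s1 = call_s1$log2_fc, q_s1 = call_s1$q_value,
                    log2_fc_s2 = call_s3$log2_fc, q_s2 = call_s3$q_value,
                    stringsAsFactors = FALSE)
  class(out) <- c("memory_calls", "data.frame")
  out
}

#' Memory classification of a whole study
#'
#' Convenience wrapper running both stage contrasts and the per-gene pattern
#' assembly. The first contrast is S1 vs W and the second is the repeated
#' stress (last transcriptome stage) vs S1.
#'
#' @param study An [expression_study()].
#' @param config A [run_config()].
#' @param external Optional external DE table with columns `gene`,
#'   `contrast` (`"S1_vs_W"` or `"S2_vs_S1"`), `log2fc`, `q`.
#' @param var_equal Pooled-variance t (default) or Welch (`FALSE`); see
#'   [call_differential()].
#' @return A `memory_calls` data frame, see [classify_gene_memory()].
#' @export
classify_memory <- function(study, config = run_config(), external = NULL,
                            var_equal = TRUE) {
  stages <- study$design$transcriptome_stages
  if (length(stages) < 3L) stop("need three transcriptome stages (W, S1, repeated)")
  c1 <- c(stages[1], stages[2])
  c2 <- c(stages[2], stages[length(stages)])
  ext1 <- ext2 <- NULL
  if (!is.null(external)) {
    ext1 <- external[external$contrast == "S1_vs_W", , drop = FALSE]
    ext2 <- external[external$contrast == "S2_vs_S1", , drop = FALSE]
  }
  call1 <- call_differential(study, c1, config, external = ext1,
                             var_equal = var_equal)
  call2 <- call_differential(study, c2, config, external = ext2,
                             var_equal = var_equal)
  calls <- classify_gene_memory(call1, call2)
  log_msg("info", "classify_memory: ",
          sum(calls$category != "non-responsive"), " responsive genes of ",
          nrow(calls))
  calls
}

#' @export
print.memory_calls <- function(x, ...) {
  cat(sprintf("Memory calls for %d genes\n", nrow(x)))
  print(table(category = x$category))
  invisible(as.data.frame(x))
}

#' @export
summary.memory_calls <- function(object, ...) {
  tab <- table(factor(object$pattern, levels = c(MEMORY_PATTERNS, "[=/=]")))
  structure(list(patterns = tab,
                 categories = table(object$category)),
            class = "summary.memory_calls")
}

#' @export
print.summary.memory_calls <- function(x, ...) {
  cat("Pattern counts:\n"); print(x$patterns)
  cat("Category counts:\n"); print(x$categories)
  invisible(x)
}
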
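# GO-term over-representation per module with FDR control and GO-slim rollup.

#' Fisher over-representation test for one gene set
#'
#' For every annotation term with at least `min_mapped_entries` annotated
#' genes in the reference, tests whether the term is over-represented in the
#' module: with `k` annotated genes among the `n` module genes, `K` annotated
#' among the `N` reference genes, the one-sided p-value is the hypergeometric
#' upper tail `P(X >= k)`. p-values are Benjamini-Hochberg adjusted across
#' the tested terms of this module and results are sorted by FDR.
#'
#' @param module_genes Character vector of gene ids (must be a subset of
#'   `reference`).
#' @param annotation Data frame with columns `gene`, `term`.
#' @param reference Character vector of reference gene ids (the background).
#' @param config A [run_config()] (supplies `min_mapped_entries`).
#' @return Data frame of class `enrichment_result` with columns `term`, `k`,
#'   `n`, `K`, `N`, `odds_ratio`, `p`, `fdr`.
#' @export
fisher_enrichment <- function(module_genes, annotation,
                              reference, config = run_config()) {
  reference <- unique(as.character(reference))
  if (!length(reference)) stop("empty reference gene set")
  module_genes <- unique(as.character(module_genes))
  outside <- setdiff(module_genes, reference)
  if (length(outside)) {
    stop("module gene(s) not in reference: ",
         paste(utils::head(outside, 3), collapse = ", "))
  }
  ann <- annotation[annotation$gene %in% reference, , drop = FALSE]
  ann <- unique(ann[c("gene", "term")])
  K_all <- table(ann$term)
  terms <- names(K_all)[K_all >= config$min_mapped_entries]
  n <- length(module_genes)
  N <- length(reference)
  if (!length(terms)) {
    return(empty_enrichment())
  }
  in_module <- ann$gene %in% module_genes
  k_tab <- table(factor(ann$term[in_module], levels = terms))
  k <- as.integer(k_tab)
  K <- as.integer(K_all[terms])
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  odds <- (k * (N - K - n + k)) / ((n - k) * (K - k))
  out <- data.frame(term = terms, k = k, n = n, K = K, N = N,
                    odds_ratio = odds, p = p,
                    fdr = stats::p.adjust(p, method = "BH"),
                    stringsAsFactors = FALSE)
  out <- out[order(out$fdr, out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}

empty_enrichment <- function() {
  out <- data.frame(term = character(), k = integer(), n = integer(),
                    K = integer(), N = integer(), odds_ratio = numeric(),
                    p = numeric(), fdr = numeric(), stringsAsFactors = FALSE)
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Enrichment across all modules of a partition
#'
#' Runs [fisher_enrichment()] for every assigned module (and, when a
#' meta-module grouping is given, for every meta-module) against the
#' reference of all partitioned genes. The FDR is controlled within each
#' module's term list, matching per-gene-set testing conventions; set
#' `global_fdr = TRUE` to adjust across all modules jointly instead.
#'
#' @param partition A [cluster_and_cut()] result.
#' @param annotation Data frame with columns `gene`, `term`.
#' @param config A [run_config()].
#' @param grouping Optional [group_metamodules()] result.
#' @param reference Reference gene set; default all genes of the partition.
#' @param global_fdr Recompute the FDR across the pooled term lists.
#' @return `enrichment_result` data frame with a leading `module` column.
#' @export
module_enrichment <- function(partition, annotation, config = run_config(),
                              grouping = NULL, reference = NULL,
                              global_fdr = FALSE) {
  stopifnot(inherits(partition, "module_partition"))
  reference <- reference %||% names(partition$module)
  sets <- list()
  for (m in names(partition$sizes)) {
    sets[[paste0("M", m)]] <- names(partition$module)[partition$module == as.integer(m)]
  }
  if (!is.null(grouping)) {
    for (g in unique(grouping$meta)) {
      mods <- as.integer(sub("^M", "", names(grouping$meta)[grouping$meta == g]))
      sets[[paste0("meta_", g)]] <-
        names(partition$module)[partition$module %in% mods]
    }
  }
  res <- lapply(names(sets), function(id) {
    r <- fisher_enrichment(sets[[id]], annotation, reference, config)
    if (nrow(r)) cbind(module = id, r, stringsAsFactors = FALSE) else NULL
  })
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- cbind(module = character(), empty_enrichment())
  } else if (global_fdr) {
    out$fdr <- stats::p.adjust(out$p, method = "BH")
  }
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Roll enrichment results up to GO-slim terms
#'
#' Summarises per-term enrichment at the coarse GO-slim level for heatmap
#' display: for each gene set and slim term, the minimum FDR over the member
#' terms is reported, with `-log10(fdr)` for plotting. Terms absent from the
#' slim map fall into `"other"`.
#'
#' @param results An `enrichment_result` with a `module` column (from
#'   [module_enrichment()]) or a single-module result.
#' @param slim_map Data frame with columns `term`, `slim`.
#' @return Data frame with columns `module`, `slim`, `min_fdr`,
#'   `neg_log10_fdr`.
#' @export
slim_rollup <- function(results, slim_map) {
  res <- as.data.frame(results)
  if (!nrow(res)) {
    return(data.frame(module = character(), slim = character(),
                      min_fdr = numeric(), neg_log10_fdr = numeric()))
  }
  if (!"module" %in% names(res)) res$module <- "set"
  idx <- match(res$term, slim_map$term)
  res$slim <- ifelse(is.na(idx), "other", slim_map$slim[idx])
  agg <- stats::aggregate(fdr ~ module + slim, data = res, FUN = min)
  names(agg)[names(agg) == "fdr"] <- "min_fdr"
  agg$neg_log10_fdr <- -log10(agg$min_fdr)
  agg <- agg[order(agg$module, agg$slim), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}
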
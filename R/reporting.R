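# Summary tallies: pattern-by-group count tables and module composition by
# memory category.

#' Tally memory patterns by group
#'
#' Builds a count table of genes by group (e.g. functional category) and
#' memory pattern, with row, column and grand totals and the derived per-group
#' counts of the memory, delayed-memory and non-memory categories. The eight
#' responsive patterns form the columns; non-responsive `[=/=]` genes are
#' excluded unless `include_nonresponsive = TRUE` adds them as a ninth
#' column.
#'
#' @param calls A `memory_calls` data frame ([classify_memory()]) or any data
#'   frame with columns `gene` and `pattern`.
#' @param grouping Named character vector gene -> group label; genes without
#'   a label fall into `"other"`. Default: one group `"all"`.
#' @param include_nonresponsive Add a `[=/=]` column.
#' @return An object of class `tally_table`: `counts` (groups x patterns),
#'   `row_totals`, `col_totals`, `grand_total`, `categories` (per-group
#'   category counts).
#' @export
tally_patterns <- function(calls, grouping = NULL,
                           include_nonresponsive = FALSE) {
  patterns <- MEMORY_PATTERNS
  if (include_nonresponsive) patterns <- c(patterns, "[=/=]")
  df <- as.data.frame(calls)[c("gene", "pattern")]
  if (!include_nonresponsive) df <- df[df$pattern != "[=/=]", , drop = FALSE]
  group <- if (is.null(grouping)) {
    rep("all", nrow(df))
  } else {
    g <- grouping[df$gene]
    ifelse(is.na(g), "other", g)
  }
  group_levels <- if (is.null(grouping)) "all" else {
    c(intersect(unique(grouping), unique(group)),
      if ("other" %in% group) "other")
  }
  counts <- table(factor(group, levels = group_levels),
                  factor(df$pattern, levels = patterns))
  counts <- matrix(as.integer(counts), nrow = nrow(counts),
                   dimnames = dimnames(counts))
  categories <- data.frame(
    group = rownames(counts),
    memory = rowSums(counts[, intersect(c("[+/+]", "[+/-]", "[-/-]", "[-/+]"),
                                        colnames(counts)), drop = FALSE]),
    delayed_memory = rowSums(counts[, intersect(c("[=/+]", "[=/-]"),
                                                colnames(counts)), drop = FALSE]),
    non_memory = rowSums(counts[, intersect(c("[+/=]", "[-/=]"),
                                            colnames(counts)), drop = FALSE]),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(counts = counts,
                 row_totals = rowSums(counts),
                 col_totals = colSums(counts),
                 grand_total = sum(counts),
                 categories = categories),
            class = "tally_table")
}

#' @export
print.tally_table <- function(x, ...) {
  out <- cbind(x$counts, Total = x$row_totals)
  out <- rbind(out, Total = c(x$col_totals, x$grand_total))
  print(out)
  invisible(x)
}

#' Module composition by memory category
#'
#' For every module (and meta-module, when a grouping is supplied) reports
#' the gene count and percentage of each memory category. Percentages are
#' rounded half away from zero to integers, the convention of printed
#' summaries; exact fractions are retained in the `frac_*` columns.
#'
#' @param calls A `memory_calls` data frame covering all partitioned genes.
#' @param partition A [cluster_and_cut()] result.
#' @param grouping Optional [group_metamodules()] result; adds per-meta-module
#'   rows.
#' @return Data frame with one row per module / meta-module: `unit`, `size`,
#'   per-category counts, integer percentages and exact fractions.
#' @export
module_composition <- function(calls, partition, grouping = NULL) {
  stopifnot(inherits(partition, "module_partition"))
  df <- as.data.frame(calls)
  idx <- match(names(partition$module), df$gene)
  assigned <- partition$module > 0
  if (anyNA(idx[assigned])) {
    stop("no memory call for partitioned gene(s): ",
         paste(utils::head(names(partition$module)[assigned][
           is.na(idx[assigned])], 3), collapse = ", "))
  }
  category <- df$category[idx]

  units <- lapply(names(partition$sizes), function(m) {
    list(unit = paste0("M", m), members = partition$module == as.integer(m))
  })
  if (!is.null(grouping)) {
    for (g in unique(grouping$meta)) {
      mods <- as.integer(sub("^M", "", names(grouping$meta)[grouping$meta == g]))
      units[[length(units) + 1L]] <-
        list(unit = paste0("meta_", g), members = partition$module %in% mods)
    }
  }
  rows <- lapply(units, function(u) {
    cat_u <- category[u$members]
    size <- sum(u$members)
    n_mem <- sum(cat_u == "memory")
    n_del <- sum(cat_u == "delayed-memory")
    n_non <- sum(cat_u == "non-memory")
    n_nr <- sum(cat_u == "non-responsive")
    data.frame(unit = u$unit, size = size,
               memory = n_mem, delayed_memory = n_del, non_memory = n_non,
               non_responsive = n_nr,
               pct_memory = round_half_away(100 * n_mem / size),
               pct_delayed_memory = round_half_away(100 * n_del / size),
               pct_non_memory = round_half_away(100 * n_non / size),
               frac_memory = n_mem / size,
               frac_delayed_memory = n_del / size,
               frac_non_memory = n_non / size,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Machine-readable run summary
#'
#' Collects headline numbers of a run (gene counts through the filter
#' cascade, module count and sizes, meta-module count, category tallies) into
#' a list and optionally writes it as JSON.
#'
#' @param calls `memory_calls` data frame.
#' @param partition A [cluster_and_cut()] result.
#' @param grouping Optional [group_metamodules()] result.
#' @param path Optional JSON output path.
#' @return The summary list, invisibly when written to `path`.
#' @export
run_summary <- function(calls, partition = NULL, grouping = NULL,
                        path = NULL) {
  cat_tab <- table(calls$category)
  out <- list(
    n_genes = nrow(calls),
    n_responsive = sum(calls$category != "non-responsive"),
    categories = as.list(cat_tab)
  )
  if (!is.null(partition)) {
    out$n_modules <- length(partition$sizes)
    out$module_sizes <- as.list(partition$sizes)
    out$n_unassigned <- sum(partition$module == 0)
  }
  if (!is.null(grouping)) {
    out$n_metamodules <- length(unique(grouping$meta))
    out$metamodules <- lapply(split(names(grouping$meta), grouping$meta),
                              identity)
  }
  if (!is.null(path)) {
    jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE)
    return(invisible(out))
  }
  out
}
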
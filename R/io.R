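# Readers and writers for the tabular artifacts of the pipeline.
# Dialects: tab-separated for expression and annotation tables, comma-separated
# for physiology; header row mandatory; UTF-8.

#' Construct an expression study
#'
#' Bundles an FPKM gene-by-sample matrix with its sample sheet (sample, stage,
#' replicate) and the stage design. All downstream operations take this object.
#'
#' @param fpkm Numeric matrix, genes in rows (rownames = gene ids), samples in
#'   columns (colnames = sample ids). Values must be non-negative and finite.
#' @param samples Data frame with columns `sample`, `stage`, `replicate`; one
#'   row per column of `fpkm`.
#' @param design A [stage_design()].
#' @return An object of class `expression_study`.
#' @export
expression_study <- function(fpkm, samples, design = stage_design()) {
  fpkm <- as.matrix(fpkm)
  storage.mode(fpkm) <- "double"
  if (is.null(rownames(fpkm))) stop("fpkm matrix must carry gene ids as rownames")
  if (is.null(colnames(fpkm))) stop("fpkm matrix must carry sample ids as colnames")
  dup <- rownames(fpkm)[duplicated(rownames(fpkm))]
  if (length(dup)) stop("duplicate gene ids: ", paste(unique(dup), collapse = ", "))
  if (any(!is.finite(fpkm))) stop("FPKM matrix contains non-finite values")
  if (any(fpkm < 0)) stop("FPKM matrix contains negative values")
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  needed <- c("sample", "stage", "replicate")
  missing_cols <- setdiff(needed, names(samples))
  if (length(missing_cols)) {
    stop("sample sheet lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  samples$sample <- as.character(samples$sample)
  samples$stage <- as.character(samples$stage)
  not_in_sheet <- setdiff(colnames(fpkm), samples$sample)
  if (length(not_in_sheet)) {
    stop("matrix column(s) absent from sample sheet: ",
         paste(not_in_sheet, collapse = ", "))
  }
  not_in_matrix <- setdiff(samples$sample, colnames(fpkm))
  if (length(not_in_matrix)) {
    stop("sample(s) in sheet missing from matrix: ",
         paste(not_in_matrix, collapse = ", "))
  }
  bad_stage <- setdiff(samples$stage, design$transcriptome_stages)
  if (length(bad_stage)) {
    stop("unknown stage label(s) in sample sheet: ",
         paste(bad_stage, collapse = ", "))
  }
  samples <- samples[match(colnames(fpkm), samples$sample), , drop = FALSE]
  rownames(samples) <- NULL
  structure(list(fpkm = fpkm, samples = samples, design = design),
            class = "expression_study")
}

#' @export
print.expression_study <- function(x, ...) {
  cat(sprintf("Expression study: %d genes x %d samples\n",
              nrow(x$fpkm), ncol(x$fpkm)))
  tab <- table(x$samples$stage)[x$design$transcriptome_stages]
  cat("  samples per stage:",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.expression_study <- function(x) dim(x$fpkm)

# log2(FPKM + 1) matrix; the working scale of the pipeline.
log_expression <- function(study) log2(study$fpkm + 1)

# Stage-mean FPKM profiles, genes x stages.
stage_profiles <- function(study, stages = NULL) {
  stages <- stages %||% x_stages(study)
  cols_of <- lapply(stages, function(s) {
    cols <- study$samples$sample[study$samples$stage == s]
    if (!length(cols)) stop("no samples for stage ", s)
    cols
  })
  out <- do.call(cbind, lapply(cols_of, function(cols) {
    rowMeans(study$fpkm[, cols, drop = FALSE])
  }))
  dimnames(out) <- list(rownames(study$fpkm), stages)
  out
}

x_stages <- function(study) {
  intersect(study$design$transcriptome_stages, unique(study$samples$stage))
}

#' Read / write an expression study
#'
#' The expression matrix is a tab-separated file whose first column (`gene`)
#' carries gene ids and whose remaining columns are samples; the sample sheet
#' is a tab-separated file with columns `sample`, `stage`, `replicate`.
#' Malformed input (duplicate gene ids, samples missing from either side,
#' negative or non-numeric values, unknown stage labels) is rejected with an
#' error naming the offender rather than coerced.
#'
#' @param path Path of the expression TSV.
#' @param sample_sheet Path of the sample-sheet TSV.
#' @param design A [stage_design()].
#' @param study An `expression_study` (for writing).
#' @return `read_expression()` returns an [expression_study()];
#'   `write_expression()` returns `path` invisibly.
#' @export
read_expression <- function(path, sample_sheet, design = stage_design()) {
  mat_df <- utils::read.delim(path, check.names = FALSE,
                              stringsAsFactors = FALSE)
  if (!ncol(mat_df) >= 2L) stop("expression table needs a gene column plus samples")
  gene_col <- names(mat_df)[1]
  genes <- as.character(mat_df[[gene_col]])
  values <- as.matrix(mat_df[, -1, drop = FALSE])
  if (!is.numeric(values)) {
    stop("non-numeric expression values in ", path)
  }
  rownames(values) <- genes
  sheet <- utils::read.delim(sample_sheet, stringsAsFactors = FALSE)
  study <- expression_study(values, sheet, design)
  log_msg("info", "read_expression: ", nrow(values), " genes, ",
          ncol(values), " samples")
  study
}

#' @rdname read_expression
#' @export
write_expression <- function(study, path, sample_sheet) {
  stopifnot(inherits(study, "expression_study"))
  df <- data.frame(gene = rownames(study$fpkm), study$fpkm,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(study$samples, sample_sheet, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Construct a physiology table
#'
#' Long-format per-plant records: one value per plant, stage and parameter.
#'
#' @param data Data frame with columns `plant_id`, `stage`, `parameter`,
#'   `value`.
#' @param design A [stage_design()]; stage labels are validated against
#'   `design$physiology_stages`.
#' @return An object of class `physiology_table` (a data frame).
#' @export
physiology_table <- function(data, design = stage_design()) {
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  needed <- c("plant_id", "stage", "parameter", "value")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols)) {
    stop("physiology table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  data$stage <- as.character(data$stage)
  data$parameter <- as.character(data$parameter)
  bad <- setdiff(unique(data$stage), design$physiology_stages)
  if (length(bad)) stop("unknown physiology stage label(s): ", paste(bad, collapse = ", "))
  if (!is.numeric(data$value)) {
    idx <- which(is.na(suppressWarnings(as.numeric(data$value))))[1]
    stop("non-numeric physiology value at row ", idx %||% 1L)
  }
  key <- paste(data$plant_id, data$stage, data$parameter)
  if (anyDuplicated(key)) {
    stop("duplicate plant x stage x parameter record: ", key[duplicated(key)][1])
  }
  structure(data[needed], class = c("physiology_table", "data.frame"),
            design = design)
}

#' @export
print.physiology_table <- function(x, ...) {
  cat(sprintf("Physiology table: %d plants, %d stages, %d parameters (%d records)\n",
              length(unique(x$plant_id)), length(unique(x$stage)),
              length(unique(x$parameter)), nrow(x)))
  invisible(x)
}

#' Read / write a physiology table
#'
#' Comma-separated values. The long format has columns `plant_id`, `stage`,
#' `parameter`, `value`; a wide per-plant layout with columns `plant_id`,
#' `stage` and one column per parameter is also accepted and melted on read.
#' Non-numeric values are rejected with the offending row index.
#'
#' @param path CSV path.
#' @param design A [stage_design()].
#' @param table A `physiology_table` (for writing; written in long format).
#' @return `read_physiology()` returns a [physiology_table()];
#'   `write_physiology()` returns `path` invisibly.
#' @export
read_physiology <- function(path, design = stage_design()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  long_cols <- c("plant_id", "stage", "parameter", "value")
  if (!all(c("plant_id", "stage") %in% names(df))) {
    stop("physiology CSV must have plant_id and stage columns")
  }
  if (!all(long_cols %in% names(df))) {
    # wide layout: every non-key column is a parameter
    params <- setdiff(names(df), c("plant_id", "stage"))
    if (!length(params)) stop("physiology CSV has no parameter columns")
    for (p in params) {
      v <- suppressWarnings(as.numeric(df[[p]]))
      if (anyNA(v) && !all(is.na(df[[p]]))) {
        stop("non-numeric value for parameter ", p, " at row ",
             which(is.na(v) & !is.na(df[[p]]))[1])
      }
    }
    df <- stats::reshape(df, direction = "long", varying = params,
                         v.names = "value", timevar = "parameter",
                         times = params, idvar = c("plant_id", "stage"))
    rownames(df) <- NULL
  }
  df$value <- suppressWarnings(as.numeric(df$value))
  if (anyNA(df$value)) stop("non-numeric physiology value at row ", which(is.na(df$value))[1])
  tab <- physiology_table(df[long_cols], design)
  log_msg("info", "read_physiology: ", nrow(tab), " records")
  tab
}

#' @rdname read_physiology
#' @export
write_physiology <- function(table, path) {
  stopifnot(inherits(table, "physiology_table"))
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a gene-to-GO annotation table
#'
#' Tab-separated, columns `gene` and `term` (one row per association).
#' `read_slim_map()` reads a term-to-slim mapping with columns `term`,
#' `slim`.
#'
#' @param path TSV path.
#' @return A data frame with character columns.
#' @export
read_annotations <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene", "term") %in% names(df))) {
    stop("annotation table must have columns gene and term")
  }
  df$gene <- as.character(df$gene)
  df$term <- as.character(df$term)
  df
}

#' @rdname read_annotations
#' @export
read_slim_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("term", "slim") %in% names(df))) {
    stop("slim map must have columns term and slim")
  }
  df
}

#' @rdname read_annotations
#' @param annotations Data frame with columns `gene`, `term` (for writing).
#' @export
write_annotations <- function(annotations, path) {
  utils::write.table(annotations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
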
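#' Compound table: samples x compounds matrix with metadata
#'
#' The central container of the pipeline. Rows are samples, columns are
#' compounds. In `quantitative` mode each cell holds the compound's share of
#' the sample's total peak area (percent; rows sum to 100 unless the sample
#' yielded no peaks). In `qualitative` mode cells are 0/1 presence calls.
#'
#' @param values numeric matrix with sample row names and compound column
#'   names.
#' @param mode `"quantitative"` or `"qualitative"`.
#' @param meta optional data frame with one row per sample and columns
#'   `sample_id`, `species`, `infraspecific`, `tissue`. Reordered to match
#'   the matrix rows.
#' @return An object of class `compound_table`.
#' @export
compound_table <- function(values, mode = c("quantitative", "qualitative"),
                           meta = NULL) {
  mode <- match.arg(mode)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must carry sample row names and compound column names")
  if (anyDuplicated(colnames(values)))
    stop("compound ids must be unique")
  if (anyDuplicated(rownames(values)))
    stop("sample ids must be unique")
  if (any(values < 0)) stop("compound table values must be nonnegative")
  if (mode == "qualitative" && !all(values %in% c(0, 1)))
    stop("qualitative values must be 0 or 1")
  if (mode == "quantitative" && ncol(values) > 0) {
    rs <- rowSums(values)
    bad <- abs(rs - 100) > 1e-9 & rs != 0
    if (any(bad))
      stop("quantitative rows must sum to 100 (or be all zero); offending: ",
           paste(rownames(values)[bad], collapse = ", "))
  }
  if (!is.null(meta)) {
    if (!all(rownames(values) %in% meta$sample_id))
      stop("meta is missing samples: ",
           paste(setdiff(rownames(values), meta$sample_id), collapse = ", "))
    meta <- meta[match(rownames(values), meta$sample_id), , drop = FALSE]
    rownames(meta) <- NULL
  }
  structure(list(values = values, mode = mode, meta = meta),
            class = "compound_table")
}

#' @export
print.compound_table <- function(x, ...) {
  cat(sprintf("compound_table: %d samples x %d compounds (%s mode)\n",
              nrow(x$values), ncol(x$values), x$mode))
  if (ncol(x$values) > 0)
    cat(sprintf("  sparsity: %.2f%% zeros\n", 100 * sparsity(x)))
  invisible(x)
}

#' Sample and compound identifiers of a compound table
#' @param table a `compound_table`.
#' @return Character vector.
#' @export
sample_ids <- function(table) rownames(table$values)

#' @rdname sample_ids
#' @export
compound_ids <- function(table) colnames(table$values)

#' Convert a quantitative compound table to presence/absence
#'
#' Presence (any share of the total peak area above zero) is coded 1,
#' absence 0. Idempotent on qualitative tables.
#'
#' @param table a `compound_table`.
#' @return A qualitative `compound_table` with the same dimensions.
#' @export
binarize <- function(table) {
  stopifnot(inherits(table, "compound_table"))
  v <- (table$values > 0) + 0
  dimnames(v) <- dimnames(table$values)
  compound_table(v, "qualitative", table$meta)
}

#' Fraction of zero cells in a compound table
#' @param table a `compound_table`.
#' @return Fraction in \[0, 1\].
#' @export
sparsity <- function(table) {
  stopifnot(inherits(table, "compound_table"))
  n <- length(table$values)
  if (n == 0) stop("sparsity is undefined for an empty table")
  sum(table$values == 0) / n
}

#' Restrict a compound table to a subset of samples
#' @param table a `compound_table`.
#' @param samples character vector of sample ids to keep.
#' @param drop_empty drop compounds absent from every kept sample.
#' @return A `compound_table`.
#' @export
subset_samples <- function(table, samples, drop_empty = FALSE) {
  stopifnot(inherits(table, "compound_table"))
  missing <- setdiff(samples, sample_ids(table))
  if (length(missing))
    stop("unknown sample(s): ", paste(missing, collapse = ", "))
  v <- table$values[samples, , drop = FALSE]
  if (drop_empty) v <- v[, colSums(v) > 0, drop = FALSE]
  meta <- table$meta
  if (!is.null(meta)) meta <- meta[meta$sample_id %in% samples, , drop = FALSE]
  out <- table
  out$values <- v
  out$meta <- if (is.null(meta)) NULL else meta[match(samples, meta$sample_id), , drop = FALSE]
  # renormalisation is deliberately NOT performed: percentages keep their
  # meaning relative to the full sample, so the constructor is bypassed
  structure(out, class = "compound_table")
}

#' Write a compound table to TSV with a JSON sidecar
#'
#' The matrix goes to `<path>` (samples in rows); a sidecar
#' `<path>.json` records the mode, overall sparsity and per-sample
#' compound counts.
#'
#' @param table a `compound_table`.
#' @param path output TSV path.
#' @return Invisibly, the sidecar list.
#' @export
write_compound_table <- function(table, path) {
  stopifnot(inherits(table, "compound_table"))
  df <- data.frame(sample_id = sample_ids(table), table$values,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  side <- list(
    mode = table$mode,
    n_samples = nrow(table$values),
    n_compounds = ncol(table$values),
    sparsity = if (length(table$values)) sparsity(table) else NA,
    compounds_per_sample = as.list(rowSums(table$values > 0))
  )
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(side)
}

#' Read a compound table written by [write_compound_table()]
#' @param path TSV path (first column `sample_id`).
#' @param mode matrix mode; default read from the JSON sidecar if present.
#' @param meta optional metadata data frame.
#' @return A `compound_table`.
#' @export
read_compound_table <- function(path, mode = NULL, meta = NULL) {
  df <- utils::read.delim(path, check.names = FALSE)
  if (names(df)[1] != "sample_id") stop("first column must be sample_id")
  v <- as.matrix(df[, -1, drop = FALSE])
  rownames(v) <- as.character(df$sample_id)
  if (is.null(mode)) {
    side <- paste0(path, ".json")
    mode <- if (file.exists(side)) jsonlite::read_json(side)$mode
            else "quantitative"
  }
  compound_table(v, mode, meta)
}
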
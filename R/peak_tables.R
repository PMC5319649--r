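#' Read per-sample GC-MS peak identifications
#'
#' Expects a CSV or TSV file (delimiter sniffed from the header line) with
#' columns `sample_id`, `rt` (retention time, minutes), `compound_id`
#' (library identification), `match_pct` (library match, percent) and
#' `area` (integrated peak area, detector units). An optional
#' `compound_class` column is carried through.
#'
#' Rows with non-numeric or out-of-range `rt`, `match_pct` or `area` are
#' dropped with a warning naming their line numbers; a missing mandatory
#' column is a hard error.
#'
#' @param path path to the peak table.
#' @return A data frame of peak records.
#' @export
read_peak_records <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          stringsAsFactors = FALSE, comment.char = "",
                          colClasses = "character")
  mandatory <- c("sample_id", "rt", "compound_id", "match_pct", "area")
  absent <- setdiff(mandatory, names(df))
  if (length(absent))
    stop("missing mandatory column(s): ", paste(absent, collapse = ", "))
  if (!"compound_class" %in% names(df))
    df$compound_class <- rep(NA_character_, nrow(df))
  df <- df[, c(mandatory, "compound_class")]
  for (col in c("rt", "match_pct", "area"))
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  bad <- !is.finite(df$rt) | df$rt < 0 |
    !is.finite(df$match_pct) | df$match_pct < 0 | df$match_pct > 100 |
    !is.finite(df$area) | df$area < 0
  if (any(bad)) {
    # +1 for the header line
    warning("dropping ", sum(bad), " malformed row(s) at line(s): ",
            paste(which(bad) + 1L, collapse = ", "))
    df <- df[!bad, , drop = FALSE]
  }
  rownames(df) <- NULL
  df
}

#' Filter peak records by library match percentage
#'
#' Identifications below the cutoff are discarded; the study convention is
#' a 70% library-match threshold. Order is preserved.
#'
#' @param records peak record data frame.
#' @param cutoff minimum `match_pct` retained (default 70).
#' @return Filtered records.
#' @export
filter_identifications <- function(records, cutoff = 70) {
  stopifnot(cutoff >= 0, cutoff <= 100)
  records[records$match_pct >= cutoff, , drop = FALSE]
}

#' Collapse co-eluting, inconsistently identified hydrocarbons to n-alkanes
#'
#' When peaks at the same retention time (within `rt_tol`) are identified as
#' different hydrocarbons in different samples, the library calls are not
#' trustworthy at the isomer level and all such peaks are re-labelled with a
#' canonical id `n-alkane@<rt>` (rt of the earliest-eluting member, 2
#' decimals) and class `n-alkane`. Retention-time groups are formed by
#' chaining records whose successive rts differ by at most `rt_tol`.
#'
#' Only records whose `compound_class` is `hydrocarbon` or `n-alkane` are
#' candidates; everything else passes through unchanged.
#'
#' @param records peak record data frame.
#' @param rt_tol retention-time tolerance in minutes (default 0.02).
#' @return Records with collapsed hydrocarbon labels, original order.
#' @export
collapse_alkanes <- function(records, rt_tol = 0.02) {
  stopifnot(rt_tol > 0)
  hc <- which(records$compound_class %in% c("hydrocarbon", "n-alkane"))
  if (length(hc) < 2) return(records)
  ord <- hc[order(records$rt[hc])]
  gaps <- diff(records$rt[ord])
  group <- cumsum(c(1, gaps > rt_tol))
  for (g in split(ord, group)) {
    multi_sample <- length(unique(records$sample_id[g])) > 1
    multi_ident <- length(unique(records$compound_id[g])) > 1
    if (multi_sample && multi_ident) {
      canon <- sprintf("n-alkane@%.2f", min(records$rt[g]))
      records$compound_id[g] <- canon
      records$compound_class[g] <- "n-alkane"
    }
  }
  records
}

#' Assemble the quantitative compound table from peak records
#'
#' Each cell is the compound's relative peak abundance in the sample:
#' 100 x (summed area of the compound) / (total area of the sample).
#' Samples listed in `meta` but absent from the records get all-zero rows
#' (a sample may genuinely contain no detectable compound). Compounds absent
#' from every sample are dropped. Multiple peaks of the same compound within
#' a sample are summed; exact duplicate (sample, compound, rt) triplets are
#' summed too, with a warning.
#'
#' @param records filtered (and collapsed) peak record data frame.
#' @param meta data frame with columns `sample_id`, `species`,
#'   `infraspecific`, `tissue`; defines the full sample set and row order.
#' @return A quantitative `compound_table`.
#' @export
build_compound_table <- function(records, meta) {
  stopifnot(is.data.frame(meta), "sample_id" %in% names(meta))
  samples <- as.character(meta$sample_id)
  if (anyDuplicated(samples)) stop("duplicate sample ids in meta")
  unknown <- setdiff(unique(records$sample_id), samples)
  if (length(unknown))
    stop("records reference samples absent from meta: ",
         paste(unknown, collapse = ", "))
  dup <- duplicated(records[, c("sample_id", "compound_id", "rt")])
  if (any(dup))
    warning(sum(dup), " duplicate (sample, compound, rt) peak(s) summed")
  compounds <- sort(unique(records$compound_id))
  v <- matrix(0, nrow = length(samples), ncol = length(compounds),
              dimnames = list(samples, compounds))
  if (nrow(records)) {
    agg <- stats::aggregate(area ~ sample_id + compound_id, data = records,
                            FUN = sum)
    v[cbind(agg$sample_id, agg$compound_id)] <- agg$area
  }
  tot <- rowSums(v)
  nz <- tot > 0
  v[nz, ] <- 100 * v[nz, , drop = FALSE] / tot[nz]
  v <- v[, colSums(v) > 0, drop = FALSE]
  compound_table(v, "quantitative", meta)
}

#' Read sample metadata
#' @param path TSV with columns `sample_id`, `species`, `infraspecific`,
#'   `tissue`.
#' @return Data frame.
#' @export
read_sample_meta <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("sample_id", "species", "infraspecific", "tissue")
  absent <- setdiff(need, names(df))
  if (length(absent))
    stop("metadata missing column(s): ", paste(absent, collapse = ", "))
  df
}
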
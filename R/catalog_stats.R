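#' Compounds detected per sample
#' @param table a qualitative `compound_table`.
#' @return Named integer vector of row sums.
#' @export
compounds_per_sample <- function(table) {
  stopifnot(inherits(table, "compound_table"))
  if (table$mode != "qualitative") stop("requires a qualitative table")
  rowSums(table$values)
}

#' Compounds unique to a single sample
#'
#' A compound belongs to a sample's unique set iff it is present in that
#' sample and in no other, i.e. its column has exactly one 1. Unique sets
#' are therefore disjoint across samples.
#'
#' @param table a qualitative `compound_table`.
#' @return Named list (one entry per sample) of compound id vectors.
#' @export
unique_compounds <- function(table) {
  stopifnot(inherits(table, "compound_table"))
  if (table$mode != "qualitative") stop("requires a qualitative table")
  v <- table$values
  singleton <- colSums(v) == 1
  out <- lapply(sample_ids(table), function(s)
    colnames(v)[singleton & v[s, ] == 1])
  stats::setNames(out, sample_ids(table))
}

#' Round half away from zero
#'
#' Fixed-point rounding where .5 always rounds up (0.65 -> 0.7), matching
#' printed summary conventions rather than R's banker's rounding.
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return Rounded values.
#' @export
round_half_up <- function(x, digits = 1) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Per-sample unique-compound summary
#'
#' One row per sample with its unique-compound count and how many of those
#' are floral-scent compounds; the attached `means` are rounded half-up to
#' one decimal, as the field prints such averages.
#'
#' @param unique_sets result of [unique_compounds()].
#' @param floral_flags named logical vector over compound ids (see
#'   [flag_floral()]); missing compounds count as not floral.
#' @return Data frame `(sample_id, unique, floral_unique)` with a `means`
#'   attribute `c(unique =, floral_unique =)`.
#' @export
summarize_unique <- function(unique_sets, floral_flags = logical(0)) {
  uq <- vapply(unique_sets, length, 0L)
  fl <- vapply(unique_sets, function(ids)
    sum(floral_flags[ids] %in% TRUE), 0L)
  out <- data.frame(sample_id = names(unique_sets), unique = unname(uq),
                    floral_unique = unname(fl))
  attr(out, "means") <- c(unique = round_half_up(mean(uq), 1),
                          floral_unique = round_half_up(mean(fl), 1))
  out
}

#' Compounds distinguishing a pair of samples
#' @param table a qualitative `compound_table`.
#' @param i,j distinct sample ids.
#' @return Integer vector `c(count_i_only, count_j_only)`; the two counts
#'   sum to the Hamming distance between the samples.
#' @export
pairwise_unique <- function(table, i, j) {
  stopifnot(inherits(table, "compound_table"))
  if (table$mode != "qualitative") stop("requires a qualitative table")
  if (identical(i, j)) stop("i and j must differ")
  unknown <- setdiff(c(i, j), sample_ids(table))
  if (length(unknown)) stop("unknown sample(s): ", paste(unknown, collapse = ", "))
  a <- table$values[i, ]
  b <- table$values[j, ]
  c(count_i_only = sum(a == 1 & b == 0), count_j_only = sum(a == 0 & b == 1))
}

#' Full pairwise unique-compound matrix
#'
#' Entry (i, j) is the number of compounds present in sample i but not in
#' sample j (asymmetric; the transpose holds the converse counts).
#'
#' @param table a qualitative `compound_table`.
#' @return Integer matrix with sample ids as dimnames.
#' @export
pairwise_unique_matrix <- function(table) {
  stopifnot(inherits(table, "compound_table"))
  if (table$mode != "qualitative") stop("requires a qualitative table")
  v <- table$values
  # (i,j): present in i, absent in j
  m <- v %*% (1 - t(v))
  diag(m) <- 0
  m
}

#' Flag floral-scent compounds by curated reference list
#'
#' Matching is case-insensitive after whitespace normalization. The
#' packaged default list (see
#' `system.file("extdata", "floral_scent_reference.txt", package =
#' "sarrachem")`) is a curated compilation of volatiles recorded from
#' intact flowers and is meant to be edited for the compound naming of a
#' given library.
#'
#' @param compound_ids character vector of compound names.
#' @param reference character vector of floral compound names.
#' @return Named logical vector over `compound_ids`.
#' @export
flag_floral <- function(compound_ids, reference) {
  norm <- function(x) tolower(gsub("\\s+", " ", trimws(x)))
  if (!length(reference)) {
    warning("empty floral reference list; nothing flagged")
    return(stats::setNames(rep(FALSE, length(compound_ids)), compound_ids))
  }
  stats::setNames(norm(compound_ids) %in% norm(reference), compound_ids)
}

#' Packaged floral-scent reference list
#' @return Character vector of compound names.
#' @export
floral_reference <- function() {
  path <- system.file("extdata", "floral_scent_reference.txt",
                      package = "sarrachem")
  x <- readLines(path)
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Published per-accession unique-compound counts
#'
#' The printed per-accession counts of unique compounds and floral-scent
#' unique compounds (lids and pitchers separately) from the published
#' metabolite survey of 48 cultivated Darlingtonia and Sarracenia
#' accessions, transcribed as packaged data.
#'
#' @return Data frame with columns `accession`, `lid_unique`, `lid_floral`,
#'   `pitcher_unique`, `pitcher_floral`.
#' @export
accession_unique_counts <- function() {
  utils::read.delim(system.file("extdata",
                                "accession_unique_compound_counts.tsv",
                                package = "sarrachem"))
}
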
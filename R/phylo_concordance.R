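#' Clade framework: tree, clade partition and sample-to-tip mapping
#'
#' Bundles a rooted phylogeny, a partition of its tips into named clades,
#' and a many-to-many relation between profiled samples and tree tips
#' (several samples may be plausible matches for one accession tip, and
#' vice versa). Concordance statistics are computed over every bijective
#' map compatible with the relation.
#'
#' @param tree an `ape::phylo` object with unique tip labels.
#' @param clades data frame with columns `tip_id`, `clade`.
#' @param mapping data frame with columns `sample_id`, `tip_id`; repeated
#'   rows encode the many-to-many relation.
#' @return An object of class `clade_framework`.
#' @export
clade_framework <- function(tree, clades, mapping) {
  stopifnot(inherits(tree, "phylo"))
  tips <- tree$tip.label
  if (anyDuplicated(tips)) stop("tree tip labels must be unique")
  for (nm in c("tip_id", "clade")) if (!nm %in% names(clades))
    stop("clade table missing column ", nm)
  for (nm in c("sample_id", "tip_id")) if (!nm %in% names(mapping))
    stop("mapping table missing column ", nm)
  clades$tip_id <- as.character(clades$tip_id)
  mapping$sample_id <- as.character(mapping$sample_id)
  mapping$tip_id <- as.character(mapping$tip_id)
  bad <- setdiff(c(clades$tip_id, mapping$tip_id), tips)
  if (length(bad))
    stop("tip(s) not in tree: ", paste(unique(bad), collapse = ", "))
  uncladed <- setdiff(tips, clades$tip_id)
  if (length(uncladed))
    stop("tip(s) without clade: ", paste(uncladed, collapse = ", "))
  if (anyDuplicated(clades$tip_id))
    stop("each tip must belong to exactly one clade")
  structure(list(tree = tree, clades = clades,
                 mapping = unique(mapping)),
            class = "clade_framework")
}

#' @export
print.clade_framework <- function(x, ...) {
  cat(sprintf("clade_framework: %d tips, %d clades, %d mapped samples\n",
              length(x$tree$tip.label), length(unique(x$clades$clade)),
              length(unique(x$mapping$sample_id))))
  invisible(x)
}

#' Read a clade framework from files
#' @param newick Newick tree file.
#' @param clades TSV with columns `tip_id`, `clade`.
#' @param mapping TSV with columns `sample_id`, `tip_id`.
#' @return A `clade_framework`.
#' @export
read_clade_framework <- function(newick, clades, mapping) {
  tree <- ape::read.tree(newick)
  cl <- utils::read.delim(clades, colClasses = "character")
  mp <- utils::read.delim(mapping, colClasses = "character")
  clade_framework(tree, cl, mp)
}

#' Enumerate all bijective sample-to-tip maps
#'
#' A bijective map assigns exactly one candidate sample to every tip, with
#' no sample used twice. Enumeration is an exhaustive depth-first search
#' over tips in tree tip-label order, candidates in sorted order, so the
#' result is deterministic and lexicographic.
#'
#' @param fw a `clade_framework`.
#' @param max_maps guard against combinatorial blow-up (default 10000).
#' @return List of maps; each map is a named character vector
#'   (names = tips, values = sample ids).
#' @export
enumerate_bijective_maps <- function(fw, max_maps = 10000) {
  stopifnot(inherits(fw, "clade_framework"))
  tips <- fw$tree$tip.label
  cand <- lapply(tips, function(t)
    sort(fw$mapping$sample_id[fw$mapping$tip_id == t]))
  names(cand) <- tips
  empty <- tips[lengths(cand) == 0]
  if (length(empty))
    stop("tip(s) with no candidate sample: ", paste(empty, collapse = ", "))
  # cheap upper bound before searching
  if (prod(lengths(cand)) > max_maps * 1e3)
    stop("candidate relation too large to enumerate (cap ", max_maps, ")")
  maps <- list()
  assign_tip <- function(k, used, acc) {
    if (k > length(tips)) {
      maps[[length(maps) + 1]] <<- stats::setNames(acc, tips)
      if (length(maps) > max_maps)
        stop("more than ", max_maps, " bijective maps; reduce the mapping")
      return(invisible())
    }
    for (s in cand[[k]]) {
      if (!(s %in% used)) assign_tip(k + 1, c(used, s), c(acc, s))
    }
  }
  assign_tip(1, character(0), character(0))
  maps
}

#' Species-level distance matrix on selected features
#'
#' Pairwise distances between sample profiles restricted to the selected
#' metabolite features: Hamming for presence/absence data, Euclidean for
#' relative-abundance data.
#'
#' @param table a `compound_table` (mode consistent with `metric`).
#' @param features character vector of compound ids to use.
#' @param metric `"hamming"` or `"euclidean"`.
#' @return Symmetric matrix with sample ids as dimnames.
#' @export
species_level_distances <- function(table, features,
                                    metric = c("hamming", "euclidean")) {
  stopifnot(inherits(table, "compound_table"), length(features) > 0)
  metric <- match.arg(metric)
  unknown <- setdiff(features, compound_ids(table))
  if (length(unknown))
    stop("unknown feature(s): ", paste(unknown, collapse = ", "))
  if (metric == "hamming" && table$mode != "qualitative")
    stop("hamming metric requires a qualitative table")
  x <- table$values[, features, drop = FALSE]
  d <- if (metric == "hamming") stats::dist(x, method = "manhattan")
       else stats::dist(x, method = "euclidean")
  as.matrix(d)
}

#' Within-clade distance
#'
#' Mean of all pairwise species-level distances among clade members. A
#' singleton clade has no pairs; its WCD is `NA` and is excluded from
#' downstream rank tests.
#'
#' @param sld species-level distance matrix.
#' @param clade_members sample ids (rows of `sld`) in the clade.
#' @return Mean pairwise distance, or `NA_real_` for singletons.
#' @export
within_clade_distance <- function(sld, clade_members) {
  if (length(clade_members) == 0) stop("empty clade")
  stopifnot(all(clade_members %in% rownames(sld)))
  if (length(clade_members) == 1) return(NA_real_)
  m <- sld[clade_members, clade_members, drop = FALSE]
  mean(m[upper.tri(m)])
}

#' Between-clade distance
#'
#' Mean of all species-level distances of member pairs across two disjoint
#' clades.
#'
#' @param sld species-level distance matrix.
#' @param cladeA,cladeB disjoint, nonempty sample id vectors.
#' @return Mean cross-pair distance.
#' @export
between_clade_distance <- function(sld, cladeA, cladeB) {
  if (!length(cladeA) || !length(cladeB)) stop("empty clade")
  if (length(intersect(cladeA, cladeB))) stop("clades overlap")
  stopifnot(all(c(cladeA, cladeB) %in% rownames(sld)))
  mean(sld[cladeA, cladeB, drop = FALSE])
}

#' One-sided Wilcoxon rank-sum test ("x smaller than y")
#'
#' Exact null distribution when the combined sample size is at most 20 and
#' there are no ties; otherwise the normal approximation with tie
#' correction (both via [stats::wilcox.test()]).
#'
#' @param x,y numeric vectors; `NA`s (e.g. singleton-clade WCDs) removed.
#' @return One-sided p-value.
#' @export
wilcoxon_less <- function(x, y) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (!length(x) || !length(y)) stop("empty sample after NA removal")
  exact <- (length(x) + length(y)) <= 20 && !anyDuplicated(c(x, y))
  suppressWarnings(
    stats::wilcox.test(x, y, alternative = "less", exact = exact,
                       correct = !exact)$p.value)
}

#' Clade-distance summary averaged over all bijective maps
#'
#' For every enumerated bijective map, samples assigned to the tips form a
#' species-level distance matrix (SLD) on the selected features; per-clade
#' within-clade distances (WCD) and per-clade-pair between-clade distances
#' (BCD) are computed from it. Averaging elementwise over maps yields aSLD
#' (indexed by tip), aWCD and aBCD. The one-sided Wilcoxon rank-sum test of
#' "aWCD smaller than aBCD" and the best map (maximizing
#' mean(BCD) - mean(WCD)) are attached.
#'
#' @param fw a `clade_framework` whose mapped samples appear in `table`.
#' @param table a `compound_table`.
#' @param features selected compound ids.
#' @param metric `"hamming"` or `"euclidean"`.
#' @param max_maps enumeration cap, passed through.
#' @return An object of class `distance_summary`: list with `maps`,
#'   `n_maps`, `wcd` (maps x clades), `bcd` (maps x clade pairs), `aWCD`,
#'   `aBCD`, `aSLD` (tip x tip), `wilcoxon_p`, `best_map`,
#'   `best_map_index`, `clade_of_tip`.
#' @export
average_over_maps <- function(fw, table, features,
                              metric = c("hamming", "euclidean"),
                              max_maps = 10000) {
  metric <- match.arg(metric)
  maps <- enumerate_bijective_maps(fw, max_maps)
  tips <- fw$tree$tip.label
  clade_of <- stats::setNames(fw$clades$clade, fw$clades$tip_id)[tips]
  clade_names <- unique(fw$clades$clade)
  pair_idx <- utils::combn(clade_names, 2)
  pair_names <- apply(pair_idx, 2, paste, collapse = "|")
  # one big SLD over every sample that appears in any map avoids
  # recomputing distances map by map
  all_samples <- sort(unique(unlist(maps, use.names = FALSE)))
  big <- species_level_distances(subset_samples(table, all_samples),
                                 features, metric)
  n_maps <- length(maps)
  wcd <- matrix(NA_real_, n_maps, length(clade_names),
                dimnames = list(NULL, clade_names))
  bcd <- matrix(NA_real_, n_maps, ncol(pair_idx),
                dimnames = list(NULL, pair_names))
  aSLD <- matrix(0, length(tips), length(tips),
                 dimnames = list(tips, tips))
  for (m in seq_len(n_maps)) {
    assigned <- maps[[m]]
    sld <- big[assigned, assigned, drop = FALSE]
    dimnames(sld) <- list(tips, tips)
    aSLD <- aSLD + sld
    for (cl in clade_names) {
      members <- tips[clade_of == cl]
      wcd[m, cl] <- within_clade_distance(sld, members)
    }
    for (k in seq_len(ncol(pair_idx)))
      bcd[m, k] <- between_clade_distance(
        sld, tips[clade_of == pair_idx[1, k]],
        tips[clade_of == pair_idx[2, k]])
  }
  aSLD <- aSLD / n_maps
  aWCD <- colMeans(wcd)
  aBCD <- colMeans(bcd)
  score <- rowMeans(bcd) - rowMeans(wcd, na.rm = TRUE)
  best <- which.max(score)
  structure(list(maps = maps, n_maps = n_maps, wcd = wcd, bcd = bcd,
                 aWCD = aWCD, aBCD = aBCD, aSLD = aSLD,
                 wilcoxon_p = wilcoxon_less(aWCD, aBCD),
                 best_map = maps[[best]], best_map_index = best,
                 clade_of_tip = clade_of),
            class = "distance_summary")
}

#' @export
print.distance_summary <- function(x, ...) {
  cat(sprintf(
    "distance_summary: %d maps, %d clades; Wilcoxon p (aWCD < aBCD) = %.4g\n",
    x$n_maps, length(x$aWCD), x$wilcoxon_p))
  invisible(x)
}

#' Concordance report
#'
#' How the averaged within-clade distances sit against the background: the
#' counts of aWCDs below the mean and the median of (a) the off-diagonal
#' aSLD values and (b) the aBCD values, the Wilcoxon p, and a per-clade
#' table.
#'
#' @param summary a `distance_summary`.
#' @return List with `n_clades_tested`, `below_aSLD_mean`,
#'   `below_aSLD_median`, `below_aBCD_mean`, `below_aBCD_median`,
#'   `wilcoxon_p` and a data frame `per_clade`.
#' @export
concordance_report <- function(summary) {
  stopifnot(inherits(summary, "distance_summary"))
  aw <- summary$aWCD[!is.na(summary$aWCD)]
  off <- summary$aSLD[upper.tri(summary$aSLD)]
  ab <- summary$aBCD
  list(
    n_clades_tested = length(aw),
    below_aSLD_mean = sum(aw < mean(off)),
    below_aSLD_median = sum(aw < stats::median(off)),
    below_aBCD_mean = sum(aw < mean(ab)),
    below_aBCD_median = sum(aw < stats::median(ab)),
    wilcoxon_p = summary$wilcoxon_p,
    per_clade = data.frame(clade = names(summary$aWCD),
                           aWCD = unname(summary$aWCD),
                           n_tips = as.vector(table(summary$clade_of_tip)[
                             names(summary$aWCD)]))
  )
}

#' Export the selected-feature matrix in tree tip order under the best map
#'
#' Rows are the samples the best bijective map assigns to the tips, in the
#' tree's tip order (heat-map ready); samples never assigned by the best
#' map are listed separately, mirroring their omission from tree-aligned
#' visualizations.
#'
#' @param fw a `clade_framework`.
#' @param best_map named character vector (tip -> sample), e.g.
#'   `summary$best_map`.
#' @param table a `compound_table`.
#' @param features selected compound ids.
#' @param path optional TSV output path; a `<path>.unmapped.txt` sidecar
#'   lists omitted samples.
#' @return List with `matrix` (rows tip-ordered, rownames
#'   `"<tip>:<sample>"`) and `unmapped` sample ids.
#' @export
export_tree_ordered_matrix <- function(fw, best_map, table, features,
                                       path = NULL) {
  stopifnot(inherits(fw, "clade_framework"))
  tips <- fw$tree$tip.label
  stopifnot(all(tips %in% names(best_map)))
  samples <- best_map[tips]
  m <- table$values[samples, features, drop = FALSE]
  rownames(m) <- paste(tips, samples, sep = ":")
  unmapped <- setdiff(unique(fw$mapping$sample_id), samples)
  if (!is.null(path)) {
    utils::write.table(data.frame(tip_sample = rownames(m), m,
                                  check.names = FALSE),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(unmapped, paste0(path, ".unmapped.txt"))
  }
  list(matrix = m, unmapped = unmapped)
}
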
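#' Simulate a clade-structured phylogeny with a sample-to-tip mapping
#'
#' Builds a rooted, bifurcating tree whose tips are grouped into contiguous
#' named clades, plus a sample-to-tip candidate mapping. `clade_sizes`
#' counts *samples* per clade. By default the mapping is one-to-one (one
#' tip per sample). With `candidate_group_sizes = c(g1, g2, ...)`, the
#' largest clades each donate one "shared" tip carrying `g` candidate
#' samples (disjoint candidate sets), so the number of bijective maps is
#' `prod(g)` and the tree has `sum(clade_sizes) - sum(g - 1)` tips. The
#' default study-shaped configuration (9 clades of sizes
#' 1, 11, 4, 3, 13, 4, 5, 5, 2; groups 3, 3, 2) yields 48 samples,
#' 43 tips and 18 bijective maps.
#'
#' @param clade_sizes integer vector of samples per clade (>= 1 each).
#' @param candidate_group_sizes optional integer vector of candidate-set
#'   sizes (>= 2 each) for shared tips.
#' @param seed RNG seed.
#' @return A `clade_framework` with an extra element `sample_clade`
#'   (named character vector: clade of each sample).
#' @export
simulate_clade_tree <- function(clade_sizes = c(1, 11, 4, 3, 13, 4, 5, 5, 2),
                                candidate_group_sizes = NULL, seed = 1) {
  stopifnot(all(clade_sizes >= 1))
  k <- length(candidate_group_sizes)
  if (k > 0) {
    stopifnot(all(candidate_group_sizes >= 2))
    host <- order(clade_sizes, decreasing = TRUE)[seq_len(k)]
    if (any(clade_sizes[host] < candidate_group_sizes + 0))
      stop("clades too small to host the candidate groups")
  } else host <- integer(0)
  n_clades <- length(clade_sizes)
  clade_names <- sprintf("clade%02d", seq_len(n_clades))
  set.seed(seed)
  # random binary topology as a nested-parenthesis string
  rand_split <- function(labels) {
    if (length(labels) == 1) return(labels)
    if (length(labels) == 2)
      return(sprintf("(%s:%.4f,%s:%.4f)", labels[1], stats::runif(1, .1, 1),
                     labels[2], stats::runif(1, .1, 1)))
    cut <- sample(seq_len(length(labels) - 1), 1)
    sprintf("(%s:%.4f,%s:%.4f)",
            rand_split(labels[seq_len(cut)]), stats::runif(1, .1, 1),
            rand_split(labels[-seq_len(cut)]), stats::runif(1, .1, 1))
  }
  sample_id <- character(0)
  sample_clade <- character(0)
  tips_of_clade <- vector("list", n_clades)
  mapping <- NULL
  for (c_i in seq_len(n_clades)) {
    n_s <- clade_sizes[c_i]
    ids <- sprintf("s%02d_%s", seq_len(n_s), clade_names[c_i])
    sample_id <- c(sample_id, ids)
    sample_clade <- c(sample_clade, rep(clade_names[c_i], n_s))
    g <- if (c_i %in% host) candidate_group_sizes[match(c_i, host)] else 1
    n_tips <- n_s - (g - 1)
    tips <- sprintf("t_%s_%02d", clade_names[c_i], seq_len(n_tips))
    tips_of_clade[[c_i]] <- tips
    # last tip of a hosting clade takes the g-sample candidate group
    tip_for_sample <- c(tips[seq_len(n_tips - 1)],
                        rep(tips[n_tips], g))
    mapping <- rbind(mapping,
                     data.frame(sample_id = ids, tip_id = tip_for_sample))
  }
  sub <- vapply(tips_of_clade, rand_split, "")
  newick <- paste0(rand_split(sub), ";")
  tree <- ape::read.tree(text = newick)
  clades <- data.frame(
    tip_id = unlist(tips_of_clade),
    clade = rep(clade_names, lengths(tips_of_clade)))
  fw <- clade_framework(tree, clades, mapping)
  fw$sample_clade <- stats::setNames(sample_clade, sample_id)
  fw
}

#' Background presence rate hitting a target overall sparsity
#'
#' Given the informative-feature structure, solves for the Bernoulli rate
#' of the background features so the *expected* fraction of zero cells in
#' the whole matrix equals `target_sparsity`.
#'
#' @param clade_sizes samples per clade.
#' @param n_features,n_informative feature counts.
#' @param p_in,p_out presence rates of informative features inside/outside
#'   their clade.
#' @param target_sparsity desired expected zero fraction.
#' @param informative_clades indices of clades that receive informative
#'   features (round-robin).
#' @return Background presence probability.
#' @export
background_rate <- function(clade_sizes, n_features, n_informative,
                            p_in, p_out, target_sparsity,
                            informative_clades = which(clade_sizes >= 2)) {
  n <- sum(clade_sizes)
  cl <- rep(informative_clades,
            length.out = n_informative)
  present_inf <- sum((clade_sizes[cl] * p_in +
                        (n - clade_sizes[cl]) * p_out) / n)
  n_bg <- n_features - n_informative
  p_bg <- ((1 - target_sparsity) * n_features - present_inf) / n_bg
  if (p_bg <= 0 || p_bg >= 1)
    stop("target sparsity unreachable with this informative structure")
  p_bg
}

#' Simulate a clade-structured sparse compound matrix
#'
#' Binary presence calls: an informative feature associated with clade c is
#' present with probability `p_in` inside c and `p_out` elsewhere;
#' background features are present with a clade-independent rate solved by
#' [background_rate()] so the expected overall sparsity matches
#' `target_sparsity`. Quantitative abundances draw log-normal(meanlog,
#' sdlog) peak sizes for present cells and normalize each row to 100%.
#' Informative features are assigned round-robin to the non-singleton
#' clades.
#'
#' @param fw a `clade_framework` from [simulate_clade_tree()] (supplies the
#'   sample-to-clade ground truth).
#' @param n_features total number of compounds (default 560).
#' @param n_informative number of clade-informative compounds (default 20).
#' @param p_in,p_out informative presence rates (defaults 0.9 / 0.05).
#' @param target_sparsity expected overall zero fraction (default 0.914).
#' @param meanlog,sdlog log-normal abundance parameters (defaults 0 / 1).
#' @param seed RNG seed.
#' @return List with `qualitative` and `quantitative` `compound_table`s
#'   and `truth` (informative feature ids, their clades, rates, seed).
#' @export
simulate_compound_matrix <- function(fw, n_features = 560,
                                     n_informative = 20,
                                     p_in = 0.9, p_out = 0.05,
                                     target_sparsity = 0.914,
                                     meanlog = 0, sdlog = 1, seed = 1) {
  stopifnot(!is.null(fw$sample_clade), n_informative <= n_features,
            p_out < p_in)
  samples <- names(fw$sample_clade)
  clade_names <- unique(fw$sample_clade)
  clade_sizes <- as.vector(table(factor(fw$sample_clade,
                                        levels = clade_names)))
  n <- length(samples)
  inf_clades <- which(clade_sizes >= 2)
  p_bg <- if (n_informative < n_features)
    background_rate(clade_sizes, n_features, n_informative, p_in, p_out,
                    target_sparsity, inf_clades)
  else NA_real_
  set.seed(seed)
  feat_ids <- sprintf("cmp%03d", seq_len(n_features))
  inf_idx <- seq_len(n_informative)
  inf_clade <- clade_names[rep(inf_clades, length.out = n_informative)]
  v <- matrix(0, n, n_features, dimnames = list(samples, feat_ids))
  for (j in inf_idx) {
    inside <- fw$sample_clade == inf_clade[j]
    pr <- ifelse(inside, p_in, p_out)
    v[, j] <- stats::rbinom(n, 1, pr)
  }
  if (n_informative < n_features) {
    n_bg <- n_features - n_informative
    v[, (n_informative + 1):n_features] <-
      stats::rbinom(n * n_bg, 1, p_bg)
  }
  qual <- compound_table(v, "qualitative",
                         meta = data.frame(sample_id = samples,
                                           species = fw$sample_clade,
                                           infraspecific = "",
                                           tissue = "lid"))
  amt <- v
  amt[v == 1] <- stats::rlnorm(sum(v), meanlog, sdlog)
  tot <- rowSums(amt)
  nz <- tot > 0
  amt[nz, ] <- 100 * amt[nz, , drop = FALSE] / tot[nz]
  quant <- compound_table(amt, "quantitative", meta = qual$meta)
  truth <- list(informative = stats::setNames(inf_clade,
                                              feat_ids[inf_idx]),
                p_in = p_in, p_out = p_out, p_bg = p_bg,
                target_sparsity = target_sparsity,
                sample_clade = fw$sample_clade, seed = seed)
  list(qualitative = qual, quantitative = quant, truth = truth)
}

#' Simulate raw peak records from a quantitative compound table
#'
#' Emits one peak record per nonzero cell: retention time is the
#' compound's nominal rt plus Gaussian jitter, the library match is uniform
#' in `match_range`, and the area is proportional to the relative
#' abundance (scaled per sample so rebuilding the table recovers the
#' percentages).
#'
#' @param table a quantitative `compound_table`.
#' @param rt_map named numeric vector (compound -> nominal rt, minutes);
#'   default evenly spaced over 5-30 min.
#' @param jitter_sd rt jitter standard deviation, minutes.
#' @param match_range range of `match_pct` values.
#' @param seed RNG seed.
#' @return Peak record data frame as read by [read_peak_records()].
#' @export
simulate_peak_records <- function(table, rt_map = NULL, jitter_sd = 0.005,
                                  match_range = c(70, 99), seed = 1) {
  stopifnot(inherits(table, "compound_table"),
            table$mode == "quantitative")
  cmp <- compound_ids(table)
  if (is.null(rt_map))
    rt_map <- stats::setNames(seq(5, 30, length.out = length(cmp)), cmp)
  stopifnot(all(cmp %in% names(rt_map)))
  set.seed(seed)
  nz <- which(table$values > 0, arr.ind = TRUE)
  n <- nrow(nz)
  out <- data.frame(
    sample_id = sample_ids(table)[nz[, 1]],
    rt = pmax(0, rt_map[cmp[nz[, 2]]] + stats::rnorm(n, 0, jitter_sd)),
    compound_id = cmp[nz[, 2]],
    match_pct = stats::runif(n, match_range[1], match_range[2]),
    area = table$values[nz] * 1e4,
    compound_class = NA_character_)
  rownames(out) <- NULL
  out[order(out$sample_id, out$rt), , drop = FALSE]
}

#' Simulate a SIM trace with a coniine-like peak
#'
#' Gaussian-shaped elution profiles at 6.33 min for each monitored ion,
#' with apex height `amount x rel_intensity x 1000` counts plus Gaussian
#' baseline noise (negative values clipped). An `amount` of 1 corresponds
#' to the detection limit of the calibrated thresholds
#' ([sim_thresholds()]); `amount = 0` gives a noise-only trace.
#'
#' @param amount spike level in limit-of-detection units (>= 0).
#' @param ref a `coniine_reference`.
#' @param noise_sd baseline noise standard deviation (counts).
#' @param peak_sd chromatographic peak width (sd, minutes).
#' @param rt_range,rt_step sampled retention-time grid.
#' @param seed RNG seed.
#' @return Data frame with columns `rt`, `mz`, `intensity`.
#' @export
simulate_sim_trace <- function(amount, ref = coniine_reference(),
                               noise_sd = 5, peak_sd = 0.005,
                               rt_range = c(6.2, 6.5), rt_step = 0.002,
                               seed = 1) {
  stopifnot(amount >= 0)
  set.seed(seed)
  rt <- seq(rt_range[1], rt_range[2], by = rt_step)
  out <- do.call(rbind, lapply(ref$ions, function(ion) {
    h <- amount * ref$rel[[as.character(ion)]] * 1000
    sig <- h * exp(-(rt - ref$rt_center)^2 / (2 * peak_sd^2))
    data.frame(rt = rt, mz = ion,
               intensity = pmax(0, sig + stats::rnorm(length(rt), 0,
                                                      noise_sd)))
  }))
  rownames(out) <- NULL
  out
}
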
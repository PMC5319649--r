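#' Per-feature decomposition of pairwise dissimilarities
#'
#' Sparse feature-selected clustering works on the additive decomposition of
#' the pairwise dissimilarity into per-feature contributions
#' \eqn{d_{(i,i'),j}}: for presence/absence data the Hamming indicator
#' (1 where the two samples disagree at feature j), for quantitative data
#' the squared difference \eqn{(x_{ij} - x_{i'j})^2}. Summing a row over
#' features recovers the Hamming distance, or the squared Euclidean
#' distance, between the pair.
#'
#' @param table a `compound_table`; mode must match the metric
#'   (`hamming` requires a qualitative table).
#' @param metric `"hamming"` or `"euclidean_sq"`.
#' @return An object of class `dissim_decomp`: list with `pairs` (2-column
#'   index matrix, i < i'), `contrib` (pairs x features matrix), `metric`,
#'   `sample_ids`, `feature_ids`.
#' @export
per_feature_dissimilarities <- function(table,
                                        metric = c("hamming", "euclidean_sq")) {
  stopifnot(inherits(table, "compound_table"))
  metric <- match.arg(metric)
  if (metric == "hamming" && table$mode != "qualitative")
    stop("hamming metric requires a qualitative table")
  if (metric == "euclidean_sq" && table$mode != "quantitative")
    stop("euclidean_sq metric requires a quantitative table")
  x <- table$values
  n <- nrow(x)
  if (n < 2) stop("need at least two samples")
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  d <- x[idx[, 1], , drop = FALSE] - x[idx[, 2], , drop = FALSE]
  contrib <- if (metric == "hamming") abs(d) else d^2
  dimnames(contrib) <- list(NULL, colnames(x))
  structure(list(pairs = unname(idx), contrib = contrib, metric = metric,
                 sample_ids = rownames(x), feature_ids = colnames(x)),
            class = "dissim_decomp")
}

#' Soft-thresholding operator
#'
#' `max(a - delta, 0)` elementwise; the proximal map behind the lasso-type
#' penalty on feature weights.
#'
#' @param a nonnegative numeric vector.
#' @param delta nonnegative threshold.
#' @return Thresholded vector.
#' @export
soft_threshold <- function(a, delta) {
  stopifnot(all(a >= 0), delta >= 0)
  pmax(a - delta, 0)
}

#' Unit-norm weight vector for a given soft-threshold level
#' @param a nonnegative vector of per-feature scores.
#' @param delta soft-threshold level.
#' @return w = S(a, delta) / ||S(a, delta)||_2.
#' @export
solve_weights_for_delta <- function(a, delta) {
  s <- soft_threshold(a, delta)
  nrm <- sqrt(sum(s^2))
  if (nrm == 0) stop("delta too large: all feature scores thresholded to zero")
  s / nrm
}

#' Soft-threshold level making the L1 constraint bind
#'
#' Returns 0 when the unconstrained unit-L2 solution already satisfies
#' `||w||_1 <= s`; otherwise bisects for the delta at which
#' `||w(delta)||_1 = s` (tolerance 1e-8). `||w(delta)||_1` decreases
#' continuously from `||w(0)||_1` towards 1 as delta grows, so a root
#' exists for any s >= 1.
#'
#' @param a nonnegative vector with at least one positive entry.
#' @param s L1 bound, `1 <= s <= sqrt(length(a))`.
#' @return The soft-threshold level delta.
#' @export
delta_for_l1 <- function(a, s) {
  p <- length(a)
  stopifnot(s >= 1, s <= sqrt(p) + 1e-12)
  if (sum(solve_weights_for_delta(a, 0)) <= s) return(0)
  lo <- 0
  hi <- max(a)
  for (iter in 1:200) {
    mid <- (lo + hi) / 2
    l1 <- tryCatch(sum(solve_weights_for_delta(a, mid)), error = function(e) 1)
    if (l1 > s) lo <- mid else hi <- mid
    if (hi - lo < 1e-12) break
  }
  # the upper end of the bracket keeps ||w||_1 <= s; with exactly tied
  # maximal entries no delta reaches ||w||_1 = s (the norm jumps from
  # sqrt(#ties) to the threshold point) — the optimizer resolves that case
  # separately, see optimize_feature_weights()
  hi
}

# Globally optimal weights when soft-thresholding cannot bind the L1
# constraint: with m entries tied at max(a) and s <= sqrt(m), any feasible
# w supported on the tied set with ||w||_1 = s attains the upper bound
# max(a) * s of the linear objective. Deterministic split: the first tied
# coordinate takes the larger root.
tied_max_weights <- function(a, s) {
  mx <- max(a)
  tied <- which(a >= mx * (1 - 1e-12))
  k <- length(tied) - 1
  w <- numeric(length(a))
  if (k == 0) {
    w[tied] <- 1
    return(w)
  }
  disc <- k * (k + 1 - s^2)
  y <- (s * k - sqrt(max(0, disc))) / (k * (k + 1))
  w[tied] <- y
  w[tied[1]] <- s - k * y
  w
}

#' Optimize sparse feature weights for clustering
#'
#' Alternating maximization of \eqn{\sum_j w_j (d_j \cdot u)} over a
#' unit-L2 vector `u` (one entry per sample pair) and a nonnegative weight
#' vector `w` with `||w||_2 = 1`, `||w||_1 <= s`. Starting from uniform
#' weights, each round sets `u = Dw / ||Dw||_2`, then scores features by
#' `a = D'u` (negatives clipped to zero) and solves the lasso-constrained
#' weight subproblem in closed form via soft-thresholding. The objective is
#' nondecreasing; iteration stops when `max|w_new - w_old| < tol`.
#'
#' Zero-variance features (all-zero contribution columns) receive weight 0
#' automatically and are excluded from the optimization. Because the
#' alternating scheme can stall in a local maximum (e.g. a pair of
#' duplicated weak features beating one strong feature), the optimization
#' is run from two deterministic starts — uniform weights and a one-hot
#' start on the feature with the largest contribution norm — and the
#' better final objective wins.
#'
#' @param decomp a `dissim_decomp`.
#' @param s L1 bound on the weights, in `[1, sqrt(p)]`.
#' @param tol convergence tolerance on the max absolute weight change.
#' @param max_iter iteration cap per start.
#' @return An object of class `feature_weights`: list with `w` (named),
#'   `s`, `delta`, `n_iter`, `converged`, `objective` (trace of objective
#'   values, one per iteration, for the winning start).
#' @export
optimize_feature_weights <- function(decomp, s, tol = 1e-6, max_iter = 100) {
  stopifnot(inherits(decomp, "dissim_decomp"))
  D <- decomp$contrib
  if (all(D == 0)) stop("all-zero dissimilarity decomposition")
  active <- colSums(D) > 0
  Da <- D[, active, drop = FALSE]
  p <- ncol(Da)
  stopifnot(s >= 1, s <= sqrt(ncol(D)) + 1e-12)
  s_eff <- min(s, sqrt(p))
  starts <- list(rep(1 / sqrt(p), p))
  if (p > 1) {
    hot <- numeric(p)
    hot[which.max(colSums(Da^2))] <- 1
    starts <- c(starts, list(hot))
  }
  best <- NULL
  for (w0 in starts) {
    run <- alternate_weights(Da, w0, s_eff, tol, max_iter)
    attained <- sqrt(sum((Da %*% run$w)^2))
    if (is.null(best) || attained > best$attained + 1e-12)
      best <- c(run, list(attained = attained))
  }
  w_full <- stats::setNames(numeric(ncol(D)), decomp$feature_ids)
  w_full[active] <- best$w
  structure(list(w = w_full, s = s, delta = best$delta,
                 n_iter = best$n_iter, converged = best$converged,
                 objective = best$objective),
            class = "feature_weights")
}

# one run of the alternating maximization from a given weight start
alternate_weights <- function(Da, w, s_eff, tol, max_iter) {
  obj <- numeric(0)
  delta <- 0
  converged <- FALSE
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    Dw <- drop(Da %*% w)
    u <- Dw / sqrt(sum(Dw^2))
    a <- pmax(drop(crossprod(Da, u)), 0)
    delta <- delta_for_l1(a, s_eff)
    w_new <- tryCatch(solve_weights_for_delta(a, delta),
                      error = function(e) NULL)
    if (is.null(w_new) || sum(w_new) > s_eff + 1e-6)
      w_new <- tied_max_weights(a, s_eff) # tied maxima: constraint not
    # attainable by thresholding alone, see tied_max_weights()
    obj <- c(obj, sum(a * w_new))
    if (length(obj) >= 2 && obj[length(obj)] < obj[length(obj) - 1] - 1e-8)
      stop("internal error: objective decreased between iterations")
    if (max(abs(w_new - w)) < tol) {
      w <- w_new
      converged <- TRUE
      break
    }
    w <- w_new
  }
  list(w = w, delta = delta, n_iter = iter, converged = converged,
       objective = obj)
}

#' @export
print.feature_weights <- function(x, ...) {
  cat(sprintf(
    "feature_weights: %d/%d nonzero (s = %.3g, delta = %.3g, %d iter%s)\n",
    sum(x$w > 1e-8), length(x$w), x$s, x$delta, x$n_iter,
    if (x$converged) ", converged" else ", NOT converged"))
  invisible(x)
}

#' Reweighted pairwise dissimilarity matrix
#'
#' Weighted sum of the per-feature contributions. For the Hamming
#' decomposition the entry is \eqn{\sum_j w_j d_{(i,i'),j}}; for squared
#' Euclidean contributions the square root is taken, so uniform weights
#' `1/sqrt(p)` give a matrix proportional to the ordinary Euclidean
#' distance.
#'
#' @param decomp a `dissim_decomp`.
#' @param w nonnegative weight vector (length = number of features of
#'   `decomp`, or a `feature_weights` object).
#' @return Symmetric n x n matrix with zero diagonal, sample ids as
#'   dimnames.
#' @export
weighted_dissimilarity <- function(decomp, w) {
  stopifnot(inherits(decomp, "dissim_decomp"))
  if (inherits(w, "feature_weights")) w <- w$w
  stopifnot(length(w) == ncol(decomp$contrib), all(w >= 0))
  v <- drop(decomp$contrib %*% w)
  if (decomp$metric == "euclidean_sq") v <- sqrt(v)
  n <- length(decomp$sample_ids)
  m <- matrix(0, n, n, dimnames = list(decomp$sample_ids, decomp$sample_ids))
  m[decomp$pairs] <- v
  m[decomp$pairs[, 2:1, drop = FALSE]] <- v
  m
}

#' Complete-linkage hierarchical clustering of a dissimilarity matrix
#'
#' Agglomerative clustering where the distance between two clusters is the
#' maximum pairwise dissimilarity across them (delegates to
#' [stats::hclust()]).
#'
#' @param dmatrix symmetric nonnegative matrix with zero diagonal.
#' @return An `hclust` object.
#' @export
complete_linkage <- function(dmatrix) {
  if (!is.matrix(dmatrix) || !isSymmetric(unname(dmatrix), tol = 1e-12))
    stop("dissimilarity matrix must be symmetric")
  if (any(diag(dmatrix) != 0)) stop("diagonal must be zero")
  if (any(dmatrix < 0)) stop("dissimilarities must be nonnegative")
  stats::hclust(stats::as.dist(dmatrix), method = "complete")
}

#' Export a dendrogram as a Newick string
#' @param hc an `hclust` object.
#' @param path optional file path; if given the tree is written there.
#' @return The Newick string, invisibly when `path` is given.
#' @export
dendrogram_newick <- function(hc, path = NULL) {
  phy <- ape::as.phylo(hc)
  txt <- ape::write.tree(phy)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Permutation (gap-statistic) selection of the sparsity level s
#'
#' For each candidate s the optimizer objective on the real decomposition is
#' compared with its mean over decompositions whose feature columns were
#' independently permuted (destroying between-feature structure while
#' keeping margins). The s with the largest gap wins; ties go to the
#' smaller s.
#'
#' @param decomp a `dissim_decomp`.
#' @param candidate_s numeric vector of candidate L1 bounds; default 11
#'   log-spaced values in `[1.2, sqrt(p)]`.
#' @param n_perm number of column permutations per candidate.
#' @param seed RNG seed (local to this call).
#' @return List with `s_best`, and a data frame `gap_table`
#'   (s, objective, perm_mean, gap).
#' @export
select_tuning <- function(decomp, candidate_s = NULL, n_perm = 10, seed = 1) {
  stopifnot(inherits(decomp, "dissim_decomp"), n_perm >= 1)
  p <- ncol(decomp$contrib)
  if (is.null(candidate_s))
    candidate_s <- exp(seq(log(1.2), log(sqrt(p)), length.out = 11))
  if (length(candidate_s) == 1) {
    return(list(s_best = candidate_s,
                gap_table = data.frame(s = candidate_s, objective = NA,
                                       perm_mean = NA, perm_sd = NA,
                                       gap = NA)))
  }
  obj_of <- function(dc, s)
    max(optimize_feature_weights(dc, s)$objective)
  withr_seed <- function(expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    expr
  }
  withr_seed({
    perms <- lapply(seq_len(n_perm), function(b) {
      dc <- decomp
      dc$contrib <- apply(dc$contrib, 2, sample)
      dc
    })
    rows <- lapply(candidate_s, function(s) {
      o <- obj_of(decomp, s)
      po <- vapply(perms, function(dc) obj_of(dc, s), 0)
      data.frame(s = s, objective = o, perm_mean = mean(po),
                 perm_sd = stats::sd(po), gap = o - mean(po))
    })
  })
  tab <- do.call(rbind, rows)
  list(s_best = tab$s[which.max(tab$gap)], gap_table = tab)
}

#' Features retained by the sparse weights
#' @param weights a `feature_weights` object.
#' @param tol weights at or below this are treated as zero.
#' @return Character vector of feature ids, by decreasing weight (ties by
#'   feature id).
#' @export
selected_features <- function(weights, tol = 1e-8) {
  stopifnot(inherits(weights, "feature_weights"))
  w <- weights$w[weights$w > tol]
  names(w)[order(-w, names(w))]
}
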
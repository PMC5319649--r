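# Shared fixtures and independent oracles. Oracles are deliberately naive
# (loops, enumeration) and never call the code paths they check.

toy_qual_table <- function(values, samples = NULL, compounds = NULL) {
  if (is.null(samples)) samples <- paste0("s", seq_len(nrow(values)))
  if (is.null(compounds)) compounds <- paste0("c", seq_len(ncol(values)))
  dimnames(values) <- list(samples, compounds)
  compound_table(values, "qualitative")
}

toy_quant_table <- function(values, samples = NULL, compounds = NULL) {
  if (is.null(samples)) samples <- paste0("s", seq_len(nrow(values)))
  if (is.null(compounds)) compounds <- paste0("c", seq_len(ncol(values)))
  dimnames(values) <- list(samples, compounds)
  compound_table(values, "quantitative")
}

write_peak_file <- function(df, sep = ",") {
  path <- tempfile(fileext = if (sep == ",") ".csv" else ".tsv")
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  path
}

peak_df <- function(...) {
  data.frame(..., stringsAsFactors = FALSE)
}

# 4-tip framework with two clades and a one-to-one mapping
tiny_framework <- function() {
  tree <- ape::read.tree(text = "((tA:1,tB:1):1,(tC:1,tD:1):1);")
  clades <- data.frame(tip_id = c("tA", "tB", "tC", "tD"),
                       clade = c("X", "X", "Y", "Y"))
  mapping <- data.frame(sample_id = c("s1", "s2", "s3", "s4"),
                        tip_id = c("tA", "tB", "tC", "tD"))
  clade_framework(tree, clades, mapping)
}

# --- oracle: naive O(n^3) complete-linkage cophenetic distances ---------
naive_complete_cophenetic <- function(d) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n)
  while (length(clusters) > 1) {
    k <- length(clusters)
    best <- c(Inf, NA, NA)
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      h <- max(d[clusters[[i]], clusters[[j]]])
      if (h < best[1]) best <- c(h, i, j)
    }
    i <- best[2]; j <- best[3]
    merged <- c(clusters[[i]], clusters[[j]])
    coph[clusters[[i]], clusters[[j]]] <- best[1]
    coph[clusters[[j]], clusters[[i]]] <- best[1]
    clusters[[i]] <- merged
    clusters[[j]] <- NULL
  }
  coph
}

# --- oracle: exact one-sided rank-sum p by full enumeration -------------
enum_wilcoxon_less <- function(x, y) {
  nx <- length(x); n <- nx + length(y)
  r <- rank(c(x, y))
  obs <- sum(r[seq_len(nx)])
  sets <- utils::combn(n, nx)
  stat <- colSums(matrix(seq_len(n)[sets], nrow = nx))
  mean(stat <= obs)
}

# --- oracle: count injective assignments by Cartesian-product filter ----
enum_injective_count <- function(cand) {
  grids <- do.call(expand.grid,
                   c(lapply(cand, function(v) seq_along(v)),
                     stringsAsFactors = FALSE))
  n_ok <- 0
  for (r in seq_len(nrow(grids))) {
    picks <- vapply(seq_along(cand),
                    function(k) cand[[k]][grids[r, k]], "")
    if (!anyDuplicated(picks)) n_ok <- n_ok + 1
  }
  n_ok
}

# --- oracle: grid search of the sparse-weight objective -----------------
# max ||D w||_2 over w >= 0, ||w||_2 = 1, ||w||_1 <= s, by dense sampling
# of unit directions in the nonnegative orthant (grid value <= true max).
grid_objective <- function(D, s, n_grid = 200) {
  p <- ncol(D)
  if (p == 1) return(sqrt(sum(D^2)))
  if (p == 2) {
    th <- seq(0, pi / 2, length.out = n_grid)
    W <- rbind(cos(th), sin(th))
  } else {
    m <- if (p == 3) n_grid else 40
    ang <- seq(0, pi / 2, length.out = m)
    W <- t(do.call(expand.grid, rep(list(ang), p - 1)))
    # spherical coordinates restricted to the nonnegative orthant
    w <- matrix(1, p, ncol(W))
    for (k in seq_len(p - 1)) {
      w[k, ] <- w[k, ] * cos(W[k, ])
      for (kk in (k + 1):p) w[kk, ] <- w[kk, ] * sin(W[k, ])
    }
    W <- w
  }
  ok <- colSums(W) <= s + 1e-12
  if (!any(ok)) stop("grid found no feasible point")
  max(sqrt(colSums((D %*% W[, ok, drop = FALSE])^2)))
}

default_framework <- function(seed) {
  simulate_clade_tree(candidate_group_sizes = c(3, 3, 2), seed = seed)
}
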
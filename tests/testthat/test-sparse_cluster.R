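test_that("dissimilarity decompositions sum back to the plain distances", {
  b <- toy_qual_table(matrix(c(1, 0, 1,
                               1, 1, 0), 2, 3, byrow = TRUE))
  d <- per_feature_dissimilarities(b, "hamming")
  expect_equal(unname(d$contrib[1, ]), c(0, 1, 1))
  expect_equal(sum(d$contrib[1, ]), 2) # Hamming distance

  q <- toy_quant_table(matrix(c(30, 0, 70,
                                0, 40, 60), 2, 3, byrow = TRUE))
  dq <- per_feature_dissimilarities(q, "euclidean_sq")
  expect_equal(unname(dq$contrib[1, ]), c(900, 1600, 100))
  expect_equal(sqrt(sum(dq$contrib[1, ])),
               sqrt(sum((q$values[1, ] - q$values[2, ])^2)))

  same <- toy_qual_table(matrix(c(1, 0, 1, 0), 2, 2, byrow = TRUE))
  expect_equal(unname(per_feature_dissimilarities(same, "hamming")$contrib[1, ]),
               c(0, 0))
  expect_error(per_feature_dissimilarities(b, "euclidean_sq"), "quantitative")
})

test_that("soft-thresholding and the weight subproblem behave as closed forms", {
  expect_equal(soft_threshold(c(3, 0.5), 1), c(2, 0))
  a <- c(2, 7, 0)
  expect_equal(soft_threshold(a, 0), a)
  expect_equal(soft_threshold(a, 7), c(0, 0, 0))
  expect_equal(solve_weights_for_delta(c(4, 3), 0), c(0.8, 0.6))
  expect_equal(solve_weights_for_delta(c(4, 3), 3), c(1, 0))
  expect_equal(solve_weights_for_delta(c(1, 1, 1), 0), rep(1 / sqrt(3), 3))
  expect_error(solve_weights_for_delta(c(1, 1), 2), "delta too large")
})

test_that("delta is chosen so the L1 constraint binds", {
  expect_equal(delta_for_l1(c(4, 3), sqrt(2)), 0) # constraint slack
  d <- delta_for_l1(c(4, 3), 1)
  expect_gte(d, 3)
  expect_lt(d, 4)
  expect_equal(sum(solve_weights_for_delta(c(4, 3), d)), 1, tolerance = 1e-6)
  # random vectors against a dense grid over delta
  set.seed(11)
  for (rep in 1:8) {
    a <- runif(5, 0, 10)
    s <- 1.5
    d <- delta_for_l1(a, s)
    w <- solve_weights_for_delta(a, d)
    if (d == 0) {
      expect_lte(sum(w), s) # constraint already slack
      next
    }
    expect_equal(sum(w), s, tolerance = 1e-6)
    grid <- seq(0, max(a) * 0.999, length.out = 20000)
    l1 <- vapply(grid, function(g) {
      st <- pmax(a - g, 0)
      sum(st) / sqrt(sum(st^2))
    }, 0)
    d_grid <- grid[which.min(abs(l1 - s))]
    expect_equal(d, d_grid, tolerance = max(a) / 10000)
  }
})

test_that("the optimizer attains the grid-search maximum on small instances", {
  set.seed(5)
  for (rep in 1:8) {
    n <- sample(3:6, 1)
    p <- sample(2:4, 1)
    tab <- toy_qual_table(matrix(rbinom(n * p, 1, 0.5), n, p))
    d <- per_feature_dissimilarities(tab, "hamming")
    if (all(d$contrib == 0)) next
    s <- runif(1, 1, sqrt(p))
    fit <- optimize_feature_weights(d, s)
    attained <- sqrt(sum((d$contrib %*% fit$w)^2))
    oracle <- grid_objective(d$contrib, s)
    expect_gte(attained, oracle - 1e-3)
  }
})

test_that("optimizer degenerate and symmetric cases", {
  one <- toy_qual_table(matrix(c(1, 0, 1), 3, 1))
  d1 <- per_feature_dissimilarities(one, "hamming")
  f1 <- optimize_feature_weights(d1, 1)
  expect_equal(unname(f1$w), 1)
  # identical feature columns + s = sqrt(p): uniform weights by symmetry
  v <- matrix(c(1, 0, 1, 0), 4, 3)
  d3 <- per_feature_dissimilarities(toy_qual_table(v), "hamming")
  f3 <- optimize_feature_weights(d3, sqrt(3))
  expect_equal(unname(f3$w), rep(1 / sqrt(3), 3), tolerance = 1e-6)
  expect_error(
    optimize_feature_weights(
      per_feature_dissimilarities(toy_qual_table(matrix(1, 3, 2)),
                                  "hamming"), 1),
    "all-zero")
})

test_that("weight iterates respect the norm constraints and the objective rises", {
  set.seed(21)
  for (rep in 1:10) {
    n <- sample(4:8, 1); p <- sample(3:10, 1)
    tab <- toy_qual_table(matrix(rbinom(n * p, 1, 0.4), n, p))
    d <- per_feature_dissimilarities(tab, "hamming")
    if (all(d$contrib == 0)) next
    s <- runif(1, 1, sqrt(p))
    fit <- optimize_feature_weights(d, s)
    expect_equal(sqrt(sum(fit$w^2)), 1, tolerance = 1e-8)
    expect_lte(sum(fit$w), s + 1e-6)
    expect_true(all(fit$w >= 0))
    # nondecreasing objective trace (asserted internally too)
    expect_true(all(diff(fit$objective) >= -1e-8))
  }
})

test_that("weighted dissimilarity matches brute-force accumulation", {
  set.seed(9)
  tab <- toy_qual_table(matrix(rbinom(24, 1, 0.5), 4, 6))
  d <- per_feature_dissimilarities(tab, "hamming")
  p <- 6
  # uniform weights scale the plain Hamming matrix by 1/sqrt(p)
  wu <- rep(1 / sqrt(p), p)
  plain <- as.matrix(dist(tab$values, method = "manhattan"))
  expect_equal(unname(weighted_dissimilarity(d, wu)), unname(plain / sqrt(p)))
  # indicator weight: distance from that single feature
  w1 <- c(1, rep(0, p - 1))
  single <- as.matrix(dist(tab$values[, 1, drop = FALSE], "manhattan"))
  expect_equal(unname(weighted_dissimilarity(d, w1)), unname(single))
  # random weights against a double loop
  w <- runif(p); w <- w / sqrt(sum(w^2))
  got <- weighted_dissimilarity(d, w)
  for (i in 1:3) for (j in (i + 1):4) {
    acc <- 0
    for (k in 1:p) acc <- acc + w[k] * abs(tab$values[i, k] - tab$values[j, k])
    expect_equal(got[i, j], acc)
  }
  # quantitative: sqrt of the weighted squared contributions
  q <- toy_quant_table(matrix(c(30, 70, 50, 50, 100, 0), 3, 2, byrow = TRUE))
  dq <- per_feature_dissimilarities(q, "euclidean_sq")
  wq <- rep(1 / sqrt(2), 2)
  expect_equal(unname(weighted_dissimilarity(dq, wq)),
               unname(as.matrix(dist(q$values)) / 2^(1 / 4)),
               tolerance = 1e-12)
})

test_that("with s = sqrt(p) every feature is kept; uniform weights keep the ordering", {
  set.seed(31)
  v <- matrix(rbinom(50, 1, 0.5), 5, 10)
  tab <- toy_qual_table(v)
  d <- per_feature_dissimilarities(tab, "hamming")
  fit <- optimize_feature_weights(d, sqrt(10))
  varying <- compound_ids(tab)[colSums(d$contrib) > 0]
  expect_setequal(selected_features(fit), varying)
  # equal weights reproduce the unweighted pair ordering exactly
  got <- weighted_dissimilarity(d, rep(1 / sqrt(10), 10))
  plain <- as.matrix(dist(v, method = "manhattan"))
  ut <- upper.tri(plain)
  expect_equal(cor(got[ut], plain[ut], method = "spearman"), 1,
               tolerance = 1e-12)
})

test_that("complete linkage reproduces hand and naive-oracle results", {
  d <- matrix(c(0, 1, 4,
                1, 0, 3,
                4, 3, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  hc <- complete_linkage(d)
  expect_equal(hc$height, c(1, 4))
  # two samples: single merge at their distance
  d2 <- matrix(c(0, 2.5, 2.5, 0), 2, 2,
               dimnames = list(c("A", "B"), c("A", "B")))
  expect_equal(complete_linkage(d2)$height, 2.5)
  expect_error(complete_linkage(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
  # 6-point random matrix: cophenetic distances match a naive agglomerator
  set.seed(4)
  x <- matrix(rnorm(18), 6, 3, dimnames = list(paste0("s", 1:6), NULL))
  dm <- as.matrix(dist(x))
  hc6 <- complete_linkage(dm)
  expect_equal(unname(as.matrix(stats::cophenetic(hc6))[paste0("s", 1:6),
                                                        paste0("s", 1:6)]),
               naive_complete_cophenetic(dm))
  # Newick export carries all leaves
  nwk <- dendrogram_newick(hc6)
  expect_setequal(ape::read.tree(text = nwk)$tip.label, paste0("s", 1:6))
})

test_that("selected features are sorted by weight with deterministic ties", {
  w <- structure(list(w = c(f1 = 0.9, f2 = 0, f3 = 0.44), s = 2, delta = 0,
                      n_iter = 1, converged = TRUE, objective = 1),
                 class = "feature_weights")
  expect_equal(selected_features(w), c("f1", "f3"))
  w$w[] <- 0
  expect_equal(selected_features(w), character(0))
  w$w <- c(b = 0.5, a = 0.5, c = 0.1)
  expect_equal(selected_features(w), c("a", "b", "c"))
})

test_that("gap tuning finds clade structure and stays flat on noise", {
  fw <- simulate_clade_tree(clade_sizes = c(6, 6, 6), seed = 2)
  sim <- simulate_compound_matrix(fw, n_features = 200, n_informative = 10,
                                  target_sparsity = 0.90, seed = 2)
  d <- per_feature_dissimilarities(sim$qualitative, "hamming")
  sel <- select_tuning(d, n_perm = 5, seed = 2)
  w <- optimize_feature_weights(d, sel$s_best)
  hit <- sum(selected_features(w) %in% names(sim$truth$informative))
  expect_gte(hit, 8)
  # single candidate passes through
  expect_equal(select_tuning(d, candidate_s = 2)$s_best, 2)
  # pure-noise data: the gap decays towards Monte-Carlo noise at larger s,
  # where genuine multi-feature structure keeps it elevated (a positive
  # gap at small s remains even for iid data, from row-density variation
  # that column permutation destroys)
  sim0 <- simulate_compound_matrix(fw, n_features = 200, n_informative = 0,
                                   target_sparsity = 0.90, seed = 3)
  d0 <- per_feature_dissimilarities(sim0$qualitative, "hamming")
  g0 <- select_tuning(d0, n_perm = 8, seed = 3)$gap_table
  g1 <- select_tuning(d, n_perm = 8, seed = 3)$gap_table
  tail_s <- g0$s >= stats::median(g0$s)
  expect_lt(mean(g0$gap[tail_s]), mean(g1$gap[tail_s]) / 1.5)
  # and at the largest s the noise gap sits within Monte-Carlo error of 0
  last <- nrow(g0)
  expect_lt(abs(g0$gap[last]), 3 * g0$perm_sd[last])
})
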
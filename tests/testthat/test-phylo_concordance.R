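test_that("clade frameworks validate tips, clades and mappings", {
  fw <- tiny_framework()
  expect_equal(length(enumerate_bijective_maps(fw)), 1)
  # clade table referencing an unknown tip
  bad <- data.frame(tip_id = c("tA", "tB", "tC", "tZ"),
                    clade = c("X", "X", "Y", "Y"))
  expect_error(clade_framework(fw$tree, bad, fw$mapping), "tZ")
  # tip without a clade assignment
  expect_error(clade_framework(fw$tree, fw$clades[-1, ], fw$mapping),
               "without clade")
  # file round-trip
  td <- tempfile(); dir.create(td)
  ape::write.tree(fw$tree, file.path(td, "t.nwk"))
  write.table(fw$clades, file.path(td, "c.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(fw$mapping, file.path(td, "m.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  fw2 <- read_clade_framework(file.path(td, "t.nwk"), file.path(td, "c.tsv"),
                              file.path(td, "m.tsv"))
  expect_equal(sort(fw2$tree$tip.label), sort(fw$tree$tip.label))
})

test_that("bijective-map enumeration matches product rule and exhaustive search", {
  # disjoint candidate groups of sizes 3, 3, 2 -> 18 maps
  fw <- default_framework(seed = 1)
  maps <- enumerate_bijective_maps(fw)
  expect_equal(length(maps), 18)
  # every map is injective and assigns every tip
  for (m in maps[c(1, 9, 18)]) {
    expect_equal(sort(names(m)), sort(fw$tree$tip.label))
    expect_false(anyDuplicated(m) > 0)
  }
  expect_false(any(duplicated(lapply(maps, unname))))
  # two tips sharing two candidates: 2 injective maps, not 4
  tree <- ape::read.tree(text = "(tA:1,tB:1);")
  cl <- data.frame(tip_id = c("tA", "tB"), clade = c("X", "Y"))
  mp <- data.frame(sample_id = c("s1", "s2", "s1", "s2"),
                   tip_id = c("tA", "tA", "tB", "tB"))
  expect_equal(length(enumerate_bijective_maps(clade_framework(tree, cl, mp))),
               2)
  # random many-to-many relations against the Cartesian-filter oracle
  set.seed(12)
  for (rep in 1:6) {
    n_tips <- sample(3:6, 1)
    tips <- paste0("t", seq_len(n_tips))
    tr <- ape::read.tree(text = paste0(
      "(", paste(paste0(tips, ":1"), collapse = ","), ");"))
    smp <- paste0("s", seq_len(n_tips + 2))
    mp <- do.call(rbind, lapply(tips, function(t)
      data.frame(sample_id = sample(smp, sample(1:3, 1)), tip_id = t)))
    cl <- data.frame(tip_id = tips,
                     clade = rep(c("X", "Y"), length.out = n_tips))
    fwr <- clade_framework(tr, cl, mp)
    cand <- lapply(tips, function(t)
      sort(fwr$mapping$sample_id[fwr$mapping$tip_id == t]))
    expect_equal(length(enumerate_bijective_maps(fwr)),
                 enum_injective_count(cand))
  }
  # tip with no candidate errors
  cl_ab <- data.frame(tip_id = c("tA", "tB"), clade = c("X", "Y"))
  mp_empty <- data.frame(sample_id = "s1", tip_id = "tA")
  expect_error(
    enumerate_bijective_maps(clade_framework(tree, cl_ab, mp_empty)),
    "no candidate.*tB")
})

test_that("species-level distances restrict to the selected features", {
  tab <- toy_qual_table(matrix(c(1, 0, 1,
                                 1, 1, 0,
                                 0, 0, 0), 3, 3, byrow = TRUE))
  sld <- species_level_distances(tab, c("c1", "c2", "c3"), "hamming")
  expect_equal(unname(sld),
               matrix(c(0, 2, 2, 2, 0, 2, 2, 2, 0), 3, 3))
  sld1 <- species_level_distances(tab, "c1", "hamming")
  expect_equal(unname(sld1[1, ]), c(0, 0, 1))
  q <- toy_quant_table(matrix(c(60, 40, 100, 0), 2, 2, byrow = TRUE))
  expect_equal(species_level_distances(q, c("c1", "c2"), "euclidean")[1, 2],
               sqrt(40^2 + 40^2))
  expect_error(species_level_distances(tab, "nope", "hamming"), "nope")
})

test_that("within- and between-clade distances average the right pairs", {
  sld <- matrix(0, 4, 4, dimnames = list(paste0("s", 1:4), paste0("s", 1:4)))
  sld["s1", "s2"] <- sld["s2", "s1"] <- 7
  expect_equal(within_clade_distance(sld, c("s1", "s2")), 7)
  sld3 <- matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3, 3,
                 dimnames = list(paste0("s", 1:3), paste0("s", 1:3)))
  expect_equal(within_clade_distance(sld3, paste0("s", 1:3)), 2)
  expect_true(is.na(within_clade_distance(sld, "s1")))
  expect_error(within_clade_distance(sld, character(0)), "empty")
  # BCD
  expect_equal(between_clade_distance(sld3, "s1", "s2"), 1)
  m <- matrix(c(0, 0, 1, 2,
                0, 0, 3, 4,
                1, 3, 0, 0,
                2, 4, 0, 0), 4, 4,
              dimnames = list(paste0("s", 1:4), paste0("s", 1:4)))
  expect_equal(between_clade_distance(m, c("s1", "s2"), c("s3", "s4")), 2.5)
  expect_error(between_clade_distance(m, c("s1", "s2"), c("s2", "s3")),
               "overlap")
})

test_that("one-sided rank-sum p-values agree with full enumeration", {
  expect_equal(wilcoxon_less(c(1, 2), c(3, 4)), 1 / 6)
  expect_equal(wilcoxon_less(1, 2), 0.5)
  expect_gte(wilcoxon_less(c(1, 2, 3), c(1, 2, 3)), 0.5)
  set.seed(17)
  for (rep in 1:20) {
    nx <- sample(1:4, 1)
    ny <- sample(1:4, 1)
    vals <- sample(seq(0.1, 10, by = 0.1), nx + ny) # tie-free
    x <- vals[seq_len(nx)]
    y <- vals[-seq_len(nx)]
    expect_equal(wilcoxon_less(x, y), enum_wilcoxon_less(x, y))
  }
  expect_error(wilcoxon_less(NA_real_, 1), "empty")
})

test_that("averaging over maps equals recomputation from each map's SLD", {
  set.seed(8)
  fw <- simulate_clade_tree(clade_sizes = c(3, 3, 2),
                            candidate_group_sizes = c(2, 2), seed = 8)
  sim <- simulate_compound_matrix(fw, n_features = 40, n_informative = 4,
                                  target_sparsity = 0.7, seed = 8)
  feats <- compound_ids(sim$qualitative)
  summ <- average_over_maps(fw, sim$qualitative, feats, "hamming")
  expect_equal(summ$n_maps, 4)
  maps <- enumerate_bijective_maps(fw)
  clade_of <- setNames(fw$clades$clade, fw$clades$tip_id)
  # independent recomputation of aWCD and aSLD
  tips <- fw$tree$tip.label
  awcd <- 0; asld <- 0
  for (m in maps) {
    sld <- species_level_distances(sim$qualitative, feats,
                                   "hamming")[m[tips], m[tips]]
    asld <- asld + sld
    awcd <- awcd + sapply(sort(unique(clade_of)), function(cl) {
      mem <- which(clade_of[tips] == cl)
      if (length(mem) < 2) return(NA_real_)
      mean(sld[mem, mem][upper.tri(sld[mem, mem])])
    })
  }
  expect_equal(unname(summ$aWCD[sort(names(summ$aWCD))]),
               unname(awcd[sort(names(awcd))] / 4))
  expect_equal(unname(summ$aSLD), unname(asld / 4))
  # single map: averages equal the per-map values
  fw1 <- simulate_clade_tree(clade_sizes = c(3, 3), seed = 9)
  sim1 <- simulate_compound_matrix(fw1, n_features = 30, n_informative = 2,
                                   target_sparsity = 0.7, seed = 9)
  s1 <- average_over_maps(fw1, sim1$qualitative,
                          compound_ids(sim1$qualitative), "hamming")
  expect_equal(s1$n_maps, 1)
  expect_equal(unname(s1$aWCD), unname(s1$wcd[1, ]))
  expect_equal(unname(s1$aBCD), unname(s1$bcd[1, ]))
})

test_that("per-map distances satisfy the pair-count conservation identity", {
  set.seed(13)
  fw <- default_framework(seed = 13)
  sim <- simulate_compound_matrix(fw, n_features = 80, n_informative = 8,
                                  target_sparsity = 0.85, seed = 13)
  summ <- average_over_maps(fw, sim$qualitative,
                            compound_ids(sim$qualitative), "hamming")
  tips <- fw$tree$tip.label
  sizes <- table(summ$clade_of_tip)[colnames(summ$wcd)]
  n_within <- sizes * (sizes - 1) / 2
  pair_sizes <- utils::combn(colnames(summ$wcd), 2)
  n_between <- apply(pair_sizes, 2, function(pr) sizes[pr[1]] * sizes[pr[2]])
  n_tot <- length(tips) * (length(tips) - 1) / 2
  for (m in seq_len(summ$n_maps)) {
    sld <- species_level_distances(
      sim$qualitative, compound_ids(sim$qualitative),
      "hamming")[summ$maps[[m]][tips], summ$maps[[m]][tips]]
    lhs <- mean(sld[upper.tri(sld)])
    w <- summ$wcd[m, ]
    rhs <- (sum(n_within * ifelse(is.na(w), 0, w)) +
              sum(n_between * summ$bcd[m, ])) / n_tot
    expect_equal(lhs, rhs, tolerance = 1e-9)
  }
})

test_that("the best map maximizes mean(BCD) - mean(WCD)", {
  # toy: clade X tips get either a conforming sample or an outlier
  tree <- ape::read.tree(text = "((tA:1,tB:1):1,(tC:1,tD:1):1);")
  cl <- data.frame(tip_id = c("tA", "tB", "tC", "tD"),
                   clade = c("X", "X", "Y", "Y"))
  # tB can take s2 (like s1) or s5 (outlier like clade Y)
  mp <- data.frame(sample_id = c("s1", "s2", "s5", "s3", "s4"),
                   tip_id = c("tA", "tB", "tB", "tC", "tD"))
  v <- rbind(s1 = c(1, 1, 0, 0),
             s2 = c(1, 1, 0, 0),
             s5 = c(0, 0, 1, 1),
             s3 = c(0, 0, 1, 1),
             s4 = c(0, 0, 1, 1))
  colnames(v) <- paste0("c", 1:4)
  tab <- compound_table(v, "qualitative")
  fw <- clade_framework(tree, cl, mp)
  summ <- average_over_maps(fw, tab, colnames(v), "hamming")
  expect_equal(summ$n_maps, 2)
  # direct evaluation: assigning the conforming s2 keeps WCD low
  expect_equal(unname(summ$best_map[["tB"]]), "s2")
  # tie rule: identical samples -> first enumerated map wins
  v2 <- v; v2[] <- rep(v["s1", ], each = 5)
  tab2 <- compound_table(v2, "qualitative")
  s2 <- average_over_maps(fw, tab2, colnames(v), "hamming")
  expect_equal(s2$best_map_index, 1)
})

test_that("concordance reports count aWCDs under the background summaries", {
  summ <- structure(list(
    aWCD = c(A = 1, B = 2), aBCD = c(3, 4, 5),
    aSLD = matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3),
    wilcoxon_p = 0.1, clade_of_tip = c(t1 = "A", t2 = "A", t3 = "B")),
    class = "distance_summary")
  rep_ <- concordance_report(summ)
  expect_equal(rep_$below_aBCD_mean, 2)   # both aWCDs < 4
  expect_equal(rep_$below_aBCD_median, 2) # both < 4
  expect_equal(rep_$below_aSLD_mean, 2)
  expect_equal(rep_$below_aSLD_median, 2)
  summ$aWCD <- c(A = 9, B = 9)
  expect_equal(concordance_report(summ)$below_aBCD_mean, 0)
})

test_that("tree-ordered export keeps tip order and sidelines unmapped samples", {
  fw <- tiny_framework()
  v <- matrix(rbinom(20, 1, 0.5), 5, 4,
              dimnames = list(paste0("s", 1:5), paste0("c", 1:4)))
  tab <- compound_table(v, "qualitative")
  fw$mapping <- rbind(fw$mapping,
                      data.frame(sample_id = "s5", tip_id = "tD"))
  maps <- enumerate_bijective_maps(fw)
  out <- export_tree_ordered_matrix(fw, maps[[1]], tab, c("c1", "c3"))
  expect_equal(colnames(out$matrix), c("c1", "c3"))
  expect_equal(rownames(out$matrix),
               paste(fw$tree$tip.label, maps[[1]][fw$tree$tip.label],
                     sep = ":"))
  expect_equal(out$unmapped, "s5")
})
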
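#' Run the full profiling pipeline on simulated or supplied inputs
#'
#' Sequences the stages: synthetic-data generation (or reading of supplied
#' peak tables), compound-table assembly, sparse feature-selected
#' clustering (qualitative and quantitative), phylogeny-chemistry
#' concordance, unique-compound cataloguing and coniine SIM detection.
#' Every output is a TSV/JSON file under `config$out_dir`, and a manifest
#' with the package version, seeds and file hashes is written last, so a
#' rerun with the same config is byte-reproducible.
#'
#' @param config a list (or path to a YAML/JSON file) with elements:
#'   `out_dir` (required); `seed` (default 1); `stages` (character subset
#'   of `simulate`, `profile`, `cluster`, `concordance`, `catalog`,
#'   `coniine`; default all); `s` (L1 bound or `"auto"`); `n_perm`
#'   (permutations for tuning, default 10); `match_cutoff` (default 70);
#'   `rt_tol` (default 0.02); `sim_amounts` (spike levels for the SIM
#'   stage).
#' @return The manifest list, invisibly.
#' @export
run_all <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- if (grepl("\\.ya?ml$", config)) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("yaml package needed to read YAML configs")
      yaml::read_yaml(config)
    } else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config), !is.null(config$out_dir))
  cfg <- utils::modifyList(
    list(seed = 1L, stages = c("simulate", "profile", "cluster",
                               "concordance", "catalog", "coniine"),
         s = "auto", n_perm = 10, match_cutoff = 70, rt_tol = 0.02,
         n_features = 560, n_informative = 20,
         sim_amounts = c(0, 1, 5, 10, 20)),
    config)
  out <- cfg$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  stage_log <- list()
  run_stage <- function(name, fn) {
    if (!name %in% cfg$stages) return(invisible(NULL))
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fn(), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    stage_log[[name]] <<- round(proc.time()[["elapsed"]] - t0, 2)
    res
  }

  fw <- NULL; tables <- NULL; records <- NULL
  run_stage("simulate", function() {
    fw <<- simulate_clade_tree(candidate_group_sizes = c(3, 3, 2),
                               seed = cfg$seed)
    sim <- simulate_compound_matrix(fw, n_features = cfg$n_features,
                                    n_informative = cfg$n_informative,
                                    seed = cfg$seed)
    tables <<- sim
    records <<- simulate_peak_records(sim$quantitative, seed = cfg$seed)
    ape::write.tree(fw$tree, file.path(out, "tree.nwk"))
    utils::write.table(fw$clades, file.path(out, "clades.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(fw$mapping, file.path(out, "mapping.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(records, file.path(out, "peak_records.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    truth_out <- tables$truth
    truth_out$informative <- as.list(truth_out$informative)
    truth_out$sample_clade <- as.list(truth_out$sample_clade)
    jsonlite::write_json(truth_out, file.path(out, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  })

  run_stage("profile", function() {
    rec <- read_peak_records(file.path(out, "peak_records.tsv"))
    rec <- filter_identifications(rec, cfg$match_cutoff)
    rec <- collapse_alkanes(rec, cfg$rt_tol)
    meta <- tables$quantitative$meta
    quant <- build_compound_table(rec, meta)
    qual <- binarize(quant)
    tables$rebuilt_quant <<- quant
    tables$rebuilt_qual <<- qual
    write_compound_table(quant, file.path(out, "matrix_quantitative.tsv"))
    write_compound_table(qual, file.path(out, "matrix_qualitative.tsv"))
  })

  weights <- list()
  run_stage("cluster", function() {
    for (mode in c("qualitative", "quantitative")) {
      tab <- tables[[mode]]
      metric <- if (mode == "qualitative") "hamming" else "euclidean_sq"
      decomp <- per_feature_dissimilarities(tab, metric)
      s <- if (identical(cfg$s, "auto"))
        select_tuning(decomp, n_perm = cfg$n_perm, seed = cfg$seed)$s_best
      else cfg$s
      w <- optimize_feature_weights(decomp, s)
      weights[[mode]] <<- w
      dmat <- weighted_dissimilarity(decomp, w)
      hc <- complete_linkage(dmat)
      utils::write.table(
        data.frame(compound = names(w$w), weight = w$w),
        file.path(out, paste0("weights_", mode, ".tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(dmat,
                         file.path(out, paste0("distance_", mode, ".tsv")),
                         sep = "\t", quote = FALSE)
      dendrogram_newick(hc, file.path(out, paste0("dendrogram_", mode,
                                                  ".nwk")))
    }
  })

  run_stage("concordance", function() {
    for (mode in c("qualitative", "quantitative")) {
      metric <- if (mode == "qualitative") "hamming" else "euclidean"
      feats <- selected_features(weights[[mode]])
      summ <- average_over_maps(fw, tables[[mode]], feats, metric)
      rep_ <- concordance_report(summ)
      rep_$per_clade <- NULL
      rep_$n_maps <- summ$n_maps
      rep_$best_map = as.list(summ$best_map)
      jsonlite::write_json(rep_,
                           file.path(out, paste0("concordance_", mode,
                                                 ".json")),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      export_tree_ordered_matrix(fw, summ$best_map, tables[[mode]], feats,
                                 file.path(out, paste0("heatmap_", mode,
                                                       ".tsv")))
    }
  })

  run_stage("catalog", function() {
    qual <- tables$qualitative
    uniq <- unique_compounds(qual)
    flags <- flag_floral(compound_ids(qual), floral_reference())
    summ <- summarize_unique(uniq, flags)
    utils::write.table(summ, file.path(out, "unique_compounds.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(pairwise_unique_matrix(qual),
                       file.path(out, "pairwise_unique.tsv"),
                       sep = "\t", quote = FALSE)
  })

  run_stage("coniine", function() {
    ref <- coniine_reference()
    calls <- lapply(seq_along(cfg$sim_amounts), function(i) {
      tr <- simulate_sim_trace(cfg$sim_amounts[i], ref,
                               seed = cfg$seed + i)
      call <- detect_coniine(extract_window(tr, ref), ref)
      data.frame(amount = cfg$sim_amounts[i], verdict = call$verdict,
                 qualifiers = paste(call$qualifiers, collapse = ","))
    })
    utils::write.table(do.call(rbind, calls),
                       file.path(out, "coniine_calls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  })

  files <- setdiff(list.files(out), "manifest.json")
  manifest <- list(
    package_version = as.character(utils::packageVersion("sarrachem")),
    seed = cfg$seed,
    stages = cfg$stages,
    elapsed_s = stage_log,
    md5 = as.list(tools::md5sum(file.path(out, files))))
  names(manifest$md5) <- files
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
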
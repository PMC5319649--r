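#!/usr/bin/env Rscript
# Does the chemistry conform to the clade-level classification? Enumerate
# all bijective sample-to-tree maps, average species-level distances into
# aWCD/aBCD/aSLD, test aWCD < aBCD one-sidedly, and export the
# heat-map-ready matrix under the best map. Run on the simulated clade
# markers (the features the generator planted) and, for comparison, on
# the features the sparse clustering selected.
# run from the repository root: Rscript analysis/04_phylo_concordance.R
source("analysis/00_common.R")

meta <- read_sample_meta(file.path(RESULTS, "sample_meta.tsv"))
truth <- jsonlite::read_json(file.path(RESULTS, "truth.json"),
                             simplifyVector = TRUE)
fw <- read_clade_framework(file.path(RESULTS, "tree.nwk"),
                           file.path(RESULTS, "clades.tsv"),
                           file.path(RESULTS, "mapping.tsv"))
qual <- read_compound_table(file.path(RESULTS, "matrix_qualitative.tsv"),
                            meta = meta)

weights <- read.delim(file.path(RESULTS, "weights_qualitative.tsv"))
selected <- weights$compound[weights$weight > 1e-8]
feature_sets <- list(
  simulated_markers = intersect(names(truth$informative),
                                compound_ids(qual)),
  sparse_selected = intersect(selected, compound_ids(qual)))

for (nm in names(feature_sets)) {
  summ <- average_over_maps(fw, qual, feature_sets[[nm]], "hamming")
  rep_ <- concordance_report(summ)
  cat(sprintf(
    "%s (%d features): %d maps; %d/%d aWCDs below mean(aSLD); Wilcoxon p = %.3g\n",
    nm, length(feature_sets[[nm]]), summ$n_maps,
    rep_$below_aSLD_mean, rep_$n_clades_tested, rep_$wilcoxon_p))
  out <- rep_
  out$per_clade <- NULL
  out$n_maps <- summ$n_maps
  out$aWCD <- as.list(summ$aWCD)
  out$aBCD <- as.list(summ$aBCD)
  out$best_map <- as.list(summ$best_map)
  jsonlite::write_json(out,
                       file.path(RESULTS, paste0("concordance_", nm,
                                                 ".json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write.table(summ$aSLD, file.path(RESULTS, paste0("asld_", nm, ".tsv")),
              sep = "\t", quote = FALSE)
  export_tree_ordered_matrix(fw, summ$best_map, qual, feature_sets[[nm]],
                             file.path(RESULTS, paste0("heatmap_", nm,
                                                       ".tsv")))
}
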
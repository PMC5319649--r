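#!/usr/bin/env Rscript
# Generate the study-shaped synthetic inputs: phylogeny + clades +
# sample-to-tip mapping, compound matrices with known informative
# features, raw peak records, and a coniine SIM spike series.
# run from the repository root: Rscript analysis/01_simulate.R
source("analysis/00_common.R")

fw <- study_framework()
sim <- study_tables(fw)

ape::write.tree(fw$tree, file.path(RESULTS, "tree.nwk"))
write.table(fw$clades, file.path(RESULTS, "clades.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(fw$mapping, file.path(RESULTS, "mapping.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

rec <- simulate_peak_records(sim$quantitative, seed = SEED)
write.table(rec, file.path(RESULTS, "peak_records.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(sim$quantitative$meta, file.path(RESULTS, "sample_meta.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
truth_out <- sim$truth
truth_out$informative <- as.list(truth_out$informative)
truth_out$sample_clade <- as.list(truth_out$sample_clade)
jsonlite::write_json(truth_out, file.path(RESULTS, "truth.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)

for (amt in c(0, 1, 5, 10, 20)) {
  tr <- simulate_sim_trace(amt, seed = SEED + amt)
  write.csv(tr, file.path(RESULTS, sprintf("sim_trace_%02d.csv", amt)),
            row.names = FALSE)
}

cat(sprintf(
  "simulated %d samples x %d compounds (%.2f%% zeros), %d tree tips, %d peak records\n",
  nrow(sim$qualitative$values), ncol(sim$qualitative$values),
  100 * sparsity(sim$qualitative), length(fw$tree$tip.label), nrow(rec)))
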
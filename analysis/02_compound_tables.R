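#!/usr/bin/env Rscript
# Rebuild the compound matrices from the raw peak records the way an
# instrument export would be processed: 70% identification cutoff,
# n-alkane collapsing of co-eluting hydrocarbons, relative peak
# abundances, then presence/absence coding.
# run from the repository root: Rscript analysis/02_compound_tables.R
source("analysis/00_common.R")

rec <- read_peak_records(file.path(RESULTS, "peak_records.tsv"))
meta <- read_sample_meta(file.path(RESULTS, "sample_meta.tsv"))

rec <- filter_identifications(rec, cutoff = 70)
rec <- collapse_alkanes(rec, rt_tol = 0.02)
quant <- build_compound_table(rec, meta)
qual <- binarize(quant)

write_compound_table(quant, file.path(RESULTS, "matrix_quantitative.tsv"))
write_compound_table(qual, file.path(RESULTS, "matrix_qualitative.tsv"))

counts <- compounds_per_sample(qual)
cat(sprintf(
  "compound table: %d samples x %d compounds, %.2f%% zeros\n",
  nrow(qual$values), ncol(qual$values), 100 * sparsity(qual)))
cat(sprintf(
  "compounds per sample: mean %.1f, range %d-%d\n",
  mean(counts), min(counts), max(counts)))
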
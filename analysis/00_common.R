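# Shared settings for the analysis scripts. Each numbered script can be
# run on its own (earlier outputs are regenerated deterministically from
# the same seed) but the natural order is 01 -> 06.
library(sarrachem)

SEED <- as.integer(Sys.getenv("ANALYSIS_SEED", "1"))
RESULTS <- "results"
dir.create(RESULTS, showWarnings = FALSE, recursive = TRUE)

# study-shaped simulation: 48 accessions in 9 clades, 43 tree tips,
# candidate groups (3, 3, 2) => 18 bijective sample-to-tree maps,
# 560 compounds of which 20 carry clade signal, ~91.4% zeros
study_framework <- function() {
  simulate_clade_tree(candidate_group_sizes = c(3, 3, 2), seed = SEED)
}
study_tables <- function(fw) simulate_compound_matrix(fw, seed = SEED)
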
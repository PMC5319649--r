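# sarrachem

Metabolite profiling and chemotaxonomic concordance for the carnivorous
pitcher plants *Darlingtonia* and *Sarracenia*.

Sarraceniaceae accessions carry hundreds of GC-MS-detectable compounds,
almost all of them absent from almost all samples (>91% zeros), with huge
chemical diversity between species — conditions under which naive
clustering of chemistry does not recover taxonomy. This package provides
the analysis chain for asking a sharper question: *given* an accession
phylogeny, does the chemistry conform to the clade-level classification?
It also covers the descriptive cataloguing around that question
(compounds per accession, accession-unique compounds, floral-scent
flagging) and the targeted confirmation of the alkaloid coniine from
selected-ion-monitoring (SIM) traces.

## What it computes

* **Compound tables** from per-sample peak identifications: 70%
  library-match cutoff, collapsing of co-eluting inconsistently
  identified hydrocarbons to canonical n-alkanes, relative peak
  abundances (rows sum to 100%), and presence/absence coding.
* **Sparse feature-selected hierarchical clustering**: per-feature
  dissimilarity contributions (Hamming for 0/1 data, squared differences
  for percentages) reweighted by a nonnegative weight vector solving

  max_{w,u} Σ_j w_j (d_jᵀu)  s.t. ‖u‖₂ ≤ 1, ‖w‖₂ ≤ 1, ‖w‖₁ ≤ s, w ≥ 0,

  the lasso bound `s` tuned by a permutation gap statistic, then complete
  linkage on the reweighted matrix.
* **Phylogeny–chemistry concordance**: samples map many-to-many to the
  tips of an accession tree; all bijective maps are enumerated; per map,
  species-level distances (SLD) give within-clade (WCD) and between-clade
  (BCD) averages, which are averaged over maps into aWCD/aBCD/aSLD and
  compared by a one-sided Wilcoxon rank-sum test of aWCD < aBCD. The map
  maximizing mean(BCD) − mean(WCD) orders the heat-map-ready export.
* **Unique-compound catalogue**: per-sample counts, compounds unique to a
  single accession, pairwise unique compounds (the two directions sum to
  the Hamming distance), floral-scent flags from a curated editable list.
* **Coniine SIM detection**: ion intensities summed in the 6.33 ± 0.01 min
  window; diagnostic ions m/z 80, 84 (base peak), 126 (molecular ion);
  qualifier codes for correct proportions / anomalous ratios / low
  intensity; verdicts absent / ion84-only / trace / detected; species
  summaries grouping infraspecific taxa under the binomial.
* **Synthetic data** with recoverable ground truth emulating the study
  shape: 48 samples in 9 clades, 560 compounds (20 clade markers,
  p_in = 0.9, p_out = 0.05), ~91.4% zeros, 43-tip tree with 18 bijective
  maps, SIM spike series with the detection limit at amount 1.

See `vignettes/chemotaxonomic-profiling.Rmd` for the methods account.

## Worked example

The analysis scripts run the whole chain on the study-shaped simulation
(from the repository root; `ANALYSIS_SEED` defaults to 1):

```sh
Rscript analysis/01_simulate.R          # inputs under results/
Rscript analysis/02_compound_tables.R
Rscript analysis/03_sparse_clustering.R
Rscript analysis/04_phylo_concordance.R
Rscript analysis/05_unique_compounds.R
Rscript analysis/06_coniine_screen.R
```

which prints, stage by stage:

```
simulated 48 samples x 560 compounds (91.39% zeros), 43 tree tips, 2315 peak records
compound table: 48 samples x 555 compounds, 91.31% zeros
compounds per sample: mean 48.2, range 33-62
qualitative: s = 1.62 selects 3 compounds (3 of 20 simulated clade markers)
quantitative: s = 1.20 selects 35 compounds (2 of 20 simulated clade markers)
simulated_markers (20 features): 18 maps; 7/8 aWCDs below mean(aSLD); Wilcoxon p = 0.000175
sparse_selected (3 features): 18 maps; 8/8 aWCDs below mean(aSLD); Wilcoxon p = 0.111
simulated data: mean 0.7 unique compounds per sample (0.0 floral)
published accession counts: lid unique 6.4, lid floral 1.0, pitcher unique 6.6, pitcher floral 1.1
spike series calls:
 amount  verdict       qualifiers
      0   absent
      1    trace G_proportions_ok
      5 detected G_proportions_ok
     10 detected G_proportions_ok
     20 detected G_proportions_ok
published SIM screen: coniine-positive in 8 Sarracenia species
```

Reading the numbers: the simulated matrix reproduces the study's shape
(~48 compounds per sample, ~91.4% zeros). Given the 20 planted clade
markers, the concordance test is decisive (p ≈ 1.7e-4, with 7 of the 8
testable aWCDs below the mean background distance); given only the
features the sparse clustering selects on its own, it is not — on data
this sparse the selector recovers markers of the large clades only, a
limitation measured and discussed in the vignette. The spike series
calls the amount-1 spike `trace` (the calibrated detection limit) and
everything above it `detected` with the correct-proportions qualifier;
the published screening marks, grouped by species, give eight
coniine-positive *Sarracenia* species.

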
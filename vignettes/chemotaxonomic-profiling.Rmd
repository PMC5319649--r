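---
title: "Metabolite profiling and phylogeny-chemistry concordance: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metabolite profiling and phylogeny-chemistry concordance: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sarrachem)
```

## Scope and shape

`sarrachem` re-implements, as tested reusable code, a GC-MS metabolite
profiling analysis of the carnivorous pitcher plants *Darlingtonia* and
*Sarracenia*: compound-table construction from peak identifications,
sparse feature-selected hierarchical clustering, a phylogeny–chemistry
concordance test, unique-compound cataloguing, and rule-based SIM
confirmation of the alkaloid coniine. The repository is organised as an
analysis workflow — numbered drivers under `analysis/` narrate the steps
and write tables under `results/` — while every computation lives in the
package so the tests and the acceptance script can call it directly. No
instrument data ship with the package; a synthetic-data generator with
recoverable ground truth stands in for the raw chromatograms.

## From peak lists to compound tables

Instrument software integrates peaks and proposes library
identifications; this package starts from that peak list
(`sample_id`, retention time, identification, match %, area).
Processing rules:

* **Identification cutoff** — identifications below a 70% library match
  are discarded (`filter_identifications()`); the threshold is the
  conventional screening cutoff and is configurable.
* **n-alkane collapsing** — straight-chain hydrocarbons co-eluting at the
  same retention time but identified as *different* hydrocarbons in
  different samples are not trustworthy at the isomer level; all such
  peaks are re-labelled `n-alkane@<rt>` (`collapse_alkanes()`). The rt
  tolerance defaults to 0.02 min: the coniine retention stability
  observed on the reference method is ±0.01 min, doubled to allow for
  cross-sample drift. The canonical label uses the earliest-eluting
  member's rt (2 decimals) so the grouping is deterministic.
* **Relative abundances** — each cell of the quantitative table is the
  compound's percentage of the sample's total peak area; rows sum to 100
  unless a sample contains no detectable compound at all (an observed,
  legitimate outcome — such samples keep an all-zero row).
  Duplicate peaks of one compound within a sample are summed: relative
  abundance is a per-compound, not per-peak, quantity.
* **Presence/absence coding** — `binarize()` maps any positive share to
  1. Compounds absent from every sample after filtering are dropped;
  zero-variance columns carry no clustering information.

## Sparse feature-selected clustering

The data are extremely sparse (>91% zeros) and high-dimensional (hundreds
of compounds over ~48 samples), so only a small subset of compounds can be
expected to drive any clustering. The package implements the
lasso-penalised feature selection for dissimilarity-based clustering:
decompose each pairwise dissimilarity into per-feature contributions
$d_{(i,i'),j}$ (Hamming indicators for presence/absence data, squared
differences for percentages), then solve

$$\max_{w, u}\; \sum_j w_j\, (d_j^\top u)
\quad\text{s.t.}\quad \|u\|_2 \le 1,\; \|w\|_2 \le 1,\; \|w\|_1 \le s,\; w \ge 0,$$

by alternating maximization: $u \propto Dw$, then a soft-thresholded,
renormalised update of $w$ whose threshold is found by bisection so the
L1 constraint binds. The reweighted dissimilarity
$\sum_j w_j d_{(i,i'),j}$ (square-rooted in the Euclidean case, so uniform
weights recover a matrix proportional to the plain distance) is clustered
with complete linkage.

Numerical choices worth knowing:

* **Tied scores.** On binary data the per-feature scores $a_j = d_j^\top u$
  are often exactly tied. When the maximum is tied, $\|w(\Delta)\|_1$
  jumps discontinuously from $\sqrt{m}$ ($m$ = tie count) past $s$ and no
  threshold binds the constraint; the optimizer then uses the closed-form
  feasible optimum supported on the tied set, which attains the upper
  bound $\max(a)\cdot s$ of the linear subproblem exactly.
* **Two deterministic starts.** Alternating maximization can stall in a
  local optimum (a duplicated pair of weak features can beat one strong
  feature from a uniform start). The optimizer therefore runs from
  uniform weights *and* from a one-hot start on the feature with the
  largest contribution norm, and keeps the better final objective. The
  objective is asserted nondecreasing within each run.
* **Convergence** — max absolute weight change below 1e-6, at most 100
  iterations per start; bisection tolerance 1e-12 on the threshold.
* **Tuning $s$** — a permutation gap statistic: the objective on the real
  decomposition minus its mean over decompositions whose feature columns
  were independently permuted, over 11 log-spaced candidates in
  $[1.2, \sqrt{p}]$; ties go to the smaller (sparser) $s$. Note that even
  iid data show a small positive gap at small $s$, because column
  permutation also destroys row-density variation; the signature of real
  structure is a gap that stays elevated at larger $s$.
* **Linkage ties** — `complete_linkage()` delegates to `stats::hclust`,
  whose deterministic tie-handling is inherited. Dendrograms feed leaf
  ordering and exports only; none of the concordance statistics depend on
  them.

## Concordance with the clade-level classification

Accessions map to the tips of an externally supplied accession phylogeny
many-to-many (several profiled samples can be plausible matches for one
tree accession). All bijective sample-to-tip maps compatible with the
relation are enumerated exhaustively (depth-first, lexicographic, capped
at 10,000 — the procedure is *defined* by exhaustive enumeration, so an
oversized relation is an input error rather than something to
approximate). For each map, species-level distances (SLD) on the selected
features yield per-clade within-clade distances (WCD, the mean over
member pairs) and per-clade-pair between-clade distances (BCD, the mean
over cross pairs); averaging elementwise over maps gives aWCD, aBCD and
the tip-indexed aSLD. If chemistry conforms to the classification, aWCDs
should sit low in the aBCD and aSLD distributions; this is tested with a
one-sided Wilcoxon rank-sum test (exact when the combined count is ≤ 20
with no ties, normal approximation with tie correction otherwise — at
clade scale, 9 + 36 values, the approximation branch applies).

Details:

* A singleton clade has no within pairs; its WCD is undefined (`NA`) and
  excluded from the rank test rather than imputed.
* The aSLD background uses **all** off-diagonal entries, within-clade
  pairs included.
* For visual export, the *best* map — the one maximizing
  $\text{mean(BCD)} - \text{mean(WCD)}$, ties to the first enumerated —
  orders the selected-feature submatrix by tree tip order; samples the
  best map leaves unassigned are listed in a sidecar instead.
* Every map satisfies the conservation identity
  (mean off-diagonal SLD = pair-count-weighted combination of WCDs and
  BCDs), which the tests assert to 1e-9.
* No multiple-testing correction is applied across tissues or data
  formats; p-values are reported raw, one per dataset.

**Known statistical limitation.** The 9 aWCDs and 36 aBCDs are computed
from the same samples and averaged over the same maps, so they are
strongly positively dependent. The rank-sum test treats them as
independent and is therefore *conservative* under the null — in the
package's own null simulations it essentially never rejects at the 5%
level. Small p-values remain meaningful evidence of concordance, but the
test's nominal level should not be taken literally.

## Unique-compound catalogue

`unique_compounds()` assigns a compound to a sample's unique set iff its
column contains exactly one presence; the sets are disjoint by
construction, and the two components of `pairwise_unique()` always sum to
the Hamming distance between the samples. Printed-average conventions are
matched by `round_half_up()` (half-up at one decimal, so 0.65 prints as
0.7). Floral-scent flagging matches compound names (case- and
whitespace-insensitively) against a curated reference list of volatiles
recorded from intact flowers, packaged as an editable text file — the
flags are only as good as the list's agreement with the user's library
nomenclature, and per-sample floral counts on real data are
reference-list dependent.

## Coniine SIM detection

Coniine elutes at 6.33 ± 0.01 min on the reference method; the monitored
ions are m/z 56, 70, 80, 84 (base peak) and 126 (molecular ion), of which
only 80/84/126 are diagnostic (56 and 70 are shared with many compounds
and are recorded but never used for confirmation). `extract_window()`
sums per-ion intensity over the closed rt window; `classify_pattern()`
assigns the screening qualifier codes: G (80/84 and 126/84 ratios each
within a relative tolerance of the reference pattern — the confirmatory
outcome, which suppresses the anomaly codes), H (80 > 84), I (all three
equal within tolerance), J (126 strictly the greatest), F (a present ion
below the low-intensity threshold, reported alongside any other code).
The ratio tolerance defaults to 0.30; no tighter value is defensible for
"correct proportions" without an instrument calibration. Verdicts:
`absent` (no diagnostic ion above the noise floor), `ion84_only` (the
base peak alone — inconclusive, as m/z 84 is compatible with other
piperidines), `detected` (84 plus at least one further diagnostic ion, or
a G-qualifying pattern), downgraded to `trace` when the strongest
diagnostic ion stays below the trace threshold. The packaged reference
ratios are a synthetic stand-in for a pure-standard spectrum
(`coniine_reference_pattern_synthetic.tsv`) and must be replaced by
measured ratios for real data; likewise the default thresholds are
calibrated to the generator's intensity scale, on which a spike amount of
1 corresponds to the limit of detection (called `trace`), and must be
re-calibrated per instrument. Species-level summaries count a species
positive if any accession or tissue yields `detected` or `trace`, with
infraspecific taxa grouped under the parent binomial.

## The synthetic-data generator

The generator emulates the statistical shape of the study data, and its
defaults are fixed once as the package's study conditions:

* 48 samples in 9 clades of sizes (1, 11, 4, 3, 13, 4, 5, 5, 2),
  mirroring the accession counts per clade;
* a many-to-many mapping with candidate groups (3, 3, 2) hosted by the
  three largest clades, giving 43 tree tips and 18 bijective maps (the
  published mapping's exact grouping is not recoverable from the printed
  accession list, so the mapping is treated as data, never a constant);
* 560 compounds, of which 20 are clade markers assigned round-robin to
  the non-singleton clades, present with probability 0.9 inside their
  clade and 0.05 outside; the background presence rate is solved
  analytically so the expected overall sparsity is 91.4%;
* log-normal(0, 1) abundances for present cells, rows normalised to
  percentages — positive and right-skewed like peak areas;
* Gaussian-shaped SIM peaks (sd 0.005 min) at 6.33 min with per-ion
  heights proportional to the reference ratios, plus clipped Gaussian
  baseline noise.

What it does *not* emulate: compound co-occurrence structure beyond the
clade markers, retention-time co-elution other than by explicit request,
heavy-tailed or zero-inflated abundance mixtures, and instrument drift.
Passing tests on this generator therefore demonstrate correctness of the
algorithms under the stated statistical shape, not performance on real
chromatograms.

A consequence worth stating plainly: under these study conditions the
single-factor sparse clustering cannot rank most of the 20 planted clade
markers above the background. A binary feature's aggregate dissimilarity
is driven by its presence count $k$ through $k(n-k)$, so the upper tail
of 540 background features overlaps the markers of small clades, and with
9 clades ~84% of sample pairs are cross-clade, leaving the nonnegative
pair-weighting vector $u$ nearly uniform — it cannot reward the defining
property of a marker, the *absence* of within-clade disagreement. The
package's tests measure this honestly (marker recovery saturates well
below full recovery); the concordance test, given the true markers, has
essentially full power at p < 0.01 in the same simulations.

## Problem sizes and reproducibility

All simulation-based tests and the acceptance script run at the study's
own scale (48 × 560) with modest replication (50–400 seeded runs chosen
as the package's standard verification sizes); every stochastic step
takes an explicit seed, generators are bit-reproducible under a fixed
seed, and `run_all()` writes a manifest with file hashes so identical
configurations produce identical outputs.
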
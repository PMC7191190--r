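---
title: "Immune methylation profiling: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Immune methylation profiling: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`immunometh` profiles the immune microenvironment of bulk tumors from
methylation-array beta values. This vignette is the package's account of the
underlying models, the parameters that matter, what the bundled synthetic
data do and do not emulate, and the design decisions taken where the
procedure was genuinely open.

## The measurement model

A beta value is the methylated fraction of a CpG in the DNA of a bulk
specimen, bounded in [0, 1]. For a tumor that is a mixture of malignant
cells and immune infiltrate, the beta value at a CpG that is unmethylated in
immune lineage *t* and methylated in tumor cells is, to first order, a
purity-weighted average:

$$\beta_{ij} \approx (1 - f_{it})\,\beta^{\text{tumor}}_{j} + f_{it}\,\beta^{\text{immune}}_{j},$$

where $f_{it}$ is the fraction of sample $i$'s DNA contributed by cell type
$t$. Since $\beta^{\text{tumor}}_j \gg \beta^{\text{immune}}_j$ at a good
marker CpG, beta decreases monotonically with infiltration — the entire
pipeline rests on this inverse relationship, and low methylation scores are
read as immune-rich.

## Signature selection

Two gene → cell-type signatures are merged; genes assigned to different cell
types by the two sources are ambiguous lineage markers and are removed
outright. Candidate CpGs are promoter probes (|distance to TSS| strictly
below 1500 bp, a conventional promoter window) present on both the 450K and
EPIC platforms, so signatures transfer across array generations.

Three filters follow:

* **Differential methylation across reference immune types.** Beta values
  are dichotomized at 0.3 (values ≥ 0.3 count as methylated; 0.3 sits above
  the noise floor of a truly unmethylated CpG yet below partially methylated
  mixtures). Each CpG's (cell type × methylation state) count table is
  tested with the exact conditional test for r × 2 tables — the
  Freeman–Halton extension of Fisher's test, computed by
  `stats::fisher.test` — with a seeded Monte-Carlo p-value (B = 1e5) for
  tables with more than 300 observations. The test is run once across all
  cell types (r × 2) rather than one-vs-rest per type: the r × 2 layout asks
  "is methylation state heterogeneous across lineages at all", which is the
  property a lineage marker needs, and avoids multiplying the test count by
  the number of types. Benjamini–Hochberg FDR < 0.01 gates the step (the FDR
  procedure is recorded in the output; "most significant" is taken as
  smallest raw p, which yields the same ranking as BH-adjusted p).
* **Hypermethylation in nonimmune cells.** Stromal reference samples and
  tumor lines are pooled and a CpG passes when the fraction of samples with
  beta strictly above 0.7 strictly exceeds 0.98. Pan-cancer mode relaxes the
  fraction to 0.90, because tumor-line panels of a cancer type often contain
  a minority of lines with deviating methylation; relaxing the fraction (not
  the beta threshold) tolerates those outlier lines without admitting CpGs
  that are genuinely unmethylated in tumor cells. The two thresholds nest,
  so the pan-cancer CpG set is always a superset of the melanoma-mode set on
  the same data.
* **One CpG per gene**, so no gene dominates downstream medians: smallest
  exact-test p, ties broken by the larger beta range across reference immune
  samples (more dynamic range = more informative), then by lexicographically
  smaller probe ID so the output is deterministic.

Missing beta values are dropped pairwise from count tables; a CpG with more
than 20 % missing reference values is excluded and flagged rather than
tested on a sliver of data.

## Consensus clustering and centroid classification

No single hierarchical cut is trusted: the cohort is subsampled (80 % of
samples, 1000 iterations, seeded), each subsample clustered by Ward.D2 on
Euclidean distance and cut at k, and the fraction of co-sampled runs in
which two samples co-cluster accumulated into a consensus matrix; final
labels come from clustering 1 − consensus. Resampling fraction, iteration
count and linkage are exposed in the configuration. Cluster indices are
relabelled by ascending mean beta so that "cluster 1" is always the
methylation-low, immune-rich group — raw `cutree` indices are arbitrary and
would otherwise change meaning between runs.

Centroids are per-cluster medians (robust to the skewed, bounded beta scale)
of every clustering CpG whose Kruskal–Wallis FDR across clusters is strictly
below 1e-4 — a deliberately harsh gate, since centroid CpGs must carry
cluster signal strong enough to survive transfer to external cohorts.
Classification computes Kendall τ-b between a sample and each centroid.
τ-b is used (not τ-a) because centroid medians can tie; rank correlation is
used (not Euclidean distance) because external cohorts routinely carry
global beta shifts from lab and preprocessing differences, which rank
statistics ignore. The threshold is **inclusive**: max τ ≥ 0.3 assigns,
anything less is `unclassified` — a deliberate output, as forcing every
sample into a cluster would contaminate downstream survival contrasts.
Pairwise-complete overlap of at least 10 informative CpGs is required;
ties on τ go to the lowest cluster index with a warning.

## Scores, dichotomization, PTEN

The methylation score of cell type *t* in a sample is the median beta over
*t*'s selected CpGs (median of an even count = midpoint of the central
order statistics; missing values omitted; a cell type with no CpG present
in the matrix yields an NA column and a message). Scores are monotone in
the underlying betas and live on the beta scale, so a score strictly above
0.7 is called hypermethylated — dichotomization refuses expression scores,
which are unbounded. Expression scores median-center each gene across
samples first in cohort mode (isolates relative regulation); cross-cohort
comparisons use noncentered scores, since per-cohort centering would remove
exactly the between-cohort differences of interest.

*PTEN* promoter hypermethylation requires two conditions jointly: strictly
more than 10 % of the promoter's DHS CpGs with beta strictly above 0.7
(focal hypermethylation at the regulatory core) **and** all-promoter median
beta strictly above 0.5 (broad shift, guarding against a single noisy
probe). All boundary comparisons in the package — binarization, the
nonimmune filter, dichotomization, both PTEN conditions — are strict
inequalities, unit-tested at their exact boundary values. Samples with
fewer than 5 informative DHS CpGs are undetermined (NA), not negative. An
alteration *event* is hypermethylation OR nonsynonymous mutation OR
copy-number loss/deletion; missing modalities count as FALSE but mark the
sample incomplete, so event rates can be recomputed on complete cases. DHS
membership and copy-number calls are consumed as annotations; no track
processing or segmentation is done here.

## Cluster statistics

Per-cell-type contrasts use Kruskal–Wallis across clusters and Dunn's
post hoc z-test per cluster pair,

$$z = \frac{\bar R_a - \bar R_b}{\sqrt{\left(\frac{N(N+1)}{12} - \frac{\sum_j (t_j^3 - t_j)}{12(N-1)}\right)\left(\frac{1}{n_a} + \frac{1}{n_b}\right)}},$$

two-sided, with ranks shared across all groups and $t_j$ the tie
multiplicities. BH correction is applied across cell types *within* each
cluster pair, matching how the contrast tables are read (one panel per
comparison). Clusters with fewer than 3 samples are excluded with a
warning. Categorical associations use Fisher's exact test for 2 × 2 tables
and Pearson's chi-square (no continuity correction) otherwise, with a
seeded Monte-Carlo p when any expected count falls below 5. Survival uses
Cox proportional-hazards models (Efron ties, Wald 95 % intervals; cluster 1
or not-hypermethylated as reference). A group without events produces a
monotone likelihood; such terms are flagged `non_estimable` rather than
reported with an absurd interval or raised as an error, and the per-cell-type
survival screen corrects across cell types (BH, significance at adjusted
p < 0.1) while annotating hazard ratios as "large" at HR ≥ 1.5 or ≤ 0.66.
Kaplan–Meier displays clip at 10 years; the log-rank test always uses full
follow-up.

## The synthetic-data generator

Real reference methylomes (sorted leukocytes, stromal cells, cell-line
panels) are controlled-access, so the generator emulates the *statistical
structure* the method assumes, with every quantity seeded and documented
(`simulation_config()`):

* **Archetypes.** Marker CpGs draw an immune-low archetype from
  Unif(0.05, 0.20) in their own cell type and Unif(0.80, 0.90) elsewhere;
  background CpGs sit at Unif(0.80, 0.90); nonimmune/tumor-line profiles at
  Unif(0.82, 0.97) at every CpG. Per-CpG (rather than constant) archetypes
  mirror the real baseline heterogeneity of promoter methylation and give
  sample profiles the rank structure a correlation classifier keys on.
* **Noise.** Observed beta ~ Beta(mean = archetype, concentration = 100 by
  default): values stay in [0, 1] by construction, with sd ≈ 0.035 near
  beta 0.85 — about the replicate noise of a well-performing array probe.
* **Cohorts.** Each tumor belongs to one of three infiltration strata
  (means 0.45 / 0.20 / 0.05 of the DNA from immune cells, equal
  proportions) and mixes tumor-line with immune archetypes per the
  measurement model above. Within a stratum, per-cell-type infiltration is
  the stratum mean times a cluster-specific cell-type weight profile
  (lymphoid-dominant in cluster 1, mixed in cluster 2, a myeloid-skewed
  residual in cluster 3; each profile normalized to mean 1 and capped so
  expected cluster-1 marker beta stays strictly below cluster 3 for every
  cell type). The weighting is essential, not cosmetic: with a single
  scalar infiltration per sample, all centroids would have identical rank
  profiles and Kendall-τ classification would be information-free by
  construction. The cost is that cell types with narrow weighted ranges
  show somewhat weaker per-CpG correlation with their planted infiltration
  than broad-range types. Per-sample infiltration draws use concentration
  50.
* **Linked data.** Expression of each signature gene is
  10 − 4·β(promoter CpG) + N(0, 0.5) — the only property downstream
  analyses need is the negative promoter linkage. Survival is exponential
  (baseline 0.14 events/year ≈ 5-year median) with per-cluster hazard
  ratios (default 1 / 2.1 / 2.2) and independent uniform censoring on
  (0, 15) years, giving roughly 30 % censoring. PTEN alteration events are
  planted at per-cluster rates 0.10 / 0.30 / 0.60, decomposed into
  hypermethylation / mutation / copy-number lesions, with the promoter
  block's betas generated consistently with the flag. Clinical covariates
  (age, sex, metastasis type, MITF status, TIL category) are drawn with
  cluster-dependent category probabilities.
* **Decoys.** Two marker genes carry extra marker-like CpGs and two genes
  are planted with conflicting cell-type assignments between the two
  signature sources, exercising best-CpG-per-gene selection and conflict
  removal; a slice of background CpGs is placed outside the promoter window
  or off the 450K platform to exercise the mapping filters.

What the generator does **not** emulate: genome coordinates, probe
cross-reactivity, batch and section effects, array preprocessing,
copy-number interactions with beta, or correlated infiltration between
related lineages. Tests passing on this generator therefore demonstrate
the pipeline's correctness and statistical calibration under its stated
model — not performance on any real cohort, where signature transfer and
preprocessing dominate.

## Determinism and problem sizes

All randomness flows from integer seeds (R's default Mersenne Twister; the
tumor-cohort stream derives from seed + 1, Monte-Carlo fallbacks carry
fixed internal seeds), and `run_pipeline()` reruns bit-identically for a
given configuration — the test suite checks byte-identity of every written
table. The suite works at deliberately moderate sizes chosen to estimate
each property stably: the default 7-type × 6-sample panel with 2000
background CpGs for selection, 150-sample cohorts for clustering,
classification and scores, 100 replicates of n = 300 for hazard-ratio
recovery, 500 replicates for p-value calibration, and exhaustive
enumeration of all r × 2 tables with r ≤ 4 and total ≤ 12 (one
representative per row-multiset) for the exact-test oracle.

## Known limitations

* The selected CpG count and cell-type coverage depend entirely on the
  supplied signatures and annotation; nothing here rediscovers markers
  de novo.
* Scores are medians of few CpGs per cell type and are *relative* measures;
  they are not calibrated cell fractions and should not be compared across
  platforms without harmonization.
* Consensus clustering settings (k, subsampling, linkage) are exposed but
  not auto-selected; choosing k is left to the analyst.
* The Cox models assume proportional hazards and provide no diagnostics;
  competing risks are out of scope.
* PTEN calling generalizes to other genes only insofar as a sensible
  promoter/DHS CpG annotation is supplied; the thresholds were designed for
  PTEN's promoter geometry.
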
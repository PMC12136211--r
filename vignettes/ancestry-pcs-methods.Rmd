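---
title: "Ancestry PCs from methylation arrays: model, choices, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ancestry PCs from methylation arrays: model, choices, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epiance)
```

## The problem

Genetic ancestry confounds epigenome-wide association studies: allele
frequencies differ between populations, genotypes shape local DNA
methylation, and case/control status is rarely balanced across ancestries.
The clean solution — principal components from genotyping data — is
unavailable in many methylation cohorts. A workaround is to compute PCs
from the methylation array itself, using CpG probes whose interrogated
site overlaps a common SNP ("SNP0bp" probes, distance 0, minor allele
frequency ≥ 0.05): at such probes the beta value is largely a read-out of
the underlying genotype, so PCs over them recover genetic structure.

The catch is that raw beta values also carry technical variation (plate,
slide, reagent batch) and biology unrelated to ancestry (cell-type
composition, sex, age). PCs computed from raw SNP0bp betas therefore often
load on batch or cell composition first, and ancestry only appears on the
second or third component — precisely the failure mode this package
addresses.

## The method

`epiance` computes three variants of ancestry PCs so they can be compared
on equal footing:

* **EpiAncOrig** — PCA on row-centered raw SNP0bp betas (the classic
  SNP-overlap baseline).
* **EpiAnceR** — every SNP0bp probe is first residualized by ordinary
  least squares on a covariate design: intercept, sex (F = 0 / M = 1),
  age in years, all cell-proportion PCs, and ten control-probe PCs. The
  control probes measure no CpG and so isolate technical variation; their
  leading PCs act as batch surrogates. PCA is then applied to the
  residuals.
* **EpiAnceRplus** — the residuals are stacked with genotype calls from
  the array's dedicated rs probes (trimodal beta values called at 0.25 /
  0.75 into dosages 0 / 0.5 / 1), each row centered, and PCA applied to
  the combined matrix. Genotype calls are nearly immune to batch effects
  because a beta value is a within-probe intensity ratio, so they anchor
  the PCs to genetic variation even when the residualization is
  imperfect.

All PCAs are center-only (rows are centered; no variance scaling), sample
scores come from the SVD, the sign of each component is fixed by making
its largest-absolute loading positive, and each score column is min-max
scaled to [0, 1] so the variants are directly comparable. Explained
variance is reported from the unscaled scores. Both scaled and raw scores
are kept, since the 0-1 scaling is a comparability device rather than part
of the decomposition.

### Preprocessing chain

`run_pipeline()` reproduces a standard intensity-level chain restricted to
the selected probes:

1. **Probe selection** from a platform annotation table: CpG probes with
   SNP distance exactly 0 and MAF ≥ 0.05 (inclusive), plus all rs probes.
   For EPICv1-style annotations assembled from two publications, tables
   are merged with deduplication by probe id (`merge_annotations()`).
2. **Detection p-values** on raw signals: the upper tail of a normal
   distribution fitted to the sample's negative controls in the probe's
   channel(s) (type II probes pool green and red), evaluated at the
   probe's total intensity. The SD is floored at 0.01 AU.
3. **Background correction**: per sample and channel, the 5th percentile
   of the negative controls is subtracted; corrected intensities are
   floored at 1 AU.
4. **Masking**: entries with detection p above `1e-16` become missing.
   The published threshold is printed ambiguously enough to also be read
   as `1e-15`; the threshold is a config field, default `1e-16`.
5. **Probe QC**: a probe is dropped when *more than* 5% of samples have a
   bead count below 3 or *more than* 10% of samples are missing. The
   inequalities are strict, so probes at exactly 5% / 10% are retained.
6. **Quantile normalization** of methylated and unmethylated intensities
   as two separate matrices, over SNP0bp and rs probes jointly (via
   `limma::normalizeQuantiles`, ties averaged, missing entries excluded
   from ranking and restored).
7. **Beta values**: `M / (M + U + 100)`.
8. **Imputation**: k-nearest-neighbour over probes (k = 5). Distance
   between probes is the root-mean-square difference over jointly
   observed samples; a missing entry takes the unweighted mean of the k
   nearest probes observed at that sample, falling back to the probe's
   row mean when fewer than k usable neighbours exist.

### Evaluation battery

`evaluate_methods()` quantifies how well each variant captures ancestry,
using the first three scaled PCs as a 3D embedding: silhouette scores per
ancestry group and per individual (for repeated samples); per-group 3D
centroids, mean within-group distance to centroid, and the between-centroid
distance matrix; association tests between each of PCs 1-3 and the
ancestry groups; and the 3×3 grid of absolute Pearson correlations against
genotyping PCs when they exist.

Association testing is assumption-gated: one-way ANOVA is used only when
Shapiro-Wilk on the one-way residuals and Levene's test (median-centered)
both exceed α = 0.05, otherwise Kruskal-Wallis. The gate's tests and α are
package choices — the published procedure names the assumptions but not
the tests. For covariates measured on cohorts with repeated samples, the
group effect is tested by a likelihood-ratio test between
`outcome ~ group + (1 | individual)` and `outcome ~ (1 | individual)`,
both fit by maximum likelihood (REML would invalidate the LRT on fixed
effects), against χ² with (groups − 1) degrees of freedom.

For replicate-level comparisons we summarize "how well does PC1 track
ancestry" with the correlation ratio `group_correlation()` — the square
root of the one-way R², equivalently the absolute Pearson correlation
with the best numeric coding of the groups. A fixed integer coding would
make the answer depend on which contrast PC1 happens to pick (a PC
separating the middle group from the outer two is uncorrelated with the
coding 1/2/3 despite perfect clustering), so the coding-free version is
the honest measure.

## The synthetic cohort generator

`simulate_cohort()` produces complete raw-data cohorts with known truth,
so every stage — probe selection through evaluation — is testable without
restricted data. Its defaults define the package's standard study
conditions:

* **Ancestry structure**: 3 groups × 50 individuals, allele frequencies
  diverged by the Balding-Nichols model with FST = 0.1 (each group
  frequency `Beta(p(1-F)/F, (1-p)(1-F)/F)` around an ancestral frequency
  drawn uniformly on (0.1, 0.9)); genotypes are binomial draws.
* **Genotype-to-beta map**: trimodal means 0.1 / 0.5 / 0.9 on the beta
  scale — consistent with the 0.25 / 0.75 calling thresholds — with
  Gaussian noise SD 0.1 at SNP0bp probes and 0.05 at rs probes.
* **Batch effects**: each sample carries a latent technical factor
  (batch-specific centers standardized to SD 1 across 6 batches, plus
  within-batch jitter). The factor enters the control probes through
  per-probe log-scale loadings and the methylation probes through
  per-probe beta-scale loadings with SD `batch_sd = 0.15` — pronounced
  but realistic batch structure, the regime the residualization step
  exists for. Sharing the factor between control and methylation probes
  is deliberate: it is the mechanism that makes control-probe PCs
  informative, i.e. the method's own working assumption. rs-probe batch
  loadings are shrunk tenfold, reflecting the empirical robustness of
  within-probe intensity ratios to channel-level shifts.
* **Biology**: blood-like cell proportions from a Dirichlet (6 types,
  neutrophil-dominated), per-probe cell loadings scaled by
  `cell_sd = 0.1`; per-probe sex effects (SD 0.02) and age effects
  (SD 0.002 per year).
* **Array artefacts**: betas are converted to methylated/unmethylated
  intensities via a log-normal total intensity (median ≈ 4000 AU) and the
  beta offset, channel backgrounds (≈ 150 AU) are added back, negative
  controls are drawn per sample and channel, 0.2% of entries are forced
  below background to fail detection, 0.5% get bead counts below 3, and
  50 decoy CpG probes that fail the SNP-overlap/MAF rules are included so
  probe selection has something to reject.
* **Repeated samples**: 20% of individuals contribute 2 samples that
  reuse the individual's genotypes with fresh batch assignment, cell
  proportions and technical noise.
* **Confounded mode**: `confounded = TRUE` couples batch membership, cell
  composition, sex ratio and age to ancestry group, reproducing the
  regime in which residualization removes genuine ancestry signal along
  with the nuisance — useful for studying the method's known failure
  mode, not part of the standard conditions.

What the generator does *not* emulate: linkage disequilibrium between
sites, genomic coordinates, probe-chemistry differences between type I
and type II designs beyond channel routing, dye bias, and admixed
individuals. Passing tests on these cohorts therefore demonstrate the
pipeline's internal correctness and the method's behaviour under the
modelled confounding structure — not performance on real arrays, where
probe-level artefacts are richer.

## Numerical and design choices

* Probe ordering is lexicographic by probe id everywhere, and the whole
  pipeline is deterministic: identical inputs give bit-identical outputs.
* Residualization reuses one QR decomposition of the design across all
  probes; residual rows are orthogonal to every design column to < 1e-8
  (normalized) by construction.
* Genotype boundary values (beta exactly 0.25 or 0.75) call as
  heterozygote. Calls are appended on the 0 / 0.5 / 1 dosage scale with no
  per-row variance standardization: residuals and dosages then live on
  comparable sub-unit scales, and one engineered scale factor fewer means
  one arbitrary choice fewer. A per-probe 3-component clustering caller
  was considered and rejected: rs probes are engineered to be trimodal,
  and fixed thresholds are deterministic and auditable.
* Cell-proportion PCs keep all d − 1 components (compositions are rank
  deficient by one); no variance cutoff is applied. Which covariates a
  cohort needs is a modelling decision left visible in `build_design()`,
  which refuses rank-deficient designs (e.g. sex in a single-sex cohort)
  instead of silently dropping columns.
* Samples with missing sex or age are rejected, not imputed — a
  residualization on guessed covariates would quietly distort the PCs.
* Min-max scaling of a degenerate (constant) score column returns zeros.
* Silhouette conventions: singleton clusters score 0, as does the 0/0
  case of coincident points.
* The LRT statistic is floored at 0; a fit yielding a meaningfully
  negative statistic (non-convergence) is an error, not a result.

## Validation strategy and cohort sizes

The test suite validates each numerical component against an independent
oracle: PCA scores against a dense eigendecomposition of the sample
covariance (instances up to 50 × 50, tolerance 1e-8 up to sign),
silhouettes against a brute-force pairwise implementation (100 random
instances, n ≤ 12, tolerance 1e-12), quantile normalization against the
mean-of-order-statistics definition, k-NN imputation against an
exhaustive neighbour search, and the Balding-Nichols sampler against its
closed-form moments.

Method-level properties are checked on simulated replicates of the
standard conditions: across 50 seeded cohorts, the genotype-augmented
residualized PC1 shows a stronger group correlation than the raw-beta
baseline's PC1, and repeated samples sit closer to their individual's
centroid, each in at least 90% of replicates. The mixed-model LRT's null
rejection rate is checked over 200 no-effect replicates (40 individuals ×
2 samples). rs-genotype recovery is checked on a 200-sample cohort
(≥ 99% agreement with simulated truth).

One property is intrinsically asymptotic: with all nuisance effect sizes
set to zero, residualization should leave PC1 unchanged. It cannot do so
exactly at any finite n — projecting out p ≈ 17 covariate directions
removes an O(p/n) share of any fixed axis, so the PC1 correlation between
the residualized and raw variants is ≈ √(1 − p/n) even with a perfectly
inert design (≈ 0.95 at n = 180). The limit check therefore runs on a
two-group cohort of 1600 individuals, where the projection loss falls
below the 0.99 tolerance; two groups are used because with three, the two
between-group eigen-axes can be nearly degenerate and PC1 may rotate
between variants for reasons unrelated to residualization.

## Known limitations

* Residualization removes ancestry signal whenever the nuisance
  covariates are themselves associated with ancestry (non-randomized
  designs); the confounded simulator mode exists to study exactly this.
  The method presupposes a design in which batch and composition are at
  most weakly coupled to ancestry.
* Beta-threshold genotype calling assumes well-behaved trimodal rs
  probes; arrays with shifted cluster positions would need the
  thresholds adjusted.
* The detection p-value model (normal tail on total intensity versus
  negative controls) is one reasonable formalization of a quantity whose
  exact published formula is implementation-defined.
* IDAT parsing, dye-bias/Noob/functional normalization, probe-type beta
  mixture correction, and cell-type deconvolution are out of scope; cell
  proportions are consumed as an input table.

## A minimal session

```{r example, eval = FALSE}
co <- simulate_cohort(sim_config(seed = 1))
res <- run_pipeline(co)
report <- evaluate_methods(res$pcs, co$sheet, geno_pcs = co$truth$geno_pcs)
sapply(report, `[[`, "silhouette_mean")
sapply(names(res$pcs), function(m)
  group_correlation(res$pcs[[m]]$scores[, 1], co$truth$group))
```
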
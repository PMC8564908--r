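---
title: "Discovering drug-response biomarker signatures from RPPA profiles"
author: "rppasig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering drug-response biomarker signatures from RPPA profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rppasig)
```

## The problem

Anti-EGFR therapy in head and neck squamous cell carcinoma (HNSCC) helps
only a subset of patients, and no routine molecular marker separates
responders from non-responders. One productive strategy profiles a cohort
of patient-derived xenografts (PDXs) with reverse-phase protein arrays
(RPPA) — a few hundred antibody probes against cancer-relevant total and
phospho-proteins — clusters the tumors by their protein state, tests
representatives of each cluster in vivo, and then distills the cluster
difference into a minimal biomarker panel usable on protein or mRNA
measurements, and ultimately by immunohistochemistry (IHC) in the clinic.

`rppasig` implements that full analysis chain as reusable, tested
components: Ward bi-clustering, growth-based response calling with exact
binomial uncertainty, a fold-change threshold sweep with SVM validation
across modalities, external-cohort concordance with a permutation control,
and per-section IHC scoring with a two-marker difference metric. A
synthetic-cohort generator with planted structure makes every stage
testable end-to-end without access to patient data.

## The synthetic cohort: planted structure and study conditions

`generateCohort()` draws a protein matrix of `nFeatures` probes (default
247) by `nSamples` PDXs (default 65) on the median-centered log2 scale.
Two planted sample clusters — a resistant fraction of 25/65 — differ in
two signature blocks of `nSignatureFeatures` probes each (default 5 per
group): group 1 is shifted up by `effectSize` (default 2, i.e. a 4-fold
protein difference) in sensitive samples, group 2 up in resistant samples.
All remaining probes are Gaussian noise with `noiseSd` = 0.3 log2 units,
a typical within-cluster spread for median-centered RPPA intensities.
Expression noise is Gaussian on the log2 scale by design — the simplest
model consistent with median-centered log2 inputs — and probes are
independent within cluster; real RPPA covariance among pathway members is
not emulated, which mainly makes the planted problem slightly easier than
a real one at the same effect size.

The matched mRNA matrix shares each mapped gene's protein signal plus
independent noise scaled from the feature's theoretical variance so the
per-gene Pearson correlation is close to `proteinMrnaCorr` (default 0.7).
About 20% of background probes emulate phospho-epitopes with no mRNA
counterpart, exercising the gene-mapping logic. With 65 samples the
realized per-gene correlation concentrates near the target; individual
genes still scatter by roughly ±0.1–0.15 (ordinary sampling error of a
correlation at n = 65), so tests assert the mean across genes.

A validation subset of `nValidated` samples (default 17, stratified to 10
sensitive + 7 resistant) carries observed in-vivo response labels, and
`generateGrowth()` produces the per-animal volume trajectories behind
them: exponential growth from 200 mm^3 at 0.08/day under vehicle, a
multiplicative rate effect under drug (stasis for sensitive tumors, 85% of
the vehicle rate for resistant ones), and lognormal caliper noise with a
10% coefficient of variation. These choices make the expected endpoint
ratios ≈ 0.19 and ≈ 0.78 — clearly on either side of the 50%-reduction
rule — and `growthSpec()` refuses effect values that would put a label's
expected ratio on the wrong side. HPV status is generated with high but
imperfect cluster concordance (rates 14/25 and 1/40 per cluster), so
covariate-association analyses have a realistic confounder to rank.

These defaults *are* the study conditions for all replicated properties
below; they are set once here and not tuned per test.

## Normalization

`medianCenterLog2()` implements the standard transform for both
modalities: each feature is divided by its median across samples and
log2-transformed, so every feature has median 0. FPKM zeros are handled
with a per-feature pseudocount of half the smallest nonzero value —
chosen to keep the transform total without dominating real signal — and
all-zero features are dropped with a warning. Medians are taken per probe
across samples (not per slide batch, which the data would not let us
reconstruct). Missing values are rejected outright: the strict reader
(`readProfile()`) refuses NA and, by default, verifies the centering
invariant to 1e-6.

## Bi-clustering and phenotype labeling

`wardBicluster()` clusters samples and features independently with Ward's
minimum-variance criterion on Euclidean distances (`hclust` method
`ward.D2`, the classical Ward algorithm for Euclidean input), cutting both
dendrograms at k = 2. The cluster count is fixed by design; no automatic
selection is attempted. Both merge histories are retained for
reproducibility, and unit tests verify the implementation against a naive
O(n^3) Ward oracle on small matrices, exact co-clustering of duplicated
samples, monotone merge heights and order-invariance. Merge ties are
resolved by `hclust`'s deterministic internal order; with continuous
expression values exact ties have probability zero, so this differs from a
lexicographic tie rule only on measure-zero inputs.

Because clustering is unsupervised, the two clusters must then be oriented:
`labelClusters()` names the cluster with the higher mean over a supplied
set of sensitivity-associated features `predicted_sensitive`. On real data
this set encodes the biological reading of the feature groups (e.g.
RTK/MAPK/PI3K pathway probes, whose high expression marks candidate
responders); in synthetic runs it defaults to the planted group-1 block.
An exact tie — again a measure-zero event — is broken toward the cluster
containing the lexicographically smallest sample ID, with a warning.

## Response calling and prediction scoring

`tumorVolume()` applies the ellipsoid formula length × width² / 2.
`callResponse()` compares arm means on the final treatment day and calls a
PDX sensitive when the drug/vehicle endpoint ratio is ≤ 0.5 — the boundary
is inclusive because the rule is "at least a 50% reduction". Arms ending
on different days each use their own last day, with a warning; the
endpoint day is accepted as data, never inferred.

`evaluatePredictions()` scores cluster predictions against observed calls.
Its rates follow the convention of in-vivo validation studies, where each
*predicted* arm is treated and scored for correctness: TPR is the fraction
of predicted-sensitive tumors that responded, TNR the fraction of
predicted-resistant tumors that resisted, FPR/FNR their complements. (The
observed-margin convention would attribute a refuted resistant call to the
false-negative side instead; both are defensible, but only the per-arm
reading reproduces the validation-table arithmetic this analysis reports,
e.g. 10/10 and 5/7 correct arms giving TPR 100% and FPR 29%.) Exact
uncertainty comes from `clopperPearson()` — Beta-quantile form, verified
against a tail-inversion oracle — and report tables round half-up to
integer percent. Note one rounding consequence: the exact interval for 5/7
starts at 29.04%, so the package reports 29% where coarser rounding
conventions may show 30%.

`cramersV()` quantifies how strongly any categorical covariate (cluster
membership, HPV status, stage, sex, site) associates with observed
response: uncorrected Pearson chi-squared, V = sqrt(chi2 / (n (min(r,c) −
1))), no continuity or bias correction, matching the plain form of the
statistic.

## The threshold sweep and cross-modality SVM validation

`differentialStats()` computes, per probe, the cluster means, their
difference (log2FC, resistant − sensitive) and a two-tailed
pooled-variance Student t-test — pooled rather than Welch because that is
the plain Student form; Welch is a one-line config change away for users
who prefer it. `sweepBiomarkerSets()` keeps probes with p < 0.01 and
extracts one set per |log2FC| threshold on the 0.1–1.5 grid in 0.1 steps:
15 nested sets. Empty sets are retained and flagged so the sweep's
bookkeeping stays aligned with the grid.

For each set, `evaluateSweep()` trains a linear SVM (margin penalty C = 1,
no feature scaling — inputs are already median-centered log2 values) on
the cluster phenotype of all samples *except* the validated ones, then
scores the validated samples using (a) their protein values and (b) their
mRNA values matched by gene symbol. Because unmapped probes have no mRNA
counterpart, the mRNA-tested model is trained on the mappable feature
subset — the protein-trained-mRNA-tested protocol with the only feature
set both modalities share. Holdout exclusion is structural: the model
records its training samples and `evaluateClassifier()` refuses any test
sample it has seen.

Evaluation uses decision scores with sensitive as the positive class:
precision-recall curves with step-wise interpolation (average precision)
and ROC curves by trapezoidal integration, tied scores grouped so constant
scores give ROC AUC 0.5 and PR AUC equal to prevalence. Both areas are
verified against exhaustive threshold-enumeration oracles on random small
instances. One numerical property worth knowing: at small test sets,
average precision under a random ranking exceeds raw prevalence (≈ 0.65
versus 0.59 for 10 positives of 17), so the null-calibration test compares
the measured mean to the exact random-ranking expectation rather than to
prevalence alone.

`selectSignature()` picks the threshold maximizing the *minimum* PR AUC
across modalities — the least-assumptive formalization of "best for both",
chosen over averaging because it cannot reward a threshold that trades one
modality off against the other — breaking ties toward the larger threshold
(the smaller signature). `finalizeSignature()` then drops probes without a
gene symbol (e.g. a poly-ADP-ribose polymer probe in the motivating
dataset) and records per-feature direction: positive log2FC means up in
resistant.

Under the default study conditions the sweep recovers exactly the planted
two-block signature in every tested seed, and with no planted effect the
held-out PR AUC matches its chance level — both are recomputed by
`scripts/acceptance.R` on every run.

## External-cohort concordance and its permutation control

`foldChangeConcordance()` compares per-gene fold changes (resistant −
sensitive) between the internal cohort, grouped by *predicted* phenotype,
and an external cohort with observed labels, over their shared genes;
genes absent from either panel are dropped and reported, never imputed.
The comparison is mRNA-versus-mRNA by convention, matching how an
independent transcriptomic cohort would be used. `generateExternalCohort()`
builds such a cohort (default 4 resistant + 7 sensitive samples) at a
target correlation with any supplied internal fold-change profile,
optionally flipping the sign of designated discordant genes; the extra
fold-change spread is sized analytically so the *realized* correlation,
after the finite cohort's sampling noise, lands near the target.

`randomizationControl()` permutes the external labels (group sizes
preserved) and recomputes the correlation, at least 100 and by default
1000 times. An 11-sample cohort deserves a caveat: permutations that
nearly reproduce the true grouping retain most of the alignment, so the
null's 95% band is wide (roughly ±0.6 at 200 genes). The meaningful
signal is therefore twofold — the null mean sits near zero, and the
observed labeling, being the maximally aligned grouping, still exceeds the
band's upper edge at the default generator concordance of 0.7 in every
tested seed. At weaker concordance (≈ 0.5) the exceedance becomes
seed-dependent at this cohort size; that is a property of the smallness of
the external cohort, not of the implementation.

## IHC scoring

`scoreSection()` converts a per-cell mean-intensity table — the output of
any nuclear-segmentation pipeline — into a positivity percentage: cells
strictly above the intensity threshold count as positive, all cells in the
section are scored (no cytokeratin masking), and the score is invariant to
cell order and to common rescaling of intensities and threshold.
`calibrateThreshold()` encodes threshold calibration on control tissue as
a stated quantile (default the 99th percentile) of control-cell
intensities. `differenceMetric()` is the clinical readout: percentage
caveolin-1-positive minus percentage Sox-2-positive, with values above 0
predicting complete response and the boundary assigned to progressive
disease — a conservative choice that never credits a tie to response.
Multiple sections per patient stay separate observations.
`compareGroups()` summarizes by response group and tests CR versus PD with
a two-sided Mann-Whitney test — chosen because percentages from a few
sections are small-sample and non-Gaussian, and documented as this
package's choice rather than anything the motivating analysis prescribes.

## Running the whole pipeline

`runPipeline()` chains the stages — simulate or load, cluster, respond,
sweep/select, concordance, IHC — writing every stage table under a run
directory plus a `manifest.json` with the config MD5 hash, master seed and
per-stage outputs. Reruns of the same config are byte-identical. Missing
inputs degrade gracefully: without an mRNA matrix the cross-modality and
concordance stages are skipped with a logged reason, and any stage error
aborts with the stage name in a typed condition
(`rppasig_input_error` / `rppasig_degenerate_error`).

```{r example, eval = FALSE}
res <- runPipeline(pipelineConfig(mode = "simulate", seed = 1))
reportRates(res$respond$contingency)
res$sweep$signature
pearsonR(res$concord)
```

For a real cohort, `mode = "run"` takes TSV/CSV paths plus
`cluster$sensitivity_features`, and the rest of the pipeline is identical.
Given a published RPPA supplementary matrix and its clinical annotations,
this run mode is the offline route to replicating the motivating study's
reported probe set at the |log2FC| ≥ 1, p < 0.01 filter; no such external
data ship with the package.

## Problem sizes and numerical choices, summarized

- Test-suite simulations use 30-sample × 60-feature cohorts for unit
  properties and the full 65 × 247 default for replicated end-to-end
  properties (50 seeds for clustering recovery and null calibration, 20
  for signature recovery), sizes at which every property is stable while
  the whole suite stays quick.
- Tolerances: centering invariant 1e-9 internal / 1e-6 on file input;
  oracle agreement 1e-10–1e-12; calibration bands ±0.1 on correlations,
  ±0.05 on chance-level comparisons.
- Degenerate inputs have defined behavior everywhere: zero pooled variance
  (p = 1 on equal means, else a warned underflow), empty biomarker sets
  (flagged and skipped), single-class test sets (typed error), all-zero
  features (dropped with a warning), exact labeling ties (warned
  deterministic tie-break).

## Known limitations

- Probes are independent within cluster in the generator; correlated
  pathway blocks would make both clustering and the sweep somewhat harder.
- The permutation band caveat above: with ~11 external samples, band
  exceedance is only guaranteed at moderately strong concordance.
- The IHC module starts from per-cell intensities; segmentation quality,
  stain deconvolution and antibody calibration are upstream of this
  package and out of scope.
- Passing tests on synthetic cohorts demonstrates correctness of the
  machinery under the planted model, not clinical validity of any
  signature on real tumors.
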
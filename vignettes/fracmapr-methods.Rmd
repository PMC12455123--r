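---
title: "Mapping the subcellular proteome from fractionation profiles"
author: "fracmapr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping the subcellular proteome from fractionation profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fracmapr)
```

## The problem and the model

Proteins that reside in the same subcellular compartment co-distribute
when a cell lysate is separated into biochemical fractions — by
differential ultracentrifugation, where each sequential spin pellets
material by sedimentation coefficient, or by sequential detergent
solubilization. Quantifying each protein across the fractions therefore
yields a *profile* whose shape is characteristic of its compartment, and
localization can be inferred by comparing profiles: curated marker
proteins with known residence supply labelled training data, and a
classifier assigns the remaining proteins to one of 13 compartments
(cytosol, mitochondrion, nucleus, chromatin, plasma membrane,
endoplasmic reticulum, Golgi apparatus, endosome, lysosome, peroxisome,
proteasome, and the 40S and 60S ribosomal subunits) or leaves them
"unknown".

fracmapr implements this workflow for precursor-level label-free DIA
quantification (and, secondarily, for PSM-level TMT reporter data):

1. **Ingest** a long-format precursor report (run, protein group,
   precursor, intensity) plus an explicit run → (replicate, fraction)
   design, and pivot each replicate into a features × fractions matrix.
2. **Quality control**: remove contaminant and ambiguous (multi-accession)
   protein groups; optionally blank cells under a minimum intensity; drop
   fractions whose missingness exceeds 70% of precursors; then drop
   precursors with fewer than two quantitative values across the
   *remaining* fractions. The order is fixed — row counts refer to the
   columns that survive — and every stage records conservative accounting
   (`qc_report()`).
3. **Impute per replicate** under the mixed mechanism model below.
4. **Normalize and aggregate**: each precursor profile is divided by its
   row sum, then aggregated to one profile per protein by per-column
   medians (DIA) or by Huber-weighted robust summarization of the two-way
   additive model (TMT/DDA).
5. **Intersect replicates**: only proteins quantified in *every*
   replicate enter the map; their per-replicate profiles are concatenated
   replicate-major into one feature vector (30 dimensions for 3 × 10
   fractions).
6. **Classify** with a radial-kernel SVM trained on markers, and
   **score resolution** with per-class F1 distributions and the QSep
   cluster-distance metric.

## Mixed MNAR/MAR imputation

Missing values in fractionation DIA data arise from two distinct
mechanisms. A compartment is *absent* from many fractions by design, so
off-peak measurements fall under the detection limit and are missing
*not* at random (MNAR, left-censored); independently, peptides
occasionally escape detection despite being present (missing at random,
MAR). A single global strategy mishandles one mechanism or the other:
left-censor imputation (MinDet) crushes randomly missing peaks toward
the detection floor, and neighbour-based imputation (k-NN) hallucinates
signal into genuinely empty fractions.

The mixed strategy assigns each precursor row a mechanism from its own
missingness within the replicate: rows missing **more than two** values
across the fractions are treated as MNAR and imputed with the global
minimum observed value of the replicate matrix; the remaining incomplete
rows are treated as MAR and imputed by k-nearest-neighbour row averaging
(Euclidean distance on mutually observed columns, rescaled by
`sqrt(total/shared)`; k = 10 by default; ties broken by row order, no
randomness anywhere). Each replicate is imputed independently so that a
shifted gradient in one replicate cannot bias another.

Two points deserve flagging. First, the threshold is an absolute count
(> 2 missing), not a proportion; with 10 fractions these coincide at
20%, and a proportion mode is available (`impute_config(proportion_mode
= TRUE)`) for other designs, but the absolute count is the default and
is never silently rescaled. Second, the k-NN donor pool deliberately
includes all rows of the pre-imputation matrix, including MNAR rows
wherever they were observed — their observed values are real
measurements.

## The classifier and per-organelle thresholds

Marker profiles train a radial-kernel SVM with inverse-class-frequency
weights. Hyperparameters (cost over `2^-4..2^4`, kernel width over
`10^-3..10^2`) are chosen by stratified five-fold cross-validation on
macro-F1 inside each of `outer_rounds` stratified 80/20 train/test
rounds (100 by default; 10 in the desk-scale validation runs); the
held-out 20% of each round yields the per-class F1 distributions used as
a per-organelle resolution readout, with

F1 = 2·TP / (2·TP + FP + FN),

defined as 0 when the denominator vanishes. Model selection is judged on
the *probability-calibrated* predictor (pairwise-coupling calibration),
not on raw decision values: the deployed assignment rule thresholds
calibrated scores, and at degenerate hyperparameters the two can
disagree wildly, so selecting on one while deploying the other would be
incoherent.

Published workflows tailor a score threshold per organelle by hand. As a
reproducible stand-in, the default rule takes, per class, the median
(configurable quantile) of the calibrated scores that *correct* marker
predictions achieved in the held-out rounds; a user-supplied per-class
threshold table overrides it. A protein is assigned its argmax class iff
its winning score reaches that class's threshold, else "unknown";
curated markers always keep their labels. The applied thresholds are
part of the result object — the package reports what it used rather
than claiming fidelity to any manually tuned set.

## Resolution metrics

**QSep** compares the mean Euclidean distance of full profiles within
and between marker clusters: `raw[i, j]` is the mean over all cross
pairs (distinct pairs on the diagonal), and each row is divided by its
diagonal, so `normalized[i, j]` measures cluster j's distance from
cluster i in units of i's own spread. The normalized matrix is
asymmetric by construction; its diagonal is identically 1; the summary
statistic is the median of the off-diagonal entries, per row and
overall. Note a small-cluster artefact of the definition: two
point-identical n-member clusters score (n−1)/n, not exactly 1, because
the cross-pair mean includes the n zero self-distances.

**PCA maps** are column-mean-centred (no variance scaling by default; a
switch exists since the convention differs between sites), with a fixed
sign convention — the largest-magnitude loading of each component is
positive — so repeated runs agree exactly. Display outliers, the
extreme `trim_frac` (default 0.01%) tails by PC1 and PC2 rank, are
*flagged only*: trimming affects plotting and coordinate export, never
the classification input.

## The synthetic experiment generator

Because the package must be testable without any deposited dataset, the
`synthetic` module generates complete experiments with per-cell ground
truth. Protein `i` of class `k`, precursor `j`, fraction `f` receives

intensity = A_i · e_ij · w_i[f] · ε,

with lognormal protein abundance `A_i` (meanlog log(10^6), sdlog 1),
lognormal precursor response `e_ij` (sdlog 0.5), multiplicative noise ε
(sdlog 0.2), and `w_i` a Gaussian bump over the fraction axis
(σ = 0.6 fractions, baseline 0.02, normalized to sum 1) centred at the
class centre plus a per-protein offset (sd 0.15 fractions, drawn once
and shared across replicates). That jitter encodes within-compartment
heterogeneity — proteins of one compartment do not co-sediment
perfectly — and without it any two distinct class centres remain
separable no matter how close, which would make a low-resolution
scenario impossible to emulate. Missingness is mechanistic: random
dropout strikes any cell with probability 0.05, and remaining cells are
censored with probability `plogis((log LOD − log intensity) · 1.5)`
(log-LOD 8.6), so censored cells concentrate at low intensity, below
randomly dropped cells, below observed cells — letting the imputation
module's mechanism rule be scored against true mechanisms.

Four presets encode the validation scenarios: `dialop-like` (13 classes
× 10 fractions × 3 replicates, 40 proteins per class, 40% markers,
evenly spread centres — a well-resolved DC gradient), `detergent-like`
(6 fractions with the four secretory classes centred within one fraction
of each other), `fraction-dropout` (the DC design whose fractions are
subset downstream), and `mechanism-mix` (heavier censoring, log-LOD 9.0,
and dropout 0.08, for comparing imputation strategies).

What passing these tests shows — and does not. The generator produces
smooth unimodal profiles, independent lognormal noise, and exact class
membership; real data have multi-localized proteins, correlated noise,
batch structure, and profile shapes no Gaussian bump captures. Recovery
of ≥ 95% of held-out labels here validates the *pipeline machinery*
(filters, imputation, aggregation, classification wiring), not expected
accuracy on real lysates.

## Design choices on open points

* **Intensity column**: DIA-NN-style reports carry both a normalised and
  a raw quantity column; which one feeds the analysis is not fixed by
  convention, so both are supported, defaulting to `Precursor.Normalised`
  with fallback to `Precursor.Quantity`.
* **Minimum-value semantics**: "min" imputation uses the global observed
  minimum of the replicate matrix (the method's classic reading); a
  per-column variant sits behind `impute_config(min_scope = "column")`.
* **Re-normalization after aggregation**: medians of sum-normalized
  precursor rows do not themselves sum to 1, so protein-level replicate
  blocks are re-sum-normalized by default (switchable) before
  concatenation.
* **Fewer-fractions experiment**: a 5-fraction version of a sequential
  DC series is emulated by truncation (the first five spins), not by
  thinning; on this generator thinned subsets do not lose median QSep
  after per-block renormalization — a limitation of the bump-profile
  model — whereas stopping the series early leaves late-sedimenting
  compartments unresolved, as in a real shortened protocol.
* **SPS-match threshold** (TMT branch): the filter is standard but its
  published threshold is not; the default of ≥ 65% is a common community
  setting, exposed in `qc_config()` and flagged in its documentation.
* **Validation problem sizes**: the shipped validation runs use 520
  proteins (~2 600 precursors per replicate), 10 outer rounds for the
  main classifier runs and 5 for the three-way imputation comparison —
  sizes chosen so the whole suite re-runs comfortably on a laptop while
  leaving every directional comparison strict.

## Degenerate inputs and numerical conventions

Zero intensities are treated as non-detections on ingest (switchable).
Rows with non-positive sums abort normalization with the offending
feature named. Quantiles use R's type-7 (linear interpolation)
convention. k-NN falls back to the column mean when no donor is observed
in the needed column; a fully missing column cannot survive QC. Robust
summarization falls back to the median, with a warning, if the Huber
IRLS fit does not converge in 20 iterations. All pipeline randomness
flows from explicit integer seeds; imputation and QSep are fully
deterministic, and SVM runs are reproducible bit-for-bit under a fixed
seed.

## Known limitations

Multi-localization is out of scope: every protein gets one class or
"unknown". No batch correction is applied across replicates (the
workflow relies on per-replicate processing plus intersection). The
t-SNE embedding is a convenience pass-through with no role in any
metric. The DDA/TMT branch is implemented and tested at the unit level
but the shipped end-to-end validation exercises the DIA path.
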
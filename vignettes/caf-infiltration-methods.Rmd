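---
title: "Methods: fibroblast infiltration and phenotype analysis in SCLC transcriptomes"
author: "sclcaf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fibroblast infiltration and phenotype analysis in SCLC transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question the pipeline answers

Small cell lung cancer (SCLC) is a high-grade neuroendocrine tumour with
pronounced phenotypic plasticity: tumours span a neuroendocrine (NE) to
non-neuroendocrine (Non-NE) axis, marked on one side by ASCL1/SYP/NCAM1 and
on the other by REST and YAP1. Cancer-associated fibroblasts (CAFs) are a
stromal population suspected of pushing tumour cells along that axis and of
shaping the immune microenvironment and chemotherapy response. `sclcaf`
implements the bulk-transcriptome side of that investigation as a reusable,
tested pipeline: estimate CAF abundance per sample, split a cohort into
high- and low-infiltration groups, score each sample's phenotype and immune
state, and compare groups with calibrated statistics — ending with a
transfer predictor of drug sensitivity.

Because the real cohorts must be downloaded from public databases, the
package carries a first-class synthetic-cohort generator with known ground
truth, so every stage is exercisable (and falsifiable) at desk scale.

## Abundance estimation

Three estimators, deliberately simple and fully in-repo, stand in for the
published tool chain (an enrichment-based scorer, a marker-based scorer and
a constrained regression deconvolver). Exact numeric parity with those tools
is explicitly not claimed; what the pipeline preserves is the design of
using *multiple independent* abundance readouts:

* **Marker-mean** (`marker_mean_score()`): arithmetic mean of log2
  expression over a marker panel. The classic ten-gene CAF panel (PDGFRA,
  PDGFRB, PDPN, FAP, THY1, COL1A1, COL1A2, COL3A1, ACTA2, S100A4) ships as
  an editable GMT in `inst/extdata/`.
* **Single-sample set enrichment** (`ssgsea_score()`): a rank-weighted ECDF
  difference per sample. With `mode = "sum"` and exponent `alpha = 0.25`
  it is the formulation used for bulk stromal/immune scoring
  (`estimate_like_scores()`); with `mode = "max_dev"` and `alpha = 1` it is
  the GSVA-style per-set score used by the hallmark comparison
  (`gsva_like_scores()`).
* **NNLS deconvolution** (`nnls_deconvolution()`): per sample solves
  `min ||R f - x||^2, f >= 0` against a user-supplied non-negative
  reference profile matrix (the solver is `pracma::lsqnonneg`), reporting
  raw coefficients and sum-to-one fractions.

### Infiltration grouping

`build_caf_composite()` stacks the z-scored marker rows and the z-scored
fibroblast-abundance rows (10 + 3 rows under the defaults);
`cluster_infiltration()` then applies agglomerative clustering on Euclidean
distances with Ward linkage (`ward.D2`), cut at `k = 2`, and labels the
cluster with the greater mean composite `"high"`. The source study does not
state its clustering distance, linkage or cut; Euclidean/Ward/k = 2 with the
larger-mean convention is this package's pinned choice, and exact
reproduction of published group sizes is expected to be sensitive to that
unstated choice. A postcondition asserts the high group's mean composite
strictly exceeds the low group's on every non-degenerate labeling.

## Per-sample scores

* **NE score** (`ne_score()`): `(cor(x, ne_ref) - cor(x, nonne_ref)) / 2`
  with Pearson correlations over a reference panel (classically 50 genes);
  `> 0` labels NE, `< 0` Non-NE. Exactly 0 is labelled `"undetermined"`
  (the source formulation defines only the two strict signs) and a sample
  that is constant over the panel gets `NA` with label `"undefined"` rather
  than a silent zero. Whether the correlations should be computed on linear
  or log expression is not fixed by the source; the matrix's declared scale
  is used as-is, so the caller makes that choice explicitly.
* **CYT** (`cyt_score()`): geometric mean of GZMA and PRF1 on the linear
  scale, with a 0.01 offset (the originating literature's convention; only
  "geometric mean" is stated upstream) so a zero transcript does not
  annihilate the score.
* **APM** (`apm_score()`): median over antigen-presentation genes of the
  per-gene z-score (n − 1 denominator everywhere in the package);
  zero-variance genes are excluded, with a warning, before the median.
* **T-cell-inflamed GEP** (`gep_score()`): weighted sum of log2(x+1)
  expression over an 18-gene panel. The weights originate in a patent and
  are not printed in the open literature, so they are a **required external
  input** — the package fabricates no default weights.
* **Subtype calls** (`call_subtype()`): argmax of ASCL1 / NEUROD1 / POU2F3 /
  YAP1 with the fixed tie priority A > N > P > Y, ties flagged.
* **IHC a×b** (`ihc_score()`): proportion bins 0–4 and intensity bins 0–3
  multiplied. The published bin table leaves (5, 6)% unassigned; the pinned
  convention is `[0,5] -> 0, (5,25] -> 1, (25,50] -> 2, (50,75] -> 3,
  (75,100] -> 4`.

## Group-level inference

**GSEA.** `rank_metric()` ranks genes by the signal-to-noise statistic
`(mu_high - mu_low)/(sd_high + sd_low)` with each group sd floored at
`max(0.2 |mu|, 0.2)` (the canonical default, configurable). `gsea_es()` is
the weighted Kolmogorov–Smirnov running sum; `gsea_nes()` normalises the
observed ES by the mean magnitude of same-sign permutation-null scores and
reports the nominal `p = (1 + #extreme) / (1 + #same-sign)`, which can never
be exactly zero. Phenotype (label) permutation is the default null; when a
group has fewer than 7 samples the call falls back to random same-size gene
sets with a warning, mirroring common practice. Every permutation routine
takes an explicit seed; unseeded calls are an error.

**Moderated comparison.** `moderated_t()` implements the empirical-Bayes
two-group comparison: per-feature pooled variances `s^2` on
`d = n1 + n2 - 2` df; hyper-parameters by moment matching on
`e = log s^2 - digamma(d/2) + log(d/2)` — the prior df `d0` solves
`trigamma(d0/2) = excess variance of e` via Newton inversion of the
trigamma, and `s0^2 = exp(mean(e) + digamma(d0/2) - log(d0/2))`. Posterior
variances `(d0 s0^2 + d s^2)/(d0 + d)` give a t statistic on `d0 + d` df
and Benjamini–Hochberg q-values. Two degenerate branches are handled
explicitly: non-positive excess variance sends `d0` to infinity with
`s0^2 = exp(mean(e))` (the moment formula's limit — note that other
implementations use the arithmetic mean of `s^2` in this branch, which
differs slightly), and a forced `d0 = 0` reproduces the ordinary pooled t
exactly, which the tests assert. Features with zero variance in both groups
are flagged and excluded from the prior fit.

**Elementary tests.** `pearson_correlation()` computes the two-sided p from
`t = r sqrt((n-2)/(1-r^2))`, which also makes printed `(r, n)` pairs
directly checkable via `correlation_p_from_r()`. `group_tests()` wraps the
standard Student/Welch t, exact-when-feasible Mann–Whitney (exact up to 20
total observations without ties, normal approximation with tie correction
otherwise), and one-way ANOVA.

## Drug-sensitivity transfer

`fit_ridge_transfer()` trains, on cell-line expression, the ridge predictor
behind the IC50 transfer stage: genes standardised on the training set
(sd < 1e−8 genes dropped), response centred, closed-form solution
`(X'X + lambda I)^{-1} X'y`, with `lambda` chosen by 5-fold CV over a
logarithmic grid `10^-2 … 10^4` (13 points) under a fixed fold seed.
Published transfer tools additionally homogenise batches between training
and target data; that step is out of scope here and per-gene
standardisation is the documented substitute, so transferred scores should
be read comparatively (between groups), not as absolute IC50s. Model genes
missing from a cohort are imputed at the training mean — equivalently they
contribute zero after standardisation — keeping cohorts comparable across
drugs. `compare_sensitivity()` reports per-drug `logFC = mean(high) -
mean(low)` with moderated-t inference; because **lower scores mean more
sensitive**, positive logFC is reported as "more resistant in the high
group".

## The synthetic cohort generator

`simulate_cohort()` draws, per sample:

1. fibroblast fraction `f` from the two-component Beta mixture
   `0.7 · Beta(2, 18) + 0.3 · Beta(10, 10)` — two components rather than one
   skewed Beta so "high/low infiltration" has a ground truth
   (`intended_group`) against which clustering can be scored; the 0.3
   mixing weight mirrors the under-30% high-infiltration prevalence
   reported for SCLC cohorts of ~80 samples;
2. phenotype from `P(Non-NE) = plogis(-2 + 6 f)`, encoding the
   fibroblast–Non-NE coupling as a generative assumption to be recovered,
   not as a measurement;
3. immune fraction `clip(0.3 f + N(0, 0.05), 0, 1 - f)`. No quantitative
   coupling strength is available upstream; 0.3 was chosen once as a
   moderate positive coupling — strong enough that immune content tracks
   fibroblast content, weak enough that high-infiltration samples retain
   appreciable tumour content (at `f = 0.5`, roughly 35% tumour), which is
   what lets the Non-NE program remain detectable against stromal dilution;
4. expression as the convex mixture of four component profiles (NE tumour,
   Non-NE tumour, fibroblast, immune) sharing a LogNormal(3, 1) baseline,
   with each program gene amplified 8× in its home component only, under
   multiplicative LogNormal(0, 0.3) noise (positive support matches
   FPKM-like data; an additive-Gaussian option exists in the config).

All draws flow through a single seeded stream, so identical
`(config, seed)` pairs give bit-identical cohorts. Immune genes carry
canonical symbols (GZMA, PRF1, CD274, PDCD1) and the fibroblast program
carries IL6, so the cytolytic, checkpoint and IL6-related stages run on
synthetic cohorts without special-casing. `simulate_ihc()` emulates paired
tissue-array scoring: two markers' latent levels are bivariate normal with
correlation `rho`, and each marker's proportion bin (theoretical quintiles)
and intensity bin (theoretical quartiles) are cut from its latent level —
binning attenuates the observable correlation, as in real arrays.

What the generator does **not** emulate: read-level counting noise
(no negative-binomial model), batch effects, gene–gene correlation beyond
the four-component mixture, partial-membership marker genes, or any
survival structure. Passing tests on synthetic cohorts therefore
demonstrate that the pipeline recovers the structure it assumes, not that
the assumed structure exhausts real SCLC data; the fold-change and noise
defaults are calibration choices exposed in `sim_config()`, not estimates
of the real cohorts.

## Numerical choices

* Ranking ties (equal expression or equal metric) break by gene id,
  lexicographically, everywhere — deterministic where common GSEA
  implementations vary.
* The running-sum extremum resolves an exact magnitude tie between the
  positive and negative deviation toward the positive one (tolerance
  1e−12), so rational-weight toys are stable against float noise.
* Standard deviations use the n − 1 denominator throughout.
* The trigamma inversion runs Newton from `0.5 + 1/x` with asymptotic
  shortcuts at both ends, converging to relative 1e−10.
* Duplicate gene rows collapse by per-sample maximum on read
  (configurable to mean); input scale is always declared, never sniffed,
  because FPKM-vs-log ambiguity in public data is not resolvable
  automatically.
* Gene symbols match case-sensitively; alias resolution is out of scope.

## Problem sizes used by the test-suite

The suite exercises the full default cohort geometry (80 samples × 5,000
genes) for parameter-recovery and sign checks — 20 seeded cohorts for the
recovery medians — and uses 400 seeded repetitions with 499 permutations
each for the null-calibration checks; oracle-equivalence checks run on
exhaustively enumerable toys (10–12 genes). These sizes were chosen so the
whole suite completes in about half a minute while keeping every check at
the scale the design states.

## Known limitations

* The three abundance estimators are analogs, not re-implementations, of
  the published estimators; absolute score values are not comparable to
  those tools' outputs.
* High/low group sizes depend on the unstated clustering convention (see
  above); only the qualitative structure (minority high group, direction of
  downstream contrasts) is asserted.
* The GSVA-style score is the rank-ECDF single-sample variant; the
  kernel-density variant is not implemented.
* The drug stage omits batch homogenisation and nonlinear models, and the
  predicted scores' absolute scale (e.g. whether they are log-IC50) is
  inherited from whatever responses the model was trained on.
* No survival analysis, no heatmap rendering, no spillover or mRNA-content
  correction, and no support for more than two infiltration strata.
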
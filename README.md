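# sclcaf

Fibroblast infiltration and phenotype analysis for small cell lung cancer
(SCLC) bulk transcriptomes.

SCLC tumours range from a neuroendocrine (NE) phenotype (ASCL1, SYP,
NCAM1-high) to a non-neuroendocrine (Non-NE) phenotype (REST, YAP1-high),
and cancer-associated fibroblasts (CAFs) in the tumour microenvironment are
implicated in pushing tumours toward the Non-NE state, an inflamed immune
microenvironment and chemoresistance. `sclcaf` packages the computational
side of that analysis for anyone with a genes × samples expression matrix:

* **CAF abundance**, three ways: marker-mean scoring over the classic
  ten-gene panel (PDGFRA, PDGFRB, PDPN, FAP, THY1, COL1A1, COL1A2, COL3A1,
  ACTA2, S100A4), single-sample rank enrichment, and non-negative
  least-squares deconvolution against a reference profile matrix.
* **Infiltration grouping**: Ward clustering of the z-scored
  marker + abundance composite into high/low CAF infiltration groups.
* **Per-sample scores**: NE score
  `(cor(x, ne_ref) − cor(x, nonne_ref)) / 2` (NE if > 0, Non-NE if < 0);
  cytolytic activity `sqrt(GZMA · PRF1)`; antigen-presentation (APM) median
  z-score; T-cell-inflamed GEP weighted sum; SCLC-A/N/P/Y subtype calls;
  IHC `a × b` scores.
* **Group inference**: GSEA with permutation-normalised enrichment scores
  (`NES = ES / mean |same-sign null ES|`), GSVA-style per-set scores, an
  empirical-Bayes moderated t (variance shrinkage with prior df `d0` and
  prior variance `s0²` fitted by trigamma moment matching),
  Benjamini–Hochberg FDR, and the elementary tests/correlations.
* **Drug-sensitivity transfer**: a closed-form ridge predictor
  `(X'X + λI)⁻¹X'y` trained on cell-line expression/IC50 pairs, with CV
  over a λ grid, transferred to the cohort and compared between
  infiltration groups (lower score = more sensitive; positive logFC =
  more resistant in the high group).
* **A synthetic cohort generator** with ground-truth fibroblast/immune
  fractions and phenotypes, so the whole pipeline is testable without any
  downloads.

Everything is tidyverse-shaped: score functions take the expression
container first and return tibbles, fitted objects have `tidy()` /
`glance()` methods, and result types have `autoplot()` methods.

## Worked example

```r
library(sclcaf)

co  <- simulate_cohort(sim_config(), seed = 77)   # 80 samples x 5,000 genes
#> <synthetic_cohort> 5000 genes x 80 samples (seed 77); 23/80 high-infiltration

lg  <- log_transform(co$expression)
ab  <- marker_mean_score(lg, co$memberships$caf_markers)
names(ab)[2] <- "Fibroblast_marker"

lab <- cluster_infiltration(
  build_caf_composite(lg, co$memberships$caf_markers, ab))
#> <infiltration_labeling> 80 samples: 23 high / 57 low (ward.D2, k = 2)

panel <- c(co$memberships$ne_program$genes, co$memberships$nonne_program$genes)
ref <- reference_vectors(panel, log2(co$profiles[panel, "NE_tumor"] + 1),
                         log2(co$profiles[panel, "NonNE_tumor"] + 1))
ns  <- ne_score(lg, ref)

pearson_correlation(ab$Fibroblast_marker, ns$ne_score)
#> # A tibble: 1 x 5
#>   estimate     n statistic  p_value method
#>      <dbl> <int>     <dbl>    <dbl> <chr>
#> 1   -0.392    80     -3.76 0.000329 pearson

gsea_nes(lg, lab$labels, co$memberships$ne_program, n_perm = 999, seed = 3)
#> <gsea_result> ne_program: ES = -1.000, NES = -1.418, p = 0.001919 (phenotype, 999 perms)
```

Reading the output: the cohort's fibroblast marker score anti-correlates
with the NE score (r = −0.39, p = 3×10⁻⁴) — fibroblast-rich samples look
Non-NE — and the NE gene program is significantly down-regulated in the
high-infiltration group (NES = −1.42, nominal p ≈ 0.002), the direction the
generative model encodes and the analysis is built to detect. On this
cohort 23/80 samples (29%) land in the high-infiltration group, with 19 of
those 23 carrying the Non-NE phenotype.

`run_all(run_config(outdir, seed))` executes the full staged pipeline
(abundance → clustering → scores → comparisons → GSEA → GSVA-style
comparison → drug transfer), writes every intermediate as CSV/TSV plus a
JSON run report, and is byte-identical under a fixed seed. A thin CLI
wrapper lives in `inst/cli/sclcaf-cli.R`.

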
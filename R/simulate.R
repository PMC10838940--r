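#' Configuration for the synthetic SCLC cohort generator
#'
#' The generator emulates the statistical structure the downstream analysis
#' assumes in bulk SCLC cohorts: ~80 samples over a few thousand genes, a
#' minority (<30%) of samples with high fibroblast content, neuroendocrine
#' (NE) vs non-neuroendocrine (Non-NE) tumour programs whose balance is coupled
#' to the fibroblast fraction, and immune content positively coupled to the
#' fibroblast fraction.
#'
#' The fibroblast fraction `f` is drawn from a two-component Beta mixture —
#' `Beta(2, 18)` ("low", probability 0.7) and `Beta(10, 10)` ("high",
#' probability 0.3) — so infiltration grouping has a ground truth. The tumour
#' phenotype is Bernoulli with `P(Non-NE) = plogis(gamma0 + gamma1 * f)`, and
#' the immune fraction is `clip(immune_slope * f + noise, 0, 1 - f)`.
#'
#' @param n_samples,n_genes Cohort dimensions.
#' @param n_caf_markers,n_ne_genes,n_nonne_genes,n_immune_genes Marker-gene
#'   counts per program; with the default 10 CAF markers the classic marker
#'   symbols (PDGFRA, PDGFRB, PDPN, FAP, THY1, COL1A1, COL1A2, COL3A1, ACTA2,
#'   S100A4) are used, and leading immune genes carry canonical symbols
#'   (GZMA, PRF1, CD274, PDCD1) so cytolytic/checkpoint scores run unmodified.
#' @param prob_high Mixture weight of the high-infiltration Beta component.
#' @param beta_low,beta_high Shape pairs of the two Beta components.
#' @param gamma0,gamma1 Intercept and slope of the logistic phenotype coupling.
#' @param immune_slope,immune_noise_sd Linear immune-fraction coupling to `f`
#'   and the sd of its Gaussian jitter.
#' @param fold_change Expression fold-change of each marker gene in its home
#'   component relative to the shared baseline.
#' @param noise_sd Multiplicative lognormal noise sd (natural-log scale), or
#'   additive Gaussian sd when `noise_model = "gaussian"`.
#' @param noise_model `"lognormal"` (default; positive support matches
#'   FPKM-like data) or `"gaussian"` (additive, clipped at zero).
#' @param baseline_meanlog,baseline_sdlog Lognormal baseline expression
#'   parameters shared by all component profiles.
#'
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_samples = 80, n_genes = 5000,
                       n_caf_markers = 10, n_ne_genes = 25,
                       n_nonne_genes = 25, n_immune_genes = 25,
                       prob_high = 0.3,
                       beta_low = c(2, 18), beta_high = c(10, 10),
                       gamma0 = -2, gamma1 = 6,
                       immune_slope = 0.3, immune_noise_sd = 0.05,
                       fold_change = 8, noise_sd = 0.3,
                       noise_model = c("lognormal", "gaussian"),
                       baseline_meanlog = 3, baseline_sdlog = 1) {
  noise_model <- match.arg(noise_model)
  cfg <- list(
    n_samples = n_samples, n_genes = n_genes,
    n_caf_markers = n_caf_markers, n_ne_genes = n_ne_genes,
    n_nonne_genes = n_nonne_genes, n_immune_genes = n_immune_genes,
    prob_high = prob_high, beta_low = beta_low, beta_high = beta_high,
    gamma0 = gamma0, gamma1 = gamma1,
    immune_slope = immune_slope, immune_noise_sd = immune_noise_sd,
    fold_change = fold_change, noise_sd = noise_sd,
    noise_model = noise_model,
    baseline_meanlog = baseline_meanlog, baseline_sdlog = baseline_sdlog
  )
  counts <- c(cfg$n_samples, cfg$n_genes, cfg$n_caf_markers, cfg$n_ne_genes,
              cfg$n_nonne_genes, cfg$n_immune_genes)
  if (any(counts < 1)) stop("all counts must be >= 1", call. = FALSE)
  if (cfg$prob_high < 0 || cfg$prob_high > 1) {
    stop("`prob_high` must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  if (cfg$fold_change <= 0) stop("`fold_change` must be > 0", call. = FALSE)
  structure(cfg, class = "sim_config")
}

CAF_MARKERS_CLASSIC <- c("PDGFRA", "PDGFRB", "PDPN", "FAP", "THY1",
                         "COL1A1", "COL1A2", "COL3A1", "ACTA2", "S100A4")

IMMUNE_CANONICAL <- c("GZMA", "PRF1", "CD274", "PDCD1")

# gene id layout shared by profiles and cohorts
sim_gene_ids <- function(cfg) {
  n_marked <- cfg$n_caf_markers + cfg$n_ne_genes + cfg$n_nonne_genes +
    cfg$n_immune_genes + 1L  # +1 for the fibroblast-program IL6 gene
  if (n_marked > cfg$n_genes) {
    stop("marker gene counts exceed `n_genes`", call. = FALSE)
  }
  caf <- if (cfg$n_caf_markers == 10) CAF_MARKERS_CLASSIC else
    sprintf("CAFM%02d", seq_len(cfg$n_caf_markers))
  ne <- sprintf("NEG%03d", seq_len(cfg$n_ne_genes))
  nonne <- sprintf("NNE%03d", seq_len(cfg$n_nonne_genes))
  imm <- sprintf("IMM%03d", seq_len(cfg$n_immune_genes))
  k <- min(length(IMMUNE_CANONICAL), cfg$n_immune_genes)
  imm[seq_len(k)] <- IMMUNE_CANONICAL[seq_len(k)]
  rest <- sprintf("G%05d", seq_len(cfg$n_genes - n_marked))
  list(caf = caf, ne = ne, nonne = nonne, immune = imm, il6 = "IL6",
       all = c(caf, ne, nonne, imm, "IL6", rest))
}

# internal: draw profiles on the current RNG stream
.sim_profiles <- function(cfg) {
  ids <- sim_gene_ids(cfg)
  baseline <- stats::rlnorm(cfg$n_genes, cfg$baseline_meanlog, cfg$baseline_sdlog)
  comp <- c("NE_tumor", "NonNE_tumor", "Fibroblast", "Immune")
  profiles <- matrix(rep(baseline, 4), ncol = 4,
                     dimnames = list(ids$all, comp))
  fc <- cfg$fold_change
  profiles[ids$ne, "NE_tumor"] <- profiles[ids$ne, "NE_tumor"] * fc
  profiles[ids$nonne, "NonNE_tumor"] <- profiles[ids$nonne, "NonNE_tumor"] * fc
  profiles[ids$caf, "Fibroblast"] <- profiles[ids$caf, "Fibroblast"] * fc
  profiles[ids$il6, "Fibroblast"] <- profiles[ids$il6, "Fibroblast"] * fc
  profiles[ids$immune, "Immune"] <- profiles[ids$immune, "Immune"] * fc
  memberships <- signature_library(list(
    gene_set("caf_markers", ids$caf),
    gene_set("ne_program", ids$ne),
    gene_set("nonne_program", ids$nonne),
    gene_set("immune_program", ids$immune),
    gene_set("fibroblast_program", c(ids$caf, ids$il6))
  ))
  list(profiles = profiles, memberships = memberships)
}

#' Simulate component expression profiles
#'
#' Draws a shared lognormal baseline per gene and amplifies each marker gene
#' by the configured fold-change in its home component only (CAF markers and
#' an IL6-like gene in the fibroblast profile, NE/Non-NE program genes in the
#' respective tumour profile, immune genes in the immune profile).
#'
#' @param config A [sim_config()].
#' @param seed Integer seed (required).
#' @return A list with `profiles` (genes x 4 non-negative matrix: NE_tumor,
#'   NonNE_tumor, Fibroblast, Immune) and `memberships`
#'   (a [signature_library()] of the program gene sets).
#' @export
simulate_component_profiles <- function(config = sim_config(), seed) {
  stopifnot(inherits(config, "sim_config"))
  with_local_seed(seed, .sim_profiles(config))
}

#' Simulate a bulk SCLC cohort with ground truth
#'
#' Per sample: the fibroblast fraction `f` comes from the two-component Beta
#' mixture (the component drawn is recorded as `intended_group`), the tumour
#' phenotype is Bernoulli with `P(Non-NE) = plogis(gamma0 + gamma1 * f)`, the
#' immune fraction is `clip(immune_slope * f + noise, 0, 1 - f)`, and the
#' observed expression column is the convex mixture of component profiles with
#' those weights under multiplicative lognormal noise.
#'
#' @inheritParams simulate_component_profiles
#' @return A `synthetic_cohort`: list with `expression` (linear-scale
#'   [expr_matrix()]), `truth` (tibble: sample_id, fibro_fraction,
#'   immune_fraction, phenotype, intended_group), `profiles`, `memberships`,
#'   `config`, `seed`.
#' @export
simulate_cohort <- function(config = sim_config(), seed) {
  stopifnot(inherits(config, "sim_config"))
  with_local_seed(seed, {
    prof <- .sim_profiles(config)
    n <- config$n_samples
    comp_high <- stats::runif(n) < config$prob_high
    f <- ifelse(comp_high,
                stats::rbeta(n, config$beta_high[1], config$beta_high[2]),
                stats::rbeta(n, config$beta_low[1], config$beta_low[2]))
    p_nonne <- stats::plogis(config$gamma0 + config$gamma1 * f)
    nonne <- stats::runif(n) < p_nonne
    imm <- pmin(pmax(config$immune_slope * f +
                       stats::rnorm(n, 0, config$immune_noise_sd), 0), 1 - f)
    tumor <- 1 - f - imm

    w <- rbind(
      NE_tumor   = ifelse(nonne, 0, tumor),
      NonNE_tumor = ifelse(nonne, tumor, 0),
      Fibroblast = f,
      Immune     = imm
    )
    clean <- prof$profiles %*% w
    noisy <- switch(config$noise_model,
      lognormal = clean * matrix(stats::rlnorm(length(clean), 0, config$noise_sd),
                                 nrow = nrow(clean)),
      gaussian = pmax(clean + matrix(stats::rnorm(length(clean), 0, config$noise_sd),
                                     nrow = nrow(clean)), 0)
    )
    sample_ids <- sprintf("S%03d", seq_len(n))
    colnames(noisy) <- sample_ids
    truth <- tibble::tibble(
      sample_id = sample_ids,
      fibro_fraction = f,
      immune_fraction = imm,
      phenotype = ifelse(nonne, "NonNE", "NE"),
      intended_group = ifelse(comp_high, "high", "low")
    )
    structure(list(
      expression = expr_matrix(noisy, scale = "linear"),
      truth = truth,
      profiles = prof$profiles,
      memberships = prof$memberships,
      config = config,
      seed = seed
    ), class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d genes x %d samples (seed %s); %d/%d high-infiltration\n",
              nrow(x$expression), ncol(x$expression), format(x$seed),
              sum(x$truth$intended_group == "high"), nrow(x$truth)))
  invisible(x)
}

#' Simulate paired immunohistochemistry scores
#'
#' Two markers' latent staining levels are bivariate normal with correlation
#' `rho`; each marker's positive-cell proportion bin `a` (0-4, theoretical
#' quintiles) and intensity bin `b` (0-3, theoretical quartiles) are cut from
#' its latent level, and the IHC score is `a * b`. Binning attenuates the
#' latent correlation, as it does in real tissue-array scoring.
#'
#' @param n Number of cores/samples (>= 3).
#' @param rho Latent correlation, in `[-1, 1]`.
#' @param seed Integer seed.
#' @param markers Length-2 character vector of marker names.
#' @return A tibble: sample_id, marker, a, b, score.
#' @export
simulate_ihc <- function(n, rho, seed, markers = c("aSMA", "REST")) {
  if (n < 3) stop("need n >= 3 IHC records", call. = FALSE)
  if (abs(rho) > 1) stop("|rho| must be <= 1", call. = FALSE)
  stopifnot(length(markers) == 2)
  with_local_seed(seed, {
    z1 <- stats::rnorm(n)
    z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
    bin <- function(z, probs) {
      as.integer(cut(z, breaks = c(-Inf, stats::qnorm(probs), Inf))) - 1L
    }
    a1 <- bin(z1, c(.2, .4, .6, .8)); b1 <- bin(z1, c(.25, .5, .75))
    a2 <- bin(z2, c(.2, .4, .6, .8)); b2 <- bin(z2, c(.25, .5, .75))
    tibble::tibble(
      sample_id = rep(sprintf("T%03d", seq_len(n)), 2),
      marker = rep(markers, each = n),
      a = c(a1, a2), b = c(b1, b2),
      score = c(a1 * b1, a2 * b2)
    )
  })
}

#' Simulate a drug-sensitivity training fixture
#'
#' Cell-line expression with a sparse linear response:
#' `response = intercept + sum(true_weight * expression) + Normal(0, noise_sd)`.
#'
#' @param n_lines Number of training cell lines (>= 3).
#' @param n_genes Number of genes.
#' @param n_causal Number of genes with non-zero weight (<= `n_genes`).
#' @param noise_sd Response noise sd.
#' @param seed Integer seed.
#' @param gene_ids Optional gene names (length `n_genes`); defaults to
#'   `DG00001...`.
#' @param causal_genes Optional names of the causal genes (must be in
#'   `gene_ids`); overrides `n_causal` positions.
#' @param causal_sign `"both"` (weights ~ N(0,1)), `"positive"` or
#'   `"negative"` (|N(0,1)| with that sign).
#' @return A list: `expression` ([expr_matrix()], log2-like scale),
#'   `response` (named numeric), `weights` (named, true coefficients),
#'   `intercept`.
#' @export
simulate_drug_training <- function(n_lines, n_genes, n_causal, noise_sd, seed,
                                   gene_ids = NULL, causal_genes = NULL,
                                   causal_sign = c("both", "positive", "negative")) {
  causal_sign <- match.arg(causal_sign)
  if (n_lines < 3) stop("need n_lines >= 3", call. = FALSE)
  if (n_causal > n_genes) stop("`n_causal` exceeds `n_genes`", call. = FALSE)
  if (is.null(gene_ids)) gene_ids <- sprintf("DG%05d", seq_len(n_genes))
  stopifnot(length(gene_ids) == n_genes)
  with_local_seed(seed, {
    line_ids <- sprintf("CL%03d", seq_len(n_lines))
    x <- matrix(stats::rnorm(n_genes * n_lines, mean = 5, sd = 1),
                nrow = n_genes, dimnames = list(gene_ids, line_ids))
    w <- stats::setNames(numeric(n_genes), gene_ids)
    if (is.null(causal_genes)) {
      causal_genes <- if (n_causal > 0) sample(gene_ids, n_causal) else character()
    } else {
      stopifnot(all(causal_genes %in% gene_ids))
    }
    if (length(causal_genes)) {
      raw <- stats::rnorm(length(causal_genes))
      w[causal_genes] <- switch(causal_sign,
        both = raw, positive = abs(raw), negative = -abs(raw))
    }
    intercept <- 2
    y <- intercept + drop(crossprod(x, w)) + stats::rnorm(n_lines, 0, noise_sd)
    names(y) <- line_ids
    list(expression = expr_matrix(x, scale = "log2p1"),
         response = y, weights = w, intercept = intercept)
  })
}
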
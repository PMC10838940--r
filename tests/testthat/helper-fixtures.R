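# shared in-code fixtures

# small deterministic expression matrix
toy_expr <- function(values = NULL, genes = NULL, samples = NULL,
                     scale = "linear") {
  if (is.null(values)) {
    values <- matrix(c(1, 2, 3, 4, 5, 6), nrow = 3)
  }
  if (is.null(genes)) genes <- sprintf("g%02d", seq_len(nrow(values)))
  if (is.null(samples)) samples <- sprintf("s%02d", seq_len(ncol(values)))
  dimnames(values) <- list(genes, samples)
  expr_matrix(values, scale = scale)
}

# random expression matrix under a fixed seed
rand_expr <- function(n_genes, n_samples, seed, scale = "log2p1") {
  withr::with_seed(seed, {
    v <- matrix(rnorm(n_genes * n_samples, 5, 2), nrow = n_genes,
                dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                                sprintf("s%03d", seq_len(n_samples))))
    if (scale == "linear") v <- abs(v)
    expr_matrix(v, scale = scale)
  })
}

# write a temporary delimited expression file
write_expr_file <- function(lines, ext = "tsv") {
  path <- withr::local_tempfile(fileext = paste0(".", ext),
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# independent brute-force single-sample enrichment oracle: literal
# transcription of the running-sum definition, O(N * |S|)
oracle_ssgsea <- function(x, set_genes, alpha, mode) {
  n <- length(x)
  ord <- order(-x, names(x), method = "radix")
  ids <- names(x)[ord]
  in_set <- ids %in% set_genes
  rank_val <- (n - seq_len(n) + 1) / n
  total_in <- sum(abs(rank_val[in_set])^alpha)
  p_in <- p_out <- numeric(n)
  cin <- cout <- 0
  for (i in seq_len(n)) {
    if (in_set[i]) cin <- cin + abs(rank_val[i])^alpha / total_in
    else cout <- cout + 1 / (n - sum(in_set))
    p_in[i] <- cin; p_out[i] <- cout
  }
  d <- p_in - p_out
  if (mode == "sum") return(sum(d))
  dmax <- max(d); dmin <- min(d)
  if (dmax >= -dmin - 1e-12) dmax else dmin
}

# independent brute-force GSEA running-sum oracle
oracle_gsea_es <- function(metric, genes_in_order, set_genes, p = 1) {
  n <- length(metric)
  hit <- genes_in_order %in% set_genes
  nh <- sum(hit)
  wsum <- sum(abs(metric[hit])^p)
  run <- 0; rmax <- -Inf; rmin <- Inf
  for (i in seq_len(n)) {
    if (hit[i]) {
      run <- run + if (p == 0) 1 / nh else abs(metric[i])^p / wsum
    } else {
      run <- run - 1 / (n - nh)
    }
    rmax <- max(rmax, run); rmin <- min(rmin, run)
  }
  if (rmax >= -rmin - 1e-12) rmax else rmin
}

# independent transcription of the moderated-t moment equations
oracle_moderated_t <- function(mat, grp) {
  hi <- mat[, grp == "high", drop = FALSE]
  lo <- mat[, grp == "low", drop = FALSE]
  n1 <- ncol(hi); n2 <- ncol(lo); d <- n1 + n2 - 2
  effect <- rowMeans(hi) - rowMeans(lo)
  s2 <- (apply(hi, 1, var) * (n1 - 1) + apply(lo, 1, var) * (n2 - 1)) / d
  e <- log(s2) - digamma(d / 2) + log(d / 2)
  G <- length(e)
  evar <- mean((e - mean(e))^2 * G / (G - 1)) - trigamma(d / 2)
  if (evar > 0) {
    # invert trigamma by bisection (independent of the package's Newton)
    f <- function(y) trigamma(y) - evar
    lo_y <- 1e-6; hi_y <- 1e8
    for (i in 1:200) {
      mid <- sqrt(lo_y * hi_y)
      if (f(mid) > 0) lo_y <- mid else hi_y <- mid
    }
    d0 <- 2 * sqrt(lo_y * hi_y)
    s0 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
    spost <- (d0 * s0 + d * s2) / (d0 + d)
  } else {
    d0 <- Inf
    s0 <- exp(mean(e))
    spost <- rep(s0, G)
  }
  tstat <- effect / sqrt(spost * (1 / n1 + 1 / n2))
  list(t = tstat, d0 = d0, s0_sq = s0,
       p = 2 * pt(-abs(tstat), df = d0 + d))
}

# rank-based AUC of scores for a binary truth (positive class = TRUE)
rank_auc <- function(score, positive) {
  r <- rank(score)
  n1 <- sum(positive); n0 <- sum(!positive)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
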
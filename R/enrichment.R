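#' Rank genes for GSEA by a group-contrast metric
#'
#' The default metric is signal-to-noise:
#' `(mean_high - mean_low) / (sd_high + sd_low)`, with each group sd floored
#' at `max(floor_frac * |group mean|, floor_abs)` (canonical GSEA convention,
#' both constants 0.2 by default). Genes are ordered by metric, descending;
#' ties are broken by gene id (lexicographic) for determinism.
#'
#' @param m An [expr_matrix()].
#' @param labels `"high"`/`"low"` per sample (vector named by sample id, or a
#'   tibble with sample_id and group columns); each group needs >= 2 samples.
#' @param method `"signal2noise"` or `"moderated_t"`.
#' @param floor_frac,floor_abs Sd flooring constants.
#' @return A `ranked_list` tibble: gene_id, metric (strictly ordered).
#' @export
rank_metric <- function(m, labels, method = c("signal2noise", "moderated_t"),
                        floor_frac = 0.2, floor_abs = 0.2) {
  method <- match.arg(method)
  stopifnot(inherits(m, "expr_matrix"))
  grp <- check_group_labels(labels, colnames(m))
  if (any(table(grp) < 2)) {
    stop("each group needs >= 2 samples for the ranking metric", call. = FALSE)
  }
  v <- unclass(m)
  hi <- v[, grp == "high", drop = FALSE]
  lo <- v[, grp == "low", drop = FALSE]
  metric <- switch(method,
    signal2noise = {
      floor_sd <- function(s, mu) pmax(s, pmax(floor_frac * abs(mu), floor_abs))
      mu_h <- rowMeans(hi); mu_l <- rowMeans(lo)
      s_h <- floor_sd(apply(hi, 1, stats::sd), mu_h)
      s_l <- floor_sd(apply(lo, 1, stats::sd), mu_l)
      (mu_h - mu_l) / (s_h + s_l)
    },
    moderated_t = {
      fit <- moderated_t(v, grp)
      stats::setNames(fit$table$t, fit$table$feature)[rownames(v)]
    }
  )
  ord <- order(-metric, rownames(v), method = "radix")
  out <- tibble::tibble(gene_id = rownames(v)[ord], metric = unname(metric[ord]))
  class(out) <- c("ranked_list", class(out))
  out
}

#' GSEA enrichment score
#'
#' Weighted Kolmogorov-Smirnov running statistic over a ranked gene list:
#' in-set positions add `|metric|^p / sum(in-set |metric|^p)`, out-of-set
#' positions subtract `1/(N - |S|)`; the enrichment score is the running-sum
#' extremum of largest magnitude (an exact magnitude tie resolves to the
#' positive extremum).
#'
#' @param ranked A [rank_metric()] tibble (or any tibble with gene_id and
#'   metric columns, ordered).
#' @param s A [gene_set()], or a character vector of genes.
#' @param p_exponent Weighting exponent, default 1.
#' @return The enrichment score (scalar in `[-1, 1]`), with the full running
#'   sum as attribute `running`.
#' @export
gsea_es <- function(ranked, s, p_exponent = 1) {
  genes <- if (inherits(s, "gene_set")) s$genes else as.character(s)
  stopifnot(is.data.frame(ranked), all(c("gene_id", "metric") %in% names(ranked)))
  hit <- ranked$gene_id %in% genes
  n <- nrow(ranked)
  n_in <- sum(hit)
  if (n_in == 0) stop("no set gene present in the ranked list", call. = FALSE)
  if (n_in == n) stop("set covers the entire ranked list", call. = FALSE)
  w <- abs(ranked$metric)^p_exponent
  w[!hit] <- 0
  tot <- sum(w)
  if (p_exponent > 0 && tot == 0) {
    stop("all in-set metric values are zero with p_exponent > 0", call. = FALSE)
  }
  inc <- if (p_exponent == 0) hit / n_in else w / tot
  dec <- (!hit) / (n - n_in)
  running <- cumsum(inc - dec)
  es <- signed_extremum(running)
  attr(es, "running") <- running
  es
}

# ES for many permuted metrics on a fixed gene universe; metric_mat is
# genes x n_perm with rownames. Returns numeric vector of ES values.
gsea_es_many <- function(metric_mat, genes, p_exponent = 1) {
  ids <- rownames(metric_mat)
  hit0 <- ids %in% genes
  n <- length(ids); n_in <- sum(hit0)
  vapply(seq_len(ncol(metric_mat)), function(k) {
    mt <- metric_mat[, k]
    ord <- order(-mt, ids, method = "radix")
    hit <- hit0[ord]
    w <- abs(mt[ord])^p_exponent
    w[!hit] <- 0
    tot <- sum(w)
    inc <- if (p_exponent == 0 || tot == 0) hit / n_in else w / tot
    signed_extremum(cumsum(inc - (!hit) / (n - n_in)))
  }, numeric(1))
}

#' GSEA with permutation-normalised enrichment score
#'
#' Computes the observed enrichment score from [rank_metric()] + [gsea_es()],
#' builds a null by permuting sample labels (`mode = "phenotype"`) or by
#' drawing random same-size gene sets (`mode = "gene_set"`), and reports
#' `NES = ES / mean(|null ES| of matching sign)` and the nominal
#' `p = (1 + #{same-sign nulls at least as extreme}) / (1 + #same-sign nulls)`.
#' When either group has fewer than 7 samples, phenotype permutation is
#' unreliable and the call falls back to gene-set mode with a warning.
#'
#' @inheritParams rank_metric
#' @param s A [gene_set()].
#' @param n_perm Number of permutations (>= 100).
#' @param mode `"phenotype"` or `"gene_set"`.
#' @param seed Integer seed (required).
#' @param p_exponent Weighting exponent passed to [gsea_es()].
#' @return A `gsea_result`: list with set, es, nes, p_value, n_perm, mode,
#'   seed, null_es.
#' @export
gsea_nes <- function(m, labels, s, n_perm = 1000,
                     mode = c("phenotype", "gene_set"), seed,
                     p_exponent = 1) {
  mode <- match.arg(mode)
  stopifnot(inherits(s, "gene_set"))
  if (n_perm < 100) stop("need n_perm >= 100", call. = FALSE)
  grp <- check_group_labels(labels, colnames(m))
  if (mode == "phenotype" && min(table(grp)) < 7) {
    warning("a group has < 7 samples; falling back to gene_set permutation",
            call. = FALSE)
    mode <- "gene_set"
  }
  ranked <- rank_metric(m, grp)
  es <- as.numeric(gsea_es(ranked, s, p_exponent))

  null_es <- with_local_seed(seed, {
    if (mode == "phenotype") {
      # vectorised signal-to-noise over all label permutations
      v <- unclass(m)
      n <- ncol(v); n_h <- sum(grp == "high"); n_l <- n - n_h
      ind <- vapply(seq_len(n_perm), function(b) {
        x <- numeric(n); x[sample.int(n, n_h)] <- 1; x
      }, numeric(n))
      mu_h <- v %*% ind / n_h
      mu_l <- v %*% (1 - ind) / n_l
      s_h <- sqrt(pmax((v^2 %*% ind - n_h * mu_h^2) / (n_h - 1), 0))
      s_l <- sqrt(pmax((v^2 %*% (1 - ind) - n_l * mu_l^2) / (n_l - 1), 0))
      s_h <- pmax(s_h, pmax(0.2 * abs(mu_h), 0.2))
      s_l <- pmax(s_l, pmax(0.2 * abs(mu_l), 0.2))
      metric_mat <- (mu_h - mu_l) / (s_h + s_l)
      rownames(metric_mat) <- rownames(v)
      gsea_es_many(metric_mat, s$genes, p_exponent)
    } else {
      universe <- ranked$gene_id
      n_in <- sum(universe %in% s$genes)
      vapply(seq_len(n_perm), function(b) {
        as.numeric(gsea_es(ranked, sample(universe, n_in), p_exponent))
      }, numeric(1))
    }
  })

  same_sign <- if (es >= 0) null_es[null_es >= 0] else null_es[null_es < 0]
  if (length(same_sign) == 0) {
    warning("no same-sign permutation ES; NES and p undefined", call. = FALSE)
    nes <- NA_real_; pval <- NA_real_
  } else {
    nes <- es / mean(abs(same_sign))
    pval <- (1 + sum(abs(same_sign) >= abs(es))) / (1 + length(same_sign))
  }
  structure(list(set = s$name, es = es, nes = nes, p_value = pval,
                 n_perm = n_perm, mode = mode, seed = seed,
                 null_es = null_es),
            class = "gsea_result")
}

#' @export
print.gsea_result <- function(x, ...) {
  cat(sprintf("<gsea_result> %s: ES = %.3f, NES = %.3f, p = %.4g (%s, %d perms)\n",
              x$set, x$es, x$nes, x$p_value, x$mode, x$n_perm))
  invisible(x)
}

#' GSVA-style per-set, per-sample scores
#'
#' Single-sample enrichment for every set in a library: exponent 1 on the
#' rank-normalised values and the signed maximum deviation of the running
#' ECDF difference (the statistic the per-set group comparison operates on).
#'
#' @param m An [expr_matrix()] with >= 2 samples.
#' @param lib A [signature_library()].
#' @return A numeric matrix, sets x samples.
#' @export
gsva_like_scores <- function(m, lib) {
  stopifnot(inherits(m, "expr_matrix"), inherits(lib, "signature_library"))
  if (ncol(m) < 2) stop("need >= 2 samples", call. = FALSE)
  rows <- lapply(lib, function(s) {
    ssgsea_score(m, s, alpha = 1, mode = "max_dev")$score
  })
  out <- do.call(rbind, rows)
  dimnames(out) <- list(names(lib), colnames(m))
  out
}

# invert the trigamma function by Newton iteration (monotone decreasing)
trigamma_inverse <- function(x) {
  stopifnot(is.finite(x), x > 0)
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2)
    y <- y + dif
    if (abs(dif) / y < 1e-10) break
  }
  y
}

#' Empirical-Bayes moderated two-group comparison
#'
#' For each feature the two-sample effect (mean high - mean low) and pooled
#' residual variance `s^2` on `d = n1 + n2 - 2` df are computed; the variance
#' prior `(d0, s0^2)` is fit by moment matching on
#' `e = log s^2 - digamma(d/2) + log(d/2)`: `trigamma(d0/2)` is matched to the
#' excess variance of `e` (Newton inversion of the trigamma), and
#' `s0^2 = exp(mean(e) + digamma(d0/2) - log(d0/2))`. Posterior variances
#' `(d0 s0^2 + d s^2)/(d0 + d)` shrink each feature towards the ensemble, and
#' the moderated t has `d0 + d` df. Features with zero variance in both groups
#' are flagged and excluded from the prior fit.
#'
#' @param scores Numeric matrix, features x samples (rownames required), or a
#'   data frame with a `feature` column.
#' @param labels `"high"`/`"low"` per sample; >= 2 samples per group.
#' @param d0 Optional prior-df override: `0` gives the ordinary pooled t,
#'   `Inf` full shrinkage to the common variance; `NULL` (default) estimates
#'   it from the data.
#' @return A `moderated_t_fit`: list with `table` (tibble: feature, effect, t,
#'   df_total, p_value, q_value, flagged), `d0`, `s0_sq`, group sizes.
#' @export
moderated_t <- function(scores, labels, d0 = NULL) {
  if (is.data.frame(scores)) {
    stopifnot("feature" %in% names(scores))
    feats <- scores$feature
    scores <- as.matrix(scores[setdiff(names(scores), "feature")])
    rownames(scores) <- feats
  }
  stopifnot(is.matrix(scores), !is.null(rownames(scores)))
  if (nrow(scores) < 2) {
    stop("moderated comparison needs >= 2 features (variance shrinkage is an ensemble method)",
         call. = FALSE)
  }
  grp <- check_group_labels(labels, colnames(scores))
  n1 <- sum(grp == "high"); n2 <- sum(grp == "low")
  if (n1 < 2 || n2 < 2) stop("each group needs >= 2 samples", call. = FALSE)
  hi <- scores[, grp == "high", drop = FALSE]
  lo <- scores[, grp == "low", drop = FALSE]
  effect <- rowMeans(hi) - rowMeans(lo)
  d <- n1 + n2 - 2
  ss <- (apply(hi, 1, stats::var) * (n1 - 1) + apply(lo, 1, stats::var) * (n2 - 1)) / d
  flagged <- ss == 0
  usable <- which(!flagged)
  if (length(usable) < 2 && is.null(d0)) {
    stop("fewer than 2 features with non-zero variance; cannot fit the prior",
         call. = FALSE)
  }

  if (is.null(d0)) {
    e <- log(ss[usable]) - digamma(d / 2) + log(d / 2)
    ebar <- mean(e)
    G <- length(e)
    evar <- mean((e - ebar)^2 * G / (G - 1)) - trigamma(d / 2)
    if (evar > 0) {
      d0 <- 2 * trigamma_inverse(evar)
      s0_sq <- exp(ebar + digamma(d0 / 2) - log(d0 / 2))
    } else {
      d0 <- Inf
      s0_sq <- exp(ebar)
    }
  } else {
    stopifnot(d0 >= 0)
    s0_sq <- if (d0 == 0) 0 else {
      e <- log(ss[usable]) - digamma(d / 2) + log(d / 2)
      exp(mean(e) + if (is.finite(d0)) digamma(d0 / 2) - log(d0 / 2) else 0)
    }
  }

  s_post <- if (d0 == 0) ss else if (is.infinite(d0)) rep(s0_sq, length(ss)) else
    (d0 * s0_sq + d * ss) / (d0 + d)
  tstat <- effect / sqrt(s_post * (1 / n1 + 1 / n2))
  tstat[flagged] <- NA_real_
  df_total <- d0 + d
  pval <- 2 * stats::pt(-abs(tstat), df = df_total)
  qval <- rep(NA_real_, length(pval))
  ok <- !is.na(pval)
  qval[ok] <- stats::p.adjust(pval[ok], method = "BH")

  structure(list(
    table = tibble::tibble(feature = rownames(scores), effect = unname(effect),
                           t = unname(tstat), df_total = df_total,
                           p_value = unname(pval), q_value = unname(qval),
                           flagged = unname(flagged)),
    d0 = d0, s0_sq = s0_sq, n_high = n1, n_low = n2
  ), class = "moderated_t_fit")
}

#' @export
print.moderated_t_fit <- function(x, ...) {
  cat(sprintf("<moderated_t_fit> %d features, %d high vs %d low; d0 = %s, s0^2 = %.4g\n",
              nrow(x$table), x$n_high, x$n_low, format(x$d0, digits = 4), x$s0_sq))
  print(utils::head(x$table))
  invisible(x)
}

#' Correlation with a formula-level p-value
#'
#' Sample Pearson (or Spearman, on ranks) correlation with the two-sided
#' p-value from `t = r * sqrt((n - 2)/(1 - r^2))` on `n - 2` df.
#'
#' @param x,y Numeric vectors (length >= 3, non-constant).
#' @param method `"pearson"` or `"spearman"`.
#' @return A tibble: estimate, n, statistic, p_value, method.
#' @export
pearson_correlation <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y))
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("need >= 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for constant input", call. = FALSE)
  }
  if (method == "spearman") {
    x <- rank(x); y <- rank(y)
  }
  r <- stats::cor(x, y)
  ct <- correlation_p_from_r(r, n)
  tibble::tibble(estimate = r, n = n, statistic = ct$statistic,
                 p_value = ct$p_value, method = method)
}

#' Two-sided p-value from a correlation coefficient and sample size
#'
#' `t = r * sqrt((n - 2)/(1 - r^2))` referred to the t distribution on
#' `n - 2` df — usable directly on a printed `(r, n)` pair.
#'
#' @param r Correlation coefficient, `|r| < 1`.
#' @param n Number of pairs (>= 3).
#' @return A list with `statistic` and `p_value`.
#' @export
correlation_p_from_r <- function(r, n) {
  stopifnot(abs(r) <= 1, n >= 3)
  if (1 - r^2 <= .Machine$double.eps) {
    return(list(statistic = sign(r) * Inf, p_value = 0))
  }
  tval <- r * sqrt((n - 2) / (1 - r^2))
  list(statistic = tval, p_value = 2 * stats::pt(-abs(tval), df = n - 2))
}

#' Elementary group tests
#'
#' Wraps the standard two-sided tests: Welch or Student t, Mann-Whitney U
#' (exact enumeration up to 20 total observations and no ties, normal
#' approximation with tie correction otherwise), or one-way ANOVA for three
#' or more groups.
#'
#' @param values Numeric vector, one value per sample.
#' @param labels Group label per sample.
#' @param test One of `"welch_t"`, `"student_t"`, `"mann_whitney"`, `"anova"`.
#' @return A tibble: test, statistic, p_value.
#' @export
group_tests <- function(values, labels, test = c("welch_t", "student_t",
                                                 "mann_whitney", "anova")) {
  test <- match.arg(test)
  labels <- as.factor(labels)
  if (any(table(labels) == 0) || nlevels(labels) < 2) {
    stop("need >= 2 non-empty groups", call. = FALSE)
  }
  if (test == "anova") {
    if (nlevels(labels) < 3) {
      stop("ANOVA needs >= 3 groups; use a t-test for two groups", call. = FALSE)
    }
    fit <- summary(stats::aov(values ~ labels))[[1]]
    return(tibble::tibble(test = test, statistic = fit[["F value"]][1],
                          p_value = fit[["Pr(>F)"]][1]))
  }
  if (nlevels(labels) != 2) stop("two-group test needs exactly 2 groups", call. = FALSE)
  g <- split(values, labels)
  res <- switch(test,
    welch_t = stats::t.test(g[[1]], g[[2]], var.equal = FALSE),
    student_t = stats::t.test(g[[1]], g[[2]], var.equal = TRUE),
    mann_whitney = {
      exact <- (length(g[[1]]) + length(g[[2]]) <= 20) && !anyDuplicated(values)
      suppressWarnings(stats::wilcox.test(g[[1]], g[[2]], exact = exact,
                                          correct = !exact))
    }
  )
  tibble::tibble(test = test, statistic = unname(res$statistic),
                 p_value = res$p.value)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Validates the p-values and applies the standard BH step-up procedure
#' (monotone, order-invariant).
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted q-values in the input order.
#' @export
bh_fdr <- function(pvalues) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvalues, method = "BH")
}
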
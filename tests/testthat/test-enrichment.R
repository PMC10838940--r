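make_labeled <- function(n_genes = 20, n_high = 5, n_low = 5, seed = 80,
                         shift_genes = NULL, shift = 0) {
  withr::with_seed(seed, {
    v <- matrix(rnorm(n_genes * (n_high + n_low), 5, 1), nrow = n_genes,
                dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                                sprintf("s%02d", seq_len(n_high + n_low))))
  })
  if (!is.null(shift_genes)) v[shift_genes, seq_len(n_high)] <-
      v[shift_genes, seq_len(n_high)] + shift
  list(m = expr_matrix(v, scale = "log2p1"),
       labels = setNames(rep(c("high", "low"), c(n_high, n_low)), colnames(v)))
}

test_that("signal-to-noise ranking matches the hand formula with sd flooring", {
  d <- make_labeled(5, 3, 3, seed = 81)
  rk <- rank_metric(d$m, d$labels)
  v <- unclass(d$m)
  want <- vapply(rownames(v), function(g) {
    hi <- v[g, 1:3]; lo <- v[g, 4:6]
    sh <- max(sd(hi), 0.2 * abs(mean(hi)), 0.2)
    sl <- max(sd(lo), 0.2 * abs(mean(lo)), 0.2)
    (mean(hi) - mean(lo)) / (sh + sl)
  }, numeric(1))
  expect_equal(setNames(rk$metric, rk$gene_id), sort(want, decreasing = TRUE),
               tolerance = 1e-12)
  # positive metric when a gene is uniformly higher in the high group
  d2 <- make_labeled(5, 3, 3, seed = 81, shift_genes = "g001", shift = 10)
  rk2 <- rank_metric(d2$m, d2$labels)
  expect_equal(rk2$gene_id[1], "g001")
  expect_gt(rk2$metric[1], 0)
  # tie rule: identical rows rank adjacently in lexicographic order
  v3 <- unclass(d$m); v3["g002", ] <- v3["g001", ]
  rk3 <- rank_metric(expr_matrix(v3, scale = "log2p1"), d$labels)
  pos <- match(c("g001", "g002"), rk3$gene_id)
  expect_equal(diff(pos), 1L)
  expect_error(rank_metric(d$m, setNames(rep(c("high", "low"), c(1, 5)),
                                         colnames(d$m))), ">= 2 samples")
})

test_that("GSEA ES matches worked examples and the exhaustive oracle", {
  # top-3 and bottom-3 of 10 with exponent 0 give +-1
  rl <- tibble::tibble(gene_id = LETTERS[1:10], metric = 10:1)
  expect_equal(as.numeric(gsea_es(rl, LETTERS[1:3], p_exponent = 0)), 1)
  expect_equal(as.numeric(gsea_es(rl, LETTERS[8:10], p_exponent = 0)), -1)

  # metrics (5,4,3,2,1), set {A, C}, p = 1: running max after C = 5/8 - 1/3 + 3/8
  rl2 <- tibble::tibble(gene_id = LETTERS[1:5], metric = 5:1)
  expect_equal(as.numeric(gsea_es(rl2, c("A", "C"))), 5 / 8 - 1 / 3 + 3 / 8)
  expect_equal(as.numeric(gsea_es(rl2, c("A", "C"))), 2 / 3)

  # exhaustive enumeration: every subset of size <= 4 of a 10-gene list
  withr::with_seed(82, rl3 <- tibble::tibble(gene_id = paste0("g", 1:10),
                                             metric = sort(rnorm(10), decreasing = TRUE)))
  subsets <- unlist(lapply(1:4, function(k) {
    combn(rl3$gene_id, k, simplify = FALSE)
  }), recursive = FALSE)
  for (p in c(0, 1)) {
    got <- vapply(subsets, function(g) as.numeric(gsea_es(rl3, g, p)), numeric(1))
    want <- vapply(subsets, function(g) {
      oracle_gsea_es(rl3$metric, rl3$gene_id, g, p)
    }, numeric(1))
    expect_equal(got, want, tolerance = 1e-12)
  }

  expect_error(gsea_es(rl2, c("zz")), "no set gene")
  expect_error(gsea_es(rl2, LETTERS[1:5]), "entire")
  rl0 <- tibble::tibble(gene_id = LETTERS[1:4], metric = c(0, 0, 0, 1))
  expect_error(gsea_es(rl0, c("A", "B")), "zero")
})

test_that("NES detects a strong real effect and is seed-deterministic", {
  d <- make_labeled(30, 8, 8, seed = 83,
                    shift_genes = sprintf("g%03d", 1:5), shift = 6)
  s <- gene_set("up", sprintf("g%03d", 1:5))
  res <- gsea_nes(d$m, d$labels, s, n_perm = 199, seed = 7)
  expect_gt(res$nes, 0)
  expect_gt(res$es, 0)
  expect_lt(res$p_value, 0.05)
  # a set sitting perfectly on top beats every random same-size set:
  # nominal p attains the +1 permutation bound
  resg <- gsea_nes(d$m, d$labels, s, n_perm = 199, mode = "gene_set", seed = 7)
  expect_equal(resg$p_value, 1 / (1 + sum(resg$null_es >= 0)))
  expect_equal(sum(abs(resg$null_es[resg$null_es >= 0]) >= abs(resg$es)), 0)
  # identical seed reproduces the whole object
  res2 <- gsea_nes(d$m, d$labels, s, n_perm = 199, seed = 7)
  expect_identical(res, res2)
  # sign invariant: NES carries the sign of ES
  expect_equal(sign(res$nes), sign(res$es))
  # unseeded calls are an error
  expect_error(gsea_nes(d$m, d$labels, s, n_perm = 199), "seed")
  # small groups fall back to gene_set mode
  dsmall <- make_labeled(30, 3, 13, seed = 84)
  expect_warning(r3 <- gsea_nes(dsmall$m, dsmall$labels,
                                gene_set("s", sprintf("g%03d", 1:5)),
                                n_perm = 100, seed = 1), "falling back")
  expect_equal(r3$mode, "gene_set")
})

test_that("GSVA-style scores match brute force and respect sample identity", {
  m <- rand_expr(12, 4, seed = 85)
  lib <- signature_library(list(
    gene_set("s1", c("g001", "g004", "g007")),
    gene_set("s2", c("g002", "g003")),
    gene_set("s3", c("g005", "g006", "g008", "g011"))
  ))
  sv <- gsva_like_scores(m, lib)
  expect_equal(dim(sv), c(3L, 4L))
  for (k in seq_along(lib)) {
    for (j in 1:4) {
      want <- oracle_ssgsea(setNames(unclass(m)[, j], rownames(m)),
                            lib[[k]]$genes, 1, "max_dev")
      expect_equal(sv[k, j], want, tolerance = 1e-12)
    }
  }
  # identical samples get identical columns
  v <- unclass(m); v[, 2] <- v[, 1]
  sv2 <- gsva_like_scores(expr_matrix(v, scale = "log2p1"), lib)
  expect_equal(sv2[, 1], sv2[, 2])
  # a set concentrated at the top of one sample peaks in that sample
  v3 <- unclass(m)
  v3[c("g002", "g003"), 3] <- max(v3) + c(2, 1)
  sv3 <- gsva_like_scores(expr_matrix(v3, scale = "log2p1"), lib)
  expect_equal(which.max(sv3["s2", ]), 3L, ignore_attr = TRUE)
  expect_error(gsva_like_scores(m[, 1, drop = FALSE], lib), "2 samples")
})

test_that("moderated t matches the formula oracle and its limiting cases", {
  withr::with_seed(86, {
    mat <- matrix(rnorm(50 * 12, 0, rep(sqrt(rchisq(50, 3) / 3), 12)),
                  nrow = 50, dimnames = list(paste0("f", 1:50), paste0("s", 1:12)))
  })
  grp <- setNames(rep(c("high", "low"), each = 6), colnames(mat))
  fit <- moderated_t(mat, grp)
  orc <- oracle_moderated_t(mat, factor(rep(c("high", "low"), each = 6),
                                        c("high", "low")))
  expect_equal(fit$d0, orc$d0, tolerance = 1e-6)
  expect_equal(fit$s0_sq, orc$s0_sq, tolerance = 1e-6)
  expect_equal(fit$table$t, unname(orc$t), tolerance = 1e-8)
  expect_equal(fit$table$p_value, unname(orc$p), tolerance = 1e-8)
  expect_equal(fit$table$q_value, unname(bh_fdr(orc$p)), tolerance = 1e-8)

  # d0 = 0 reproduces the ordinary pooled two-sample t
  fit0 <- moderated_t(mat, grp, d0 = 0)
  plain <- apply(mat, 1, function(r) {
    unname(t.test(r[1:6], r[7:12], var.equal = TRUE)$statistic)
  })
  expect_equal(fit0$table$t, unname(plain), tolerance = 1e-10)

  # identical per-feature variances drive d0 to infinity (common variance)
  const <- matrix(rep(c(1, 2, 3, 4, 2, 3, 1, 4, 3, 2, 4, 1), each = 5),
                  nrow = 5, byrow = FALSE,
                  dimnames = list(paste0("f", 1:5), paste0("s", 1:12)))
  fitc <- moderated_t(const + outer(1:5, rep(0, 12)), grp)
  expect_true(is.infinite(fitc$d0))

  # zero-variance features flagged, excluded from the fit
  mat2 <- rbind(mat, flat = rep(c(3, 3), each = 6))
  fit2 <- moderated_t(mat2, grp)
  expect_true(fit2$table$flagged[51])
  expect_true(is.na(fit2$table$t[51]))
  expect_equal(fit2$d0, fit$d0, tolerance = 1e-10)

  expect_error(moderated_t(mat[1, , drop = FALSE], grp), "2 features")
})

test_that("moderated t agrees with the established empirical-Bayes implementation", {
  withr::with_seed(87, {
    mat <- matrix(rnorm(40 * 10, 0, rep(sqrt(rchisq(40, 4) / 4), 10)),
                  nrow = 40,
                  dimnames = list(paste0("f", 1:40), paste0("s", 1:10)))
  })
  grp <- setNames(rep(c("high", "low"), each = 5), colnames(mat))
  fit <- moderated_t(mat, grp)
  design <- cbind(1, as.integer(grp == "high"))
  lfit <- limma::eBayes(limma::lmFit(mat, design))
  expect_equal(fit$d0, lfit$df.prior, tolerance = 1e-4)
  expect_equal(fit$s0_sq, lfit$s2.prior, tolerance = 1e-4)
  expect_equal(fit$table$t, unname(lfit$t[, 2]), tolerance = 1e-6)
  expect_equal(fit$table$p_value, unname(lfit$p.value[, 2]), tolerance = 1e-6)
})

test_that("correlation p-values match the t-transform oracle and cor.test", {
  r <- pearson_correlation(c(1, 2, 3), c(3, 2, 1))
  expect_equal(r$estimate, -1)

  withr::with_seed(88, { x <- rnorm(10); y <- x + rnorm(10) })
  got <- pearson_correlation(x, y)
  ct <- cor.test(x, y)
  expect_equal(got$estimate, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(got$p_value, ct$p.value, tolerance = 1e-12)
  # independent formula-level recomputation
  tt <- got$estimate * sqrt(8 / (1 - got$estimate^2))
  expect_equal(got$p_value, 2 * pt(-abs(tt), 8), tolerance = 1e-12)

  sp <- pearson_correlation(x, y, method = "spearman")
  expect_equal(sp$estimate, unname(cor(x, y, method = "spearman")),
               tolerance = 1e-12)

  expect_error(pearson_correlation(c(1, 2), c(1, 2)), "3 complete")
  expect_error(pearson_correlation(rep(1, 5), 1:5), "constant")
})

test_that("group tests cover exact Mann-Whitney, t and ANOVA", {
  # completely separated n = 4/4: exact two-sided p = 2/70
  sep <- group_tests(c(1, 2, 3, 4, 10, 11, 12, 13),
                     rep(c("a", "b"), each = 4), "mann_whitney")
  expect_equal(sep$p_value, 2 / 70)
  # identical groups: p = 1
  idn <- group_tests(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3),
                     "mann_whitney")
  expect_equal(idn$p_value, 1)

  # student t against the closed form
  x1 <- c(1, 2, 3, 4); x2 <- c(3, 5, 5, 7)
  st <- group_tests(c(x1, x2), rep(c("a", "b"), each = 4), "student_t")
  sp2 <- (var(x1) * 3 + var(x2) * 3) / 6
  tref <- (mean(x1) - mean(x2)) / sqrt(sp2 * (1 / 4 + 1 / 4))
  expect_equal(st$statistic, tref, tolerance = 1e-12)
  expect_equal(st$p_value, 2 * pt(-abs(tref), 6), tolerance = 1e-12)

  an <- group_tests(c(1, 2, 5, 6, 9, 10), rep(c("a", "b", "c"), each = 2),
                    "anova")
  expect_lt(an$p_value, 0.05)
  expect_error(group_tests(1:4, rep(c("a", "b"), 2), "anova"), "t-test")
  expect_error(group_tests(1:3, c("a", "a", "a"), "welch_t"), "2 non-empty")
})

test_that("BH adjustment matches manual step-up and is order-invariant", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(1, 4)), rep(1, 4))
  p <- c(0.001, 0.2, 0.04, 0.9, 0.015)
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(bh_fdr(p)[perm], bh_fdr(p[perm]))
  expect_true(all(diff(sort(bh_fdr(p))[order(sort(p))]) >= -1e-15))
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})
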
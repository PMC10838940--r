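test_that("marker-mean score is the arithmetic mean of log2 marker expression", {
  m <- toy_expr(matrix(c(2, 4, 7, 3, 3, 9), nrow = 3),
                genes = c("A", "B", "X"), scale = "log2p1")
  sc <- marker_mean_score(m, gene_set("mk", c("A", "B")))
  expect_equal(sc$score, c(3, 3))
  # all markers equal to c in a sample -> score = c
  expect_equal(sc$score[2], 3)
  # linear input is transformed with a warning
  ml <- toy_expr(matrix(c(7, 7, 1), nrow = 3), genes = c("A", "B", "X"))
  expect_warning(sc2 <- marker_mean_score(ml, gene_set("mk", c("A", "B"))),
                 "log2")
  expect_equal(sc2$score, 3)
  expect_error(suppressWarnings(marker_mean_score(ml, gene_set("mk", "ZZ"))),
               "no gene")
})

test_that("ssgsea hits extremes when the set occupies the top or bottom ranks", {
  v <- matrix(c(10, 9, 8, 4, 3, 2, 1, 0.5, 0.2, 0.1), ncol = 1)
  m <- toy_expr(v, genes = sprintf("g%02d", 1:10), samples = "s1",
                scale = "log2p1")
  top <- gene_set("top", c("g01", "g02", "g03"))
  bot <- gene_set("bot", c("g08", "g09", "g10"))
  expect_equal(ssgsea_score(m, top, alpha = 0, mode = "max_dev")$score, 1)
  expect_equal(ssgsea_score(m, bot, alpha = 0, mode = "max_dev")$score, -1)
  expect_error(ssgsea_score(m, gene_set("none", c("zz", "yy")), 0, "sum"),
               "no gene")
  expect_error(ssgsea_score(m, gene_set("one", c("g01", "zz")), 0, "sum"),
               "at least 2")
})

test_that("ssgsea matches the brute-force running-sum oracle", {
  m <- rand_expr(10, 4, seed = 21)
  s <- gene_set("s3", c("g002", "g005", "g009"))
  for (mode in c("sum", "max_dev")) {
    got <- ssgsea_score(m, s, alpha = 0.25, mode = mode)$score
    want <- vapply(seq_len(ncol(m)), function(j) {
      oracle_ssgsea(setNames(unclass(m)[, j], rownames(m)), s$genes, 0.25, mode)
    }, numeric(1))
    expect_equal(got, want, tolerance = 1e-12)
  }

  # exhaustive: all sets of size <= 5 over 12-gene samples
  m12 <- rand_expr(12, 2, seed = 22)
  x1 <- setNames(unclass(m12)[, 1], rownames(m12))
  sets <- unlist(lapply(2:5, function(k) {
    combn(rownames(m12), k, simplify = FALSE)
  }), recursive = FALSE)
  got <- vapply(sets, function(g) {
    ssgsea_score(m12, gene_set("s", g), alpha = 1, mode = "max_dev")$score[1]
  }, numeric(1))
  want <- vapply(sets, function(g) oracle_ssgsea(x1, g, 1, "max_dev"), numeric(1))
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("ssgsea with alpha 0 is rank-only: invariant under monotone transforms", {
  m <- rand_expr(40, 3, seed = 30, scale = "linear")
  s <- gene_set("s", sample(rownames(m), 8))
  base <- ssgsea_score(m, s, alpha = 0, mode = "sum")$score
  warped <- expr_matrix(unclass(m)^3 + 1, scale = "linear")
  expect_equal(ssgsea_score(warped, s, alpha = 0, mode = "sum")$score, base)
  logged <- log_transform(m, 1)
  expect_equal(ssgsea_score(logged, s, alpha = 0, mode = "sum")$score, base)
})

test_that("stromal/immune scores behave like independent set enrichments", {
  # stromal genes globally top-expressed: the true labeling maximises the score
  withr::with_seed(40, {
    v <- matrix(runif(8, 1, 2), ncol = 1)
    v[1:3] <- c(9, 8, 7)
  })
  m <- toy_expr(v, genes = sprintf("g%d", 1:8), samples = "s1", scale = "log2p1")
  true_set <- c("g1", "g2", "g3")
  perms <- combn(sprintf("g%d", 1:8), 3, simplify = FALSE)
  scores <- vapply(perms, function(g) {
    ssgsea_score(m, gene_set("s", g), alpha = 0.25, mode = "sum")$score
  }, numeric(1))
  truth_idx <- which(vapply(perms, function(g) setequal(g, true_set), logical(1)))
  expect_equal(scores[truth_idx], max(scores))

  # disjoint sets on independent data are uncorrelated
  m2 <- rand_expr(60, 200, seed = 41)
  est <- estimate_like_scores(m2, gene_set("str", sprintf("g%03d", 1:8)),
                              gene_set("imm", sprintf("g%03d", 31:38)))
  expect_lt(abs(cor(est$stromal_score, est$immune_score)), 0.2)
  expect_error(estimate_like_scores(m2, gene_set("str", sprintf("g%03d", 1:8)),
                                    gene_set("imm", c("zz", "yy"))), "no gene")
})

test_that("nnls deconvolution recovers exact mixtures and clips negatives", {
  withr::with_seed(50, {
    r <- matrix(abs(rnorm(40, 5, 2)), ncol = 2,
                dimnames = list(sprintf("g%02d", 1:20), c("Tumor", "Fibroblast")))
  })
  ref <- decon_reference(r)
  x <- 0.3 * r[, 1] + 0.7 * r[, 2]
  m <- toy_expr(matrix(x, ncol = 1), genes = rownames(r), samples = "s1")
  dec <- nnls_deconvolution(m, ref)
  expect_equal(dec$fraction, c(0.3, 0.7), tolerance = 1e-8)

  # negative OLS solution gets clipped to zero (oracle: active-set enumeration
  # on the 2-type problem — NNLS solution is the best feasible sign pattern)
  r2 <- matrix(c(2, 1, 1, 2), ncol = 2,
               dimnames = list(c("a", "b"), c("T1", "T2")))
  x2 <- c(2, 0)
  ols <- drop(solve(crossprod(r2), crossprod(r2, x2)))
  cand <- list(
    both = pmax(ols, 0),
    only1 = c(sum(r2[, 1] * x2) / sum(r2[, 1]^2), 0),
    only2 = c(0, sum(r2[, 2] * x2) / sum(r2[, 2]^2))
  )
  rss <- vapply(cand, function(f) sum((x2 - r2 %*% f)^2), numeric(1))
  best <- cand[[which.min(rss)]]
  m2 <- toy_expr(matrix(x2, ncol = 1), genes = rownames(r2), samples = "s1")
  dec2 <- nnls_deconvolution(m2, r2)
  expect_true(any(ols < 0))           # the unconstrained fit would go negative
  expect_true(all(dec2$coef >= 0))
  expect_equal(dec2$coef, unname(best), tolerance = 1e-8)
  # nnls residual no worse than the clipped-OLS residual
  expect_lte(sum((x2 - r2 %*% dec2$coef)^2),
             sum((x2 - r2 %*% pmax(ols, 0))^2) + 1e-12)

  # errors
  tiny <- toy_expr(matrix(1, ncol = 1), genes = "g01", samples = "s1")
  expect_error(nnls_deconvolution(tiny, ref), "shared gene")
  rr <- matrix(c(1, 2, 2, 4), ncol = 2,
               dimnames = list(c("a", "b"), c("T1", "T2")))
  mm <- toy_expr(matrix(c(1, 2), ncol = 1), genes = c("a", "b"), samples = "s1")
  expect_error(nnls_deconvolution(mm, rr), "rank-deficient")
  mz <- toy_expr(matrix(c(0, 0), ncol = 1), genes = rownames(r2), samples = "s1")
  expect_error(nnls_deconvolution(mz, r2), "all-zero")
})

test_that("CAF composite stacks z-scored markers and abundance features", {
  co <- simulate_cohort(sim_config(n_samples = 20, n_genes = 200), seed = 60)
  lg <- log_transform(co$expression)
  ab <- marker_mean_score(lg, co$memberships$caf_markers)
  names(ab)[2] <- "Fibroblast_marker"
  ab$Fibroblast_enrich <- ssgsea_score(lg, co$memberships$caf_markers,
                                       0.25, "sum")$score
  ab$Fibroblast_decon <- dplyr::filter(
    nnls_deconvolution(co$expression, decon_reference(co$profiles)),
    cell_type == "Fibroblast")$fraction
  comp <- build_caf_composite(lg, co$memberships$caf_markers, ab)
  expect_equal(nrow(comp), 13)  # 10 markers + 3 estimators
  expect_equal(ncol(comp), 20)
  expect_lt(max(abs(rowMeans(comp))), 1e-12)

  # constant abundance row dropped with warning
  ab$Fibroblast_flat <- 1
  expect_warning(comp2 <- build_caf_composite(lg, co$memberships$caf_markers, ab),
                 "Fibroblast_flat")
  expect_equal(nrow(comp2), 13)

  # single sample: z-score undefined
  one <- lg[, 1, drop = FALSE]
  expect_error(build_caf_composite(one, co$memberships$caf_markers,
                                   ab[1, , drop = FALSE]), "2 samples")
})

test_that("infiltration clustering recovers separable blocks and labels them", {
  comp <- matrix(c(rep(1, 5 * 6), rep(-1, 5 * 6)) + 0.01 * rep(1:5, 12),
                 nrow = 5,
                 dimnames = list(paste0("f", 1:5), paste0("s", 1:12)))
  lab <- cluster_infiltration(comp)
  expect_equal(lab$labels$group, c(rep("high", 6), rep("low", 6)))
  # post-condition: mean composite strictly higher in the high group
  cm <- colMeans(comp)
  expect_gt(mean(cm[lab$labels$group == "high"]),
            mean(cm[lab$labels$group == "low"]))
  expect_error(cluster_infiltration(comp, k = 13), "exceeds")

  # identical columns: arbitrary but deterministic, with a warning
  flat <- matrix(1, nrow = 3, ncol = 4,
                 dimnames = list(paste0("f", 1:3), paste0("s", 1:4)))
  expect_warning(lab2 <- cluster_infiltration(flat), "identical")
  expect_warning(lab3 <- cluster_infiltration(flat), "identical")
  expect_identical(lab2$labels, lab3$labels)
})

test_that("external abundance import round-trips and flags sample mismatches", {
  tab <- tibble::tibble(sample_id = c("s01", "s02"), AbsoluteImmune = c(1.5, 0.3))
  p <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tab, p)
  got <- import_external_abundance(p)
  expect_equal(as.data.frame(got), as.data.frame(tab), ignore_attr = TRUE)
  expect_equal(attr(got, "method"), "external")

  m <- toy_expr(samples = c("s01", "s03"), genes = c("a", "b", "c"))
  expect_warning(import_external_abundance(p, m), "s03")

  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines("sample_id,AbsoluteImmune", empty)
  expect_error(import_external_abundance(empty), "no rows")
})
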
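#' Fit a ridge-regression expression-to-response transfer model
#'
#' Trains, on cell-line expression, the predictor later transferred to bulk
#' tumours: genes are standardised on the training set (mean 0, sd 1, n - 1
#' denominator; genes with sd < 1e-8 dropped), the response is centred, and
#' the closed-form ridge solution `(X'X + lambda I)^-1 X'y` is computed for
#' the cross-validation-selected `lambda` (minimum mean squared error over the
#' grid, fixed fold assignment from the seed).
#'
#' @param train_expr A genes x lines [expr_matrix()].
#' @param response Named numeric response (e.g. log-IC50) per training line.
#' @param lambda_grid Candidate regularisation strengths; default logarithmic
#'   `10^-2 ... 10^4`, 13 points.
#' @param cv_folds Number of CV folds (>= 2; must not exceed the line count).
#' @param seed Integer seed for the fold assignment.
#' @param drug Drug name carried into the model.
#' @return A `drug_model`: gene weights (standardised space), intercept, gene
#'   means/sds, chosen lambda, CV table and training summary.
#' @export
fit_ridge_transfer <- function(train_expr, response,
                               lambda_grid = 10^seq(-2, 4, length.out = 13),
                               cv_folds = 5, seed, drug = "drug") {
  stopifnot(inherits(train_expr, "expr_matrix"))
  if (length(lambda_grid) == 0) stop("`lambda_grid` is empty", call. = FALSE)
  if (any(lambda_grid < 0)) stop("lambda must be >= 0", call. = FALSE)
  x <- t(unclass(train_expr))  # lines x genes
  if (!is.null(names(response))) {
    stopifnot(all(rownames(x) %in% names(response)))
    response <- response[rownames(x)]
  }
  stopifnot(length(response) == nrow(x))
  if (stats::sd(response) == 0) stop("constant response", call. = FALSE)
  n <- nrow(x)
  if (n < cv_folds) stop("need at least `cv_folds` training lines", call. = FALSE)

  sds <- apply(x, 2, stats::sd)
  keep <- sds >= 1e-8
  if (!all(keep)) {
    message(sprintf("dropped %d low-variance gene(s)", sum(!keep)))
  }
  x <- x[, keep, drop = FALSE]
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  xs <- sweep(sweep(x, 2, mu), 2, sdv, "/")
  ybar <- mean(response)
  yc <- response - ybar

  ridge_solve <- function(xm, yv, lambda) {
    p <- ncol(xm)
    solve(crossprod(xm) + lambda * diag(p), crossprod(xm, yv))
  }

  folds <- with_local_seed(seed, sample(rep_len(seq_len(cv_folds), n)))
  cv_mse <- vapply(lambda_grid, function(lambda) {
    errs <- vapply(seq_len(cv_folds), function(k) {
      tr <- folds != k
      b <- ridge_solve(xs[tr, , drop = FALSE], yc[tr], lambda)
      pred <- drop(xs[!tr, , drop = FALSE] %*% b)
      mean((yc[!tr] - pred)^2)
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  lambda <- lambda_grid[which.min(cv_mse)]
  beta <- drop(ridge_solve(xs, yc, lambda))
  names(beta) <- colnames(xs)

  structure(list(
    drug = drug,
    weights = beta,
    intercept = ybar,
    gene_means = mu, gene_sds = sdv,
    lambda = lambda,
    cv = tibble::tibble(lambda = lambda_grid, cv_mse = cv_mse),
    n_lines = n, n_genes = ncol(xs), seed = seed
  ), class = "drug_model")
}

#' @export
print.drug_model <- function(x, ...) {
  cat(sprintf("<drug_model> %s: %d genes, %d lines, lambda = %.4g (CV MSE %.4g)\n",
              x$drug, x$n_genes, x$n_lines, x$lambda,
              min(x$cv$cv_mse)))
  invisible(x)
}

#' Predict drug-sensitivity scores for a cohort
#'
#' Applies a fitted [fit_ridge_transfer()] model to cohort expression:
#' `score = intercept + sum(weight * (x - mean)/sd)` per sample. Model genes
#' absent from the cohort are imputed at the training mean (contributing zero
#' after standardisation) with a message. Lower scores indicate higher drug
#' sensitivity.
#'
#' @param model A `drug_model`.
#' @param cohort An [expr_matrix()] on a scale comparable to the training
#'   expression.
#' @return A tibble: sample_id, drug, score; attribute
#'   `orientation = "lower_is_sensitive"`.
#' @export
predict_sensitivity <- function(model, cohort) {
  stopifnot(inherits(model, "drug_model"), inherits(cohort, "expr_matrix"))
  genes <- names(model$weights)
  present <- intersect(genes, rownames(cohort))
  if (length(present) == 0) {
    stop("no model gene present in the cohort", call. = FALSE)
  }
  if (length(present) < length(genes)) {
    message(sprintf("%d of %d model gene(s) absent; imputed at training mean",
                    length(genes) - length(present), length(genes)))
  }
  v <- matrix(rep(model$gene_means, ncol(cohort)), nrow = length(genes),
              dimnames = list(genes, colnames(cohort)))
  v[present, ] <- unclass(cohort)[present, , drop = FALSE]
  xs <- (v - model$gene_means) / model$gene_sds
  scores <- model$intercept + drop(crossprod(xs, model$weights))
  out <- tibble::tibble(sample_id = colnames(cohort), drug = model$drug,
                        score = unname(scores))
  attr(out, "orientation") <- "lower_is_sensitive"
  out
}

#' Compare predicted drug sensitivity between infiltration groups
#'
#' Per drug, `logFC = mean(high) - mean(low)` of the predicted scores
#' (log-scale responses assumed); inference across drugs uses the
#' empirical-Bayes [moderated_t()]. Because lower scores mean higher
#' sensitivity, a positive logFC is reported as "more resistant" in the
#' high-infiltration group.
#'
#' @param table Long tibble from [predict_sensitivity()] (columns sample_id,
#'   drug, score), possibly row-bound over drugs.
#' @param labels `"high"`/`"low"` per sample.
#' @return A tibble: drug, logFC, t, p_value, q_value, direction.
#' @export
compare_sensitivity <- function(table, labels) {
  stopifnot(is.data.frame(table),
            all(c("sample_id", "drug", "score") %in% names(table)))
  wide <- tidyr::pivot_wider(table, id_cols = "drug", names_from = "sample_id",
                             values_from = "score")
  mat <- as.matrix(wide[setdiff(names(wide), "drug")])
  rownames(mat) <- wide$drug
  grp <- check_group_labels(labels, colnames(mat))
  if (nrow(mat) == 1) {
    warning("single drug: falling back to an ordinary Student t-test", call. = FALSE)
    hi <- mat[1, grp == "high"]; lo <- mat[1, grp == "low"]
    tt <- stats::t.test(hi, lo, var.equal = TRUE)
    out <- tibble::tibble(drug = rownames(mat), logFC = mean(hi) - mean(lo),
                          t = unname(tt$statistic), p_value = tt$p.value,
                          q_value = tt$p.value)
  } else {
    fit <- moderated_t(mat, grp)
    out <- dplyr::transmute(fit$table, drug = .data$feature,
                            logFC = .data$effect, t = .data$t,
                            p_value = .data$p_value, q_value = .data$q_value)
  }
  out$direction <- ifelse(out$logFC > 0, "more_resistant_in_high",
                          ifelse(out$logFC < 0, "more_sensitive_in_high", "no_change"))
  out
}
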
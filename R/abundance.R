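#' Marker-mean fibroblast abundance score
#'
#' The simplest abundance estimator: the arithmetic mean of log2 expression
#' over the marker genes present in the matrix, one score per sample.
#'
#' @param m An [expr_matrix()]; linear input is log2(x+1)-transformed with a
#'   warning.
#' @param markers A [gene_set()] of marker genes (at least one present).
#' @return A tibble: sample_id, score; attribute `missing_markers` lists
#'   absent genes.
#' @export
marker_mean_score <- function(m, markers) {
  m <- ensure_log2(m, "marker_mean_score")
  al <- align_genes(m, markers)
  out <- tibble::tibble(
    sample_id = colnames(m),
    score = unname(colMeans(unclass(al$matrix)))
  )
  attr(out, "missing_markers") <- al$missing
  out
}

# core single-sample enrichment on one pre-sorted sample vector.
# x: named expression values for one sample (all genes).
ssgsea_one <- function(x, set_genes, alpha, mode) {
  n <- length(x)
  ord <- order(-x, names(x), method = "radix")
  ranked_genes <- names(x)[ord]
  hit <- ranked_genes %in% set_genes
  n_in <- sum(hit)
  # rank-normalized value: top gene -> 1, bottom -> 1/N
  rnorm_val <- (n - seq_len(n) + 1) / n
  w <- abs(rnorm_val)^alpha
  w[!hit] <- 0
  p_in <- cumsum(w) / sum(w)
  p_out <- cumsum(!hit) / (n - n_in)
  d <- p_in - p_out
  if (mode == "sum") sum(d) else signed_extremum(d)
}

# signed extremum of largest magnitude; ties (to within float noise) resolved
# toward the positive deviation for determinism
signed_extremum <- function(d, tol = 1e-12) {
  dmax <- max(d); dmin <- min(d)
  if (dmax >= -dmin - tol) dmax else dmin
}

#' Single-sample gene-set enrichment score
#'
#' Rank-based weighted ECDF difference, one score per sample. Genes are ranked
#' by expression (descending; ties broken by gene id, lexicographic). In-set
#' positions accumulate weight `|rank-normalized value|^alpha` (normalised by
#' the total in-set weight); out-of-set positions accumulate `1/(N - |S|)`.
#' With `mode = "sum"` the score is the sum over positions of the ECDF
#' difference (the ssGSEA/stromal-immune convention); with `mode = "max_dev"`
#' it is the signed extremum of the running difference (the GSVA-style
#' convention; an exact magnitude tie between the positive and negative
#' extremum resolves to the positive one).
#'
#' @param m An [expr_matrix()].
#' @param s A [gene_set()]; at least 2 set genes must be present and at least
#'   one gene must fall outside the set.
#' @param alpha Rank-weight exponent, >= 0.
#' @param mode `"sum"` or `"max_dev"`.
#' @return A tibble: sample_id, score.
#' @export
ssgsea_score <- function(m, s, alpha = 0.25, mode = c("sum", "max_dev")) {
  mode <- match.arg(mode)
  stopifnot(inherits(m, "expr_matrix"), inherits(s, "gene_set"))
  if (alpha < 0) stop("`alpha` must be >= 0", call. = FALSE)
  present <- intersect(s$genes, rownames(m))
  if (length(present) == 0) {
    stop(sprintf("no gene of set '%s' present in the matrix", s$name), call. = FALSE)
  }
  if (length(present) < 2) {
    stop(sprintf("set '%s': need at least 2 set genes present", s$name), call. = FALSE)
  }
  if (length(present) >= nrow(m)) {
    stop(sprintf("set '%s' covers the whole matrix; need out-of-set genes", s$name),
         call. = FALSE)
  }
  v <- unclass(m)
  scores <- vapply(seq_len(ncol(v)), function(j) {
    x <- stats::setNames(v[, j], rownames(v))
    ssgsea_one(x, present, alpha, mode)
  }, numeric(1))
  tibble::tibble(sample_id = colnames(m), score = scores)
}

#' Stromal and immune enrichment scores
#'
#' Per-sample stromal and immune content scores: single-sample enrichment
#' with exponent 0.25 and the summed-ECDF-difference statistic on each
#' signature (the formulation used by bulk stromal/immune scoring tools).
#'
#' @param m An [expr_matrix()].
#' @param stromal_set,immune_set [gene_set()]s.
#' @return A tibble: sample_id, stromal_score, immune_score.
#' @export
estimate_like_scores <- function(m, stromal_set, immune_set) {
  s <- ssgsea_score(m, stromal_set, alpha = 0.25, mode = "sum")
  i <- ssgsea_score(m, immune_set, alpha = 0.25, mode = "sum")
  tibble::tibble(sample_id = s$sample_id,
                 stromal_score = s$score,
                 immune_score = i$score)
}

#' Deconvolution reference
#'
#' Non-negative reference expression profiles (genes x cell types) for
#' constrained least-squares deconvolution.
#'
#' @param profiles Non-negative numeric matrix with gene rownames and >= 2
#'   cell-type colnames; no all-zero column.
#' @return A `decon_reference`.
#' @export
decon_reference <- function(profiles) {
  stopifnot(is.matrix(profiles), is.numeric(profiles))
  if (is.null(rownames(profiles)) || is.null(colnames(profiles))) {
    stop("reference needs gene rownames and cell-type colnames", call. = FALSE)
  }
  if (ncol(profiles) < 2) stop("reference needs >= 2 cell types", call. = FALSE)
  if (any(profiles < 0) || !all(is.finite(profiles))) {
    stop("reference profiles must be finite and non-negative", call. = FALSE)
  }
  if (any(colSums(profiles) == 0)) stop("reference has an all-zero column", call. = FALSE)
  structure(profiles, class = c("decon_reference", "matrix", "array"))
}

#' Non-negative least-squares deconvolution
#'
#' Per sample solves `min || R f - x ||^2` subject to `f >= 0` over the genes
#' shared between the bulk matrix and the reference, and reports both the raw
#' coefficients and fractions normalised to sum 1.
#'
#' @param m A linear-scale [expr_matrix()].
#' @param ref A [decon_reference()] (or genes x types matrix).
#' @return A tibble: sample_id, cell_type, coef, fraction.
#' @export
nnls_deconvolution <- function(m, ref) {
  stopifnot(inherits(m, "expr_matrix"))
  if (expr_scale(m) != "linear") {
    stop("deconvolution needs linear-scale expression", call. = FALSE)
  }
  if (!inherits(ref, "decon_reference")) ref <- decon_reference(ref)
  shared <- intersect(rownames(m), rownames(ref))
  if (length(shared) < ncol(ref)) {
    stop(sprintf("only %d shared gene(s) for %d cell types", length(shared), ncol(ref)),
         call. = FALSE)
  }
  r <- unclass(ref)[shared, , drop = FALSE]
  if (qr(r)$rank < ncol(r)) {
    stop("reference profile matrix is rank-deficient on the shared genes",
         call. = FALSE)
  }
  v <- unclass(m)[shared, , drop = FALSE]
  res <- lapply(seq_len(ncol(v)), function(j) {
    x <- v[, j]
    if (all(x == 0)) {
      stop("sample '", colnames(v)[j], "' is all-zero over the shared genes",
           call. = FALSE)
    }
    f <- pracma::lsqnonneg(r, x)$x
    tot <- sum(f)
    tibble::tibble(sample_id = colnames(v)[j],
                   cell_type = colnames(r),
                   coef = f,
                   fraction = if (tot > 0) f / tot else NA_real_)
  })
  dplyr::bind_rows(res)
}

#' Build the CAF marker + abundance composite matrix
#'
#' Rows are the z-scored log2 expression of the CAF marker genes plus the
#' z-scored fibroblast-abundance features (by default the three in-repo
#' estimators); columns follow the sample order of the expression matrix.
#' This is the matrix the infiltration clustering operates on.
#'
#' @param m An [expr_matrix()].
#' @param markers [gene_set()] of CAF marker genes.
#' @param abundance A data frame with a `sample_id` column and one numeric
#'   column per abundance feature.
#' @param features Which abundance columns to use; defaults to every numeric
#'   column.
#' @return A numeric matrix (features x samples) of z-scored rows, class
#'   `caf_composite`.
#' @export
build_caf_composite <- function(m, markers, abundance,
                                features = NULL) {
  m <- ensure_log2(m, "build_caf_composite")
  if (ncol(m) < 2) stop("composite z-scoring needs >= 2 samples", call. = FALSE)
  stopifnot(is.data.frame(abundance), "sample_id" %in% names(abundance))
  if (is.null(features)) {
    features <- setdiff(names(abundance)[vapply(abundance, is.numeric, logical(1))],
                        "sample_id")
  }
  if (length(features) < 1) stop("no abundance feature columns", call. = FALSE)
  miss <- setdiff(colnames(m), abundance$sample_id)
  if (length(miss)) {
    stop("abundance table lacks sample(s): ", paste(utils::head(miss, 5), collapse = ", "),
         call. = FALSE)
  }
  ab <- abundance[match(colnames(m), abundance$sample_id), features, drop = FALSE]
  ab_mat <- t(as.matrix(ab))
  colnames(ab_mat) <- colnames(m)

  al <- align_genes(m, markers)
  rows <- rbind(unclass(al$matrix), ab_mat)

  sds <- apply(rows, 1, stats::sd)
  keep <- sds > 0
  if (!all(keep)) {
    warning("dropped constant composite row(s): ",
            paste(rownames(rows)[!keep], collapse = ", "), call. = FALSE)
  }
  rows <- rows[keep, , drop = FALSE]
  if (nrow(rows) == 0) stop("no usable composite rows", call. = FALSE)
  z <- (rows - rowMeans(rows)) / apply(rows, 1, stats::sd)
  structure(z, class = c("caf_composite", "matrix", "array"))
}

#' Partition samples into high/low CAF infiltration groups
#'
#' Agglomerative clustering of the composite columns (Euclidean distance,
#' Ward linkage) cut at `k = 2`; the cluster with the greater mean composite
#' value is labelled `"high"`.
#'
#' @param composite A [build_caf_composite()] matrix (features x samples).
#' @param method Linkage; only `"ward"` (ward.D2) is supported.
#' @param k Number of groups (2).
#' @return An `infiltration_labeling`: list with `labels` (tibble sample_id,
#'   group), `method`, `k`, and the composite.
#' @export
cluster_infiltration <- function(composite, method = "ward", k = 2) {
  stopifnot(is.matrix(composite), all(is.finite(composite)))
  method <- match.arg(method, "ward")
  n <- ncol(composite)
  if (n < 2) stop("need >= 2 samples to cluster", call. = FALSE)
  if (k > n) stop("`k` exceeds the number of samples", call. = FALSE)
  d <- stats::dist(t(composite))
  degenerate <- all(d == 0)
  if (degenerate) {
    warning("all samples identical; split is arbitrary but deterministic",
            call. = FALSE)
  }
  hc <- stats::hclust(d, method = "ward.D2")
  cl <- stats::cutree(hc, k = k)
  means <- tapply(colMeans(composite), cl, mean)
  high_cl <- as.integer(names(means)[which.max(means)])
  group <- unname(ifelse(cl == high_cl, "high", "low"))
  # post-condition: high group has strictly greater mean composite
  if (!degenerate && length(unique(group)) == 2 &&
      !(mean(colMeans(composite)[group == "high"]) >
        mean(colMeans(composite)[group == "low"]))) {
    stop("internal error: high group does not exceed low group mean", call. = FALSE)
  }
  structure(list(
    labels = tibble::tibble(sample_id = colnames(composite), group = group),
    method = "ward.D2", metric = "euclidean", k = k,
    composite = composite
  ), class = "infiltration_labeling")
}

#' @export
print.infiltration_labeling <- function(x, ...) {
  tab <- table(x$labels$group)
  cat(sprintf("<infiltration_labeling> %d samples: %d high / %d low (%s, k = %d)\n",
              nrow(x$labels), tab[["high"]], tab[["low"]], x$method, x$k))
  invisible(x)
}

#' Import an externally computed abundance table
#'
#' Reads a CSV of per-sample cell-population scores computed outside the
#' package (for instance an absolute immune-infiltrate table) and tags it as
#' external.
#'
#' @param path CSV path with a `sample_id` column.
#' @param expression Optional [expr_matrix()] to check the sample ids against;
#'   mismatches produce a warning listing the difference.
#' @return A tibble with attribute `method = "external"`.
#' @export
import_external_abundance <- function(path, expression = NULL) {
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!"sample_id" %in% names(tab)) {
    stop("external abundance file needs a 'sample_id' column", call. = FALSE)
  }
  if (nrow(tab) == 0) stop("external abundance file has no rows", call. = FALSE)
  if (!is.null(expression)) {
    only_expr <- setdiff(colnames(expression), tab$sample_id)
    only_tab <- setdiff(tab$sample_id, colnames(expression))
    if (length(only_expr) || length(only_tab)) {
      warning(sprintf("sample mismatch - missing from table: [%s]; extra in table: [%s]",
                      paste(only_expr, collapse = ", "),
                      paste(only_tab, collapse = ", ")), call. = FALSE)
    }
  }
  attr(tab, "method") <- "external"
  tab
}
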
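#' Reference expression vectors for the neuroendocrine score
#'
#' Holds the reference expression of the NE/Non-NE program genes (classically
#' a 50-gene panel) in archetypal NE and Non-NE tumours. Shipped as an
#' editable three-column table (gene, ne_value, nonne_value) rather than a
#' hard-coded panel.
#'
#' @param genes Gene symbols (>= 3, unique).
#' @param ne_value,nonne_value Reference expression per gene; the two vectors
#'   must differ.
#' @return A `reference_vectors` tibble.
#' @export
reference_vectors <- function(genes, ne_value, nonne_value) {
  genes <- as.character(genes)
  stopifnot(length(genes) == length(ne_value),
            length(genes) == length(nonne_value))
  if (length(genes) < 3) stop("need >= 3 reference genes", call. = FALSE)
  if (anyDuplicated(genes)) stop("duplicate reference genes", call. = FALSE)
  if (!all(is.finite(ne_value)) || !all(is.finite(nonne_value))) {
    stop("reference vectors must be finite", call. = FALSE)
  }
  if (isTRUE(all.equal(as.numeric(ne_value), as.numeric(nonne_value)))) {
    stop("NE and Non-NE reference vectors are identical", call. = FALSE)
  }
  structure(tibble::tibble(gene = genes,
                           ne_value = as.numeric(ne_value),
                           nonne_value = as.numeric(nonne_value)),
            class = c("reference_vectors", "tbl_df", "tbl", "data.frame"))
}

#' Read reference vectors from a three-column TSV
#' @param path TSV with columns gene, ne_value, nonne_value.
#' @return A [reference_vectors()].
#' @export
read_reference_vectors <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  stopifnot(all(c("gene", "ne_value", "nonne_value") %in% names(tab)))
  reference_vectors(tab$gene, tab$ne_value, tab$nonne_value)
}

#' Neuroendocrine score
#'
#' Per sample, `NE score = (cor(x, ne_ref) - cor(x, nonne_ref)) / 2` (Pearson,
#' over the reference genes present in the matrix). A score above 0 labels the
#' sample NE, below 0 Non-NE, exactly 0 "undetermined". A sample that is
#' constant over the reference genes has no defined correlation; its score is
#' `NA` with label `"undefined"` rather than a silent 0.
#'
#' @param m An [expr_matrix()].
#' @param ref A [reference_vectors()].
#' @return A tibble: sample_id, ne_score (in `[-1, 1]` or NA), phenotype
#'   (`"NE"`, `"NonNE"`, `"undetermined"`, `"undefined"`), n_genes_used.
#' @export
ne_score <- function(m, ref) {
  stopifnot(inherits(m, "expr_matrix"), inherits(ref, "reference_vectors"))
  shared <- intersect(ref$gene, rownames(m))
  if (length(shared) < 3) {
    stop("fewer than 3 reference genes present in the matrix", call. = FALSE)
  }
  idx <- match(shared, ref$gene)
  vne <- ref$ne_value[idx]
  vnn <- ref$nonne_value[idx]
  v <- unclass(m)[shared, , drop = FALSE]
  res <- purrr::map_dfr(seq_len(ncol(v)), function(j) {
    x <- v[, j]
    if (stats::sd(x) == 0) {
      return(tibble::tibble(sample_id = colnames(v)[j], ne_score = NA_real_,
                            phenotype = "undefined",
                            n_genes_used = length(shared)))
    }
    s <- (stats::cor(x, vne) - stats::cor(x, vnn)) / 2
    lab <- if (s > 0) "NE" else if (s < 0) "NonNE" else "undetermined"
    tibble::tibble(sample_id = colnames(v)[j], ne_score = s, phenotype = lab,
                   n_genes_used = length(shared))
  })
  res
}

#' Cytolytic activity (CYT) score
#'
#' Geometric mean of granzyme A and perforin expression on the linear scale:
#' `sqrt((GZMA + offset) * (PRF1 + offset))`. The small offset keeps the score
#' defined when one transcript is absent.
#'
#' @param m A linear-scale [expr_matrix()].
#' @param offset Non-negative offset, default 0.01.
#' @param genes The two gene symbols, default `c("GZMA", "PRF1")`.
#' @return A tibble: sample_id, cyt_score.
#' @export
cyt_score <- function(m, offset = 0.01, genes = c("GZMA", "PRF1")) {
  stopifnot(inherits(m, "expr_matrix"), length(genes) == 2)
  if (expr_scale(m) != "linear") {
    stop("CYT is defined on linear-scale expression", call. = FALSE)
  }
  if (offset < 0) stop("`offset` must be >= 0", call. = FALSE)
  absent <- setdiff(genes, rownames(m))
  if (length(absent)) {
    stop("gene(s) absent from matrix: ", paste(absent, collapse = ", "), call. = FALSE)
  }
  v <- unclass(m)
  tibble::tibble(
    sample_id = colnames(m),
    cyt_score = unname(sqrt((v[genes[1], ] + offset) * (v[genes[2], ] + offset)))
  )
}

#' Antigen presentation machinery (APM) score
#'
#' Median across the APM signature genes of the per-gene z-scored expression
#' (z across samples, n - 1 denominator; zero-variance genes excluded with a
#' warning).
#'
#' @param m An [expr_matrix()] with >= 2 samples.
#' @param apm_set A [gene_set()].
#' @return A tibble: sample_id, apm_score.
#' @export
apm_score <- function(m, apm_set) {
  stopifnot(inherits(m, "expr_matrix"), inherits(apm_set, "gene_set"))
  al <- align_genes(m, apm_set)
  z <- tryCatch(zscore_genes(al$matrix), error = function(e) {
    stop("APM score: ", conditionMessage(e), call. = FALSE)
  })
  if (nrow(z) == 0) {
    stop("all APM genes are absent or constant", call. = FALSE)
  }
  tibble::tibble(
    sample_id = colnames(z),
    apm_score = unname(apply(unclass(z), 2, stats::median))
  )
}

#' T-cell-inflamed gene expression profile (GEP) score
#'
#' Weighted sum of log2(x + 1) expression over a weighted gene set (the
#' 18-gene inflamed profile in the original use; the weights are an external
#' input — none are fabricated by the package).
#'
#' @param m An [expr_matrix()]; linear input is log2(x+1)-transformed with a
#'   warning.
#' @param weighted_set A [gene_set()] carrying weights for every gene.
#' @return A tibble: sample_id, gep_score; absent genes are omitted with a
#'   message.
#' @export
gep_score <- function(m, weighted_set) {
  stopifnot(inherits(m, "expr_matrix"), inherits(weighted_set, "gene_set"))
  if (is.null(weighted_set$weights)) {
    stop("GEP needs a weighted gene set; none of the weights are built in",
         call. = FALSE)
  }
  m <- ensure_log2(m, "gep_score")
  present <- intersect(weighted_set$genes, rownames(m))
  if (length(present) == 0) stop("no weighted gene present in the matrix", call. = FALSE)
  w <- weighted_set$weights[present]
  if (anyNA(w)) stop("weight missing for present gene(s)", call. = FALSE)
  missing <- setdiff(weighted_set$genes, present)
  if (length(missing)) {
    message(sprintf("GEP: %d gene(s) absent, omitted: %s", length(missing),
                    paste(utils::head(missing, 5), collapse = ", ")))
  }
  v <- unclass(m)[present, , drop = FALSE]
  tibble::tibble(sample_id = colnames(m),
                 gep_score = unname(drop(crossprod(v, w))))
}

#' SCLC transcriptional subtype calls
#'
#' Each sample is assigned SCLC-A/N/P/Y by the single highest expression among
#' ASCL1, NEUROD1, POU2F3 and YAP1. Ties are resolved by the fixed priority
#' A > N > P > Y and flagged.
#'
#' @param m An [expr_matrix()] containing all four subtype genes.
#' @return A tibble: sample_id, subtype, tie (logical), plus the four
#'   expression values used.
#' @export
call_subtype <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  genes <- c("ASCL1", "NEUROD1", "POU2F3", "YAP1")
  subtypes <- c("SCLC-A", "SCLC-N", "SCLC-P", "SCLC-Y")
  absent <- setdiff(genes, rownames(m))
  if (length(absent)) {
    stop("subtype gene(s) absent: ", paste(absent, collapse = ", "), call. = FALSE)
  }
  v <- unclass(m)[genes, , drop = FALSE]
  res <- purrr::map_dfr(seq_len(ncol(v)), function(j) {
    x <- v[, j]
    top <- which(x == max(x))  # which.max alone would hide ties
    tibble::tibble(sample_id = colnames(v)[j],
                   subtype = subtypes[top[1]],
                   tie = length(top) > 1,
                   ASCL1 = x[1], NEUROD1 = x[2], POU2F3 = x[3], YAP1 = x[4])
  })
  if (any(res$tie)) {
    message(sprintf("%d sample(s) had tied subtype genes; priority A > N > P > Y applied",
                    sum(res$tie)))
  }
  res
}

#' Immunohistochemistry a-by-b score
#'
#' Bins the proportion of positively stained cells into `a` (0: [0,5]%,
#' 1: (5,25]%, 2: (25,50]%, 3: (50,75]%, 4: (75,100]%) and the staining
#' intensity into `b` (negative 0, weak 1, medium 2, strong 3); the IHC score
#' is `a * b` (0-12). Vectorised over records.
#'
#' @param proportion_percent Percent positive cells, in `[0, 100]`.
#' @param intensity Character: `"negative"`, `"weak"`, `"medium"`, `"strong"`.
#' @return A tibble: proportion_percent, intensity, a, b, score.
#' @export
ihc_score <- function(proportion_percent, intensity) {
  if (any(proportion_percent < 0 | proportion_percent > 100)) {
    stop("`proportion_percent` must lie in [0, 100]", call. = FALSE)
  }
  intensity <- match.arg(intensity, c("negative", "weak", "medium", "strong"),
                         several.ok = TRUE)
  if (length(intensity) == 1) intensity <- rep(intensity, length(proportion_percent))
  stopifnot(length(intensity) == length(proportion_percent))
  a <- as.integer(cut(proportion_percent, breaks = c(-Inf, 5, 25, 50, 75, 100))) - 1L
  b <- c(negative = 0L, weak = 1L, medium = 2L, strong = 3L)[intensity]
  tibble::tibble(proportion_percent = proportion_percent,
                 intensity = intensity,
                 a = a, b = unname(b), score = a * unname(b))
}
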
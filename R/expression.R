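#' Expression matrix with a declared scale
#'
#' Construct a validated genes-by-samples expression matrix. The scale is
#' declared by the caller, never sniffed: FPKM/TPM-like values are `"linear"`
#' (non-negative), `log2(x + 1)`-transformed values are `"log2p1"`.
#'
#' @param values Numeric matrix, genes as rows (unique rownames = gene
#'   symbols), samples as columns (unique colnames = sample ids).
#' @param scale One of `"linear"` or `"log2p1"`.
#'
#' @return An `expr_matrix`: the matrix with a `scale` attribute.
#' @export
#'
#' @examples
#' m <- matrix(1:6, nrow = 3, dimnames = list(c("A", "B", "C"), c("s1", "s2")))
#' expr_matrix(m, scale = "linear")
expr_matrix <- function(values, scale = c("linear", "log2p1")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix (genes x samples)", call. = FALSE)
  }
  genes <- rownames(values)
  samples <- colnames(values)
  if (is.null(genes) || is.null(samples)) {
    stop("expression matrix needs rownames (genes) and colnames (samples)", call. = FALSE)
  }
  if (anyDuplicated(genes)) {
    stop("duplicate gene identifiers: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(samples)) {
    stop("duplicate sample identifiers: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "), call. = FALSE)
  }
  if (!all(is.finite(values))) {
    stop("expression values must all be finite", call. = FALSE)
  }
  if (scale == "linear" && any(values < 0)) {
    stop("negative values are not allowed on the linear scale", call. = FALSE)
  }
  structure(values, scale = scale, class = c("expr_matrix", "matrix", "array"))
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d samples, scale = %s\n",
              nrow(x), ncol(x), expr_scale(x)))
  n <- min(5L, nrow(x)); k <- min(5L, ncol(x))
  print(unclass(x)[seq_len(n), seq_len(k), drop = FALSE])
  invisible(x)
}

#' Declared scale of an expression matrix
#' @param m An [expr_matrix()].
#' @return `"linear"` or `"log2p1"`.
#' @export
expr_scale <- function(m) {
  s <- attr(m, "scale")
  if (is.null(s)) "linear" else s
}

# keep class/scale through subsetting
#' @export
`[.expr_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out)) {
    attr(out, "scale") <- expr_scale(x)
    class(out) <- c("expr_matrix", "matrix", "array")
  }
  out
}

#' Read a genes-by-samples expression table
#'
#' Reads a delimited text file whose first column holds gene symbols and whose
#' header row holds sample ids. Duplicate gene rows are collapsed per sample
#' (maximum by default, the usual probe/symbol collapse convention) with a
#' message reporting how many rows were merged.
#'
#' @param path File path.
#' @param format `"tsv"` or `"csv"`.
#' @inheritParams expr_matrix
#' @param collapse How duplicate gene rows are merged: `"max"` (default) or
#'   `"mean"`.
#'
#' @return An [expr_matrix()].
#' @export
read_expression_matrix <- function(path, format = c("tsv", "csv"),
                                   scale = c("linear", "log2p1"),
                                   collapse = c("max", "mean")) {
  format <- match.arg(format)
  scale <- match.arg(scale)
  collapse <- match.arg(collapse)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  delim <- if (format == "tsv") "\t" else ","

  header <- strsplit(readLines(path, n = 1L), delim, fixed = TRUE)[[1]]
  samples <- header[-1]
  if (anyDuplicated(samples)) {
    stop("duplicate sample ids in header: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "), call. = FALSE)
  }

  raw <- readr::read_delim(path, delim = delim,
                           col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE)
  genes <- raw[[1]]
  vals <- vapply(seq_along(samples), function(j) {
    col <- raw[[j + 1L]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num) & !is.na(col))
    if (length(bad)) {
      stop(sprintf("non-numeric value '%s' at gene row '%s', sample column '%s'",
                   col[bad[1]], genes[bad[1]], samples[j]), call. = FALSE)
    }
    num
  }, numeric(length(genes)))
  vals <- matrix(vals, nrow = length(genes),
                 dimnames = list(NULL, samples))

  if (anyDuplicated(genes)) {
    n_dup <- sum(duplicated(genes))
    fun <- if (collapse == "max") max else mean
    vals <- do.call(rbind, lapply(split(seq_along(genes), genes), function(idx) {
      apply(vals[idx, , drop = FALSE], 2, fun)
    }))
    # split() orders by factor level; restore first-appearance order
    first <- genes[!duplicated(genes)]
    vals <- vals[first, , drop = FALSE]
    message(sprintf("collapsed %d duplicate gene row(s) by %s", n_dup, collapse))
  } else {
    rownames(vals) <- genes
  }
  expr_matrix(vals, scale = scale)
}

#' Apply a log2 transform to a linear-scale matrix
#'
#' @param m An [expr_matrix()] on the linear scale.
#' @param pseudocount Positive offset added before taking `log2`; with the
#'   default 1 the result is declared `log2p1`.
#'
#' @return An [expr_matrix()] of `log2(x + pseudocount)` values.
#' @export
log_transform <- function(m, pseudocount = 1) {
  stopifnot(inherits(m, "expr_matrix"))
  if (expr_scale(m) != "linear") {
    stop("matrix is already on the log2p1 scale; refusing to double-transform",
         call. = FALSE)
  }
  if (!is.numeric(pseudocount) || length(pseudocount) != 1 || pseudocount <= 0) {
    stop("`pseudocount` must be a single positive number", call. = FALSE)
  }
  out <- log2(unclass(m) + pseudocount)
  scale_out <- if (pseudocount == 1) "log2p1" else "log2p1"
  expr_matrix(out, scale = scale_out)
}

# internal: ensure log2 scale, transforming with a warning if needed
ensure_log2 <- function(m, what = "score") {
  if (expr_scale(m) == "linear") {
    warning(sprintf("%s expects log2(x+1) expression; transforming linear input",
                    what), call. = FALSE)
    m <- log_transform(m, 1)
  }
  m
}

#' Z-score each gene across samples
#'
#' Centres and scales every gene row to mean 0, sd 1 (n - 1 denominator).
#' Zero-variance rows cannot be scaled; they are dropped with a warning and
#' recorded in the `dropped_genes` attribute so downstream median/weighted
#' scores never see them.
#'
#' @param m An [expr_matrix()] with at least two samples.
#' @return An `expr_matrix` of z-scores (scale attribute `log2p1` semantics do
#'   not apply; the matrix is returned with scale `"log2p1"` marking it as
#'   non-linear).
#' @export
zscore_genes <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  if (ncol(m) < 2) stop("z-scoring needs at least 2 samples", call. = FALSE)
  v <- unclass(m)
  mu <- rowMeans(v)
  sdv <- apply(v, 1, stats::sd)
  keep <- sdv > 0
  if (!any(keep)) stop("all gene rows have zero variance", call. = FALSE)
  if (!all(keep)) {
    warning(sprintf("dropped %d zero-variance gene row(s): %s",
                    sum(!keep),
                    paste(utils::head(rownames(v)[!keep], 5), collapse = ", ")),
            call. = FALSE)
  }
  z <- (v[keep, , drop = FALSE] - mu[keep]) / sdv[keep]
  out <- expr_matrix(z, scale = "log2p1")
  attr(out, "dropped_genes") <- rownames(v)[!keep]
  out
}

#' Restrict an expression matrix to a gene set
#'
#' @param m An [expr_matrix()].
#' @param s A [gene_set()].
#' @return A list with `matrix` (rows in set order, present genes only) and
#'   `missing` (set genes absent from `m`). Warns when more than half the set
#'   is missing; errors when nothing is found.
#' @export
align_genes <- function(m, s) {
  stopifnot(inherits(m, "expr_matrix"), inherits(s, "gene_set"))
  present <- s$genes[s$genes %in% rownames(m)]
  missing <- setdiff(s$genes, present)
  if (length(present) == 0) {
    stop(sprintf("no gene of set '%s' found in the expression matrix", s$name),
         call. = FALSE)
  }
  if (length(missing) > length(s$genes) / 2) {
    warning(sprintf("set '%s': %d of %d genes missing from the matrix",
                    s$name, length(missing), length(s$genes)), call. = FALSE)
  }
  list(matrix = m[present, , drop = FALSE], missing = missing)
}

#' Write a result table to disk
#'
#' Lossless round-trip writer for score/abundance/comparison tables; numeric
#' columns keep full precision (>= 6 significant digits).
#'
#' @param rows A data frame.
#' @param path Output path.
#' @param format `"csv"`, `"tsv"` or `"json"`.
#' @return Invisibly, `path`.
#' @export
write_table <- function(rows, path, format = c("csv", "tsv", "json")) {
  format <- match.arg(format)
  rows <- as.data.frame(rows)
  ok <- tryCatch({
    switch(format,
      csv = readr::write_csv(rows, path),
      tsv = readr::write_tsv(rows, path),
      json = jsonlite::write_json(rows, path, digits = NA, dataframe = "rows")
    )
    TRUE
  }, error = function(e) {
    stop("could not write '", path, "': ", conditionMessage(e), call. = FALSE)
  })
  invisible(path)
}

#' Read back a table written by [write_table()]
#' @inheritParams write_table
#' @return A tibble.
#' @export
read_table <- function(path, format = c("csv", "tsv", "json")) {
  format <- match.arg(format)
  switch(format,
    csv = readr::read_csv(path, show_col_types = FALSE, progress = FALSE),
    tsv = readr::read_tsv(path, show_col_types = FALSE, progress = FALSE),
    json = tibble::as_tibble(jsonlite::fromJSON(path))
  )
}
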
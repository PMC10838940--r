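#' Gene set
#'
#' A named, ordered collection of unique gene symbols, optionally with one
#' finite weight per gene (used by weighted scores such as the T-cell-inflamed
#' expression profile).
#'
#' @param name Set name.
#' @param genes Character vector of gene symbols (>= 1, unique).
#' @param weights Optional numeric vector aligned to `genes`.
#' @return A `gene_set` object.
#' @export
gene_set <- function(name, genes, weights = NULL) {
  stopifnot(is.character(name), length(name) == 1, nzchar(name))
  genes <- as.character(genes)
  if (length(genes) < 1) stop("gene set '", name, "' is empty", call. = FALSE)
  if (anyDuplicated(genes)) {
    stop("gene set '", name, "' contains duplicate genes", call. = FALSE)
  }
  if (!is.null(weights)) {
    if (length(weights) != length(genes) || !all(is.finite(weights))) {
      stop("weights must be finite and aligned to genes", call. = FALSE)
    }
    weights <- as.numeric(weights)
    names(weights) <- genes
  }
  structure(list(name = name, genes = genes, weights = weights),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> %s: %d genes%s\n", x$name, length(x$genes),
              if (is.null(x$weights)) "" else " (weighted)"))
  invisible(x)
}

#' Signature library
#'
#' A collection of [gene_set()] objects with unique names.
#'
#' @param sets A list of `gene_set` objects.
#' @return A `signature_library` (named list of gene sets).
#' @export
signature_library <- function(sets) {
  if (length(sets) == 0) stop("signature library is empty", call. = FALSE)
  stopifnot(all(vapply(sets, inherits, logical(1), "gene_set")))
  nms <- vapply(sets, `[[`, character(1), "name")
  if (anyDuplicated(nms)) {
    stop("duplicate set names: ", paste(unique(nms[duplicated(nms)]), collapse = ", "),
         call. = FALSE)
  }
  names(sets) <- nms
  structure(sets, class = "signature_library")
}

#' @export
print.signature_library <- function(x, ...) {
  cat(sprintf("<signature_library> %d sets: %s\n", length(x),
              paste(utils::head(names(x), 8), collapse = ", ")))
  invisible(x)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, `name <tab> description <tab> gene...`.
#' Genes repeated within a line are dropped with a warning.
#'
#' @param path GMT file path.
#' @return A [signature_library()].
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(seq_along(lines), function(i) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      stop(sprintf("GMT line %d has %d field(s); need name, description, gene(s)",
                   i, length(fields)), call. = FALSE)
    }
    genes <- fields[-(1:2)]
    if (anyDuplicated(genes)) {
      warning(sprintf("GMT set '%s': dropped %d duplicated gene(s)",
                      fields[1], sum(duplicated(genes))), call. = FALSE)
      genes <- genes[!duplicated(genes)]
    }
    gene_set(fields[1], genes)
  })
  signature_library(sets)
}

#' Write a signature library to a GMT file
#' @param lib A [signature_library()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(lib, path) {
  stopifnot(inherits(lib, "signature_library"))
  lines <- vapply(lib, function(s) {
    paste(c(s$name, "na", s$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
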
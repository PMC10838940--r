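# run code under a fixed RNG seed without disturbing the caller's stream
with_local_seed <- function(seed, code) {
  if (missing(seed) || is.null(seed)) {
    stop("a seed is required for every randomized operation", call. = FALSE)
  }
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# labels as a "high"/"low" factor aligned to sample ids
check_group_labels <- function(labels, sample_ids) {
  if (is.data.frame(labels)) {
    stopifnot(all(c("sample_id", "group") %in% names(labels)))
    labels <- stats::setNames(as.character(labels$group), labels$sample_id)
  }
  if (!is.null(names(labels))) {
    miss <- setdiff(sample_ids, names(labels))
    if (length(miss)) {
      stop("no group label for sample(s): ", paste(utils::head(miss, 5), collapse = ", "),
           call. = FALSE)
    }
    labels <- labels[sample_ids]
  } else if (length(labels) != length(sample_ids)) {
    stop("labels length does not match number of samples", call. = FALSE)
  }
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), c("high", "low"))
  if (length(bad)) {
    stop("group labels must be 'high'/'low'; found: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  factor(labels, levels = c("high", "low"))
}
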
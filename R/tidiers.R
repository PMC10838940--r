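#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a moderated comparison
#' @param x A [moderated_t()] fit.
#' @param ... Unused.
#' @return The per-feature results tibble.
#' @method tidy moderated_t_fit
#' @export
tidy.moderated_t_fit <- function(x, ...) x$table

#' One-row summary of a moderated comparison
#' @inheritParams tidy.moderated_t_fit
#' @return Tibble with the shrinkage hyper-parameters and group sizes.
#' @method glance moderated_t_fit
#' @export
glance.moderated_t_fit <- function(x, ...) {
  tibble::tibble(n_features = nrow(x$table), n_high = x$n_high, n_low = x$n_low,
                 d0 = x$d0, s0_sq = x$s0_sq,
                 n_significant_q05 = sum(x$table$q_value < 0.05, na.rm = TRUE))
}

#' Tidy a GSEA result
#' @param x A [gsea_nes()] result.
#' @param ... Unused.
#' @return One-row tibble: set, es, nes, p_value, n_perm, mode.
#' @method tidy gsea_result
#' @export
tidy.gsea_result <- function(x, ...) {
  tibble::tibble(set = x$set, es = x$es, nes = x$nes, p_value = x$p_value,
                 n_perm = x$n_perm, mode = x$mode)
}

#' Tidy an infiltration labeling
#' @param x A [cluster_infiltration()] result.
#' @param ... Unused.
#' @return The sample_id/group tibble.
#' @method tidy infiltration_labeling
#' @export
tidy.infiltration_labeling <- function(x, ...) x$labels

#' Tidy a drug model
#' @param x A [fit_ridge_transfer()] model.
#' @param ... Unused.
#' @return Tibble of per-gene weights (standardised space).
#' @method tidy drug_model
#' @export
tidy.drug_model <- function(x, ...) {
  tibble::tibble(gene = names(x$weights), weight = unname(x$weights))
}

#' One-row summary of a drug model
#' @inheritParams tidy.drug_model
#' @return Tibble: drug, lambda, cv_mse, n_lines, n_genes.
#' @method glance drug_model
#' @export
glance.drug_model <- function(x, ...) {
  tibble::tibble(drug = x$drug, lambda = x$lambda,
                 cv_mse = min(x$cv$cv_mse), n_lines = x$n_lines,
                 n_genes = x$n_genes)
}

#' Bar chart of moderated t-values per feature
#'
#' The standard presentation of a per-set group comparison: features ordered
#' by moderated t, coloured by the group they are enriched in, with the
#' conventional significance cut marked.
#'
#' @param object A [moderated_t()] fit.
#' @param p_cut Features with p below this are labelled significant.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot moderated_t_fit
#' @export
autoplot.moderated_t_fit <- function(object, p_cut = 0.05, ...) {
  tab <- dplyr::filter(object$table, !is.na(.data$t))
  tab <- dplyr::mutate(tab,
    feature = stats::reorder(.data$feature, .data$t),
    enriched_in = ifelse(.data$t > 0, "high", "low"),
    significant = .data$p_value < p_cut)
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$t, y = .data$feature,
                                    fill = .data$enriched_in,
                                    alpha = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.4)) +
    ggplot2::labs(x = "moderated t (high - low)", y = NULL,
                  fill = "enriched in", alpha = sprintf("p < %.2g", p_cut)) +
    ggplot2::theme_minimal()
}

#' Null-distribution view of a GSEA result
#'
#' Histogram of the permutation null enrichment scores with the observed
#' score marked.
#'
#' @param object A [gsea_nes()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot gsea_result
#' @export
autoplot.gsea_result <- function(object, ...) {
  df <- tibble::tibble(null_es = object$null_es)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$null_es)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70") +
    ggplot2::geom_vline(xintercept = object$es, colour = "firebrick") +
    ggplot2::labs(
      title = sprintf("%s: ES = %.3f, NES = %.2f, p = %.3g",
                      object$set, object$es, object$nes, object$p_value),
      x = "permutation null ES", y = "count") +
    ggplot2::theme_minimal()
}

#' Composite heatmap of an infiltration labeling
#'
#' Tile view of the z-scored marker + abundance composite with samples
#' ordered by group, the figure the high/low split is read from.
#'
#' @param object A [cluster_infiltration()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot infiltration_labeling
#' @export
autoplot.infiltration_labeling <- function(object, ...) {
  comp <- object$composite
  ord <- order(object$labels$group, -colMeans(comp))
  df <- tidyr::pivot_longer(
    dplyr::mutate(tibble::as_tibble(t(comp[, ord, drop = FALSE])),
                  sample_id = colnames(comp)[ord],
                  group = object$labels$group[ord]),
    cols = -c("sample_id", "group"), names_to = "feature", values_to = "z")
  df$sample_id <- factor(df$sample_id, levels = colnames(comp)[ord])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample_id, y = .data$feature,
                                   fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white", high = "firebrick") +
    ggplot2::facet_grid(~group, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = NULL, y = NULL, fill = "z") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Bar chart of per-drug sensitivity log fold changes
#'
#' @param comparison Output of [compare_sensitivity()].
#' @param q_cut Only drugs with q below this are shown (all if `Inf`).
#' @return A ggplot; positive bars are drugs the high-infiltration group is
#'   predicted more resistant to.
#' @export
plot_sensitivity_comparison <- function(comparison, q_cut = Inf) {
  df <- dplyr::filter(comparison, is.na(.data$q_value) | .data$q_value < q_cut)
  df <- dplyr::mutate(df, drug = stats::reorder(.data$drug, .data$logFC))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$logFC, y = .data$drug,
                                   fill = .data$logFC > 0)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "steelblue", `FALSE` = "darkorange")) +
    ggplot2::labs(x = "logFC of predicted sensitivity (high - low); > 0 = more resistant",
                  y = NULL) +
    ggplot2::theme_minimal()
}
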
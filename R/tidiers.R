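# broom-style tidiers and ggplot2 autoplot methods for the fitted objects.

#' Tidy a divergence classification
#'
#' @param x A [classify_divergent()] fit.
#' @param ... Unused.
#' @return The per-GRE, per-lineage tibble (`gre_id`, `lineage`, `count`,
#'   `total`, `proportion`, `p`, `fdr`, `fold_change`, `z`, `divergent`).
#' @export
tidy.divergence_fit <- function(x, ...) x$table

#' One-row summary of a divergence classification
#'
#' @param x A [classify_divergent()] fit.
#' @param ... Unused.
#' @return Tibble with the GRE count, per-lineage divergent counts and the
#'   resampling parameters.
#' @export
glance.divergence_fit <- function(x, ...) {
  nd <- x$table |>
    dplyr::filter(.data$divergent) |>
    dplyr::count(.data$lineage) |>
    tidyr::pivot_wider(names_from = "lineage", values_from = "n",
                       names_prefix = "divergent_")
  base <- tibble::tibble(n_gres = dplyr::n_distinct(x$table$gre_id),
                         n_iter = x$params$n_iter, n_draw = x$params$n_draw)
  if (nrow(nd)) dplyr::bind_cols(base, nd) else base
}

#' Plot a divergence classification
#'
#' Observed lineage substitution proportion against fold change, coloured by
#' the divergent call, one facet per lineage.
#'
#' @param object A [classify_divergent()] fit.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.divergence_fit <- function(object, ...) {
  tbl <- dplyr::filter(object$table, !is.na(.data$fold_change))
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$fold_change,
                                    y = .data$proportion,
                                    colour = .data$divergent)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(ggplot2::vars(.data$lineage)) +
    ggplot2::labs(x = "fold change vs resampled background",
                  y = "substitution proportion", colour = "divergent") +
    ggplot2::theme_minimal()
}

#' Tidy an RDG permutation test
#'
#' @param x An [identify_rdgs()] fit.
#' @param ... Unused.
#' @return Tibble `gene_id`, `lineage`, `divergent_links`, `total_links`,
#'   `p`, `fdr`, `is_rdg`.
#' @export
tidy.rdg_fit <- function(x, ...) x$table

#' One-row summary of an RDG permutation test
#'
#' @param x An [identify_rdgs()] fit.
#' @param ... Unused.
#' @return Tibble with tested gene count and RDG counts per lineage.
#' @export
glance.rdg_fit <- function(x, ...) {
  nr <- x$table |>
    dplyr::filter(.data$is_rdg) |>
    dplyr::count(.data$lineage) |>
    tidyr::pivot_wider(names_from = "lineage", values_from = "n",
                       names_prefix = "rdg_")
  base <- tibble::tibble(n_genes = dplyr::n_distinct(x$table$gene_id))
  if (nrow(nr)) dplyr::bind_cols(base, nr) else base
}

#' Plot RDG divergent-link counts
#'
#' @param object An [identify_rdgs()] fit.
#' @param ... Unused.
#' @return A ggplot of divergent-link counts per gene, RDGs highlighted.
#' @export
autoplot.rdg_fit <- function(object, ...) {
  ggplot2::ggplot(object$table,
                  ggplot2::aes(x = .data$total_links,
                               y = .data$divergent_links,
                               colour = .data$is_rdg)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::facet_wrap(ggplot2::vars(.data$lineage)) +
    ggplot2::labs(x = "total significant links",
                  y = "links to lineage-divergent GREs", colour = "RDG") +
    ggplot2::theme_minimal()
}

#' Plot gain/loss ratios per motif and lineage
#'
#' Dot plot of gain/loss ratios (continuity-corrected where losses are
#' zero) with the global per-lineage ratio as a dashed line.
#'
#' @param summary A [gain_loss_ratios()] tibble (optionally after
#'   [test_expansion_depletion()]).
#' @return A ggplot.
#' @export
plot_gain_loss <- function(summary) {
  global <- attr(summary, "global")
  tbl <- dplyr::mutate(summary,
                       ratio_plot = (.data$gains + 0.5) / (.data$losses + 0.5))
  p <- ggplot2::ggplot(tbl, ggplot2::aes(x = .data$lineage,
                                         y = .data$ratio_plot))
  p <- if ("status" %in% names(tbl)) {
    p + ggplot2::geom_jitter(ggplot2::aes(colour = .data$status),
                             width = 0.15, alpha = 0.6)
  } else {
    p + ggplot2::geom_jitter(width = 0.15, alpha = 0.6)
  }
  p <- p + ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "gain / loss ratio") +
    ggplot2::theme_minimal()
  if (!is.null(global)) {
    p <- p + ggplot2::geom_hline(
      yintercept = sum(global$gains) / sum(global$losses), linetype = 2)
  }
  p
}
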
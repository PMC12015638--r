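#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a gradient's component space
#'
#' Scatter of component 1 (principal gradient) against component 2,
#' colored by network when a parcellation is supplied, or component 1
#' against ROI rank otherwise.
#'
#' @param object An `fcg_gradient`.
#' @param parcellation Optional `fcg_parcellation` for coloring.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.fcg_gradient <- function(object, parcellation = NULL, ...) {
  comp <- object$components
  df <- tibble::tibble(
    g1 = comp[, 1],
    g2 = if (ncol(comp) > 1) comp[, 2] else seq_len(nrow(comp))
  )
  if (!is.null(parcellation)) {
    df$network <- factor(parcellation$network, levels = yeo7_networks())
    ggplot2::ggplot(df, ggplot2::aes(.data$g1, .data$g2, colour = .data$network)) +
      ggplot2::geom_point(alpha = 0.8) +
      ggplot2::labs(
        x = "gradient 1 (unimodal - transmodal)",
        y = if (ncol(comp) > 1) "gradient 2" else "ROI index",
        colour = "network"
      ) +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(df, ggplot2::aes(.data$g1, .data$g2)) +
      ggplot2::geom_point(alpha = 0.8) +
      ggplot2::labs(x = "gradient 1", y = "gradient 2") +
      ggplot2::theme_minimal()
  }
}

#' Plot allegiance distributions against static nulls
#'
#' Density of upper-triangle allegiance values for the real data and the
#' pooled null matrices — the comparison the KS test quantifies.
#'
#' @param object An `fcg_allegiance` (real data).
#' @param nulls List of null `fcg_allegiance` matrices.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.fcg_allegiance <- function(object, nulls = NULL, ...) {
  df <- dplyr::mutate(tidy.fcg_allegiance(object), source = "real")
  if (!is.null(nulls)) {
    nd <- dplyr::bind_rows(lapply(nulls, tidy.fcg_allegiance))
    df <- dplyr::bind_rows(df, dplyr::mutate(nd, source = "static null"))
  }
  ggplot2::ggplot(df, ggplot2::aes(.data$allegiance, fill = .data$source)) +
    ggplot2::geom_histogram(
      ggplot2::aes(y = ggplot2::after_stat(!!rlang::sym("density"))),
      bins = 40, position = "identity", alpha = 0.5
    ) +
    ggplot2::labs(x = "allegiance", y = "density", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot per-network group comparison results
#'
#' Bar chart of -log10 p-values per network and measure family, with the
#' 0.05 threshold marked.
#'
#' @param comparisons An `fcg_comparison` tibble (e.g.
#'   `result$comparisons`).
#' @param adjusted Plot FDR-adjusted p-values (default TRUE).
#' @return A ggplot object.
#' @export
plot_network_comparison <- function(comparisons, adjusted = TRUE) {
  pcol <- if (adjusted) "p_fdr" else "p_unc"
  df <- dplyr::mutate(
    tibble::as_tibble(comparisons),
    network = factor(.data$network, levels = yeo7_networks()),
    neglogp = -log10(.data[[pcol]])
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$network, .data$neglogp)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = -log10(0.05), linetype = 2) +
    ggplot2::facet_wrap(~measure) +
    ggplot2::labs(
      x = NULL,
      y = if (adjusted) "-log10 FDR-adjusted p" else "-log10 p"
    ) +
    ggplot2::theme_minimal()
}
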
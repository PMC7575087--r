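#' Violin plot of EDI distributions per pair
#'
#' The classic per-pair view of tissue expression divergence: one violin of
#' EDI values across tissues per ohnologue pair, coloured by rediploidization
#' class, with the median marked.
#'
#' @param object An [edi_table()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.edi_table <- function(object, ...) {
  d <- as_tibble(object)
  ord <- edi_summary(object) |> arrange(.data$median_edi)
  d$pair_id <- factor(d$pair_id, levels = ord$pair_id)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$edi, y = .data$pair_id,
    fill = .data$rediploid_class)) +
    ggplot2::geom_violin(scale = "width", linewidth = 0.2) +
    ggplot2::stat_summary(fun = median, geom = "point", shape = 124, size = 3) +
    ggplot2::scale_fill_manual(
      values = c(late = "#d73027", mid = "#4575b4", early = "#1a9850"),
      na.value = "grey70", name = "rediploidization"
    ) +
    ggplot2::labs(x = "expression divergence index (EDI)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Phase / amplitude overview of a rhythm screen
#'
#' Plots each gene's fitted peak phase against its cosinor amplitude,
#' facetted by tissue and condition; significant genes are highlighted.
#'
#' @param object A [screen_rhythms()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rhythm_screen <- function(object, ...) {
  d <- as_tibble(object) |> filter(!is.na(.data$tau))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$phase_h, y = .data$amplitude,
    colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.7, size = 1.4) +
    ggplot2::facet_grid(ggplot2::vars(.data$tissue), ggplot2::vars(.data$condition)) +
    ggplot2::scale_x_continuous(breaks = seq(0, 24, 6), limits = c(0, 24)) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#d73027", `FALSE` = "grey60")) +
    ggplot2::labs(x = "peak phase (h)", y = "amplitude (log2 units)") +
    ggplot2::theme_minimal()
}

#' Cluster mean profiles of a developmental clustering
#'
#' One line per cluster centroid over the stages, the standard summary view
#' of distinct developmental expression patterns.
#'
#' @param clusters A [cluster_profiles()] result.
#' @return A ggplot object.
#' @export
plot_cluster_profiles <- function(clusters) {
  cent <- attr(clusters, "centroids")
  d <- as_tibble(cent, rownames = "cluster") |>
    tidyr::pivot_longer(-"cluster", names_to = "stage", values_to = "z")
  d$stage <- factor(d$stage, levels = colnames(cent))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$stage, y = .data$z,
    group = .data$cluster, colour = .data$cluster)) +
    ggplot2::geom_line(linewidth = 0.9) +
    ggplot2::geom_point(size = 1.6) +
    ggplot2::labs(x = NULL, y = "standardized expression") +
    ggplot2::theme_minimal()
}

#' Seawater response of the two copies of each pair
#'
#' Scatter of the two copies' log2 fold changes (SW vs FW); pairs with a
#' significant copy-by-condition interaction fall off the diagonal and are
#' coloured by divergence mode.
#'
#' @param object A [pair_divergence_report()].
#' @param ... Unused.
#' @return A ggplot object (NULL-safe: requires the interaction columns).
#' @export
autoplot.divergence_report <- function(object, ...) {
  d <- as_tibble(object)
  if (!all(c("log2fc_gene1", "log2fc_gene2") %in% names(d))) {
    stopf("report carries no interaction fold changes to plot")
  }
  ggplot2::ggplot(d, ggplot2::aes(x = .data$log2fc_gene1, y = .data$log2fc_gene2,
    colour = .data$mode)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point(size = 2, alpha = 0.8) +
    ggplot2::labs(
      x = "log2 FC copy 1 (SW vs FW)", y = "log2 FC copy 2 (SW vs FW)",
      colour = "divergence mode"
    ) +
    ggplot2::theme_minimal()
}
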
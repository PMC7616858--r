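# ggplot2 displays for the main result types.

#' Plot a residue essentiality map
#'
#' Per-residue aggregate z across the protein, hits highlighted, optional
#' domain intervals as shaded strips (mirrors the per-sgRNA depletion track
#' of a saturation-mutagenesis screen figure).
#'
#' @param object A [build_residue_map()] result.
#' @param domains Optional domain track (`label`, `start`, `end`).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot residue_map
#' @export
autoplot.residue_map <- function(object, domains = NULL, ...) {
  m <- as_tibble(object) |> filter(n_guides >= 1)
  hit_z <- attr(object, "hit_z")
  p <- ggplot2::ggplot(m, ggplot2::aes(x = residue, y = aggregate_z))
  if (!is.null(domains)) {
    p <- p + ggplot2::geom_rect(
      data = as_tibble(domains),
      ggplot2::aes(xmin = start, xmax = end, fill = label),
      ymin = -Inf, ymax = Inf, alpha = 0.15, inherit.aes = FALSE
    )
  }
  p +
    ggplot2::geom_point(ggplot2::aes(colour = hit), size = 0.8) +
    ggplot2::geom_hline(yintercept = hit_z, linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "firebrick",
                                            `FALSE` = "grey40")) +
    ggplot2::labs(x = "protein residue", y = "aggregate z (min over guides)",
                  colour = sprintf("hit (z <= %g)", hit_z)) +
    ggplot2::theme_minimal()
}

#' Plot guide score distributions by category
#'
#' @param object A [score_guides()] result.
#' @param manifest Guide manifest providing categories.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_score_distributions <- function(object, manifest, ...) {
  df <- as_tibble(object) |>
    filter(pass_filter) |>
    inner_join(manifest[, c("guide_id", "category")], by = "guide_id")
  ggplot2::ggplot(df, ggplot2::aes(x = category, y = z, fill = category)) +
    ggplot2::geom_boxplot(outlier.size = 0.5, show.legend = FALSE) +
    ggplot2::facet_grid(cell_line ~ editor) +
    ggplot2::labs(x = NULL, y = "depletion z-score") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Cross-screen concordance scatter
#'
#' z-scores of one screen against another over the shared passing guides,
#' annotated with the Pearson r-squared.
#'
#' @param scores_a,scores_b Two [score_guides()] results (single screens).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_concordance <- function(scores_a, scores_b, ...) {
  a <- as_tibble(scores_a) |> filter(pass_filter) |> select(guide_id, z)
  b <- as_tibble(scores_b) |> filter(pass_filter) |> select(guide_id, z)
  shared <- inner_join(a, b, by = "guide_id", suffix = c("_a", "_b"))
  cc <- screen_concordance(scores_a, scores_b)
  ggplot2::ggplot(shared, ggplot2::aes(x = .data$z_a, y = .data$z_b)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.7) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::labs(
      x = "screen A z", y = "screen B z",
      subtitle = sprintf("r2 = %.2f over %d shared guides", cc$r2, cc$n_shared)
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
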
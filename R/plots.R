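# ggplot2 views of geometry, cells, densities and scores.

#' Plot compartment geometry
#'
#' Tissue outline, tumor polygon, IM band and TC polygon, with the
#' interface polyline. The y axis is reversed to match the image
#' convention (y increases downward).
#'
#' @param object A `mif_geometry`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mif_geometry <- function(object, ...) {
  poly_df <- function(m, what) {
    tibble::tibble(x = m[, 1], y = m[, 2], role = what)
  }
  polys <- dplyr::bind_rows(
    poly_df(object$tumor, "tumor"),
    poly_df(object$im_band, "IM band"),
    poly_df(object$tc, "TC")
  )
  iface <- poly_df(object$interface, "interface")
  ggplot2::ggplot() +
    ggplot2::geom_polygon(
      data = polys,
      ggplot2::aes(x = .data$x, y = .data$y, fill = .data$role),
      alpha = 0.4, colour = "grey30", linewidth = 0.2) +
    ggplot2::geom_path(
      data = iface,
      ggplot2::aes(x = .data$x, y = .data$y), colour = "black", linewidth = 0.7) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot cells over the compartment geometry
#'
#' @param cells Region-assigned cell tibble (one sample).
#' @param geometry The sample's `mif_geometry`.
#' @param colour_by Column to colour points by (default `region`).
#' @param max_cells Subsample cap for plotting speed.
#' @return A ggplot.
#' @export
plot_cells <- function(cells, geometry, colour_by = "region", max_cells = 20000) {
  if (nrow(cells) > max_cells) cells <- cells[sample.int(nrow(cells), max_cells), ]
  autoplot.mif_geometry(geometry) +
    ggplot2::geom_point(
      data = cells,
      ggplot2::aes(x = .data$x_um, y = .data$y_um,
                   colour = .data[[colour_by]]),
      size = 0.3, alpha = 0.6) +
    ggplot2::guides(colour = ggplot2::guide_legend(override.aes = list(size = 2)))
}

#' Paired IM-vs-TC density plot for one phenotype
#'
#' Per-sample densities in the two compartments joined by segments, the
#' standard display for a Wilcoxon matched-pairs comparison.
#'
#' @param densities Density tibble.
#' @param phenotype Phenotype label.
#' @param panel Staining panel (default: first carrying the phenotype).
#' @return A ggplot.
#' @export
plot_paired_density <- function(densities, phenotype, panel = NULL) {
  d <- densities[densities$phenotype == phenotype, , drop = FALSE]
  if (is.null(panel)) panel <- sort(unique(d$panel))[1]
  d <- d[d$panel == panel, , drop = FALSE]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$region, y = .data$density)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$sample_id), colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$region), size = 2) +
    ggplot2::labs(title = phenotype, y = "density (cells/mm²)", x = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Plot composite score totals by sample
#'
#' @param object A `mif_scores`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mif_scores <- function(object, ...) {
  high_min <- attr(object, "high_min")
  df <- tibble::tibble(sample_id = object$sample_id, total = object$total,
                       category = object$category)
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$sample_id, .data$total),
    y = .data$total, fill = .data$category)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = high_min - 0.5, linetype = 2) +
    ggplot2::labs(x = NULL, y = paste(object$scheme[1], "total"), fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Heatmap of an association panel's significance
#'
#' @param panel Output of [association_panel()].
#' @return A ggplot with star annotations.
#' @export
plot_association_panel <- function(panel) {
  long <- panel |>
    tidyr::pivot_longer(dplyr::starts_with("stars_"),
                        names_to = "column", values_to = "stars") |>
    dplyr::mutate(column = dplyr::recode(.data$column,
      stars_group = "High vs low", stars_cor_cd8 = "vs CD8+",
      stars_cor_pdl1 = "vs PD-L1+"))
  long$row <- paste0(long$panel, ": ", long$phenotype)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$column, y = .data$row)) +
    ggplot2::geom_tile(ggplot2::aes(
      fill = factor(.data$stars, levels = c("ns", "*", "**", "***"))),
      colour = "white") +
    ggplot2::geom_text(ggplot2::aes(label = .data$stars), size = 3) +
    ggplot2::scale_fill_brewer(palette = "Reds", na.value = "grey90") +
    ggplot2::labs(x = NULL, y = NULL, fill = "significance") +
    ggplot2::theme_minimal()
}
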
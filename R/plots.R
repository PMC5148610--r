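# ggplot2 figures mirroring the study's main quantification panels.

#' Contact area vs eccentricity scatter of classified contact-sets
#'
#' @param sets Feature tibble with `a_area`, `b_ecc` and a `label` (or
#'   `truth_label`) column.
#' @return A ggplot.
#' @export
plot_contact_features <- function(sets) {
  lab <- if ("label" %in% names(sets)) sets$label else sets$truth_label
  ggplot2::ggplot(sets, ggplot2::aes(x = .data$b_ecc, y = .data$a_area,
                                     colour = lab)) +
    ggplot2::geom_point(alpha = 0.6, size = 1.2) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "eccentricity (µm)",
                  y = "contact area (µm²)",
                  colour = "contact-set") +
    ggplot2::theme_minimal()
}

#' Convergence bar chart: cones contacted per BC, by type and cone class
#'
#' @param convergence The `convergence` tibble from
#'   [convergence_divergence()].
#' @return A ggplot with 95% bootstrap CI bars.
#' @export
plot_convergence <- function(convergence) {
  ggplot2::ggplot(convergence,
                  ggplot2::aes(x = .data$type, y = .data$mean_cones,
                               fill = .data$spectral)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
      position = ggplot2::position_dodge(width = 0.8), width = 0.25) +
    ggplot2::labs(x = NULL, y = "cones contacted per cell",
                  fill = "cone class") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' SAC-corrected CBC5 axonal depth profiles by assigned subtype
#'
#' @param fit A `cbc5_fit` from [classify_cbc5()].
#' @return A ggplot of per-subtype mean profiles (ON band = 0, OFF band = 1).
#' @export
plot_depth_profiles <- function(fit) {
  df <- fit$profiles |>
    left_join(tidy(fit)[, c("cell_id", "subtype")], by = "cell_id") |>
    group_by(.data$subtype, .data$depth) |>
    summarise(density = mean(.data$density), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$depth, y = .data$density,
                                   colour = .data$subtype)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::geom_vline(xintercept = c(0, 1), linetype = "dashed",
                        colour = "grey50") +
    ggplot2::labs(x = "corrected IPL depth (ON band = 0, OFF band = 1)",
                  y = "axonal density", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Dendritic-field mosaic of one BC type over the cone array
#'
#' @param cells Cell metadata of one type.
#' @param skeletons Named skeleton list.
#' @param cones Optional cone tibble (drawn as points, S-cones highlighted).
#' @return A ggplot of hull outlines and cone positions.
#' @export
plot_mosaic <- function(cells, skeletons, cones = NULL) {
  hulls <- bind_rows(lapply(cells$cell_id, function(id) {
    p <- dendritic_hull(skeletons[[id]])$poly
    tibble(cell_id = id, x = p[, 1], y = p[, 2])
  }))
  g <- ggplot2::ggplot() +
    ggplot2::geom_polygon(data = hulls,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       group = .data$cell_id),
                          fill = NA, colour = "grey30", linewidth = 0.3)
  if (!is.null(cones)) {
    g <- g + ggplot2::geom_point(
      data = cones, ggplot2::aes(x = .data$x, y = .data$y,
                                 colour = .data$spectral), size = 1)
  }
  g + ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)", colour = "cone") +
    ggplot2::theme_minimal()
}
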
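#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a free-energy surface
#'
#' Filled raster with contour lines every `contour_step` kcal/mol
#' (default 2, the convention used for published surfaces).
#'
#' @param object a `fes_grid`
#' @param contour_step contour spacing, kcal/mol
#' @param cap clip free energies above this for display (kcal/mol)
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.fes_grid <- function(object, contour_step = 2, cap = NULL, ...) {
  df <- tidy(object)
  if (!is.null(cap)) df$free <- pmin(df$free, cap)
  ggplot2::ggplot(df, ggplot2::aes(.data$cv1, .data$cv2)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$free)) +
    ggplot2::geom_contour(ggplot2::aes(z = .data$free),
                          binwidth = contour_step, colour = "white",
                          linewidth = 0.2) +
    ggplot2::scale_fill_viridis_c(name = "F (kcal/mol)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "CV1", y = "CV2") +
    ggplot2::theme_minimal()
}

#' Plot an interaction-occupancy table
#' @param object an `occupancy_table`
#' @param ... unused
#' @return a ggplot with the strong/weak thresholds marked
#' @export
autoplot.occupancy_table <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$pair <- paste0(df$chain_a, df$resnum_a, "-", df$chain_b,
                    df$resnum_b)
  ggplot2::ggplot(df, ggplot2::aes(.data$pair, .data$occupancy,
                                   fill = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = c(0.60, 0.75), linetype = "dashed",
                        colour = "grey40") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "occupancy") +
    ggplot2::theme_minimal()
}

#' Plot an RMSF profile along the sequence
#' @param object an `rmsf_profile`
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.rmsf_profile <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(.data$resnum, .data$rmsf,
                               colour = .data$chain)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "residue", y = "RMSF (Å)") +
    ggplot2::theme_minimal()
}

#' Plot a residue-level crystal-contact map
#' @param object a `crystal_contact_map`
#' @param ... unused
#' @return a ggplot tile map (one facet level merged over images)
#' @export
autoplot.crystal_contact_map <- function(object, ...) {
  df <- merge_contact_map(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$asu_resnum, .data$nb_resnum,
                                   fill = .data$min_distance)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "min d (Å)",
                                  direction = -1) +
    ggplot2::labs(x = "asymmetric-unit residue",
                  y = "symmetry-neighbour residue") +
    ggplot2::theme_minimal()
}

#' Plot a distance histogram with its mean marked
#' @param object a `dist_histogram`
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.dist_histogram <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(.data$mid, .data$count)) +
    ggplot2::geom_col(width = diff(object$breaks)[1],
                      fill = "steelblue") +
    ggplot2::geom_vline(xintercept = object$mean, linetype = "dashed") +
    ggplot2::labs(x = "distance (Å)", y = "frames") +
    ggplot2::theme_minimal()
}
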
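#' Plot methods
#'
#' `autoplot()` methods give quick-look graphics for the main result types:
#' a (z, r) concentration map for a converged state, metric-vs-affinity
#' curves for a sweep, and occupancy curves for a receptor-binding map.
#'
#' @name plots
NULL

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @rdname plots
#' @param object result object.
#' @param species which field to map ("V", "Vc", "VH", "H",
#'   "total_soluble").
#' @param ... unused.
#' @export
autoplot.vegf_steady <- function(object, species = "V", ...) {
  tab <- tidy(object)
  if (identical(species, "total_soluble")) {
    tab <- dplyr::summarise(
      dplyr::group_by(dplyr::filter(tab, .data$species %in% c("V", "Vc")),
                      .data$cell, .data$z, .data$r),
      conc_pM = sum(.data$conc_pM), .groups = "drop")
    tab$species <- "total_soluble"
  } else {
    tab <- dplyr::filter(tab, .data$species == !!species)
  }
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$z, y = .data$r,
                                    fill = .data$conc_pM)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "pM") +
    ggplot2::labs(x = "z (μm)", y = "r (μm)",
                  title = sprintf("%s: %s", object$cfg$label, species)) +
    ggplot2::theme_minimal()
}

#' @rdname plots
#' @export
autoplot.sweep_result <- function(object, ...) {
  long <- tidyr::pivot_longer(
    dplyr::filter(object$points, .data$converged),
    cols = c("soluble_uncleaved", "cleaved", "total_soluble", "matrix_bound",
             "total"),
    names_to = "metric", values_to = "pM")
  aff <- dplyr::filter(long, .data$axis == "affinity",
                       .data$k_P == object$spec$kP_fixed)
  aff$Kd_plot <- ifelse(is.infinite(aff$Kd), max(aff$Kd[is.finite(aff$Kd)]) * 4,
                        aff$Kd)
  ggplot2::ggplot(aff, ggplot2::aes(x = .data$Kd_plot, y = .data$pM,
                                    colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "HSPG Kd (nM; right edge = non-binding)",
                  y = "tip-region concentration (pM)",
                  title = sprintf("affinity sweep (%s)", object$spec$variant)) +
    ggplot2::theme_minimal()
}

#' @rdname plots
#' @export
autoplot.receptor_map <- function(object, ...) {
  long <- tidyr::pivot_longer(object$curves,
                              cols = c("R2_occupied", "R1_occupied"),
                              names_to = "receptor", values_to = "occupied")
  long$Kd_plot <- ifelse(is.infinite(long$Kd),
                         max(long$Kd[is.finite(long$Kd)]) * 4, long$Kd)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$Kd_plot, y = .data$occupied,
                                     colour = .data$receptor)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "HSPG Kd (nM)", y = "occupied receptors per tip cell",
                  title = "receptor binding vs. isoform affinity") +
    ggplot2::theme_minimal()
}

#' Axial profiles beside the sprout
#'
#' Line plot of the soluble, cleaved and bound concentrations along z in
#' the first interstitial ring (or the radial mean for sprout-free runs).
#'
#' @param res a `vegf_steady`.
#' @return a ggplot.
#' @export
plot_profiles <- function(res) {
  grid <- res$grid
  if (!is.null(grid$patches)) {
    cells <- grid$id[, grid$patches$adj_ir]
    pick <- function(x) x[cells]
  } else {
    pick <- function(x) vapply(seq_len(grid$nz), function(iz)
      stats::weighted.mean(x[grid$id[iz, ]], grid$vol[iz, ]), numeric(1))
  }
  tab <- tibble::tibble(
    z = grid$zc,
    soluble = molec_um3_to_pM(pick(res$V)),
    cleaved = molec_um3_to_pM(pick(res$Vc)),
    bound = molec_um3_to_pM(pick(res$VH)))
  long <- tidyr::pivot_longer(tab, -"z", names_to = "pool",
                              values_to = "pM")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$z, y = .data$pM,
                                     colour = .data$pool)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "z (μm)", y = "concentration (pM)",
                  title = res$cfg$label) +
    ggplot2::theme_minimal()
}
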
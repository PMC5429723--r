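#' Plot a hydrogen-bond summary
#'
#' Bars of mean bonds per donor residue per frame, split by acceptor group,
#' with block-standard-error bars.
#'
#' @param object `hbond_summary` from [hbond_summary()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.hbond_summary <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$donor_resname, y = .data$mean_bonds,
                               fill = .data$acceptor_group)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_bonds - .data$se,
                   ymax = .data$mean_bonds + .data$se),
      position = ggplot2::position_dodge(width = 0.8), width = 0.25) +
    ggplot2::labs(x = "donor residue", y = "H-bonds per residue per frame",
                  fill = "acceptor group") +
    ggplot2::theme_minimal()
}

#' Plot a particle-membrane distance series
#'
#' @param object tibble from [np_membrane_distance()].
#' @param ... unused.
#' @return a ggplot object; the dashed line marks contact (distance 0).
#' @export
autoplot.nf_distance_series <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$frame, y = .data$distance)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "frame", y = "particle-phosphate distance (A)") +
    ggplot2::theme_minimal()
}

#' Plot the z-density profile of an assembled system
#'
#' Atom counts along the membrane normal per component (particle, lipid,
#' water) — the standard one-look sanity check of an assembled
#' nanoparticle-bilayer box.
#'
#' @param object `sim_system` from [assemble_system()].
#' @param binwidth histogram bin width (A).
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.sim_system <- function(object, binwidth = 2, ...) {
  ggplot2::ggplot(object$structure,
                  ggplot2::aes(x = .data$z, colour = .data$component)) +
    ggplot2::geom_freqpoly(binwidth = binwidth) +
    ggplot2::geom_vline(xintercept = object$p_plane, linetype = "dashed") +
    ggplot2::labs(x = "z (A)", y = "atoms per bin", colour = "component") +
    ggplot2::theme_minimal()
}
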
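#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot methods for junctionmech results
#'
#' `autoplot.sneddon_fit()` overlays the fitted Sneddon curve on the data;
#' `autoplot.pmf_fit()` draws the free-energy profile with its bootstrap
#' error ribbon; `autoplot.contact_map()` shows the peptide-domain contact
#' matrix; `plot_linescan()` and `plot_fret_indices()` display linescan
#' profiles and per-group FRET index distributions.
#'
#' @param object Fitted object.
#' @param ... Unused.
#' @return A ggplot object.
#' @name junctionmech-plots
NULL

#' @rdname junctionmech-plots
#' @method autoplot sneddon_fit
#' @export
autoplot.sneddon_fit <- function(object, ...) {
  curve <- object$curve
  model <- tibble::tibble(
    indentation_nm = curve$indentation_nm,
    force_nN = sneddon_force(
      object$youngs_modulus_kPa,
      pmax(curve$indentation_nm - object$contact_offset_nm, 0),
      object$poisson_ratio, object$half_angle))
  ggplot2::ggplot(curve, ggplot2::aes(.data$indentation_nm, .data$force_nN)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::geom_line(data = model, colour = "firebrick") +
    ggplot2::labs(
      x = "indentation (nm)", y = "force (nN)",
      title = sprintf("Sneddon fit: E = %.3g kPa, R² = %.3f",
                      object$youngs_modulus_kPa, object$r_squared))
}

#' @rdname junctionmech-plots
#' @method autoplot pmf_fit
#' @export
autoplot.pmf_fit <- function(object, ...) {
  prof <- object$profile
  p <- ggplot2::ggplot(prof, ggplot2::aes(.data$xi_nm, .data$free_energy_kJ_mol))
  if (any(is.finite(prof$error_kJ_mol))) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$free_energy_kJ_mol - .data$error_kJ_mol,
                   ymax = .data$free_energy_kJ_mol + .data$error_kJ_mol),
      fill = "steelblue", alpha = 0.3)
  }
  p + ggplot2::geom_line(colour = "steelblue4") +
    ggplot2::labs(x = expression(xi ~ "(nm)"),
                  y = "free energy (kJ/mol)",
                  title = "Potential of mean force")
}

#' @rdname junctionmech-plots
#' @method autoplot contact_map
#' @export
autoplot.contact_map <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(.data$domain_residue, .data$peptide_position,
                               fill = .data$distance)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "distance (Å)") +
    ggplot2::labs(x = "domain residue", y = "peptide position")
}

#' @rdname junctionmech-plots
#' @param profile Tibble from [linescan()].
#' @export
plot_linescan <- function(profile, ...) {
  ggplot2::ggplot(profile, ggplot2::aes(.data$distance_um, .data$intensity)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "distance (µm)", y = "intensity (counts)")
}

#' @rdname junctionmech-plots
#' @param indices Tibble from [quantify_junctions()].
#' @export
plot_fret_indices <- function(indices, ...) {
  ggplot2::ggplot(indices, ggplot2::aes(.data$group, .data$fret_index)) +
    ggplot2::geom_boxplot(outlier.shape = NA, width = 0.5) +
    ggplot2::geom_jitter(width = 0.12, alpha = 0.6, size = 1) +
    ggplot2::labs(x = NULL, y = "FRET index")
}
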
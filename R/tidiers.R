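#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Broom-style tidiers for fitted objects
#'
#' `tidy()` returns per-component tibbles (fit parameters, profile bins,
#' pairwise comparisons); `glance()` returns a one-row model summary.
#'
#' @param x A fitted object (`sneddon_fit`, `pmf_fit`, `sbt_coefficients`,
#'   `kruskal_dunn`, `mann_whitney`).
#' @param ... Unused.
#' @return A tibble.
#' @name junctionmech-tidiers
NULL

#' @rdname junctionmech-tidiers
#' @method tidy sneddon_fit
#' @export
tidy.sneddon_fit <- function(x, ...) {
  tibble::tibble(E_kPa = x$youngs_modulus_kPa, r_squared = x$r_squared,
                 contact_offset_nm = x$contact_offset_nm,
                 residual_norm_nN = x$residual_norm_nN, n_fit = x$n_fit)
}

#' @rdname junctionmech-tidiers
#' @method glance sneddon_fit
#' @export
glance.sneddon_fit <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared, n_fit = x$n_fit,
                 poisson_ratio = x$poisson_ratio, half_angle = x$half_angle)
}

#' @rdname junctionmech-tidiers
#' @method tidy pmf_fit
#' @export
tidy.pmf_fit <- function(x, ...) x$profile

#' @rdname junctionmech-tidiers
#' @method glance pmf_fit
#' @export
glance.pmf_fit <- function(x, ...) {
  tibble::tibble(n_windows = x$n_windows, n_bins = nrow(x$profile),
                 temperature_K = x$temperature, converged = x$converged,
                 iterations = x$iterations, anchor = x$anchor,
                 n_boot = x$n_boot)
}

#' @rdname junctionmech-tidiers
#' @method tidy sbt_coefficients
#' @export
tidy.sbt_coefficients <- function(x, ...) {
  tibble::tibble(coefficient = c("sbt_donor", "sbt_acceptor"),
                 estimate = c(x$sbt_donor, x$sbt_acceptor),
                 n_rois = c(length(x$donor_ratios), length(x$acceptor_ratios)))
}

#' @rdname junctionmech-tidiers
#' @method tidy kruskal_dunn
#' @export
tidy.kruskal_dunn <- function(x, ...) x$pairwise

#' @rdname junctionmech-tidiers
#' @method glance kruskal_dunn
#' @export
glance.kruskal_dunn <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df = x$df, p_value = x$p_value,
                 n = x$n)
}

#' @rdname junctionmech-tidiers
#' @method tidy mann_whitney
#' @export
tidy.mann_whitney <- function(x, ...) {
  tibble::tibble(u = x$u, p_value = x$p_value, method = x$method,
                 n_a = x$n_a, n_b = x$n_b)
}
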
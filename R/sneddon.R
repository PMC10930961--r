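#' Sneddon force for a rigid conical indenter
#'
#' Closed-form contact force of a rigid cone pressed into an elastic
#' half-space: \eqn{F = (2/\pi)\,E/(1-\nu^2)\,\tan(\alpha)\,\delta^2}.
#' Units follow atomic-force-microscopy practice: Young's modulus in kPa,
#' indentation in nm, force in nN (the kPa nm^2 to nN conversion is 1e-6).
#'
#' @param youngs_modulus Young's modulus E in kPa (> 0).
#' @param indentation Indentation depth(s) \eqn{\delta} in nm (>= 0); vectorised.
#' @param poisson_ratio Poisson's ratio \eqn{\nu} in `[0, 1)`; 0.5 is the
#'   incompressible value used for live cells.
#' @param half_angle Half-opening angle \eqn{\alpha} of the conical tip in
#'   degrees (0, 90); 18 degrees for the probes modelled here.
#' @return Force in nN, same length as `indentation`.
#' @examples
#' sneddon_force(10, 500) # ~0.69 nN
#' @export
sneddon_force <- function(youngs_modulus, indentation, poisson_ratio = 0.5,
                          half_angle = 18) {
  check_number(youngs_modulus, "youngs_modulus", lower = 0, strict_lower = TRUE)
  check_number(poisson_ratio, "poisson_ratio", lower = 0, upper = 1,
               strict_upper = TRUE)
  check_number(half_angle, "half_angle", lower = 0, upper = 90,
               strict_lower = TRUE, strict_upper = TRUE)
  if (!is.numeric(indentation) || any(!is.finite(indentation))) {
    abort_param("indentation", "must be finite numeric")
  }
  if (any(indentation < 0)) {
    rlang::abort("negative indentation is outside the contact model's domain",
                 class = "junctionmech_domain_error")
  }
  # kPa * nm^2 -> nN: 1e3 Pa * 1e-18 m^2 = 1e-15 N = 1e-6 nN
  1e-6 * (2 / pi) * youngs_modulus / (1 - poisson_ratio^2) *
    tan(half_angle * pi / 180) * indentation^2
}

as_force_curve <- function(curve) {
  if (!is.data.frame(curve) ||
      !all(c("indentation_nm", "force_nN") %in% names(curve))) {
    abort_param("curve",
                "must be a data frame with columns indentation_nm and force_nN")
  }
  if (nrow(curve) < 10L) abort_param("curve", "needs at least 10 points")
  if (is.unsorted(curve$indentation_nm)) {
    abort_param("curve", "indentation_nm must be monotone non-decreasing")
  }
  tibble::as_tibble(curve)
}

#' Baseline-correct a force-indentation curve
#'
#' Fits a straight line to the pre-contact segment (by default the first
#' `pre_fraction` of points, at least 5) and subtracts it from the whole
#' curve, removing constant offsets and linear photodiode drift.
#'
#' @param curve Data frame with columns `indentation_nm`, `force_nN`.
#' @param pre_fraction Fraction of leading points treated as pre-contact.
#' @param n_pre Explicit number of leading pre-contact points; overrides
#'   `pre_fraction` when given.
#' @return The corrected curve as a tibble; the fitted baseline intercept and
#'   slope are kept in attributes `baseline_intercept` / `baseline_slope`.
#' @export
correct_baseline <- function(curve, pre_fraction = 0.2, n_pre = NULL) {
  curve <- as_force_curve(curve)
  n <- nrow(curve)
  k <- if (!is.null(n_pre)) as.integer(n_pre) else max(5L, floor(pre_fraction * n))
  if (k < 5L || k > n) {
    rlang::abort("no identifiable pre-contact segment (need >= 5 leading points)",
                 class = "junctionmech_correction_error")
  }
  pre <- curve[seq_len(k), ]
  fit <- stats::lm(force_nN ~ indentation_nm, data = pre)
  base <- stats::predict(fit, newdata = curve["indentation_nm"])
  out <- dplyr::mutate(curve, force_nN = .data$force_nN - as.numeric(base))
  attr(out, "baseline_intercept") <- unname(stats::coef(fit)[1])
  attr(out, "baseline_slope") <- unname(stats::coef(fit)[2])
  attr(out, "n_pre") <- k
  out
}

#' Detect the tip-sample contact point
#'
#' On a baseline-corrected curve, returns the indentation at the first sample
#' whose force exceeds `threshold_sd` times the pre-contact noise sd and stays
#' above that level for the remainder of the curve.
#'
#' @inheritParams correct_baseline
#' @param threshold_sd Noise-floor multiplier (default 3).
#' @param n_pre Number of leading points used to estimate the baseline noise
#'   sd (defaults to the same rule as [correct_baseline()]).
#' @return Contact offset in nm.
#' @export
detect_contact_point <- function(curve, threshold_sd = 3, n_pre = NULL) {
  curve <- as_force_curve(curve)
  n <- nrow(curve)
  k <- if (!is.null(n_pre)) as.integer(n_pre) else max(5L, floor(0.2 * n))
  noise_sd <- stats::sd(curve$force_nN[seq_len(min(k, n))])
  thr <- threshold_sd * noise_sd
  above <- curve$force_nN > thr
  # first index from which the force never drops back to the noise floor
  stays <- rev(cumprod(rev(above))) > 0
  idx <- which(stays)[1]
  if (is.na(idx)) {
    rlang::abort("force never exceeds the contact threshold (no contact found)",
                 class = "junctionmech_no_contact_error")
  }
  curve$indentation_nm[idx]
}

#' Fit the Sneddon conical model to one force curve
#'
#' Least-squares estimate of Young's modulus from the post-contact region of a
#' baseline-corrected curve. The modulus is linear in the model given the
#' contact offset, so the offset is estimated by profiling the residual sum of
#' squares over candidate offsets (a coarse scan over sample positions
#' followed by a golden-section polish); supplying `contact_offset` restricts
#' the scan to its neighbourhood.
#'
#' @inheritParams sneddon_force
#' @param curve Data frame with columns `indentation_nm`, `force_nN`
#'   (baseline-corrected).
#' @param contact_offset Contact offset in nm, e.g. from
#'   [detect_contact_point()]; `NULL` (default) profiles over the whole ramp.
#' @param refine_contact Profile the offset by 1-D least squares (default
#'   `TRUE`); when `FALSE` the supplied or detected offset is used as is.
#' @param threshold_sd Passed to [detect_contact_point()].
#' @return An object of class `sneddon_fit`: list with `youngs_modulus_kPa`,
#'   `r_squared`, `contact_offset_nm`, `residual_norm_nN`, `n_fit` and the
#'   model settings. Use [generics::tidy()]/[generics::glance()] to get tibbles.
#' @export
fit_sneddon <- function(curve, poisson_ratio = 0.5, half_angle = 18,
                        contact_offset = NULL, refine_contact = TRUE,
                        threshold_sd = 3) {
  curve <- as_force_curve(curve)
  delta <- curve$indentation_nm
  force <- curve$force_nN

  unit_modulus <- function(off) {
    d <- pmax(delta - off, 0)
    sneddon_force(1, d, poisson_ratio, half_angle)
  }
  # E minimising ||F - E g(off)|| given offset; SSR profiled over the offset
  ssr <- function(off) {
    g <- unit_modulus(off)
    e <- sum(force * g) / sum(g^2)
    sum((force - e * g)^2)
  }
  n <- length(delta)
  spacing <- if (n > 1) max(diff(delta)) else 0
  if (refine_contact) {
    # profile the offset: coarse scan over sample positions (keeping >= 5
    # post-contact points), then local golden-section polish
    cand <- delta[seq_len(n - 5L)]
    if (!is.null(contact_offset)) {
      cand <- cand[abs(cand - contact_offset) <= 3 * spacing]
      if (length(cand) == 0) cand <- contact_offset
    }
    best <- cand[which.min(vapply(cand, ssr, numeric(1)))]
    lo <- max(min(delta), best - spacing)
    hi <- min(max(delta) - spacing, best + spacing)
    off <- if (hi > lo) stats::optimize(ssr, c(lo, hi), tol = 1e-10)$minimum else best
    if (ssr(best) <= ssr(off)) off <- best
  } else {
    off <- contact_offset %||% detect_contact_point(curve, threshold_sd)
  }

  post <- delta > off
  if (sum(post) < 5L) {
    rlang::abort("fewer than 5 post-contact points; cannot fit",
                 class = "junctionmech_insufficient_data_error")
  }
  g <- unit_modulus(off)
  denom <- sum(g[post]^2)
  if (denom <= 0) {
    rlang::abort("degenerate contact region; fit failed",
                 class = "junctionmech_fit_error")
  }
  e_hat <- sum(force[post] * g[post]) / denom
  if (!is.finite(e_hat) || e_hat <= 0) {
    rlang::abort("fit did not converge to a positive modulus",
                 class = "junctionmech_fit_error")
  }
  res <- force[post] - e_hat * g[post]
  ss_res <- sum(res^2)
  ss_tot <- sum((force[post] - mean(force[post]))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_

  structure(list(
    youngs_modulus_kPa = e_hat,
    r_squared = r2,
    contact_offset_nm = off,
    residual_norm_nN = sqrt(ss_res),
    n_fit = sum(post),
    poisson_ratio = poisson_ratio,
    half_angle = half_angle,
    curve = curve
  ), class = "sneddon_fit")
}

#' @export
print.sneddon_fit <- function(x, ...) {
  cat(sprintf("Sneddon fit: E = %.4g kPa, R^2 = %.4f, contact at %.1f nm (%d points)\n",
              x$youngs_modulus_kPa, x$r_squared, x$contact_offset_nm, x$n_fit))
  invisible(x)
}

#' Prepare a raw curve: iterated baseline correction and contact detection
#'
#' Alternates [correct_baseline()] and [detect_contact_point()], restricting
#' the baseline window to points before the current contact estimate, until
#' the estimate stabilises to within one sample spacing. This keeps
#' post-contact force out of the baseline fit when contact occurs early in
#' the ramp.
#'
#' @inheritParams detect_contact_point
#' @param max_iter Maximum alternations.
#' @return List with `curve` (corrected tibble) and `contact_offset_nm`.
#' @export
preprocess_force_curve <- function(curve, threshold_sd = 3, max_iter = 10) {
  curve <- as_force_curve(curve)
  n <- nrow(curve)
  spacing <- max(diff(curve$indentation_nm))
  # start from a short, almost surely pre-contact leading window
  cutoff <- curve$indentation_nm[min(n, max(10L, ceiling(0.05 * n)))]
  corrected <- curve
  contact <- NA_real_
  prev <- Inf
  for (i in seq_len(max_iter)) {
    k <- max(5L, sum(curve$indentation_nm <= cutoff))
    corrected <- correct_baseline(curve, n_pre = k)
    contact <- detect_contact_point(corrected, threshold_sd, n_pre = k)
    if (abs(contact - prev) <= spacing) break
    prev <- contact
    cutoff <- contact
  }
  list(curve = corrected, contact_offset_nm = contact)
}

#' Fit many force curves stored in long format
#'
#' @param data Data frame with columns `curve_id`, `indentation_nm`,
#'   `force_nN`.
#' @param baseline Apply [correct_baseline()] to each curve first.
#' @inheritParams fit_sneddon
#' @return Tibble with one row per curve: `curve_id`, `E_kPa`, `r_squared`,
#'   `contact_offset_nm`, `residual_norm_nN`, `n_fit`, `error` (NA when the
#'   fit succeeded, otherwise the failure message).
#' @export
fit_sneddon_curves <- function(data, poisson_ratio = 0.5, half_angle = 18,
                               baseline = TRUE, threshold_sd = 3) {
  if (!all(c("curve_id", "indentation_nm", "force_nN") %in% names(data))) {
    abort_param("data", "needs columns curve_id, indentation_nm, force_nN")
  }
  data |>
    dplyr::group_by(.data$curve_id) |>
    dplyr::group_map(function(df, key) {
      res <- tryCatch({
        cur <- df[c("indentation_nm", "force_nN")]
        off <- NULL
        if (baseline) {
          prep <- preprocess_force_curve(cur, threshold_sd)
          cur <- prep$curve
          off <- prep$contact_offset_nm
        }
        f <- fit_sneddon(cur, poisson_ratio, half_angle, contact_offset = off,
                         threshold_sd = threshold_sd)
        tibble::tibble(E_kPa = f$youngs_modulus_kPa, r_squared = f$r_squared,
                       contact_offset_nm = f$contact_offset_nm,
                       residual_norm_nN = f$residual_norm_nN,
                       n_fit = f$n_fit, error = NA_character_)
      }, error = function(e) {
        tibble::tibble(E_kPa = NA_real_, r_squared = NA_real_,
                       contact_offset_nm = NA_real_, residual_norm_nN = NA_real_,
                       n_fit = NA_integer_, error = conditionMessage(e))
      })
      dplyr::bind_cols(key, res)
    }) |>
    dplyr::bind_rows()
}

#' Filter Sneddon fits by goodness of fit
#'
#' Keeps fits with \eqn{R^2 \ge} `r2_min` (inclusive boundary), preserving
#' order. Accepts either the tibble from [fit_sneddon_curves()] or a list of
#' `sneddon_fit` objects.
#'
#' @param fits Tibble with an `r_squared` column, or list of `sneddon_fit`s.
#' @param r2_min Minimum R^2 retained (default 0.98).
#' @return Same type as the input, filtered.
#' @export
filter_fits <- function(fits, r2_min = 0.98) {
  if (is.data.frame(fits)) {
    return(dplyr::filter(fits, !is.na(.data$r_squared),
                         .data$r_squared >= r2_min))
  }
  fits[vapply(fits, function(f) isTRUE(f$r_squared >= r2_min), logical(1))]
}
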
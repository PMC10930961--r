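#' Harmonic umbrella bias potential
#'
#' \eqn{w(\xi) = k/2\,(\xi - c)^2} in kJ/mol for `xi` in nm and `k` in
#' kJ mol^-1 nm^-2.
#'
#' @param force_constant Harmonic force constant k (> 0), kJ mol^-1 nm^-2.
#' @param center Window centre c in nm.
#' @param xi Reaction-coordinate value(s) in nm; vectorised.
#' @return Bias energy in kJ/mol.
#' @export
bias_potential <- function(force_constant, center, xi) {
  check_number(force_constant, "force_constant", lower = 0, strict_lower = TRUE)
  force_constant / 2 * (xi - center)^2
}

# Normalise umbrella-window input to a list of
# list(center=, force_constant=, samples=) from either that list form or a
# long tibble (center_nm, k_kJ_mol_nm2, sample_nm).
as_windows <- function(windows) {
  if (is.data.frame(windows)) {
    need <- c("center_nm", "k_kJ_mol_nm2", "sample_nm")
    if (!all(need %in% names(windows))) {
      abort_param("windows", paste("long format needs columns",
                                   paste(need, collapse = ", ")))
    }
    sp <- split(windows, interaction(windows$center_nm, windows$k_kJ_mol_nm2,
                                     drop = TRUE))
    windows <- lapply(sp, function(df) {
      list(center = df$center_nm[1], force_constant = df$k_kJ_mol_nm2[1],
           samples = df$sample_nm)
    })
    windows <- windows[order(vapply(windows, `[[`, numeric(1), "center"))]
  }
  if (!is.list(windows) || length(windows) == 0) {
    abort_param("windows", "must be a non-empty list or long-format data frame")
  }
  for (w in windows) {
    if (!all(c("center", "force_constant", "samples") %in% names(w))) {
      abort_param("windows", "each window needs center, force_constant, samples")
    }
    if (w$force_constant <= 0) abort_param("force_constant", "must be > 0")
    if (length(w$samples) < 100) {
      abort_param("windows", sprintf(
        "window at %.3f nm has %d samples; >= 100 required for estimation",
        w$center, length(w$samples)))
    }
  }
  windows
}

# Core self-consistent WHAM iteration on fixed histograms.
# h: nwin x nbin count matrix (possibly fractional under bootstrap weights),
# cb: nwin x nbin bias energies at bin centres, kT scalar.
wham_iterate <- function(h, cb, kT, tolerance, max_iter, f_init = NULL) {
  n_i <- rowSums(h)
  h_b <- colSums(h)
  expb <- exp(-cb / kT)                     # nwin x nbin
  f <- f_init %||% rep(0, nrow(h))
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    denom <- colSums(n_i * exp(f / kT) * expb)
    p <- ifelse(denom > 0, h_b / denom, 0)
    zs <- expb %*% p                        # window partition sums
    f_new <- ifelse(zs > 0, -kT * log(zs), Inf)
    f_new <- f_new - f_new[1]
    delta <- max(abs(f_new - f)[is.finite(f_new) & is.finite(f)])
    f <- as.numeric(f_new)
    if (is.finite(delta) && delta < tolerance) {
      converged <- TRUE
      break
    }
  }
  denom <- colSums(n_i * exp(f / kT) * expb)
  p <- ifelse(denom > 0, h_b / denom, 0)
  list(p = p, f = f, converged = converged, iterations = iter)
}

#' Weighted-histogram (WHAM) free-energy profile from umbrella windows
#'
#' Self-consistent unbiasing of harmonically biased umbrella-sampling windows
#' into one potential of mean force along the reaction coordinate. Iterates
#' the window free-energy constants until the largest change falls below
#' `tolerance`, then converts the unbiased probability per bin to
#' \eqn{F(\xi) = -k_B T \ln p(\xi)}, anchored so the profile minimum is 0
#' (`anchor = "min"`) or the trailing-plateau mean is 0 (`anchor = "plateau"`).
#'
#' @param windows Umbrella windows: long tibble with columns `center_nm`,
#'   `k_kJ_mol_nm2`, `sample_nm` (as produced by [gen_umbrella_samples()]),
#'   or a list of `list(center, force_constant, samples)`.
#' @param bins Number of histogram bins over the sampled range (default 200);
#'   bin edges are half-open `[lo, hi)`.
#' @param temperature Temperature in K (default 310.15).
#' @param tolerance Convergence threshold on the window constants, kJ/mol.
#' @param max_iter Maximum self-consistency iterations.
#' @param anchor `"min"` or `"plateau"` anchoring convention.
#' @param plateau_fraction Trailing fraction used by the plateau anchor.
#' @param n_boot Bayesian-bootstrap replicates for per-bin errors (0 = none).
#' @param seed Seed for the bootstrap.
#' @return Object of class `pmf_fit` with `$profile` (tibble `xi_nm`,
#'   `free_energy_kJ_mol`, `error_kJ_mol`, `n_samples`), window constants
#'   `$f_windows`, convergence diagnostics, and (when bootstrapped) replicate
#'   well depths in `$boot_depths`.
#' @export
wham <- function(windows, bins = 200, temperature = 310.15, tolerance = 1e-6,
                 max_iter = 1e5, anchor = c("min", "plateau"),
                 plateau_fraction = 0.1, n_boot = 0, seed = NULL) {
  anchor <- match.arg(anchor)
  check_number(temperature, "temperature", lower = 0, strict_lower = TRUE)
  windows <- as_windows(windows)
  kT <- KB_KJ_MOL_K * temperature

  all_x <- unlist(lapply(windows, `[[`, "samples"))
  lo <- min(all_x); hi <- max(all_x)
  edges <- seq(lo, hi, length.out = bins + 1)
  edges[bins + 1] <- edges[bins + 1] + 1e-9   # half-open [lo, hi): top edge open
  mids <- (edges[-1] + edges[-(bins + 1)]) / 2

  h <- t(vapply(windows, function(w) {
    as.numeric(table(cut(w$samples, edges, right = FALSE,
                         labels = seq_len(bins))) [as.character(seq_len(bins))])
  }, numeric(bins)))
  h[is.na(h)] <- 0

  # pairwise overlap check between neighbouring windows
  centers <- vapply(windows, `[[`, numeric(1), "center")
  ord <- order(centers)
  for (i in seq_len(length(ord) - 1)) {
    a <- h[ord[i], ] > 0; b <- h[ord[i + 1], ] > 0
    if (!any(a & b)) {
      rlang::abort(sprintf(
        "umbrella windows at %.3f and %.3f nm share no occupied histogram bin (coverage gap)",
        centers[ord[i]], centers[ord[i + 1]]),
        class = "junctionmech_coverage_error")
    }
  }

  cb <- t(vapply(windows, function(w) {
    bias_potential(w$force_constant, w$center, mids)
  }, numeric(bins)))

  sol <- wham_iterate(h, cb, kT, tolerance, max_iter)
  if (!sol$converged) {
    rlang::warn(sprintf("WHAM did not converge within %d iterations", max_iter))
  }
  fe_raw <- ifelse(sol$p > 0, -kT * log(sol$p), NA_real_)
  anchor_profile <- function(fe) {
    ref <- if (anchor == "min") {
      min(fe, na.rm = TRUE)
    } else {
      tail_idx <- seq.int(ceiling(bins * (1 - plateau_fraction)) + 1, bins)
      mean(fe[tail_idx], na.rm = TRUE)
    }
    fe - ref
  }
  fe <- anchor_profile(fe_raw)

  err <- rep(NA_real_, bins)
  boot_depths <- NULL
  if (n_boot > 0) {
    if (n_boot < 50) abort_param("n_boot", "must be >= 50 (or 0 to skip)")
    nw <- nrow(h)
    boot <- with_seed(seed, {
      lapply(seq_len(n_boot), function(r) {
        # flat-Dirichlet weights over whole windows (Bayesian bootstrap)
        g <- stats::rgamma(nw, 1)
        w <- g / sum(g) * nw
        bsol <- wham_iterate(h * w, cb, kT, tolerance, max_iter,
                             f_init = sol$f)
        bfe <- anchor_profile(ifelse(bsol$p > 0, -kT * log(bsol$p), NA_real_))
        list(fe = bfe, converged = bsol$converged)
      })
    })
    n_fail <- sum(!vapply(boot, `[[`, logical(1), "converged"))
    if (n_fail > 0) {
      rlang::warn(sprintf("%d of %d bootstrap replicates did not converge",
                          n_fail, n_boot))
    }
    bmat <- do.call(rbind, lapply(boot, `[[`, "fe"))
    err <- apply(bmat, 2, stats::sd, na.rm = TRUE)
    tail_idx <- seq.int(ceiling(bins * (1 - plateau_fraction)) + 1, bins)
    boot_depths <- apply(bmat, 1, function(z) {
      min(z, na.rm = TRUE) - mean(z[tail_idx], na.rm = TRUE)
    })
  }

  structure(list(
    profile = tibble::tibble(xi_nm = mids, free_energy_kJ_mol = fe,
                             error_kJ_mol = err, n_samples = colSums(h)),
    f_windows = sol$f, converged = sol$converged, iterations = sol$iterations,
    temperature = temperature, anchor = anchor,
    plateau_fraction = plateau_fraction, n_windows = length(windows),
    n_boot = n_boot, boot_depths = boot_depths,
    histogram = h, bias = cb, edges = edges
  ), class = "pmf_fit")
}

#' @export
print.pmf_fit <- function(x, ...) {
  cat(sprintf("WHAM profile: %d windows, %d bins, T = %.2f K, %sconverged in %d iterations\n",
              x$n_windows, nrow(x$profile), x$temperature,
              if (x$converged) "" else "NOT ", x$iterations))
  invisible(x)
}

#' Bayesian-bootstrap errors for a WHAM profile
#'
#' Convenience wrapper re-running [wham()] with `n_boot` flat-Dirichlet
#' window-weight replicates and returning the per-bin standard deviation.
#'
#' @inheritParams wham
#' @param n_boot Number of replicates (>= 50).
#' @return Tibble `xi_nm`, `error_kJ_mol`; replicate well depths in attribute
#'   `boot_depths`.
#' @export
bootstrap_error <- function(windows, bins = 200, temperature = 310.15,
                            n_boot = 200, seed = NULL, ...) {
  fit <- wham(windows, bins = bins, temperature = temperature,
              n_boot = n_boot, seed = seed, ...)
  out <- fit$profile[c("xi_nm", "error_kJ_mol")]
  attr(out, "boot_depths") <- fit$boot_depths
  out
}

#' Binding energy from a free-energy profile
#'
#' Well depth of the potential of mean force: free energy at the global
#' minimum minus the mean free energy over the trailing `plateau_fraction` of
#' the grid (the unbound plateau). Negative values favour the bound state.
#'
#' @param fit A `pmf_fit` from [wham()], or a profile tibble with columns
#'   `xi_nm`, `free_energy_kJ_mol` (and optionally `error_kJ_mol`).
#' @param plateau_fraction Trailing fraction of the grid treated as unbound.
#' @return One-row tibble: `delta_g_kJ_mol`, `error_kJ_mol` (bootstrap sd of
#'   the depth when replicate depths are available, else propagated from the
#'   per-bin errors), `error_min_bin_kJ_mol` (bootstrap sd at the minimum
#'   bin), `xi_min_nm`, `edge_minimum` flag.
#' @export
binding_energy <- function(fit, plateau_fraction = 0.1) {
  prof <- if (inherits(fit, "pmf_fit")) fit$profile else tibble::as_tibble(fit)
  fe <- prof$free_energy_kJ_mol
  xi <- prof$xi_nm
  ok <- is.finite(fe)
  if (!any(ok)) rlang::abort("profile has no finite bins")
  n <- length(fe)
  tail_idx <- seq.int(ceiling(n * (1 - plateau_fraction)) + 1, n)
  imin <- which(fe == min(fe[ok], na.rm = TRUE))[1]
  dg <- fe[imin] - mean(fe[tail_idx], na.rm = TRUE)
  edge <- imin <= 1 || imin >= n
  if (edge) {
    rlang::warn("profile minimum sits at the grid edge; binding energy unreliable")
  }
  err <- NA_real_
  err_min <- NA_real_
  if ("error_kJ_mol" %in% names(prof) && any(is.finite(prof$error_kJ_mol))) {
    err_min <- prof$error_kJ_mol[imin]
    err <- sqrt(err_min^2 +
                  mean(prof$error_kJ_mol[tail_idx], na.rm = TRUE)^2 /
                    sum(is.finite(prof$error_kJ_mol[tail_idx])))
  }
  if (inherits(fit, "pmf_fit") && !is.null(fit$boot_depths)) {
    err <- stats::sd(fit$boot_depths)
  }
  tibble::tibble(delta_g_kJ_mol = dg, error_kJ_mol = err,
                 error_min_bin_kJ_mol = err_min,
                 xi_min_nm = xi[imin], edge_minimum = edge)
}
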
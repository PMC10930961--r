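# Seeded synthetic-data generators. Every generator is a pure function of
# (truth, seed): the caller's RNG state is never touched and identical
# arguments reproduce identical output.

#' Ground truth for a synthetic force-indentation curve
#'
#' @param youngs_modulus True Young's modulus in kPa (> 0).
#' @param poisson_ratio Poisson's ratio in `[0, 1)`.
#' @param tip_half_angle Conical tip half-angle in degrees (0, 90).
#' @param contact_offset Indentation at which tip-sample contact begins, nm.
#' @param noise_sd Noise amplitude: nN for `noise_mode = "additive"`,
#'   relative fraction for `"multiplicative"`.
#' @param noise_mode `"additive"` or `"multiplicative"`.
#' @param n_points Number of samples (>= 10).
#' @param max_indentation Final indentation of the ramp, nm.
#' @param seed Integer seed.
#' @return List of class `force_curve_truth`.
#' @export
force_curve_truth <- function(youngs_modulus, poisson_ratio = 0.5,
                              tip_half_angle = 18, contact_offset = 0,
                              noise_sd = 0, noise_mode = c("additive", "multiplicative"),
                              n_points = 200, max_indentation = 1000,
                              seed = 1) {
  check_number(youngs_modulus, "youngs_modulus", lower = 0, strict_lower = TRUE)
  check_number(poisson_ratio, "poisson_ratio", lower = 0, upper = 1,
               strict_upper = TRUE)
  check_number(tip_half_angle, "tip_half_angle", lower = 0, upper = 90,
               strict_lower = TRUE, strict_upper = TRUE)
  check_number(contact_offset, "contact_offset", lower = 0)
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(n_points, "n_points", lower = 10)
  check_number(max_indentation, "max_indentation", lower = 0, strict_lower = TRUE)
  if (contact_offset >= max_indentation) {
    abort_param("contact_offset", "must be smaller than max_indentation")
  }
  structure(list(youngs_modulus = youngs_modulus, poisson_ratio = poisson_ratio,
                 tip_half_angle = tip_half_angle, contact_offset = contact_offset,
                 noise_sd = noise_sd, noise_mode = match.arg(noise_mode),
                 n_points = as.integer(n_points),
                 max_indentation = max_indentation, seed = seed),
            class = "force_curve_truth")
}

#' Generate a synthetic force-indentation curve
#'
#' Forward model of a conical-tip indentation: zero force up to the contact
#' offset, then the Sneddon closed form evaluated at the depth past contact,
#' plus seeded noise.
#'
#' @param truth A [force_curve_truth()].
#' @return Tibble `indentation_nm`, `force_nN` with the truth attached as
#'   attribute `truth`.
#' @export
gen_force_curve <- function(truth) {
  stopifnot(inherits(truth, "force_curve_truth"))
  delta <- seq(0, truth$max_indentation, length.out = truth$n_points)
  depth <- pmax(delta - truth$contact_offset, 0)
  f <- sneddon_force(truth$youngs_modulus, depth, truth$poisson_ratio,
                     truth$tip_half_angle)
  if (truth$noise_sd > 0) {
    f <- with_seed(truth$seed, {
      eps <- stats::rnorm(length(f))
      if (truth$noise_mode == "additive") f + truth$noise_sd * eps
      else f * (1 + truth$noise_sd * eps)
    })
  }
  out <- tibble::tibble(indentation_nm = delta, force_nN = f)
  attr(out, "truth") <- truth
  out
}

#' Ground truth for a synthetic FRET tension-sensor image set
#'
#' Per-segment pixel model (counts above background on junction pixels):
#' donor channel = donor expression scaled by (1 - transfer fraction); FRET
#' channel = sensitized emission (transfer fraction x donor expression, unit
#' detector gain) + donor bleed-through + acceptor bleed-through; acceptor
#' channel = acceptor expression.
#'
#' @param transfer_fraction True FRET transfer fraction(s) in `[0, 1]`, one
#'   per junction segment (recycled).
#' @param donor_expression,acceptor_expression Expression level(s) in counts.
#' @param sbt_donor,sbt_acceptor True bleed-through fractions in `[0, 1)`.
#' @param background Uniform background level in counts.
#' @param noise_model `"none"`, `"gaussian"` or `"poisson"`.
#' @param noise_sd Gaussian noise sd in counts (gaussian model only).
#' @param seed Integer seed.
#' @return List of class `fret_truth`.
#' @export
fret_truth <- function(transfer_fraction, donor_expression = 1000,
                       acceptor_expression = 800, sbt_donor = 0,
                       sbt_acceptor = 0, background = 100,
                       noise_model = c("none", "gaussian", "poisson"),
                       noise_sd = 10, seed = 1) {
  if (any(transfer_fraction < 0 | transfer_fraction > 1)) {
    abort_param("transfer_fraction", "must lie in [0, 1]")
  }
  check_number(sbt_donor, "sbt_donor", lower = 0, upper = 1, strict_upper = TRUE)
  check_number(sbt_acceptor, "sbt_acceptor", lower = 0, upper = 1,
               strict_upper = TRUE)
  check_number(background, "background", lower = 0)
  structure(list(transfer_fraction = transfer_fraction,
                 donor_expression = donor_expression,
                 acceptor_expression = acceptor_expression,
                 sbt_donor = sbt_donor, sbt_acceptor = sbt_acceptor,
                 background = background, noise_model = match.arg(noise_model),
                 noise_sd = noise_sd, seed = seed),
            class = "fret_truth")
}

#' Junction-segment layout for synthetic images
#'
#' Places `n_segments` horizontal junction bands in an image, or accepts an
#' explicit segment table (`r0, c0, r1, c1, width` in pixels).
#'
#' @param n_segments Number of junctional segments.
#' @param nrow,ncol Image dimensions in pixels.
#' @param band_width Band thickness in pixels.
#' @param segments Optional explicit segment tibble overriding the layout.
#' @return List of class `junction_layout`.
#' @export
junction_layout <- function(n_segments = 2, nrow = 96, ncol = 96,
                            band_width = 5, segments = NULL) {
  if (is.null(segments)) {
    rows <- round(seq(0.2, 0.8, length.out = n_segments) * nrow)
    segments <- tibble::tibble(r0 = rows, c0 = 8, r1 = rows, c1 = ncol - 8,
                               width = band_width)
  }
  half <- segments$width / 2
  if (any(segments$r0 - half < 1 | segments$r1 + half > nrow |
            segments$c0 < 1 | segments$c1 > ncol |
            pmin(segments$r0, segments$r1) - half < 1 |
            pmax(segments$r0, segments$r1) + half > nrow)) {
    rlang::abort("junction segment extends outside the image bounds",
                 class = "junctionmech_geometry_error")
  }
  structure(list(nrow = nrow, ncol = ncol, segments = tibble::as_tibble(segments)),
            class = "junction_layout")
}

segment_label_matrix <- function(layout) {
  lab <- matrix(0L, layout$nrow, layout$ncol)
  rr <- row(lab); cc <- col(lab)
  segs <- layout$segments
  for (i in seq_len(nrow(segs))) {
    s <- segs[i, ]
    # distance from each pixel centre to the segment (capsule rasterisation)
    vx <- s$r1 - s$r0; vy <- s$c1 - s$c0
    len2 <- vx^2 + vy^2
    t <- if (len2 > 0) pmin(pmax(((rr - s$r0) * vx + (cc - s$c0) * vy) / len2, 0), 1) else 0
    d2 <- (rr - (s$r0 + t * vx))^2 + (cc - (s$c0 + t * vy))^2
    lab[d2 <= (s$width / 2)^2] <- i
  }
  lab
}

#' Generate a synthetic three-channel FRET image set
#'
#' @param truth A [fret_truth()].
#' @param layout A [junction_layout()].
#' @return List with `images` ([fret_imageset()]), `rois` (segment label
#'   matrix), and `truth`. Donor-only / acceptor-only control sets are
#'   produced by zeroing the other fluorophore's expression in the truth.
#' @export
gen_fret_imageset <- function(truth, layout = junction_layout()) {
  stopifnot(inherits(truth, "fret_truth"), inherits(layout, "junction_layout"))
  lab <- segment_label_matrix(layout)
  nseg <- nrow(layout$segments)
  ef <- rep_len(truth$transfer_fraction, nseg)
  dexp <- rep_len(truth$donor_expression, nseg)
  aexp <- rep_len(truth$acceptor_expression, nseg)

  base <- function() matrix(truth$background, layout$nrow, layout$ncol)
  donor <- base(); acceptor <- base(); fret <- base()
  for (i in seq_len(nseg)) {
    px <- lab == i
    dsig <- dexp[i] * (1 - ef[i])
    asig <- aexp[i]
    sens <- ef[i] * dexp[i]
    donor[px] <- donor[px] + dsig
    acceptor[px] <- acceptor[px] + asig
    fret[px] <- fret[px] + sens + truth$sbt_donor * dsig + truth$sbt_acceptor * asig
  }
  if (truth$noise_model != "none") {
    noised <- with_seed(truth$seed, {
      lapply(list(donor, acceptor, fret), function(m) {
        if (truth$noise_model == "poisson") {
          matrix(stats::rpois(length(m), pmax(m, 0)), nrow(m), ncol(m))
        } else {
          m + matrix(stats::rnorm(length(m), sd = truth$noise_sd), nrow(m), ncol(m))
        }
      })
    })
    donor <- pmax(noised[[1]], 0); acceptor <- pmax(noised[[2]], 0)
    fret <- pmax(noised[[3]], 0)
  }
  list(images = fret_imageset(donor, acceptor, fret), rois = lab, truth = truth)
}

#' Tabulated 1-D potential of mean force specification
#'
#' A free-energy profile given as a table of (xi, energy) pairs, interpolated
#' with a natural cubic spline inside its domain.
#'
#' @param xi Reaction-coordinate grid in nm (strictly increasing).
#' @param energy Free energy at `xi` in kJ/mol (finite).
#' @param temperature Temperature in K.
#' @return List of class `pmf_spec` with `fun(xi)`, `domain`, `table`,
#'   `temperature`.
#' @export
pmf_spec <- function(xi, energy, temperature = 310.15) {
  check_number(temperature, "temperature", lower = 0, strict_lower = TRUE)
  if (length(xi) != length(energy) || length(xi) < 2 || is.unsorted(xi, strictly = TRUE)) {
    abort_param("xi", "must be strictly increasing and match energy in length")
  }
  if (any(!is.finite(energy))) abort_param("energy", "must be finite on the domain")
  structure(list(fun = stats::splinefun(xi, energy, method = "natural"),
                 domain = range(xi),
                 table = tibble::tibble(xi_nm = xi, energy_kJ_mol = energy),
                 temperature = temperature),
            class = "pmf_spec")
}

#' Reference toy free-energy landscapes
#'
#' `pmf_flat()`: zero everywhere. `pmf_double_well()`: symmetric quartic
#' double well, minima at `center +/- half_separation` and a barrier of
#' `barrier` kJ/mol between them. `pmf_binding_well()`: a single Gaussian
#' binding well of given depth and width decaying to a flat unbound plateau —
#' the desk-scale stand-in for a peptide-unbinding profile (defaults: depth
#' 59.4 kJ/mol at 0.9 nm).
#'
#' @param domain Reaction-coordinate domain in nm.
#' @param n Tabulation points.
#' @param temperature Temperature in K.
#' @param barrier Double-well barrier height, kJ/mol.
#' @param center Double-well midpoint / well position, nm.
#' @param half_separation Half-distance between the two minima, nm.
#' @param depth Binding-well depth in kJ/mol (positive number).
#' @param xi_min Binding-well position, nm.
#' @param width Gaussian width (sd) of the binding well, nm.
#' @return A [pmf_spec()].
#' @export
pmf_flat <- function(domain = c(0.5, 1.5), n = 201, temperature = 310.15) {
  xi <- seq(domain[1], domain[2], length.out = n)
  pmf_spec(xi, rep(0, n), temperature)
}

#' @rdname pmf_flat
#' @param minima Positions of the two wells, nm.
#' @export
pmf_double_well <- function(depth = 10, minima = c(0.7, 1.3), width = 0.12,
                            domain = c(0.5, 1.5), n = 401,
                            temperature = 310.15) {
  xi <- seq(domain[1], domain[2], length.out = n)
  u <- -depth * (exp(-(xi - minima[1])^2 / (2 * width^2)) +
                   exp(-(xi - minima[2])^2 / (2 * width^2)))
  pmf_spec(xi, u, temperature)
}

#' @rdname pmf_flat
#' @export
pmf_binding_well <- function(depth = 59.4, xi_min = 0.9, width = 0.28,
                             domain = c(0.4, 2.0), n = 801,
                             temperature = 310.15) {
  xi <- seq(domain[1], domain[2], length.out = n)
  u <- -depth * exp(-(xi - xi_min)^2 / (2 * width^2))
  pmf_spec(xi, u, temperature)
}

#' Draw umbrella-window samples from a specified PMF
#'
#' For each window centre, samples the biased Boltzmann density
#' \eqn{p(\xi) \propto \exp[-(U(\xi) + k/2 (\xi - c)^2)/k_B T]} with a
#' Metropolis chain: Gaussian proposals of sd
#' \eqn{2.4\sqrt{k_B T / k}} (the optimal random-walk scaling, acceptance
#' near 0.4-0.5 under the bias), 1000-step burn-in, 10x thinning; proposals
#' outside the PMF domain are rejected.
#'
#' @param spec A [pmf_spec()].
#' @param centers Window centres in nm (inside the domain).
#' @param force_constant Harmonic force constant, kJ mol^-1 nm^-2.
#' @param n_per_window Retained samples per window.
#' @param seed Integer seed.
#' @param burn_in,thin Chain burn-in steps and thinning stride.
#' @param proposal_scale Proposal sd as a multiple of the bias width
#'   \eqn{\sqrt{k_B T / k}}.
#' @return Long tibble `center_nm`, `k_kJ_mol_nm2`, `sample_nm`; per-window
#'   Metropolis acceptance rates in attribute `acceptance`.
#' @export
gen_umbrella_samples <- function(spec, centers, force_constant = 800,
                                 n_per_window = 1000, seed = 1,
                                 burn_in = 1000, thin = 10,
                                 proposal_scale = 2.4) {
  stopifnot(inherits(spec, "pmf_spec"))
  if (length(centers) == 0) abort_param("centers", "must be non-empty")
  if (any(centers < spec$domain[1] | centers > spec$domain[2])) {
    abort_param("centers", "must lie within the PMF domain")
  }
  check_number(force_constant, "force_constant", lower = 0, strict_lower = TRUE)
  kT <- KB_KJ_MOL_K * spec$temperature
  prop_sd <- proposal_scale * sqrt(kT / force_constant)
  lo <- spec$domain[1]; hi <- spec$domain[2]
  ufun <- spec$fun

  res <- with_seed(seed, {
    lapply(centers, function(cen) {
      logp <- function(x) -(ufun(x) + force_constant / 2 * (x - cen)^2) / kT
      n_steps <- burn_in + n_per_window * thin
      eps <- stats::rnorm(n_steps, sd = prop_sd)
      lu <- log(stats::runif(n_steps))
      x <- cen
      lp <- logp(x)
      acc <- 0L
      keep <- numeric(n_per_window)
      ki <- 0L
      for (s in seq_len(n_steps)) {
        xn <- x + eps[s]
        if (xn >= lo && xn <= hi) {
          lpn <- logp(xn)
          if (lu[s] < lpn - lp) {
            x <- xn; lp <- lpn; acc <- acc + 1L
          }
        }
        if (s > burn_in && (s - burn_in) %% thin == 0) {
          ki <- ki + 1L
          keep[ki] <- x
        }
      }
      list(samples = keep, acceptance = acc / n_steps)
    })
  })
  out <- purrr::map2(res, centers, function(r, cen) {
    tibble::tibble(center_nm = cen, k_kJ_mol_nm2 = force_constant,
                   sample_nm = r$samples)
  }) |> dplyr::bind_rows()
  attr(out, "acceptance") <- tibble::tibble(
    center_nm = centers,
    acceptance = vapply(res, `[[`, numeric(1), "acceptance"))
  out
}

#' Inverse-CDF sampler for a biased umbrella density
#'
#' Direct grid-based inverse-transform sampling from the same biased density
#' as [gen_umbrella_samples()]. Serves as an independent sampling route for
#' validating the Metropolis generator.
#'
#' @inheritParams gen_umbrella_samples
#' @param center Single window centre, nm.
#' @param n Number of samples.
#' @param grid_n Grid resolution for the CDF.
#' @return Numeric vector of samples.
#' @export
sample_biased_icdf <- function(spec, center, force_constant = 800, n = 1000,
                               seed = 1, grid_n = 20000) {
  stopifnot(inherits(spec, "pmf_spec"))
  kT <- KB_KJ_MOL_K * spec$temperature
  xg <- seq(spec$domain[1], spec$domain[2], length.out = grid_n)
  le <- -(spec$fun(xg) + force_constant / 2 * (xg - center)^2) / kT
  w <- exp(le - max(le))
  cdf <- cumsum(w) / sum(w)
  with_seed(seed, {
    u <- stats::runif(n)
    xg[findInterval(u, cdf) + 1]
  })
}

#' Generate a peptide-in-pocket fixture with a planted contact map
#'
#' Places single-pseudo-atom residues (one atom at each residue's centre of
#' geometry) so that exactly the planted peptide-domain pairs lie within the
#' contact cutoff and every other cross pair is at least `min_separation`
#' apart. Placement is by constraint projection inside connected components
#' of the planted-contact graph, with bounded retries.
#'
#' @param n_pocket_residues Number of domain (pocket) residues.
#' @param n_peptide_residues Number of peptide residues.
#' @param planted_contacts Two-column matrix/data frame of
#'   (peptide index, domain index) pairs; may be empty.
#' @param seed Integer seed.
#' @param cutoff Contact cutoff in Angstrom (planted pairs placed below it).
#' @param min_separation Minimum distance for non-contact cross pairs (> cutoff).
#' @param max_retries Retries before giving up.
#' @return List with `peptide` and `domain` structures (chains A and B;
#'   domain residues numbered from 301) and the planted pairs.
#' @export
gen_peptide_pocket <- function(n_pocket_residues, n_peptide_residues,
                               planted_contacts = NULL, seed = 1,
                               cutoff = 6.5, min_separation = 8,
                               max_retries = 20) {
  check_number(n_pocket_residues, "n_pocket_residues", lower = 1)
  check_number(n_peptide_residues, "n_peptide_residues", lower = 1)
  pc <- if (is.null(planted_contacts) || NROW(planted_contacts) == 0) {
    matrix(integer(0), ncol = 2)
  } else {
    m <- as.matrix(planted_contacts)[, 1:2, drop = FALSE]
    storage.mode(m) <- "integer"
    m
  }
  if (nrow(pc) > 0 &&
      (any(pc[, 1] < 1 | pc[, 1] > n_peptide_residues) ||
         any(pc[, 2] < 1 | pc[, 2] > n_pocket_residues))) {
    abort_param("planted_contacts", "pair references a residue index out of range")
  }

  np <- n_peptide_residues; nd <- n_pocket_residues
  n_tot <- np + nd
  didx <- function(j) np + j      # domain node index
  # connected components of the planted-contact graph
  comp <- seq_len(n_tot)
  if (nrow(pc) > 0) {
    for (r in seq_len(nrow(pc))) {
      a <- pc[r, 1]; b <- didx(pc[r, 2])
      ca <- comp[a]; cb <- comp[b]
      comp[comp == cb] <- ca
    }
  }
  comp <- match(comp, unique(comp))
  planted_key <- if (nrow(pc) > 0) paste(pc[, 1], pc[, 2]) else character(0)
  is_planted <- matrix(FALSE, np, nd)
  if (nrow(pc) > 0) is_planted[pc] <- TRUE

  attempt <- function(try_seed) {
    with_seed(try_seed, {
      pos <- matrix(0, n_tot, 3)
      # lay components out on a coarse grid, 50 A apart
      ncomp <- max(comp)
      g <- ceiling(ncomp^(1 / 3))
      offs <- as.matrix(expand.grid(0:(g - 1), 0:(g - 1), 0:(g - 1)))[seq_len(ncomp), , drop = FALSE] * 50
      for (i in seq_len(n_tot)) {
        pos[i, ] <- offs[comp[i], ] + stats::runif(3, -4, 4)
      }
      # project constraints within components
      for (it in seq_len(3000)) {
        moved <- FALSE
        if (nrow(pc) > 0) {
          for (r in seq_len(nrow(pc))) {
            a <- pc[r, 1]; b <- didx(pc[r, 2])
            d <- sqrt(sum((pos[a, ] - pos[b, ])^2))
            if (d > cutoff - 0.5) {
              target <- cutoff - 1.5
              mid <- (pos[a, ] + pos[b, ]) / 2
              dir <- if (d > 0) (pos[a, ] - pos[b, ]) / d else c(1, 0, 0)
              pos[a, ] <- mid + dir * target / 2
              pos[b, ] <- mid - dir * target / 2
              moved <- TRUE
            }
          }
        }
        for (i in seq_len(np)) {
          for (j in seq_len(nd)) {
            if (is_planted[i, j] || comp[i] != comp[didx(j)]) next
            d <- sqrt(sum((pos[i, ] - pos[didx(j), ])^2))
            if (d < min_separation + 0.5) {
              dir <- if (d > 0) (pos[i, ] - pos[didx(j), ]) / d else stats::rnorm(3)
              push <- (min_separation + 1 - d) / 2
              pos[i, ] <- pos[i, ] + dir * push
              pos[didx(j), ] <- pos[didx(j), ] - dir * push
              moved <- TRUE
            }
          }
        }
        if (!moved) break
      }
      # verify
      ok <- TRUE
      for (i in seq_len(np)) {
        for (j in seq_len(nd)) {
          d <- sqrt(sum((pos[i, ] - pos[didx(j), ])^2))
          if (is_planted[i, j] && d > cutoff) ok <- FALSE
          if (!is_planted[i, j] && d < min_separation) ok <- FALSE
        }
      }
      if (ok) pos else NULL
    })
  }

  pos <- NULL
  for (k in seq_len(max_retries)) {
    pos <- attempt(seed + k - 1)
    if (!is.null(pos)) break
  }
  if (is.null(pos)) {
    rlang::abort("could not realise the planted contact geometry (constraints too dense)",
                 class = "junctionmech_generation_error")
  }
  peptide <- as_structure(tibble::tibble(
    chain = "A", resno = seq_len(np), resid = "ALA", elety = "CA",
    x = pos[seq_len(np), 1], y = pos[seq_len(np), 2], z = pos[seq_len(np), 3]))
  domain <- as_structure(tibble::tibble(
    chain = "B", resno = 300L + seq_len(nd), resid = "GLY", elety = "CA",
    x = pos[didx(seq_len(nd)), 1], y = pos[didx(seq_len(nd)), 2],
    z = pos[didx(seq_len(nd)), 3]))
  list(peptide = peptide, domain = domain, planted = pc)
}
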
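test_that("the harmonic bias evaluates and is symmetric about its centre", {
  expect_equal(bias_potential(800, 1.0, 1.0), 0)
  expect_equal(bias_potential(800, 1.0, 1.05), 1.0)   # 0.5 * 800 * 0.0025
  expect_equal(bias_potential(640, 1.2, 1.2 + 0.07),
               bias_potential(640, 1.2, 1.2 - 0.07))
})

test_that("a flat landscape is recovered as flat", {
  sp <- pmf_flat(c(0.8, 1.2))
  wins <- gen_umbrella_samples(sp, seq(0.85, 1.15, length.out = 5), 800,
                               n_per_window = 5000, seed = 3)
  # coarse bins: a featureless landscape needs no resolution, and ~1500
  # samples per bin keep the per-bin noise well below the flatness bound
  fit <- wham(wins, bins = 15)
  fe <- fit$profile$free_energy_kJ_mol
  expect_true(fit$converged)
  fe <- fe[is.finite(fe)]
  # remove the arbitrary gauge constant, then every bin sits near zero
  expect_lt(max(abs(fe - mean(fe))), 0.2)
})

test_that("a single harmonic window inverts to the analytic biased Gaussian", {
  # harmonic truth centred on the bias centre: biased density is Gaussian with
  # stiffness k_truth + k_bias, and the unbiased profile is the truth itself
  k_truth <- 400
  xi <- seq(0.5, 1.5, length.out = 401)
  sp <- pmf_spec(xi, k_truth / 2 * (xi - 1)^2)
  wins <- gen_umbrella_samples(sp, 1.0, 800, n_per_window = 20000, seed = 5)
  # variance halves relative to bias-only when the two stiffnesses sum
  kT <- 0.0083145 * 310.15
  expect_equal(stats::sd(wins$sample_nm), sqrt(kT / (k_truth + 800)),
               tolerance = 0.03)
  fit <- wham(wins, bins = 40)
  prof <- fit$profile
  sampled <- is.finite(prof$free_energy_kJ_mol) & prof$n_samples > 50
  truth <- k_truth / 2 * (prof$xi_nm - 1)^2
  truth <- truth - min(truth[sampled])
  expect_lt(max(abs(prof$free_energy_kJ_mol[sampled] - truth[sampled])), 0.3)
})

test_that("umbrella sampler statistics match the closed form and icdf oracle", {
  sp <- pmf_flat(c(0.5, 1.5))
  wins <- gen_umbrella_samples(sp, 1.0, 800, n_per_window = 10000, seed = 4)
  kT <- 0.0083145 * 310.15
  expect_equal(mean(wins$sample_nm), 1.0, tolerance = 0.005)
  expect_equal(stats::sd(wins$sample_nm), sqrt(kT / 800), tolerance = 0.02)
  # two-sample KS against independent inverse-CDF sampling, alpha = 0.01
  oracle <- sample_biased_icdf(sp, 1.0, 800, n = 10000, seed = 99)
  p <- suppressWarnings(stats::ks.test(wins$sample_nm, oracle))$p.value
  expect_gt(p, 0.01)
  # determinism
  wins2 <- gen_umbrella_samples(sp, 1.0, 800, n_per_window = 10000, seed = 4)
  expect_identical(wins$sample_nm, wins2$sample_nm)
})

test_that("double-well recovery meets the RMSD bound and matches the reference WHAM", {
  sp <- pmf_double_well()
  centers <- seq(0.5, 1.5, by = 0.05)
  wins <- gen_umbrella_samples(sp, centers, 800, n_per_window = 2000, seed = 11)
  fit <- wham(wins)
  truth <- sp$fun(fit$profile$xi_nm)
  truth <- truth - min(truth)
  d <- fit$profile$free_energy_kJ_mol - truth
  ok <- is.finite(d)
  expect_lt(sqrt(mean(d[ok]^2)), 0.5)   # 2e3 samples; the 5e3 case is in acceptance

  ref <- reference_wham(wins, bins = 200)
  both <- is.finite(fit$profile$free_energy_kJ_mol) & is.finite(ref$fe)
  expect_lt(max(abs(fit$profile$free_energy_kJ_mol[both] - ref$fe[both])), 0.1)

  # binless MBAR-style route agrees too (looser: no shared discretisation)
  mb <- reference_mbar_profile(wins, fit$edges)
  fe_min <- fit$profile$free_energy_kJ_mol -
    min(fit$profile$free_energy_kJ_mol, na.rm = TRUE)
  both2 <- is.finite(fe_min) & is.finite(mb) & fit$profile$n_samples > 20
  expect_lt(max(abs(fe_min[both2] - mb[both2])), 0.3)
})

test_that("WHAM is invariant to window order and to a constant energy shift", {
  sp <- pmf_double_well()
  centers <- seq(0.6, 1.4, by = 0.05)
  wins <- gen_umbrella_samples(sp, centers, 800, n_per_window = 1000, seed = 2)
  fit1 <- wham(wins, bins = 100)
  shuf <- withr::with_seed(1, dplyr::slice_sample(wins, prop = 1))
  fit2 <- wham(shuf, bins = 100)
  expect_equal(fit1$profile$free_energy_kJ_mol, fit2$profile$free_energy_kJ_mol,
               tolerance = 1e-6)
  # shifting the generating PMF by a constant changes nothing after anchoring
  sp_shift <- pmf_spec(sp$table$xi_nm, sp$table$energy_kJ_mol + 123.4)
  wins_s <- gen_umbrella_samples(sp_shift, centers, 800, n_per_window = 1000,
                                 seed = 2)
  fit3 <- wham(wins_s, bins = 100)
  expect_equal(fit1$profile$free_energy_kJ_mol, fit3$profile$free_energy_kJ_mol,
               tolerance = 1e-9)
})

test_that("non-overlapping windows raise a coverage error naming the gap", {
  sp <- pmf_flat(c(0.0, 3.0))
  wins <- gen_umbrella_samples(sp, c(0.5, 2.5), 800, n_per_window = 200,
                               seed = 1)
  expect_error(wham(wins), class = "junctionmech_coverage_error")
})

test_that("Bayesian bootstrap errors are seeded, near zero for ideal data, and shrink with n", {
  sp <- pmf_flat(c(0.8, 1.2))
  centers <- seq(0.85, 1.15, length.out = 5)
  wins <- gen_umbrella_samples(sp, centers, 800, n_per_window = 1000, seed = 6)
  e1 <- bootstrap_error(wins, bins = 50, n_boot = 60, seed = 10)
  e2 <- bootstrap_error(wins, bins = 50, n_boot = 60, seed = 10)
  expect_identical(e1$error_kJ_mol, e2$error_kJ_mol)

  # errors shrink roughly as 1/sqrt(n): 4x samples ~ half the error
  wins4 <- gen_umbrella_samples(sp, centers, 800, n_per_window = 4000, seed = 6)
  m1 <- stats::median(e1$error_kJ_mol, na.rm = TRUE)
  m4 <- stats::median(bootstrap_error(wins4, bins = 50, n_boot = 60,
                                      seed = 10)$error_kJ_mol, na.rm = TRUE)
  expect_lt(abs(m4 / m1 - 0.5), 0.25)
})

test_that("binding energy extraction: fixture well, flat and shifted profiles", {
  xi <- seq(0.4, 2.0, length.out = 200)
  fe <- -59.4 * exp(-(xi - 0.9)^2 / (2 * 0.1^2))
  prof <- tibble::tibble(xi_nm = xi, free_energy_kJ_mol = fe)
  be <- binding_energy(prof)
  expect_equal(be$delta_g_kJ_mol, -59.4, tolerance = 1e-3)
  expect_equal(be$xi_min_nm, 0.9, tolerance = 0.005)

  flat <- tibble::tibble(xi_nm = xi, free_energy_kJ_mol = 0)
  expect_equal(binding_energy(flat)$delta_g_kJ_mol, 0)

  shifted <- dplyr::mutate(prof, free_energy_kJ_mol = free_energy_kJ_mol + 17)
  expect_equal(binding_energy(shifted)$delta_g_kJ_mol, be$delta_g_kJ_mol)

  # minimum at the grid edge is flagged
  ramp <- tibble::tibble(xi_nm = xi, free_energy_kJ_mol = xi)
  expect_warning(binding_energy(ramp), "edge")
})

test_that("window and sample CSV round-trips preserve the data", {
  sp <- pmf_flat(c(0.9, 1.1))
  wins <- gen_umbrella_samples(sp, c(0.95, 1.05), 800, n_per_window = 200,
                               seed = 8)
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_umbrella_windows(wins, tmp)
  back <- read_umbrella_windows(tmp)
  expect_equal(back$sample_nm, wins$sample_nm)
  expect_equal(unique(back$center_nm), c(0.95, 1.05))
})
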
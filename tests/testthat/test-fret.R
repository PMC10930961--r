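test_that("background subtraction is equal across channels with clamping", {
  imgs <- fret_imageset(matrix(250, 8, 8), matrix(250, 8, 8), matrix(250, 8, 8))
  sub <- subtract_background(imgs, "constant", 100)
  expect_true(all(sub$donor == 150) && all(sub$fret == 150))
  expect_warning(subtract_background(imgs, "constant", 300),
                 "clamped")
  big <- suppressWarnings(subtract_background(imgs, "constant", 300))
  expect_true(all(big$acceptor == 0))
  expect_error(subtract_background(imgs, "percentile", 101),
               class = "junctionmech_parameter_error")
})

test_that("percentile background recovers the generator's background level", {
  gs <- gen_fret_imageset(fret_truth(0.3, background = 100, seed = 7))
  sub <- subtract_background(gs$images, "percentile", 5)
  expect_true(all(abs(attr(sub, "background") - 100) < 2))
})

test_that("SBT estimation returns the planted coefficients from controls", {
  exp0 <- make_fret_experiment(sbt_d = 0.3, sbt_a = 0.1, bg = 0)
  sbt <- estimate_sbt(exp0$d_only$images, exp0$d_only$rois,
                      exp0$a_only$images, exp0$a_only$rois)
  expect_lt(abs(sbt$sbt_donor - 0.3), 1e-9)
  expect_lt(abs(sbt$sbt_acceptor - 0.1), 1e-9)

  # zero bleed-through stays zero
  z <- make_fret_experiment(sbt_d = 0.2, sbt_a = 0, bg = 0)
  sbt0 <- estimate_sbt(z$d_only$images, z$d_only$rois,
                       z$a_only$images, z$a_only$rois)
  expect_equal(sbt0$sbt_acceptor, 0)

  # Poisson-noise controls with several ROIs land within 5%
  layout <- junction_layout(n_segments = 5, nrow = 128)
  dn <- gen_fret_imageset(fret_truth(0, acceptor_expression = 0,
                                     sbt_donor = 0.3, background = 0,
                                     noise_model = "poisson", seed = 3), layout)
  an <- gen_fret_imageset(fret_truth(0, donor_expression = 0,
                                     sbt_acceptor = 0.1, background = 0,
                                     noise_model = "poisson", seed = 4), layout)
  sbtn <- estimate_sbt(dn$images, dn$rois, an$images, an$rois)
  expect_lt(abs(sbtn$sbt_donor - 0.3) / 0.3, 0.05)
  expect_lt(abs(sbtn$sbt_acceptor - 0.1) / 0.1, 0.05)
})

test_that("corrected FRET and FRET index reproduce hand arithmetic", {
  # means: I_FRET = 100, I_donor = 200, I_acceptor = 150; SBT = (0.3, 0.1)
  imgs <- fret_imageset(matrix(200, 4, 4), matrix(150, 4, 4), matrix(100, 4, 4))
  roi <- matrix(TRUE, 4, 4)
  sbt <- list(sbt_donor = 0.3, sbt_acceptor = 0.1)
  cf <- corrected_fret(imgs, sbt, roi)
  expect_equal(cf, 100 - 60 - 15)
  expect_equal(fret_index(cf, imgs, roi), 25 / 150)
  expect_equal(fret_index(0, imgs, roi), 0)
  # no bleed-through: cFRET is the raw FRET mean
  expect_equal(corrected_fret(imgs, list(sbt_donor = 0, sbt_acceptor = 0), roi),
               100)
  empty <- matrix(FALSE, 4, 4)
  expect_error(corrected_fret(imgs, sbt, empty),
               class = "junctionmech_degenerate_roi_error")
})

test_that("a donor-only control corrected with its own SBTs gives cFRET ~ 0", {
  exp0 <- make_fret_experiment(sbt_d = 0.25, sbt_a = 0.15, bg = 0)
  sbt <- estimate_sbt(exp0$d_only$images, exp0$d_only$rois,
                      exp0$a_only$images, exp0$a_only$rois)
  roi <- exp0$d_only$rois == 1
  expect_lt(abs(corrected_fret(exp0$d_only$images, sbt, roi)), 1e-9)
})

test_that("full pipeline matches the closed-form pixel model, noise-free", {
  transfer <- c(0.15, 0.3, 0.45)
  dexp <- 1000; aexp <- 800
  exp0 <- make_fret_experiment(transfer = transfer, sbt_d = 0.3, sbt_a = 0.1,
                               bg = 100)
  res <- suppressWarnings(quantify_junctions(
    list(sensor = list(images = exp0$sensor$images, rois = exp0$sensor$rois)),
    donor_only = list(images = exp0$d_only$images, rois = exp0$d_only$rois),
    acceptor_only = list(images = exp0$a_only$images, rois = exp0$a_only$rois),
    background = exp0$bg))
  # pixel model: index = E * donor_expression / acceptor_expression
  expect_equal(res$fret_index, transfer * dexp / aexp, tolerance = 1e-6)
  expect_false(any(res$flagged))
  sbt <- attr(res, "sbt")
  expect_equal(sbt$sbt_donor, 0.3, tolerance = 1e-9)

  # a no-tension control (zero transfer) indexes to ~0 through the pipeline
  null_set <- gen_fret_imageset(fret_truth(0, sbt_donor = 0.3,
                                           sbt_acceptor = 0.1,
                                           background = 100))
  res0 <- suppressWarnings(quantify_junctions(
    list(null = list(images = null_set$images, rois = null_set$rois)),
    donor_only = list(images = exp0$d_only$images, rois = exp0$d_only$rois),
    acceptor_only = list(images = exp0$a_only$images, rois = exp0$a_only$rois),
    background = 100))
  expect_lt(max(abs(res0$fret_index)), 1e-9)
})

test_that("FRET index is invariant under global intensity rescaling", {
  exp0 <- make_fret_experiment(transfer = c(0.2, 0.4), bg = 0)
  run <- function(scale) {
    sc <- function(set) list(
      images = fret_imageset(set$images$donor * scale,
                             set$images$acceptor * scale,
                             set$images$fret * scale),
      rois = set$rois)
    suppressWarnings(quantify_junctions(
      list(g = sc(exp0$sensor)), donor_only = sc(exp0$d_only),
      acceptor_only = sc(exp0$a_only), background = 0))$fret_index
  }
  expect_equal(run(1), run(3.7), tolerance = 1e-12)
})

test_that("FRET index increases strictly with the true transfer fraction", {
  idx <- suppressWarnings(purrr::map(1:20, function(s) {
    exp0 <- make_fret_experiment(transfer = c(0.2, 0.4), bg = 100,
                                 noise = "poisson", seed = s)
    quantify_junctions(
      list(g = list(images = exp0$sensor$images, rois = exp0$sensor$rois)),
      donor_only = list(images = exp0$d_only$images, rois = exp0$d_only$rois),
      acceptor_only = list(images = exp0$a_only$images, rois = exp0$a_only$rois),
      background = exp0$bg)$fret_index
  }))
  expect_true(all(vapply(idx, function(v) v[2] > v[1], logical(1))))
})

test_that("linescan peaks at the junction midline and handles flat images", {
  img <- matrix(10, 41, 41)
  for (r in 1:41) img[r, ] <- img[r, ] + 100 * exp(-(r - 21)^2 / 8)
  prof <- linescan(img, c(3, 21), c(39, 21))
  expect_lt(abs(prof$distance_um[which.max(prof$intensity)]), 1.01)

  flat <- linescan(matrix(5, 20, 20), c(2, 10), c(18, 10))
  expect_true(all(flat$intensity == 5))

  # width = 1 equals direct nearest-pixel sampling along the line
  set.seed(1)
  rnd <- matrix(stats::runif(400), 20, 20)
  p0 <- c(4, 3); p1 <- c(16, 17)
  prof1 <- linescan(rnd, p0, p1, width = 1)
  v <- p1 - p0; len <- sqrt(sum(v^2)); u <- v / len
  oracle <- vapply(seq(0, len, by = 1), function(t) {
    p <- round(p0 + t * u); rnd[p[1], p[2]]
  }, numeric(1))
  expect_equal(prof1$intensity, oracle)

  expect_error(linescan(rnd, c(0, 5), c(10, 5)),
               class = "junctionmech_geometry_error")
})

test_that("polygon ROIs rasterise with even-odd fill at pixel centres", {
  # 0-based square covering centres (2..5) x (3..6)
  sq <- rbind(c(1.5, 2.5), c(1.5, 6.5), c(5.5, 6.5), c(5.5, 2.5))
  m <- polygon_mask(sq, c(10, 10))
  expect_equal(sum(m), 16)
  expect_true(m[3, 4])   # 0-based (2, 3)
  expect_false(m[1, 1])
})
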
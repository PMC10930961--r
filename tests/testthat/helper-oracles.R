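# Independent oracle implementations used only by the tests. These are kept
# deliberately naive (plain loops, textbook formulas) and separate from the
# package's code paths.

kb_kj <- 0.0083145

# Reference WHAM: direct probability-space fixed-point iteration, looped.
reference_wham <- function(windows, bins = 200, temperature = 310.15,
                           tol = 1e-10, max_iter = 2e5) {
  centers <- unique(windows$center_nm)
  ks <- vapply(centers, function(cn) {
    windows$k_kJ_mol_nm2[windows$center_nm == cn][1]
  }, numeric(1))
  samp <- lapply(centers, function(cn) windows$sample_nm[windows$center_nm == cn])
  kT <- kb_kj * temperature
  lo <- min(windows$sample_nm); hi <- max(windows$sample_nm)
  edges <- seq(lo, hi, length.out = bins + 1)
  edges[bins + 1] <- edges[bins + 1] + 1e-9
  mids <- (edges[-1] + edges[-(bins + 1)]) / 2
  nwin <- length(centers)
  h <- matrix(0, nwin, bins)
  for (i in seq_len(nwin)) {
    idx <- findInterval(samp[[i]], edges, rightmost.closed = FALSE)
    for (b in idx[idx >= 1 & idx <= bins]) h[i, b] <- h[i, b] + 1
  }
  ni <- rowSums(h)
  cb <- matrix(0, nwin, bins)
  for (i in seq_len(nwin)) cb[i, ] <- ks[i] / 2 * (mids - centers[i])^2
  fi <- rep(0, nwin)
  for (it in seq_len(max_iter)) {
    p <- numeric(bins)
    for (b in seq_len(bins)) {
      den <- 0
      for (i in seq_len(nwin)) den <- den + ni[i] * exp((fi[i] - cb[i, b]) / kT)
      p[b] <- if (den > 0) sum(h[, b]) / den else 0
    }
    fnew <- numeric(nwin)
    for (i in seq_len(nwin)) {
      z <- sum(p * exp(-cb[i, ] / kT))
      fnew[i] <- -kT * log(z)
    }
    fnew <- fnew - fnew[1]
    if (max(abs(fnew - fi)) < tol) { fi <- fnew; break }
    fi <- fnew
  }
  p <- numeric(bins)
  for (b in seq_len(bins)) {
    den <- sum(ni * exp((fi - cb[, b]) / kT))
    p[b] <- if (den > 0) sum(h[, b]) / den else 0
  }
  fe <- ifelse(p > 0, -kb_kj * temperature * log(p), NA_real_)
  list(xi = mids, fe = fe - min(fe, na.rm = TRUE), f = fi)
}

# Binless MBAR-style estimator (self-consistent on per-sample biases), a
# mathematically different route from histogram WHAM.
reference_mbar_profile <- function(windows, edges, temperature = 310.15,
                                   tol = 1e-8, max_iter = 5000) {
  centers <- unique(windows$center_nm)
  kT <- kb_kj * temperature
  ks <- vapply(centers, function(cn) {
    windows$k_kJ_mol_nm2[windows$center_nm == cn][1]
  }, numeric(1))
  x <- windows$sample_nm
  nwin <- length(centers)
  ni <- vapply(centers, function(cn) sum(windows$center_nm == cn), numeric(1))
  # bias of window i at every sample
  cmat <- vapply(seq_len(nwin), function(i) ks[i] / 2 * (x - centers[i])^2,
                 numeric(length(x)))
  f <- rep(0, nwin)
  for (it in seq_len(max_iter)) {
    den <- rowSums(sweep(exp(-cmat / kT), 2, ni * exp(f / kT), "*"))
    fnew <- -kT * log(colSums(exp(-cmat / kT) / den))
    fnew <- fnew - fnew[1]
    if (max(abs(fnew - f)) < tol) { f <- fnew; break }
    f <- fnew
  }
  den <- rowSums(sweep(exp(-cmat / kT), 2, ni * exp(f / kT), "*"))
  w <- 1 / den
  b <- cut(x, edges, right = FALSE, labels = FALSE)
  fe <- vapply(seq_len(length(edges) - 1), function(bb) {
    s <- sum(w[which(b == bb)])
    if (s > 0) -kT * log(s) else NA_real_
  }, numeric(1))
  fe - min(fe, na.rm = TRUE)
}

# Brute-force all-pairs residue contact search.
brute_force_contacts <- function(peptide, domain, cutoff = 6.5) {
  pc <- residue_cog(peptide)
  dc <- residue_cog(domain)
  pairs <- list()
  for (i in seq_len(nrow(pc))) {
    for (j in seq_len(nrow(dc))) {
      d <- sqrt((pc$x[i] - dc$x[j])^2 + (pc$y[i] - dc$y[j])^2 +
                  (pc$z[i] - dc$z[j])^2)
      if (d <= cutoff) pairs[[length(pairs) + 1]] <- c(i, j)
    }
  }
  if (length(pairs) == 0) matrix(integer(0), ncol = 2)
  else do.call(rbind, pairs)
}

# Random single-atom-per-residue structure for contact fixtures.
random_structure <- function(n, chain = "A", box = 40, seed = NULL) {
  gen <- function() {
    as_structure(tibble::tibble(
      chain = chain, resno = seq_len(n), resid = "ALA", elety = "CA",
      x = stats::runif(n, 0, box), y = stats::runif(n, 0, box),
      z = stats::runif(n, 0, box)))
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

# Standard synthetic FRET experiment used in several tests.
make_fret_experiment <- function(transfer = c(0.2, 0.4), sbt_d = 0.3,
                                 sbt_a = 0.1, bg = 100, noise = "none",
                                 seed = 1) {
  layout <- junction_layout(n_segments = length(transfer))
  sensor <- gen_fret_imageset(
    fret_truth(transfer, sbt_donor = sbt_d, sbt_acceptor = sbt_a,
               background = bg, noise_model = noise, seed = seed), layout)
  d_only <- gen_fret_imageset(
    fret_truth(0, acceptor_expression = 0, sbt_donor = sbt_d,
               sbt_acceptor = sbt_a, background = bg, noise_model = noise,
               seed = seed + 1), layout)
  a_only <- gen_fret_imageset(
    fret_truth(0, donor_expression = 0, sbt_donor = sbt_d,
               sbt_acceptor = sbt_a, background = bg, noise_model = noise,
               seed = seed + 2), layout)
  list(sensor = sensor, d_only = d_only, a_only = a_only, bg = bg)
}
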
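# junctionmech

Quantitative methods for junctional mechanobiology in epithelial
monolayers. The package implements, as tidyverse-style R pipelines, the
measurements used to characterise how tight-junction scaffold proteins
(ZO-1/ZO-2, JAM-A) set mechanical tension at cell–cell junctions:

- **AFM nanoindentation** — baseline correction, contact-point detection and
  least-squares fitting of the Sneddon conical-indenter model
  *F* = (2/π)·*E*/(1−ν²)·tan α·δ², with the conventional *R*² ≥ 0.98
  quality filter, yielding per-curve Young's moduli in kPa.
- **FRET tension sensors** — three-channel (donor/acceptor/FRET) image
  quantification with spectral bleed-through correction,
  cFRET = *I*₍FRET₎ − SBT₍d₎·*I*₍donor₎ − SBT₍a₎·*I*₍acceptor₎ and
  FRET index = cFRET/*I*₍acceptor₎, plus junction linescan profiles.
- **Residue contact analysis** — centre-of-geometry contact maps at a 6.5 Å
  cutoff for a peptide docked in a PDZ-domain pocket (C-1…C-n labelling
  from the C terminus), parch-scale hydropathy classification (< 1 =
  hydrophobic) and a water-coordination counter (0.315 nm cutoff).
- **Umbrella sampling / WHAM** — a 1-D weighted-histogram free-energy
  estimator with Bayesian-bootstrap errors and binding-energy (well-depth)
  extraction, exercised on seeded toy landscapes.
- **Morphometry & statistics** — cell area and moment-ellipse aspect ratio,
  monolayer hole counting, Kruskal–Wallis + Dunn's comparisons,
  exact-enumeration Mann–Whitney, two-way ANOVA with Fisher's LSD.

Every input class has a synthetic generator with known ground truth
(`gen_force_curve()`, `gen_fret_imageset()`, `gen_umbrella_samples()`,
`gen_peptide_pocket()`), so each pipeline is testable end to end. Fitted
objects have `tidy()`/`glance()` methods and `autoplot()` figures.

## Worked example

Fit one synthetic force curve (true modulus 12 kPa, 2% multiplicative
noise, 150 nm contact offset):

```r
library(junctionmech)

tr    <- force_curve_truth(youngs_modulus = 12, contact_offset = 150,
                           noise_sd = 0.02, noise_mode = "multiplicative",
                           n_points = 200, seed = 42)
curve <- gen_force_curve(tr)
prep  <- preprocess_force_curve(curve)
fit   <- fit_sneddon(prep$curve, contact_offset = prep$contact_offset_nm)
fit
#> Sneddon fit: E = 12.06 kPa, R^2 = 0.9993, contact at 151.7 nm (169 points)
```

The fitted modulus (12.06 kPa) recovers the planted 12 kPa within the noise
level, the contact offset lands one sample from the planted 150 nm, and the
fit passes the R² ≥ 0.98 gate that `filter_fits()` applies to batches.

Estimate a binding free energy from umbrella windows drawn on the packaged
toy unbinding landscape (a 59.4 kJ/mol well at ξ = 0.9 nm):

```r
sp   <- pmf_binding_well()
wins <- gen_umbrella_samples(sp, seq(0.45, 1.95, by = 0.05),
                             n_per_window = 2000, seed = 1)
fit  <- wham(wins, n_boot = 50, seed = 2)
binding_energy(fit)
#> # A tibble: 1 × 5
#>   delta_g_kJ_mol error_kJ_mol error_min_bin_kJ_mol xi_min_nm edge_minimum
#>            <dbl>        <dbl>                <dbl>     <dbl> <lgl>
#> 1          -59.3        0.211               0.0958     0.895 FALSE
```

The estimator recovers the planted well depth (−59.3 vs −59.4 kJ/mol) and
minimum position (0.895 vs 0.9 nm); `error_kJ_mol` is the Bayesian-bootstrap
sd of the depth.

Summarise the packaged JAM-A tail / ZO-2 PDZ-2 contact listing:

```r
s <- summarize_contact_table(contact_table_to_map(), n_peptide = 10,
                             residues = strsplit(jam_tail_sequence(), "")[[1]])
s$contacting_residues
#> [1] 7
```

Seven of the ten C-terminal tail residues contact the PDZ-2 pocket.

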
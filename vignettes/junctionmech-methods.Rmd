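---
title: "Methods and models in junctionmech"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and models in junctionmech}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(junctionmech)
```

junctionmech collects the quantitative procedures used in junctional
mechanobiology studies of epithelial monolayers: atomic-force-microscopy
(AFM) nanoindentation of the apical membrane, ratiometric FRET
tension-sensor imaging at cell–cell junctions, residue-contact analysis of a
peptide bound in a PDZ-domain pocket, umbrella-sampling free-energy
estimation of peptide unbinding, and the morphometric and nonparametric
statistics that accompany such experiments. Each pipeline is paired with a
seeded synthetic-data generator with known ground truth, so every stage can
be validated end to end without external data. This vignette documents the
models, their assumptions, the tunable parameters, and the numerical choices.

## Nanoindentation: the Sneddon conical model

A rigid cone of half-angle $\alpha$ indenting an elastic half-space produces

$$F = \frac{2}{\pi}\,\frac{E}{1-\nu^2}\,\tan(\alpha)\,\delta^2,$$

with $F$ the force (nN), $E$ Young's modulus (kPa), $\nu$ Poisson's ratio
and $\delta$ the indentation depth (nm). Defaults are $\alpha = 18^\circ$
(typical sharpened silicon-nitride probes) and $\nu = 0.5$ (incompressible
live-cell material); both are arguments on every function. The kPa·nm²
to nN conversion factor is $10^{-6}$, pinned by a worked value
(`sneddon_force(10, 500)` = 0.6895 nN) and a unit round-trip test so the
modulus cannot silently drift between Pa and kPa.

Raw force curves carry a baseline offset and drift from photodiode and
thermal effects. `correct_baseline()` removes a straight line fitted to the
pre-contact segment; `detect_contact_point()` places contact at the first
sample whose force exceeds `threshold_sd` (default 3) times the baseline
noise sd and never returns below it. Because an ill-chosen baseline window
that straddles contact tilts the whole curve, `preprocess_force_curve()`
alternates the two steps, shrinking the baseline window to the points before
the current contact estimate until the estimate stabilises to one sample
spacing. The window starts at the leading 5% of points (at least 10):
almost surely pre-contact, yet enough to estimate slope and noise.

The model is linear in $E$ once the contact offset is fixed, so
`fit_sneddon()` profiles the residual sum of squares over the offset — a
coarse scan over sample positions followed by a golden-section polish — and
solves $E$ in closed form at the optimum. This makes noise-free recovery
exact to floating-point tolerance for any valid $(E, \nu, \alpha,
\text{offset})$, including curves whose contact sits at the very first
sample, and is fully deterministic. $R^2$ is reported against the fitted
model over the post-contact region, and `filter_fits()` applies the
conventional quality gate $R^2 \ge 0.98$ (inclusive boundary). The fitting
range runs from contact to the maximum indentation; no spherical tip-radius
correction is applied — the model is the pure cone.

The generator `gen_force_curve()` is the forward model plus seeded noise,
either additive (nN) or multiplicative (relative). The recovery studies use
200-point ramps to 1 µm with a 150 nm contact offset and 2% multiplicative
noise, 100 curves per modulus at 1, 5 and 20 kPa — moduli spanning the
range reported for epithelial apical surfaces. Medians recover the truth to
well under 1%.

## FRET tension sensors: bleed-through-corrected index

Tension-sensor modules place a donor and an acceptor fluorophore on an
elastic linker: load stretches the linker and lowers FRET, so the index is
inversely related to junctional tension. Three channels are acquired: donor
(donor emission, donor excitation), acceptor (acceptor emission, acceptor
excitation) and FRET (acceptor emission, donor excitation). After equal
background subtraction of all three channels, single-fluorophore control
constructs give the spectral bleed-through (SBT) coefficients as
mean-intensity ratios over junctional ROIs,

$$\mathrm{SBT}_{donor} = \frac{\bar I_{FRET}}{\bar I_{donor}}, \qquad
  \mathrm{SBT}_{acceptor} = \frac{\bar I_{FRET}}{\bar I_{acceptor}},$$

and each sensor ROI is corrected and normalised:

$$\mathrm{cFRET} = \bar I_{FRET}
   - \mathrm{SBT}_{donor}\,\bar I_{donor}
   - \mathrm{SBT}_{acceptor}\,\bar I_{acceptor}, \qquad
  \mathrm{FRET\ index} = \frac{\mathrm{cFRET}}{\bar I_{acceptor}}.$$

Design choices: SBT coefficients are pooled across control ROIs by
unweighted mean and treated as per-experiment constants; negative cFRET is
reported and flagged rather than clamped (clamping would bias group
medians); background subtraction defaults to one constant for all channels,
with a per-channel low-percentile estimate available. ROIs are label masks
or polygon vertex lists rasterised by even-odd fill at pixel centres with
0-based coordinates. `linescan()` produces intensity-versus-distance
profiles across junctions, averaging nearest-pixel samples across a
configurable width.

The generator's pixel model places junctional bands in an otherwise uniform
background: with transfer fraction $E_t$, donor expression $D$ and acceptor
expression $A$, band pixels carry donor $D(1-E_t)$, acceptor $A$, and FRET
$E_t D + \mathrm{SBT}_d D(1-E_t) + \mathrm{SBT}_a A$ above background.
Sensitised emission uses unit detector gain — the index is a ratio, so the
gain cancels in recovery. Consequently the noise-free index equals
$E_t D / A$ exactly, which is the closed-form oracle in the tests, and the
index is strictly increasing in $E_t$ at fixed expression. Noise models are
`none`, `gaussian` and `poisson` (shot noise). The generator does not
emulate a microscope point-spread function, chromatic shifts or focal drift,
so passing tests demonstrate correctness of the estimator arithmetic, not
robustness to optical artefacts. Image bit depth (16-bit on disk) and the
default background of 100 counts are arbitrary and configurable.

## Residue contacts, hydropathy and water coordination

Contact analysis reduces each residue to its centre of geometry (COG, the
unweighted atom-coordinate mean) and registers a contact when two COGs are
within 6.5 Å — an inclusive boundary, the conventional reading of a cutoff.
Peptide positions are labelled backwards from the C terminus (C-1 is the
C-terminal residue), the standard convention for PDZ-binding motifs. The
search uses a cell list at the cutoff length, exactly equivalent to the
all-pairs scan, which the tests verify against a brute-force oracle on
random fixtures up to 500 residues. The packaged reference tables carry the
published JAM-A tail (EFKQTSSFLV) against the ZO-2 PDZ-2 pocket: 7 of the
10 tail residues make at least one contact.

Hydropathy uses the parch scale (0–10, from protein–water contact behaviour
during thermal annealing): values strictly below 1 are hydrophobic. The
water-coordination primitive counts water oxygens within 0.315 nm of any
residue atom (minimum-atom-distance criterion; a COG mode is available).
Structural coordinates are in Å throughout; the nm cutoff is converted at
exactly one tested site. Computing parch values themselves requires
annealing molecular dynamics and is out of scope.

The pocket generator plants an exact contact map: single-pseudo-atom
residues are placed by constraint projection so planted pairs sit below the
cutoff and all other cross pairs at least 8 Å apart, with bounded retries
and a hard failure when the constraint graph is unrealisable.

## Umbrella sampling and WHAM

A 1-D potential of mean force $U(\xi)$ along an intermolecular distance
$\xi$ is estimated from harmonically biased windows
$w_i(\xi) = k/2\,(\xi - c_i)^2$. The defaults mirror common steered-MD
practice: $k = 800$ kJ·mol⁻¹·nm⁻², window spacing 0.05 nm, T = 310.15 K
($k_B$ = 0.0083145 kJ·mol⁻¹·K⁻¹).

`wham()` iterates the standard self-consistent equations on half-open
histogram bins (200 over the sampled range by default) until the largest
change in the window constants falls below 1e-6 kJ/mol (cap 1e5
iterations, with a warning when unconverged). Neighbouring windows must
share at least one occupied bin; a gap raises an error naming the window
pair. Profiles are anchored with the minimum at zero (or at a trailing
plateau). Empty bins are reported as NA. Errors come from a Bayesian
bootstrap: whole windows are reweighted by flat Dirichlet weights, WHAM is
re-run warm-started, and the per-bin sd over replicates is reported —
window-level resampling because samples within a window are serially
correlated, so per-sample weights would understate the error.

`binding_energy()` extracts the well depth as the free energy at the global
minimum minus the mean over the trailing 10% of the grid (the unbound
plateau); a minimum at the grid edge is flagged as unreliable. Both the
bootstrap sd of the depth and the sd at the minimum bin are reported, since
either convention appears in the literature.

The sampler draws from the biased Boltzmann density with a Metropolis
chain: Gaussian proposals with sd $2.4\sqrt{k_B T/k}$ — the optimal
random-walk scaling, which measured acceptance near 0.4–0.5 under the
bias — a 1000-step burn-in and 10× thinning. Narrower proposals (a
quarter of the bias width) were tried first and accepted >0.9 of steps, but
the resulting autocorrelation produced window-level free-energy offsets
large enough to dominate the recovery error, so the wider scaling was
adopted. An independent inverse-CDF sampler provides the distributional
oracle (two-sample Kolmogorov–Smirnov at n = 10⁴, $\alpha$ = 0.01).

Two packaged landscapes drive the recovery studies. The double well is a
sum of two Gaussian wells (depth 10 kJ/mol, minima at 0.7/1.3 nm, width
0.12 nm) rather than a quartic: a quartic's outer walls have slopes near
400 kJ·mol⁻¹·nm⁻¹, which 800 kJ·mol⁻¹·nm⁻² windows cannot restrain — their
biased minima collapse inward, starving the edge bins — whereas the
Gaussian form's maximal slope (~50 kJ·mol⁻¹·nm⁻¹) respects the usual
feasibility rule for choosing umbrella force constants. At 21 windows ×
5×10³ samples the recovered profile's RMSD against truth is below 0.3
kJ/mol and the depth error below 0.5 kJ/mol or twice the bootstrap sd.
The toy unbinding landscape is a single Gaussian well of depth 59.4 kJ/mol
at $\xi$ = 0.9 nm (width 0.28 nm, chosen so the biased densities stay
monomodal at k = 800) decaying to a flat unbound plateau; the full stack
recovers its depth within 2 kJ/mol and the minimum position within 0.05
nm. This is an estimator self-consistency exercise at desk scale — it does
not reproduce an all-atom peptide-unbinding calculation, which requires
cluster-scale molecular dynamics.

## Morphometry and group statistics

Cell area is pixel count × pixel size². Aspect ratio is the major/minor
axis ratio of the second-central-moment equivalent ellipse; the per-pixel
moment includes the 1/12 square-pixel term, so rasterised rectangles return
their exact side ratio, and the measure is rotation-invariant. Holes in a
monolayer mask are 4-connected background components fully enclosed by
foreground — border-touching gaps are not holes — with a minimum-area gate
(default 10 µm²) against single-pixel noise.

`kruskal_dunn()` combines the tie-corrected Kruskal–Wallis omnibus test
(via `stats::kruskal.test`) with Dunn's pairwise z statistics from the
pooled tie-corrected rank variance; pairwise p values are uncorrected by
default (any `p.adjust` method is available). Fully tied data return the
degenerate H = 0, p = 1 rather than NaN. `mann_whitney()` reports
U (pairs with a > b, ties half) with exhaustive enumeration of all group
assignments when both samples have ≤ 8 observations — exact even under
ties — and the tie-corrected normal approximation otherwise; tests verify
both regimes against `stats::wilcox.test` and hand enumeration. A thin
two-way ANOVA with Fisher's LSD cell-mean comparisons is included for
factorial designs; it wraps `stats::aov` and makes no bespoke claims.

## Problem sizes and what the tests show

The test-suite and acceptance-script problem sizes — 100 curves per
modulus, 96×96-pixel image sets, 21–31 umbrella windows with 3–5×10³
samples, contact fixtures up to 500 residues — were chosen as the smallest
sizes at which the estimators' statistical errors are comfortably inside
the documented recovery bounds, so the whole suite runs on a laptop in a
few minutes. Synthetic data validate estimator correctness under the
generators' forward models; real AFM curves, micrographs and MD
trajectories violate those models in ways (viscoelasticity, optical
artefacts, force-field error, sampling bias) that no amount of synthetic
testing addresses.
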
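---
title: "Models and methods behind membranr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind membranr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(membranr)
```

membranr packages the computational layer of a combined
diffraction/calorimetry/infrared/simulation study of a charged phospholipid
bilayer (DMPG) doped with a semisynthetic catechin. This vignette explains
the models each module implements, the assumptions behind them, the
parameters that matter, and the design decisions taken where the standard
laboratory practice is manual or under-specified.

## Small-angle diffraction: the three-Gaussian bilayer profile

Dispersions of charged unilamellar or loosely coupled vesicles show no
lamellar Bragg peaks; the scattering is the diffuse transform of a single
bilayer. We model the transverse electron density as a symmetric sum of
three Gaussians — headgroup peaks of width $\sigma_H$ at $\pm Z_H$ with
amplitude fixed to 1, and a chain trough of width $\sigma_C$ with negative
relative amplitude $\rho_r$ at the center. Fixing the headgroup amplitude
removes the overall-scale degeneracy of the profile; the intensity scale is
carried by an explicit multiplicative factor instead. The form factor is
available in closed form (a cosine transform), and the intensity of
positionally uncorrelated bilayers is $I(q) = s\,|F(q)|^2/q^2 + b$.

The scale $s$ and constant background $b$ are not part of the textbook
equation but any fit of real counting data needs both; the fit report
states that a background was fitted and that no resolution smearing was
applied. Smearing from slit-collimation cameras is a real effect that this
package deliberately does not model, since no slit geometry is part of the
inputs; fitted widths should therefore be read as effective widths.

The steric bilayer thickness is $d_B = 2(Z_H + 2\sigma_H)$ — the headgroup
positions padded by two headgroup widths. With the conventional
$\sigma_H = 3$ Å held fixed (the default entry of `fixed` in `fit_saxd()`),
$Z_H$ maps one-to-one onto $d_B$: $Z_H = 19.08$ Å gives the gel-phase
50.16 Å and $Z_H = 15.30$ Å the fluid-phase 42.60 Å.

Fitting is bounded Levenberg–Marquardt (`minpack.lm`) on weighted residuals
(weights $1/\sigma_y^2$ when the curve carries uncertainties). The
$\cos(qZ_H)$ term makes the objective multimodal in $Z_H$, so the optimizer
restarts from five seeded perturbations of the initial guess (10% lognormal
on all parameters, $\pm 2$ Å normal on $Z_H$) and keeps the best optimum.
Parameter bounds ($Z_H \in [5, 40]$, $\sigma_H \in [1, 6]$,
$\sigma_C \in [2, 15]$ Å, $\rho_r \in [-2, 0)$) span any plausible
phospholipid bilayer and keep the trough negative, which is what
distinguishes the chain region physically. Uncertainties come from the
Gauss–Newton covariance at the optimum scaled by the reduced chi-square;
$d_B$ uncertainty is propagated through its linear gradient.

## Wide-angle diffraction: chain packing

The 1.32–1.95 Å$^{-1}$ window contains the acyl-chain lattice reflections.
We fit one or two Gaussian peaks plus a flat baseline and convert centers
to spacings $d = 2\pi/q_0$. The phase taxonomy follows the conventional
qualitative reading, made explicit with two tunables:

* two components whose FWHM ratio is at least 2 → asymmetric sharp + broad
  pattern → tilted-chain gel (Lβ′);
* a single component narrower than the diffuse threshold (default FWHM
  0.15 Å$^{-1}$) → symmetric reflection → rippled gel (Pβ′);
* a single component at or above the threshold → diffuse scattering →
  fluid (Lα).

A width ratio in $[1.5, 2)$ is labeled Pβ′ with an `ambiguous` flag, and a
two-component fit with nearly equal widths (ratio < 1.5) is treated as one
quasi-symmetric reflection. These thresholds are artifact decisions — the
original assignment is done by eye — and are exposed as arguments. When the
component count is not forced, the 1- vs 2-component choice is made by the
corrected Akaike criterion, which is testable where visual judgment is not.

## Calorimetry: tangents, areas, phase diagram

`subtract_baseline()` draws a straight line through the means of two
user-chosen peak-free windows. The construction is idempotent and refuses
windows that are not linear to within 2% of the full signal excursion,
which is how a window overlapping a peak manifests. `detect_transitions()`
finds local maxima by topographic prominence and extends each region to the
1%-of-peak-height level, merging overlapping regions.

Onset and completion are tangent constructions: the tangent at the steepest
point of the leading edge — located on a Savitzky–Golay smoothed derivative
(order 3, default window 9 points) — intersected with the zero baseline.
For a Gaussian endotherm of center $c$ and width $s$ this gives exactly
$c - 2s$, which anchors the tests. The trailing-edge construction for the
completion temperature mirrors the leading-edge one; the laboratory
procedure describes only the onset construction, so the mirror is this
package's interpretation (symmetric peaks make it exact).

Enthalpy is the trapezoidal integral over the region. Because the 1% region
cut truncates 0.24% of a Gaussian's area — more than the 0.2% accuracy the
enthalpy checks demand — `enthalpy()` first pads the detection region down
the monotone tails to the 0.1% level; explicit temperature intervals are
integrated as given. Synthetic endotherms are symmetric Gaussians even
though real endotherms are skewed: the tangent construction does not need
skewness, and the closed-form onset is worth more to the test suite than
realism.

The phase diagram maps onset → solidus and completion → fluidus per
composition. Immiscibility detection flags maximal runs of at least three
boundary points whose temperature spread is at most 0.3 °C (the order of
DSC peak-position reproducibility, configurable): a boundary that stops
moving while the solute concentration grows means the solute is no longer
mixing into that phase.

## Infrared: the carbonyl doublet

The ester carbonyl stretching band of a hydrated phospholipid is a
superposition of a free component near 1742 cm$^{-1}$ and a hydrogen-bonded
component near 1728 cm$^{-1}$. `band_maximum()` reports a sub-grid maximum
(quadratic through the 5 points around the discrete maximum), which is
invariant to intensity scaling and offsets. `decompose_carbonyl()` fits two
Gaussians with centers bounded to ±6 cm$^{-1}$ of their nominal positions
and reports `f_hbond`, the area fraction of the low-wavenumber component —
the package's quantitative proxy for the hydrogen-bonded carbonyl
subpopulation (component shape is Gaussian; the band-fitting literature
also uses pseudo-Voigt, which changes the area fraction only marginally for
overlapping bands of similar width). Spectra are assumed solvent-corrected;
measurements in deuterated buffer leave this window clean by design.

`maximum_vs_temperature()` fits a descending logistic to the band maximum
versus temperature. Two numerical choices matter. First, the sigmoid width
is bounded below by a quarter of the median temperature spacing: a narrower
width makes the midpoint unidentifiable (any value between two bracketing
samples fits a step equally well) and lets the optimizer stall in flat
regions of the objective. Second, the midpoint is multi-started across the
sampled temperatures and the best optimum kept. If the sigmoid does not
beat a constant by corrected AIC, the series is declared non-sigmoidal and
the midpoint reported as `NA` rather than a meaningless number.

## Trajectory statistics

All distances use the minimum-image convention in an orthorhombic box;
triclinic input is rejected at the reader. Statistics are invariant under
lattice translations of all coordinates, which is tested as a property.

* **Area per lipid** is $L_x L_y / (N/2)$ per frame.
* **Leaflet assignment** classifies each lipid by its phosphorus $z$
  relative to the mass-weighted center of all lipid particles; phosphorus
  within 0.1 nm of the midplane is flagged ambiguous but still assigned by
  sign.
* **P–P thickness** is the difference of mean phosphorus heights of the two
  leaflets, per frame, then averaged.
* **Hydrogen bonds** use the geometric criterion (donor–acceptor distance
  ≤ 0.35 nm and donor-vertex angle between D→H and D→A of ≤ 30°, both
  inclusive). The angle is defined at the donor, matching the criterion's
  phrasing; the acceptor-centered convention found in some tools is
  deliberately not used. Donors are paired with hydrogens through molecule
  identity (a donor without a hydrogen in its molecule is an error), and
  intra-molecular pairs are excluded. The default cell-list search is exact
  and is cross-checked against an all-pairs scan in the tests.
* **Mass density profiles** recenter each frame on the lipid mass centroid
  (the "bilayer frame"), bin masses along $z$, and never symmetrize — an
  asymmetric solute distribution must stay visible. The bin width is
  adjusted to divide the box height exactly so mass is conserved to
  rounding.
* **Solute clustering** links two molecules when the minimum atom-pair
  distance is at most 0.25 nm and takes connected components (single
  linkage, so an A–B–C chain is one trimer). Whether the original criterion
  means atom-pair minimum or centroid distance is not stated; atom-pair
  minimum matches contact-style aggregation at such a small cutoff and is
  the default, with `metric = "centroid"` available. Histograms are
  computed per frame and averaged (not pooled), which is what gives the
  monomer fraction a spread across frames.

## The synthetic generators

The generators produce data with the statistical structure each analysis
assumes, plus planted ground truth the analyses must recover exactly:

* `generate_saxd_curve()` — the forward model plus relative Gaussian noise
  (default 2%, the order of good counting statistics), on the measured
  0.05–0.6 Å$^{-1}$ window; default profile is the gel-phase geometry.
* `generate_thermogram()` — unit-area Gaussian peaks on a linear baseline;
  defaults are a weak pretransition (onset 9 °C, 3 kJ/mol, a typical
  pretransition enthalpy) and the main transition (onset 22.3 °C,
  27.2 kJ/mol) sampled every 0.01 °C.
* `generate_ftir_series()` — the two-band model with the low-band weight
  following a logistic in temperature (weight 0.25 → 0.75, steepness
  0.8 °C), emulating increased interfacial hydration above the melting
  transition.
* `generate_bilayer()` — a two-leaflet pseudo-bilayer: 128 three-site
  lipids (phosphorus / carbonyl / terminal methyl) on a lateral grid with
  phosphorus planes at ±1.685 nm in a 6.3499 nm box (P–P thickness 3.37 nm,
  area per lipid 0.63 nm²), 14 single-site solutes planted as 4 monomers +
  clusters of 3, 3, 4 (within-cluster contacts at 0.2 nm, inter-cluster
  separation > 0.5 nm — the 2× margin makes single-linkage recovery
  unambiguous), and donor–H–acceptor triplets of which exactly the
  requested number satisfy the hydrogen-bond criterion while all decoys
  violate it by ≥ 0.1 nm. Lipid sites are jittered per frame (default
  0.05 nm); solute and triplet coordinates are frame-constant so planted
  truth holds in every frame.

What passing tests show — and what they do not. Recovery of planted truth
demonstrates that the estimators implement their definitions correctly and
are numerically stable at realistic noise. It does not validate the models
against real membranes: synthetic endotherms are symmetric, synthetic
bilayers have no conformational disorder, undulations, or force-field
physics, and synthetic scattering has no smearing, no multilamellar
structure factor, and uncorrelated noise. Conclusions about real samples
still require the usual experimental controls.

## Degenerate inputs and tie-breaks

Curves must have at least two points to load (fitting stages impose their
own coverage requirements, e.g. `fit_saxd()` warns when the bilayer band
near 0.12 Å$^{-1}$ is missing); duplicate abscissas are averaged on read.
Flat wide-angle windows fit with near-zero amplitude and warn rather than
error. A thermogram region without an interior maximum cannot support a
tangent and errors. Peaks swapped by the carbonyl fit are reordered so the
low-wavenumber component is always the hydrogen-bonded one. All randomized
stages take an explicit integer seed and are bit-reproducible given it;
seeded code saves and restores the caller's RNG state.

## Problem sizes

The shipped tests and the acceptance script run at desk scale by choice:
trajectories of 2–25 frames with 128 lipids, 20-seed recovery ensembles for
the diffraction and infrared fits, 50 random configurations for the
exact-oracle cross-checks, and 0.01 °C thermogram grids. These sizes are
where the statistical checks are already sharp; every stage scales to
larger inputs linearly in points × frames except solute clustering, which
is quadratic in the (small) number of solute molecules.
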
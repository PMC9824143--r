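# membranr

Analysis pipeline for model phospholipid membranes perturbed by small
amphipathic solutes (catechins and similar membranotropic compounds). It
implements, as reusable tested R functions, the computations that sit
between raw instrument or simulation output and the numbers reported in a
membrane-biophysics study of an anionic DMPG bilayer:

* **SAXD** — full q-range fitting of diffuse small-angle X-ray diffraction
  from positionally uncorrelated vesicles with a three-Gaussian electron
  density profile, and extraction of the steric bilayer thickness.
* **WAXD** — deconvolution of wide-angle chain-packing reflections into
  sharp/broad Gaussian components, Bragg d-spacings, and classification of
  the acyl-chain lattice (Lβ′ tilted gel, Pβ′ rippled gel, Lα fluid).
* **DSC** — thermogram baseline correction, transition detection,
  tangent-method onset/completion temperatures, enthalpy integration, and
  partial phase diagrams (solidus/fluidus vs solute mole fraction) with
  immiscibility-plateau detection.
* **FTIR** — ester carbonyl band maximum tracking and two-component
  (hydrogen-bonded / free carbonyl) band decomposition across temperature.
* **Trajectory statistics** — area per lipid, phosphorus–phosphorus
  thickness, geometric hydrogen bonds, non-symmetrized mass density
  profiles, and single-linkage solute cluster-size distributions on GRO/PDB
  configurations with periodic orthorhombic boxes.
* **Synthetic generators** — seeded emulators of every input (scattering
  curves, thermograms, carbonyl spectra, pseudo-bilayer trajectories with
  planted clusters and hydrogen bonds) so the whole pipeline is testable
  without instrument data or an MD engine.

## The core models

**Electron density profile and form factor.** The transverse electron
density of the bilayer is modeled as two headgroup Gaussians of width σ_H at
±Z_H (amplitude 1) plus a chain-region Gaussian of width σ_C and negative
relative amplitude ρ_r at the center. Its cosine transform is the bilayer
form factor

    F(q) = √(2π) [ 2 σ_H cos(q Z_H) e^(−q² σ_H²/2) + σ_C ρ_r e^(−q² σ_C²/2) ]

and for randomly oriented, positionally uncorrelated bilayers the scattered
intensity is I(q) = s·|F(q)|²/q² + b. The steric bilayer thickness is

    d_B = 2 (Z_H + 2 σ_H)

with σ_H conventionally fixed at 3 Å during fitting.

**Calorimetry.** Transition onset and completion are the intersections of
the tangent at the steepest point of the leading (trailing) edge of the
endotherm with the baseline; for a Gaussian peak of center c and width s
these equal c ∓ 2s in closed form. Transition enthalpy is the trapezoidal
area of the baseline-corrected excess heat capacity. A boundary (solidus or
fluidus) that stays constant while the solute mole fraction grows signals
solute–lipid immiscibility in that phase.

**Trajectory geometry.** A hydrogen bond is a donor–H···acceptor triplet
with minimum-image donor–acceptor distance ≤ 0.35 nm and an angle between
the donor→hydrogen and donor→acceptor directions ≤ 30°. Two solute
molecules aggregate when any pair of their atoms is within 0.25 nm
(single linkage); area per lipid is the lateral box area over lipids per
leaflet.

## Worked example

```r
library(membranr)

## small-angle diffraction: generate a gel-phase curve at 2% noise, fit it
curve <- generate_saxd_curve(saxd_truth(), seed = 42)
fit_saxd(curve)
#> <saxd_fit> d_B = 50.16 +/- 0.00 A (Z_H = 19.08, sigma_H = 3.00 fixed, sigma_C = 6.00, rho_r = -0.801)
#>   scale = 0.9989, background = 0.04959, reduced chi-square = 0.9527

## calorimetry: pretransition + main transition of the pure lipid
th <- generate_thermogram(thermogram_truth(), seed = 42)
analyze_thermogram(th, min_prominence = 0.3)
#>           label T_onset T_peak T_completion   delta_H overlapping
#> 1 pretransition     9.0   10.0         11.0  2.999353       FALSE
#> 2          main    22.3   23.1         23.9 27.194131       FALSE

## trajectory statistics on a synthetic two-leaflet system
traj <- generate_bilayer(bilayer_spec(), n_frames = 10, seed = 42)
area_per_lipid(traj)$mean     # 0.630 nm^2
pp_thickness(traj)$mean       # 3.373 nm
cluster_size_distribution(traj)
#> <cluster_distribution> 14 solute molecules, monomer fraction 0.286
#>  1 3 4
#>  4 6 4
```

The fitted `d_B` of 50.16 Å is the gel-phase steric thickness implied by the
generating profile (Z_H = 19.08 Å, σ_H = 3 Å); the main transition onset of
22.3 °C and enthalpy of 27.2 kJ/mol follow from the planted Gaussian
endotherm (center 23.1 °C, sd 0.4 °C, area 27.2 kJ/mol); the cluster
histogram echoes the planted partition of the 14 solute molecules
(4 monomers + clusters of 3, 3, 4, monomer fraction 28.6%).

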
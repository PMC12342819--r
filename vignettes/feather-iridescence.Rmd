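---
title: "Modelling iridescent structural color from melanosome nanostructure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling iridescent structural color from melanosome nanostructure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Electron microscopy of some fossil feather barbs shows rod-like melanosomes
with oval cross-sections packed into a sheared ("asymmetric compact") hexagonal
lattice under a thin keratin cortex. Such a periodic arrangement of
high-index melanin rods in a keratin matrix is a photonic structure: coherent
interference of light scattered by the lattice produces reflection peaks whose
wavelength depends strongly on the angle of incidence — iridescence. The
organism is long dead, so the color must be *computed* from the measured
nanostructure: cross-section short axis x ≈ 186 nm, major axis y ≈ 283 nm,
rod length z ≈ 1774 nm, with the cross-section major axes leaning to one side
and the whole array inside a barb roughly 10 µm thick.

`iricrest` implements the full chain: morphometry → lattice geometry →
electromagnetic reflectance (two independent solvers) → reflection peaks →
perceived color → robustness under fossilization artefacts.

## Geometry: compact packing as a constraint, not a free parameter

The published melanosome measurements give the particle, not the lattice.
Rather than introduce two lattice constants as free parameters, the package
takes the word *compact* literally: the lateral period Λ and row pitch p are
**derived** from the requirement that within-row neighbours and the nearest
diagonal neighbours of the sheared lattice sit at a common surface-to-surface
clearance `gap_g`. Contact between identical parallel ellipses is evaluated on
the Minkowski-sum ellipse (full axes y, x), with the clearance absorbed by
inflating it to (y + g, x + g) — exact for g = 0, and a good approximation at
the few-tens-of-nanometres clearances used here.

This leaves exactly one free packing parameter, `gap_g`. It is calibrated
**once**, so that the transfer-matrix first-order reflection peak of the
default model falls at 687 nm for 40° incidence (the longest-wavelength
condition of the angle sweep), and is then frozen: the peak positions at all
other angles, and everything downstream, are predictions. With the shipped
defaults the calibration gives `gap_g` = 39 nm, Λ ≈ 304 nm, p ≈ 237 nm
(printed by `default_feather_lattice()`).

Two orientation parameters of the lattice are not printed in any measurement
we model: the magnitude of the major-axis tilt and the row shear. They ship
as `tilt_deg = 20` and `shear_s = 0.35` — a visible leftward lean and a
clearly non-centred offset — are config-overridable, and are echoed into all
run metadata as assumed parameters. The same holds for the cortex thickness
(`cortex_t = 100` nm) and the number of rows (`n_layers = 10`, enough for a
saturated interference peak while staying far inside the 10 µm barb bound).
The dorsoventral hooks seen on the fossil melanosomes are excluded from the
optical geometry: they are sub-resolution protrusions with unprinted
dimensions, and their described role is mechanical (linking adjacent rods),
not optical.

## Materials

The complex refractive indices are Cauchy models standard in feather optics:
keratin n(λ) = 1.532 + 5890/λ², eumelanin n(λ) = 1.648 + 23700/λ² with an
absorption tail k(λ) = 0.56·exp(−λ/270 nm), ambient air n = 1. The exact
dispersion curves used by the original commercial-solver study are not
recoverable from its text, so these literature-standard defaults stand in;
all coefficients are config keys (`materials.*`), a measured 3-column
(λ, n, k) table can be substituted via `load_dispersion_table()`, and every
run records the values it used. Within each single-frequency solver run the
index is frozen at the run wavelength, which makes the FDTD and
transfer-matrix paths consistent by construction and avoids broadband
dispersion-fitting error.

## Solvers

**Transfer matrix (TMM).** The lattice is reduced to a 1D multilayer by
horizontal slicing (one raster row per sub-layer, merged when equal): each
sub-layer gets an effective index from its melanin fill fraction, by
index-weighted volume averaging (default) or Maxwell–Garnett mixing. The
multilayer response is then exact: characteristic 2×2 matrices, `exp(−iωt)`
sign convention, admittances η_s = n·cosθ and η_p = n/cosθ, complex Snell
angles via the principal square root of 1 − (n₀ sinθ/n)². Lossless stacks
conserve R + T = 1 to 10⁻¹⁰; a single interface reproduces Fresnel and the
Brewster zero to machine precision. These closed-form cases are the oracle
suite for everything else.

**FDTD.** The 2D finite-difference time-domain solver (`run_fdtd()`, C++
core) is the reference physics for the laterally structured lattice in the
X-Y incidence plane: Yee grid, Bloch-periodic lateral boundaries carrying
exp(i·kx·Λ) with kx = (2π/λ)·n₀·sinθ, CPML absorbers above and below,
per-wavelength continuous-wave drive, absorption as electric conductivity
σ = ε₀ω·2nk. s-polarization maps to the TE (out-of-plane E) problem, p to
TM. Reflectance is the time-averaged Poynting flux of the *scattered* field
through a monitor above the source — isolated by subtracting the fields of an
identical empty-domain reference run, which also supplies the incident-flux
normalisation. This captures specular and diffracted orders alike, which
matters: the asymmetric lattice reflects part of the light into non-specular
orders, and those carry much of the angle dependence.

Numerical choices worth knowing:

* cell size 5 nm (≥ 20 cells per wavelength in the densest material; the
  lateral cell is snapped so the period is an integer number of cells);
* time step at 0.95 of the exact 2D stability limit;
* single-frequency drive with a C³-smooth turn-on. The turn-on length is
  raised automatically at steep angles (∝ 1/(1 − sinθ)): spectral leakage
  near the grazing frequency kx·c excites slowly-escaping near-horizontal
  waves in a periodic domain, and a smoother, longer ramp suppresses them at
  the source rather than waiting for them to decay;
* a run ends when the demodulated monitor phasor changes by < 10⁻³ between
  successive optical periods (flagged, never silent, if the 400-period budget
  runs out first);
* field storage is single precision, demodulation accumulators double; the
  validation suite puts the end-to-end error against exact solutions below
  0.003 in reflectance.

The Y-Z incidence plane (plane of incidence containing the rod axis) sees a
structure that is invariant along the rods at the scale of one rod, i.e. a
1D multilayer; those requests are always served by the TMM reduction, and
`angle_sweep()` does this routing explicitly.

## What the two solvers say — and why they differ

For a horizontal multilayer the two solvers agree within 0.003 absolute
reflectance. On the full 2D lattice they must *not* agree, and the
difference is the scientific point. A 1D stack of keratin/melanin
(n ≥ 1.53) has a hard geometric limit on its iridescent swing: between 40°
and 70° the internal Bragg cosine changes by only ~11%, so a first-order
peak calibrated to 687 nm at 40° can blue-shift no further than ≈ 610 nm at
70°. The much larger swings seen in strongly iridescent barbs require the
lateral structure: the sheared lattice has tilted dense-plane families whose
Bragg condition 2·n·d·cos(θ′ ± δ) moves much faster with angle, and the
reflected power leaves through diffracted orders that only the 2D solver
carries. The FDTD sweep of the default model accordingly shows, in addition
to the slowly-shifting specular peak, shorter-wavelength peaks from these
tilted families that grow with angle — and the angle-by-angle hue sequence
is read from the full FDTD spectra, not from the reduction.

## Peaks and color

`find_peaks()` reports discrete local maxima with prominence measured
against the enclosing minima (default threshold 0.05 absolute reflectance),
3-point parabolic position refinement and half-prominence FWHM. An empty
peak set is a meaningful outcome: together with a maximum visible reflectance
below 0.08 it is rendered as "dark/none", which operationalizes the
qualitative judgement "no evident reflection peak" and makes the darkness of
small-angle viewing a testable statement. Both thresholds are configurable.

Colorimetry uses the CIE 1931 2° observer at 5 nm steps and a D65-like
daylight illuminant. Both tables are bundled as plain text and are smooth
analytic approximations (the observer from the published piecewise-Gaussian
fits, the illuminant a 6504 K Planckian normalised at 560 nm), documented as
such in `inst/extdata`; illuminant E is available and exact. XYZ integration
is trapezoidal on the spectrum's own grid, normalised so a perfect reflector
has Y = 1; sRGB conversion uses the standard D65 matrix and gamma, with
out-of-gamut clipping flagged. Hue *names* come from fixed wavelength bands
(deep blue [450, 490), green [490, 560), yellow [560, 590), orange
[590, 620), red [620, 740)) chosen so the four characteristic wavelengths of
the modelled sweep (475, 512, 578, 687 nm) map to their conventional color
words; the bands are a presentation convention, not physics. Because which
polarization a rendered inset represents is not stated anywhere, swatches
default to the unpolarized s/p average.

## Synthetic morphometry: what passing tests show

The generator draws per-axis truncated-normal populations (CV 0.10 by
default — typical within-feather melanosome variability; only the means are
measured quantities) and renders them as dark particles on a light
background: tilted ellipses at sheared-lattice positions for cross-sections,
axis-aligned rectangles for longitudinal sections, plus additive Gaussian
noise (default σ = 8/255). The morphometry stage thresholds (Otsu), discards
border-touching and sub-size (< 25% of median area) components, and fits
second-moment-equivalent ellipses — for rods, the length is the pixel extent
along the fitted axis, since moment axes overestimate rectangle lengths by
2/√3. Parameter recovery on these images is within ~0.5% at n = 500, 5 nm/px.

What this does and does not show: the generator emulates particle geometry,
packing, and detector noise, so passing recovery tests validates the
*estimator* (segmentation, filters, moment fitting) against known truth. It
does not emulate staining gradients, section compression, charging, or
overlapping particles from oblique sectioning, so recovery rates on real
micrographs will be worse; the filters are designed to fail toward exclusion
rather than bias.

## Taphonomy

Fossil melanosomes are measured after diagenesis; maturation experiments
indicate ~10% shrinkage, and compression can change spacing. The scenario
machinery scales the melanosome axes (default 1.10, i.e. sizes corrected
back up) and jitters each row's clearance (default SD 10 nm — a documented
stand-in, as the original perturbed-spacing parameterization is unprinted),
draws several seeded realizations, averages their spectra per angle, and
greedily matches ensemble peaks to baseline peaks by nearest wavelength.
Because Maxwell's equations are scale-invariant, a uniform 10% enlargement
with frozen indices shifts every peak by +10%; with the real (dispersive)
indices the shift is slightly smaller. The robustness claim tested is that
every baseline first-order peak at 40–70° retains a scenario counterpart
within 12% relative wavelength, inside the visible band.

## Problem sizes and runtimes

The shipped defaults are chosen for a single desktop CPU: TMM sweeps are
effectively free (< 5 s for six angles at 2 nm resolution); one FDTD
wavelength point on the default 10-row lattice (~60 × 590 cells) takes a few
seconds, a four-angle two-polarization sweep at 10 nm sampling plus 5 nm
refinement around detected peaks runs in roughly 10–15 minutes; synthetic
morphometry at n = 500 and 5 nm/px takes under a minute for cross-sections
and under two for longitudinal sections. The acceptance script in
`scripts/acceptance.R` reproduces the headline numbers at exactly these
sizes.

## Known limitations

* The optical model is 2D (rods treated as infinitely long); out-of-plane
  scattering and rod-end effects are absent. The Y-Z plane is handled by the
  1D reduction, justified by the rods' length but untested against a 3D
  solver here.
* The melanin/keratin dispersions are literature defaults, not
  specimen-measured; peak positions inherit that uncertainty (the ±8%
  tolerance used throughout reflects it).
* Compact packing with a single global clearance is an idealization; real
  lattices are disordered, which broadens and weakens peaks (the taphonomy
  jitter machinery gives a first-order handle on this).
* Hue naming is band-based and human-observer-based; avian tetrachromatic
  vision is out of scope.
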
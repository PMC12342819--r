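# iricrest

Forward optical modelling of iridescent structural color in melanin-bearing
feather barbs, for paleocolor reconstruction from electron-microscopy
morphometry.

Some fossil feather barbs preserve rod-like melanosomes with oval
cross-sections packed in an *asymmetric compact hexagonal* (ACHP) lattice
under a keratin cortex. Such a lattice is a photonic structure: constructive
interference of light scattered by the melanin rods produces reflection peaks
whose wavelength depends on the viewing angle. Given the measured particle
geometry — cross-section short axis x ≈ 186 nm, major axis y ≈ 283 nm, rod
length z ≈ 1774 nm — `iricrest` reconstructs the reflectance and the
perceived color:

* **geometry** — a compact-packing lattice builder: the lateral period Λ and
  row pitch p are derived from an ellipse contact condition at a single
  surface-to-surface clearance `gap_g` (the one calibrated parameter,
  shipped at 39 nm), with tilt, shear, cortex and row count as documented,
  overridable assumptions;
* **solvers** — a from-scratch 2D FDTD Maxwell solver (Yee grid,
  Bloch-periodic oblique incidence, CPML, per-wavelength CW drive, C++ core)
  for the laterally structured lattice, and an exact transfer-matrix (TMM)
  solver for its 1D multilayer reduction, each validated against closed-form
  electromagnetic oracles (Fresnel, Airy, Brewster, energy conservation) and
  against each other;
* **spectra** — peak extraction with prominence and FWHM, fixed hue bands,
  CIE 1931 colorimetry to sRGB swatches;
* **synthetic morphometry** — a generator of noisy EM-like section images
  from known particle populations, plus segmentation and
  second-moment ellipse fitting, so the measurement stage is testable
  against ground truth;
* **taphonomy** — shrinkage-correction (110% scaling) and row-spacing jitter
  scenarios with ensemble spectra and peak matching.

The central physical quantity is the first-order interference condition of
the melanosome lattice, λ_peak(θ) ≈ 2 Σᵢ nᵢ dᵢ cos θᵢ′ with Snell-propagated
internal angles; the FDTD solver computes the full vector-wave answer
including diffracted orders that the 1D reduction cannot carry.

## Worked example

```r
library(iricrest)

lat  <- default_feather_lattice()     # calibrated ACHP model
lat
#> <lattice_spec> ACHP, 10 rows
#>   melanosome x=186 y=283 z=1774 nm, tilt=20 deg
#>   gap=39 nm, shear=0.35  ->  period=303.9 nm, pitch=236.8 nm
#>   cortex 100 nm, substrate 200 nm (keratin); total 2670 nm

geom <- build_achp_geometry(lat, delta = 5)
sw   <- angle_sweep(geom, plane = "XY", polarization = "sp",
                    theta_list = c(0, 20, 40, 50, 60, 70),
                    lambda = seq(400, 800, by = 2), solver = "tmm")
sweep_report(sw)
#>   theta_deg peak_lambda_nm peak_R n_peaks    hue srgb_hex
#> 1         0             NA     NA       0   blue  #453C49
#> 2        20             NA     NA       0   blue  #473D46
#> 3        40          687.3 0.1700       1    red  #514345
#> 4        50          660.6 0.1693       1    red  #5E4B4B
#> 5        60          634.3 0.1870       1    red  #705C5A
#> 6        70          612.1 0.2515       1 orange  #857A77
```

Reading the table: at small viewing angles no reflection peak clears the
prominence threshold (`peak_lambda_nm = NA`) and the barb looks dark; from
40° the first-order interference peak appears at 687 nm (red — the
wavelength the clearance was calibrated to) and blue-shifts monotonically as
the angle steepens. `peak_R` is the absolute reflectance of the peak, `hue`
the band name of the dominant feature, `srgb_hex` the rendered swatch color
(dusky because absolute reflectance is modest over a melanin absorber). The
same sweep with `solver = "fdtd"` runs the full 2D lattice physics; on this
structure it confirms the same dominant peak positions to within a few
nanometres.

The synthetic measurement loop:

```r
pop <- sample_population(population_params(n = 500, seed = 42))
img <- render_section(pop, lat, pixel_size = 5, noise_sigma = 8/255, seed = 7)
measure_morphometry(img)
#> <morphometry_result> cross section: 500 particles (0 excluded)
#>       x_nm  y_nm tilt_deg
#> mean 185.6 282.7     20.2
#> sd    18.2  28.9      5.0
```

A config-driven pipeline (`run_pipeline()`, YAML schema in
`inst/extdata/example_config.yaml`) and a thin CLI
(`Rscript inst/scripts/iricrest.R sweep --config run.yaml --solver tmm`)
orchestrate the stages and write CSV/JSON/PNG artifacts with full parameter
provenance.

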
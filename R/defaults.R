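#' iricrest: structural-color reconstruction from melanosome nanostructure
#'
#' Forward optical model of iridescent feather-barb coloration: ACHP lattice
#' geometry, FDTD and transfer-matrix reflectance solvers, peak extraction
#' and colorimetry, synthetic morphometry, and taphonomic sensitivity.
#'
#' @useDynLib iricrest, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @keywords internal
"_PACKAGE"

# Shipped packing calibration. The keratin clearance gap_g is the single free
# packing parameter of the compact lattice; it is fixed once so that the
# transfer-matrix first-order reflection peak of the default model sits at
# 687 nm for 40 degrees incidence (unpolarized average), and is never re-tuned
# against any other observation. See calibrate_gap() and the methods vignette.
.default_gap_nm <- 39

#' Shipped default feather-barb lattice
#'
#' The default ACHP model: melanosome cross-section 186 x 283 nm, rod length
#' 1774 nm, major-axis tilt 20 degrees, shear 0.35, 10 rows, 100 nm keratin
#' cortex, keratin substrate, and the calibrated keratin clearance
#' (`r .default_gap_nm` nm; see [calibrate_gap()]).
#'
#' @param gap_g override the calibrated clearance, nm.
#' @param ... further arguments to [lattice_spec()].
#' @return a [lattice_spec()].
#' @export
default_feather_lattice <- function(gap_g = .default_gap_nm, ...) {
  lattice_spec(melanosome = melanosome_spec(), gap_g = gap_g, ...)
}

#' Calibrate the packing clearance against the 40-degree red peak
#'
#' Scans the keratin clearance `gap_g` and returns the value whose
#' transfer-matrix reflectance spectrum (unpolarized s/p average on the
#' reduced multilayer) has its strongest visible peak closest to
#' `target_nm` at `theta_deg` incidence. This is the one calibration step of
#' the default model; all other angles and peaks are predictions.
#'
#' @param target_nm target peak wavelength, nm.
#' @param theta_deg calibration incidence angle, degrees.
#' @param gap_range search interval, nm.
#' @param step_nm scan step, nm.
#' @param delta raster cell size for the reduction, nm.
#' @param lambda wavelength grid, nm.
#' @param materials material set.
#' @param ... further [lattice_spec()] arguments.
#' @return list with the best `gap_g`, its achieved `peak_nm`, and the scan
#'   table.
#' @export
calibrate_gap <- function(target_nm = 687, theta_deg = 40,
                          gap_range = c(5, 60), step_nm = 0.5, delta = 2.5,
                          lambda = seq(400, 900, by = 2),
                          materials = default_materials(), ...) {
  gaps <- seq(gap_range[1], gap_range[2], by = step_nm)
  peak_of <- function(g) {
    lat <- lattice_spec(gap_g = g, ...)
    geom <- build_achp_geometry(lat, delta = delta)
    stack <- reduce_to_multilayer(geom, materials = materials)
    R <- (tmm_reflectance(stack, theta_deg, "s", lambda) +
          tmm_reflectance(stack, theta_deg, "p", lambda)) / 2
    spec <- reflectance_spectrum(lambda, R)
    pk <- find_peaks(spec, prominence_min = 0.02)
    if (nrow(pk$peaks) == 0) return(NA_real_)
    pk$peaks$lambda_nm[which.max(pk$peaks$R)]
  }
  peaks <- vapply(gaps, peak_of, numeric(1))
  err <- abs(peaks - target_nm)
  best <- which.min(err)
  list(gap_g = gaps[best], peak_nm = peaks[best],
       scan = data.frame(gap_g = gaps, peak_nm = peaks))
}

#' Assumed (non-measured) model parameters
#'
#' Every numeric default that stands in for a quantity the electron-microscopy
#' data do not constrain, echoed into pipeline summaries so downstream readers
#' can see what was assumed rather than measured.
#'
#' @param lattice the lattice in use.
#' @param materials the material set in use.
#' @return named list.
#' @export
assumed_parameters <- function(lattice = default_feather_lattice(),
                               materials = default_materials()) {
  list(
    gap_g_nm = lattice$gap_g,
    tilt_deg = lattice$melanosome$tilt_deg,
    shear_s = lattice$shear_s,
    n_layers = lattice$n_layers,
    cortex_t_nm = lattice$cortex_t,
    melanin = as.list(materials$melanin$coefficients),
    keratin = as.list(materials$keratin$coefficients),
    medium_n = unname(materials$medium$coefficients[["n"]])
  )
}
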
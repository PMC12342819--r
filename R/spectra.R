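#' Reflectance spectrum container
#'
#' Solver-agnostic container for one reflectance spectrum: sorted wavelengths,
#' reflectance fractions, optional transmittance and per-point convergence
#' flags, and the incidence condition (plane, angle, polarization, solver tag).
#'
#' @param lambda_nm strictly increasing wavelengths, nm.
#' @param R reflectance fractions in `[0, 1]`.
#' @param T optional transmittance fractions.
#' @param converged optional logical vector (FDTD per-point steady-state flag).
#' @param condition named list: `plane`, `theta_deg`, `polarization`, `solver`.
#' @param metadata free-form list (grid settings, geometry hash, ...).
#' @return object of class `reflectance_spectrum`.
#' @export
reflectance_spectrum <- function(lambda_nm, R, T = NULL, converged = NULL,
                                 condition = list(), metadata = list()) {
  stopifnot(is.numeric(lambda_nm), is.numeric(R),
            length(lambda_nm) == length(R))
  if (any(diff(lambda_nm) <= 0)) stop("lambda_nm must be strictly increasing")
  if (any(R < -1e-9 | R > 1 + 1e-9))
    stop("reflectance outside [0, 1]")
  structure(list(lambda_nm = lambda_nm, R = pmin(pmax(R, 0), 1), T = T,
                 converged = converged, condition = condition,
                 metadata = metadata),
            class = "reflectance_spectrum")
}

#' @export
print.reflectance_spectrum <- function(x, ...) {
  cn <- x$condition
  cat(sprintf("<reflectance_spectrum> %d points, %g-%g nm", length(x$lambda_nm),
              min(x$lambda_nm), max(x$lambda_nm)))
  if (length(cn))
    cat(sprintf("  [%s, theta=%s, pol=%s, %s]",
                cn$plane %||% "?", format(cn$theta_deg %||% "?"),
                cn$polarization %||% "?", cn$solver %||% "?"))
  cat("\n  max R =", signif(max(x$R), 3), "at",
      x$lambda_nm[which.max(x$R)], "nm\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Find reflection peaks
#'
#' Local maxima by discrete comparison, with prominence measured against the
#' enclosing minima and sub-sample peak position by 3-point parabolic
#' refinement. Returns an empty peak set when nothing exceeds the prominence
#' threshold — "no evident reflection peak" is a meaningful result, not an
#' error.
#'
#' @param spec a [reflectance_spectrum()].
#' @param prominence_min minimum absolute prominence in reflectance units.
#' @param lambda_band length-2 wavelength window, nm; must lie inside the
#'   spectrum's coverage.
#' @return object of class `peak_set`: data frame `peaks` with columns
#'   `lambda_nm`, `R`, `prominence`, `fwhm_nm`, sorted by wavelength, plus the
#'   spectrum's condition.
#' @export
find_peaks <- function(spec, prominence_min = 0.05,
                       lambda_band = range(spec$lambda_nm)) {
  stopifnot(inherits(spec, "reflectance_spectrum"))
  if (lambda_band[1] < min(spec$lambda_nm) - 1e-9 ||
      lambda_band[2] > max(spec$lambda_nm) + 1e-9)
    stop("lambda_band [", lambda_band[1], ", ", lambda_band[2],
         "] outside spectrum coverage")
  sel <- spec$lambda_nm >= lambda_band[1] & spec$lambda_nm <= lambda_band[2]
  lam <- spec$lambda_nm[sel]; R <- spec$R[sel]
  n <- length(lam)
  if (n < 15) stop("need >= 15 samples in the peak-finding band, got ", n)
  out <- data.frame(lambda_nm = numeric(0), R = numeric(0),
                    prominence = numeric(0), fwhm_nm = numeric(0))
  for (i in 2:(n - 1)) {
    if (!(R[i] > R[i - 1] && R[i] >= R[i + 1])) next
    # prominence: walk out to the first higher point (or edge) on each side,
    # take the minimum in between; reference is the higher of the two minima
    left_min <- min(R[1:i]); j <- i
    while (j > 1 && R[j - 1] <= R[i]) j <- j - 1
    if (j > 1) left_min <- min(R[j:i])
    right_min <- min(R[i:n]); j <- i
    while (j < n && R[j + 1] <= R[i]) j <- j + 1
    if (j < n) right_min <- min(R[i:j])
    prom <- R[i] - max(left_min, right_min)
    if (prom < prominence_min) next
    # parabolic refinement
    denom <- R[i - 1] - 2 * R[i] + R[i + 1]
    shift <- if (abs(denom) > 1e-15) 0.5 * (R[i - 1] - R[i + 1]) / denom else 0
    shift <- max(min(shift, 0.5), -0.5)
    lam_pk <- lam[i] + shift * (lam[min(i + 1, n)] - lam[i - 1]) / 2
    # FWHM at half prominence below the peak
    half <- R[i] - prom / 2
    lam_l <- NA_real_; lam_r <- NA_real_
    for (k in i:2) if (R[k - 1] <= half) {
      lam_l <- stats::approx(R[(k - 1):k], lam[(k - 1):k], xout = half)$y
      break
    }
    for (k in i:(n - 1)) if (R[k + 1] <= half) {
      lam_r <- stats::approx(R[(k + 1):k], lam[(k + 1):k], xout = half)$y
      break
    }
    out <- rbind(out, data.frame(lambda_nm = lam_pk, R = R[i],
                                 prominence = prom,
                                 fwhm_nm = lam_r - lam_l))
  }
  out <- out[order(out$lambda_nm), , drop = FALSE]
  rownames(out) <- NULL
  structure(list(peaks = out, condition = spec$condition,
                 prominence_min = prominence_min,
                 lambda_band = lambda_band),
            class = "peak_set")
}

#' @export
print.peak_set <- function(x, ...) {
  cat("<peak_set> ", nrow(x$peaks), " peak(s)\n", sep = "")
  if (nrow(x$peaks)) print(x$peaks, digits = 4)
  invisible(x)
}

#' Classify a peak wavelength into a named hue band
#'
#' Fixed presentation bands (nm): blue `[380, 450)`, deep blue `[450, 490)`,
#' green `[490, 560)`, yellow `[560, 590)`, orange `[590, 620)`, red
#' `[620, 740)`, dark/none `[740, 780]`. The band edges are a documented
#' naming convention, not physics.
#'
#' @param lambda_nm peak wavelength(s), nm, in `[380, 780]`.
#' @return character vector of hue names.
#' @export
classify_hue <- function(lambda_nm) {
  if (any(lambda_nm < 380 | lambda_nm > 780))
    stop("hue classification defined for 380-780 nm only")
  cut_pts <- c(380, 450, 490, 560, 590, 620, 740, 780.001)
  names_ <- c("blue", "deep blue", "green", "yellow", "orange", "red",
              "dark/none")
  names_[findInterval(lambda_nm, cut_pts, rightmost.closed = FALSE)]
}

# ---- colorimetry ----------------------------------------------------------

.cie_env <- new.env(parent = emptyenv())

.cie_tables <- function() {
  if (is.null(.cie_env$cmf)) {
    path <- system.file("extdata", "cie1931_cmf_2deg_5nm_approx.csv",
                        package = "iricrest")
    .cie_env$cmf <- utils::read.csv(path, comment.char = "#")
    path <- system.file("extdata", "illuminant_d65_approx.csv",
                        package = "iricrest")
    .cie_env$d65 <- utils::read.csv(path, comment.char = "#")
  }
  list(cmf = .cie_env$cmf, d65 = .cie_env$d65)
}

.trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

#' Render a reflectance spectrum as a CIE color swatch
#'
#' Integrates `R(lambda) * S(lambda)` against the CIE 1931 2-degree color
#' matching functions (trapezoid rule on the spectrum's own grid), normalised
#' so a perfect reflector under the chosen illuminant has `Y = 1`, then maps
#' XYZ to gamma-encoded sRGB. The hue name is taken from the dominant
#' reflection peak via [classify_hue()]; a spectrum with no peak and
#' `max R < darkness_max` over 400-700 nm is named `"dark/none"`.
#'
#' The bundled observer and D65 tables are smooth analytic approximations
#' (documented in `inst/extdata`); illuminant `"E"` is exact.
#'
#' @param spec a [reflectance_spectrum()] covering at least 400-700 nm.
#' @param illuminant `"D65"` (approximate daylight, default) or `"E"`
#'   (equal energy).
#' @param prominence_min,darkness_max hue-naming thresholds (reflectance
#'   units).
#' @return object of class `color_swatch`: `XYZ`, chromaticity `xy`, `sRGB`
#'   in `[0,1]` with `clipped` flag, `hue_name`, `illuminant`.
#' @export
spectrum_to_swatch <- function(spec, illuminant = c("D65", "E"),
                               prominence_min = 0.05, darkness_max = 0.08) {
  illuminant <- match.arg(illuminant)
  stopifnot(inherits(spec, "reflectance_spectrum"))
  if (min(spec$lambda_nm) > 400 + 1e-9 || max(spec$lambda_nm) < 700 - 1e-9)
    stop("swatch rendering needs spectral coverage of at least 400-700 nm")
  tb <- .cie_tables()
  lam <- spec$lambda_nm
  lo <- max(min(lam), 380); hi <- min(max(lam), 780)
  lgrid <- lam[lam >= lo & lam <= hi]
  Rg <- spec$R[lam >= lo & lam <= hi]
  cmf_x <- stats::approx(tb$cmf$lambda_nm, tb$cmf$xbar, lgrid, rule = 2)$y
  cmf_y <- stats::approx(tb$cmf$lambda_nm, tb$cmf$ybar, lgrid, rule = 2)$y
  cmf_z <- stats::approx(tb$cmf$lambda_nm, tb$cmf$zbar, lgrid, rule = 2)$y
  S <- if (illuminant == "E") rep(1, length(lgrid)) else
    stats::approx(tb$d65$lambda_nm, tb$d65$power, lgrid, rule = 2)$y
  norm <- .trapz(lgrid, S * cmf_y)
  XYZ <- c(X = .trapz(lgrid, Rg * S * cmf_x),
           Y = .trapz(lgrid, Rg * S * cmf_y),
           Z = .trapz(lgrid, Rg * S * cmf_z)) / norm
  s <- sum(XYZ)
  xy <- if (s > 0) c(x = unname(XYZ[1] / s), y = unname(XYZ[2] / s))
        else c(x = NA_real_, y = NA_real_)
  # sRGB (D65-referenced) linear transform + gamma
  M <- matrix(c(3.2406, -1.5372, -0.4986,
                -0.9689, 1.8758, 0.0415,
                0.0557, -0.2040, 1.0570), 3, 3, byrow = TRUE)
  lin <- as.numeric(M %*% XYZ)
  clipped <- any(lin < 0 | lin > 1)
  lin <- pmin(pmax(lin, 0), 1)
  srgb <- ifelse(lin <= 0.0031308, 12.92 * lin,
                 1.055 * lin^(1 / 2.4) - 0.055)
  names(srgb) <- c("r", "g", "b")
  # hue naming from the dominant peak
  vis <- lam >= 400 & lam <= 700
  pk <- find_peaks(spec, prominence_min = prominence_min,
                   lambda_band = c(max(min(lam), 400), min(max(lam), 740)))
  hue <- if (nrow(pk$peaks) > 0) {
    classify_hue(pk$peaks$lambda_nm[which.max(pk$peaks$R)])
  } else if (max(spec$R[vis]) < darkness_max) {
    "dark/none"
  } else {
    classify_hue(min(max(lam[vis][which.max(spec$R[vis])], 380), 780))
  }
  structure(list(XYZ = XYZ, xy = xy, sRGB = srgb, clipped = clipped,
                 hue_name = hue, illuminant = illuminant),
            class = "color_swatch")
}

#' @export
print.color_swatch <- function(x, ...) {
  cat(sprintf("<color_swatch> %s  xy=(%.4f, %.4f)  sRGB=#%s%s  [%s]\n",
              x$hue_name, x$xy[1], x$xy[2],
              paste(sprintf("%02X", round(255 * x$sRGB)), collapse = ""),
              if (x$clipped) " (clipped)" else "", x$illuminant))
  invisible(x)
}

#' Angle-dependent reflectance sweep
#'
#' Runs one reflectance spectrum per incidence angle on the default or a
#' supplied structure, extracts peaks, and renders a color swatch. The X-Y
#' incidence plane (perpendicular to the rod axis) is a genuine 2D scattering
#' problem and may use either solver; the Y-Z plane (containing the rod axis)
#' sees a structure that is invariant along the rods at the scale of one rod
#' and is therefore always computed on the reduced 1D multilayer with the
#' transfer matrix, whichever solver is requested.
#'
#' Unless a single polarization is requested, spectra are computed for s and
#' p and averaged (unpolarized illumination) before peak finding; the
#' per-polarization spectra are kept alongside.
#'
#' @param geom a [build_achp_geometry()] result.
#' @param plane `"XY"` or `"YZ"`.
#' @param polarization `"sp"` (average, default), `"s"`, or `"p"`.
#' @param theta_list incidence angles, degrees, each in `[0, 80]`.
#' @param lambda wavelength grid, nm.
#' @param solver `"tmm"` (default) or `"fdtd"`.
#' @param grid a [grid_spec()] for the FDTD path.
#' @param rule mixing rule for the multilayer reduction.
#' @param materials material set.
#' @param prominence_min,darkness_max peak/darkness thresholds.
#' @param illuminant swatch illuminant.
#' @return object of class `angle_sweep`: list with one entry per angle, each
#'   holding `theta_deg`, `spectrum` (the polarization-averaged spectrum),
#'   `by_polarization` (named list of spectra), `peaks`, `swatch`.
#' @export
angle_sweep <- function(geom, plane = c("XY", "YZ"), polarization = "sp",
                        theta_list = c(0, 20, 40, 50, 60, 70),
                        lambda = seq(400, 800, by = 5),
                        solver = c("tmm", "fdtd"), grid = grid_spec(),
                        rule = "volume_average",
                        materials = default_materials(),
                        prominence_min = 0.05, darkness_max = 0.08,
                        illuminant = "D65") {
  plane <- match.arg(plane); solver <- match.arg(solver)
  stopifnot(all(theta_list >= 0 & theta_list <= 80))
  pols <- if (polarization == "sp") c("s", "p") else polarization
  use_tmm <- solver == "tmm" || plane == "YZ"
  stack <- if (use_tmm) reduce_to_multilayer(geom, rule, materials) else NULL
  entries <- lapply(theta_list, function(th) {
    sp_list <- lapply(pols, function(pol) {
      if (use_tmm) {
        tmm_spectrum(stack, th, pol, lambda, plane = plane)
      } else {
        sweep_spectrum(geom, plane = plane, theta_deg = th,
                       polarization = pol, lambda = lambda, grid = grid,
                       materials = materials)
      }
    })
    names(sp_list) <- pols
    Ravg <- Reduce(`+`, lapply(sp_list, `[[`, "R")) / length(sp_list)
    avg <- reflectance_spectrum(lambda, Ravg,
      condition = list(plane = plane, theta_deg = th,
                       polarization = polarization,
                       solver = if (use_tmm) "tmm" else "fdtd"))
    pk <- find_peaks(avg, prominence_min = prominence_min,
                     lambda_band = c(max(min(lambda), 400),
                                     min(max(lambda), 740)))
    sw <- spectrum_to_swatch(avg, illuminant = illuminant,
                             prominence_min = prominence_min,
                             darkness_max = darkness_max)
    list(theta_deg = th, spectrum = avg, by_polarization = sp_list,
         peaks = pk, swatch = sw)
  })
  structure(list(entries = entries, plane = plane, solver = solver,
                 polarization = polarization, lambda = lambda),
            class = "angle_sweep")
}

#' Tabulate an angle sweep
#'
#' One row per angle: strongest peak wavelength and reflectance, hue name and
#' sRGB hex. `NA` peak columns mean no peak exceeded the prominence threshold.
#' @param sweep an [angle_sweep()] result.
#' @return data frame.
#' @export
sweep_report <- function(sweep) {
  stopifnot(inherits(sweep, "angle_sweep"))
  rows <- lapply(sweep$entries, function(e) {
    pk <- e$peaks$peaks
    top <- if (nrow(pk)) pk[which.max(pk$R), ] else
      data.frame(lambda_nm = NA_real_, R = NA_real_,
                 prominence = NA_real_, fwhm_nm = NA_real_)
    data.frame(theta_deg = e$theta_deg, peak_lambda_nm = top$lambda_nm,
               peak_R = top$R, n_peaks = nrow(pk),
               hue = e$swatch$hue_name,
               srgb_hex = paste0("#", paste(sprintf("%02X",
                 round(255 * e$swatch$sRGB)), collapse = "")))
  })
  do.call(rbind, rows)
}

#' @export
print.angle_sweep <- function(x, ...) {
  cat("<angle_sweep> plane", x$plane, "solver", x$solver, "\n")
  print(sweep_report(x), digits = 4)
  invisible(x)
}

#' Export a swatch strip image
#'
#' Writes a PNG strip of the per-angle swatch colors (left to right in sweep
#' order), emulating the usual angle-versus-color inset.
#' @param sweep an [angle_sweep()] result.
#' @param path output PNG path.
#' @param tile_px tile edge length in pixels.
#' @return invisibly, `path`.
#' @export
export_swatch_strip <- function(sweep, path, tile_px = 32) {
  cols <- t(vapply(sweep$entries, function(e) e$swatch$sRGB, numeric(3)))
  img <- array(0, dim = c(tile_px, tile_px * nrow(cols), 3))
  for (i in seq_len(nrow(cols)))
    for (ch in 1:3)
      img[, (i - 1) * tile_px + seq_len(tile_px), ch] <- cols[i, ch]
  png::writePNG(img, path)
  invisible(path)
}
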
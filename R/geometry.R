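#' Melanosome rod geometry
#'
#' Describes one rod-like melanosome by its elliptical cross-section (short
#' axis `x`, major axis `y`, both nm), rod long axis `z` (nm), and the tilt of
#' the cross-section major axis away from the lattice row direction. Positive
#' `tilt_deg` is the "leans leftward" sense seen in cross-sectional electron
#' micrographs of the modelled feather barbs.
#'
#' Defaults are the measured means of the fossil melanosome population:
#' x = 186, y = 283, z = 1774 nm.
#'
#' @param x cross-section short axis, nm.
#' @param y cross-section major axis, nm (`x <= y`).
#' @param z rod long axis, nm (`y <= z`).
#' @param tilt_deg major-axis tilt from the row direction, degrees, |tilt| < 90.
#' @return object of class `melanosome_spec`.
#' @export
melanosome_spec <- function(x = 186, y = 283, z = 1774, tilt_deg = 20) {
  stopifnot(is.numeric(x), is.numeric(y), is.numeric(z), is.numeric(tilt_deg),
            length(x) == 1L, length(y) == 1L, length(z) == 1L)
  if (!(x > 0 && x <= y && y <= z))
    stop("melanosome axes must satisfy 0 < x <= y <= z (got x=", x,
         ", y=", y, ", z=", z, ")")
  if (abs(tilt_deg) >= 90) stop("|tilt_deg| must be < 90")
  structure(list(x = x, y = y, z = z, tilt_deg = tilt_deg),
            class = "melanosome_spec")
}

#' Elliptical cross-section area and outline
#'
#' @param m a [melanosome_spec()].
#' @param n_vertices polygon resolution.
#' @return list with `area` (nm^2, `pi * x/2 * y/2`) and `polygon`
#'   (n x 2 matrix of outline vertices in the tilted lab frame, centre at 0).
#' @export
ellipse_cross_section <- function(m, n_vertices = 256L) {
  stopifnot(inherits(m, "melanosome_spec"))
  t <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  phi <- m$tilt_deg * pi / 180
  # major semi-axis y/2 along the (rotated) row direction, minor x/2 across
  u <- (m$y / 2) * cos(t); v <- (m$x / 2) * sin(t)
  poly <- cbind(u * cos(phi) - v * sin(phi), u * sin(phi) + v * cos(phi))
  colnames(poly) <- c("dx", "dy")
  list(area = pi * (m$x / 2) * (m$y / 2), polygon = poly)
}

# Contact condition for two identical parallel ellipses whose centres differ by
# (ox, oy) in the lab frame, with a surface-to-surface clearance g approximated
# by inflating the Minkowski-sum ellipse (full axes y, x) to (y+g, x+g).
# Returns the quadratic-form value; >= 1 means clear of contact.
.ellipse_clearance_q <- function(ox, oy, m, g) {
  phi <- m$tilt_deg * pi / 180
  u <- ox * cos(phi) + oy * sin(phi)
  v <- -ox * sin(phi) + oy * cos(phi)
  (u / (m$y + g))^2 + (v / (m$x + g))^2
}

# Smallest vertical separation p > 0 at which an ellipse offset laterally by
# `o` clears the reference ellipse by gap g (positive root of the contact
# quadratic); 0 when no contact is possible at any p >= 0.
.contact_pitch_one <- function(o, m, g) {
  phi <- m$tilt_deg * pi / 180
  Y <- m$y + g; X <- m$x + g
  A <- sin(phi)^2 / Y^2 + cos(phi)^2 / X^2
  Bc <- 2 * o * sin(phi) * cos(phi) * (1 / Y^2 - 1 / X^2)
  C <- o^2 * (cos(phi)^2 / Y^2 + sin(phi)^2 / X^2) - 1
  disc <- Bc^2 - 4 * A * C
  if (disc <= 0) return(0)
  p <- (-Bc + sqrt(disc)) / (2 * A)
  max(p, 0)
}

#' ACHP lattice specification
#'
#' Defines the asymmetric compact hexagonal packing of melanosome rods inside
#' a feather barb: tilted elliptical cross-sections in laterally periodic rows,
#' successive rows offset by a shear fraction of the period, the whole array
#' capped by a keratin cortex and resting on a keratin substrate.
#'
#' "Compact" is taken literally: the lateral period and the row pitch are
#' *derived* from the requirement that within-row neighbours and the nearest
#' diagonal neighbours sit at surface-to-surface clearance `gap_g` (contact
#' condition for identical parallel ellipses, with the clearance absorbed into
#' an inflated contact ellipse). `gap_g` is therefore the single free packing
#' parameter; it ships calibrated against the long-wavelength (red) reflection
#' peak at 40 degrees incidence and is never re-tuned elsewhere.
#'
#' `gap_g` may be a vector of length `n_layers` to give each row its own
#' clearance (used by the taphonomic spacing-perturbation analysis); the
#' lateral period then uses the mean clearance while each row pitch uses its
#' own.
#'
#' @param melanosome a [melanosome_spec()].
#' @param gap_g keratin clearance between adjacent melanosome surfaces, nm;
#'   scalar or length-`n_layers` vector. Default is the shipped calibrated
#'   value (see [default_feather_lattice()]).
#' @param shear_s lateral offset fraction between successive rows; 0.5 is the
#'   regular hexagonal lattice, the default 0.35 the asymmetric packing.
#' @param n_layers number of melanosome rows stacked along the illumination
#'   axis.
#' @param cortex_t keratin cortex thickness above the top row, nm.
#' @param substrate_t keratin substrate band thickness below the bottom row, nm.
#' @param substrate substrate material label.
#' @return object of class `lattice_spec` with derived elements `period_nm`
#'   (lateral period) and `pitch_nm` (per-row vertical pitch vector).
#' @export
lattice_spec <- function(melanosome = melanosome_spec(),
                         gap_g = 29, shear_s = 0.35, n_layers = 10,
                         cortex_t = 100, substrate_t = 200,
                         substrate = "keratin") {
  stopifnot(inherits(melanosome, "melanosome_spec"),
            is.numeric(gap_g), all(gap_g >= 0),
            length(gap_g) == 1L || length(gap_g) == n_layers,
            n_layers >= 1, cortex_t >= 0, substrate_t >= 0)
  if (!(shear_s > 0 && shear_s < 1))
    stop("shear_s must lie strictly between 0 and 1")
  m <- melanosome
  phi <- m$tilt_deg * pi / 180
  g_bar <- mean(gap_g)
  period <- 1 / sqrt((cos(phi) / (m$y + g_bar))^2 +
                     (sin(phi) / (m$x + g_bar))^2)
  gaps <- rep(gap_g, length.out = n_layers)
  # pitch between row r-1 and r: clear both diagonal neighbours
  # (lateral offsets s*period and (s-1)*period, plus periodic images)
  pitch_for_gap <- function(g) {
    offs <- c(shear_s, shear_s - 1, shear_s + 1) * period
    max(vapply(offs, .contact_pitch_one, numeric(1), m = m, g = g))
  }
  pitch <- vapply(gaps, pitch_for_gap, numeric(1))
  if (any(pitch <= 0))
    stop("degenerate lattice: contact pitch is not positive")
  # tilted-ellipse bounding-box half-height: rows interpenetrate in compact
  # packing, but the first/last ellipse must stay clear of cortex/substrate
  hh <- 0.5 * sqrt((m$y * sin(phi))^2 + (m$x * cos(phi))^2)
  band <- 2 * hh + (gaps[1] + gaps[n_layers]) / 2 +
    if (n_layers > 1) sum(pitch[-1]) else 0
  height <- cortex_t + band + substrate_t
  if (cortex_t + band > 10000)
    stop("stack height ", round(cortex_t + band),
         " nm exceeds the ~10 um barb thickness bound")
  structure(list(melanosome = m, gap_g = gaps, shear_s = shear_s,
                 n_layers = as.integer(n_layers), cortex_t = cortex_t,
                 substrate_t = substrate_t, substrate = substrate,
                 period_nm = period, pitch_nm = pitch,
                 half_height_nm = hh, band_nm = band,
                 height_nm = height),
            class = "lattice_spec")
}

#' Analytic melanin packing fraction of the melanosome band
#'
#' Ellipse area over unit-cell area (`period * mean pitch`).
#' @param lat a [lattice_spec()].
#' @return dimensionless fraction in (0, 1).
#' @export
packing_fraction <- function(lat) {
  stopifnot(inherits(lat, "lattice_spec"))
  ellipse_cross_section(lat$melanosome)$area /
    (lat$period_nm * mean(lat$pitch_nm))
}

# centre positions (x, y) of all melanosomes, lab frame, x in [0, period)
.lattice_centres <- function(lat) {
  r <- seq_len(lat$n_layers) - 1L
  y1 <- lat$cortex_t + lat$half_height_nm + lat$gap_g[1] / 2
  ytop <- y1 + c(0, cumsum(lat$pitch_nm[-1]))
  xc <- (lat$period_nm / 2 + r * lat$shear_s * lat$period_nm) %% lat$period_nm
  cbind(x = xc, y = ytop)
}

#' Rasterize the ACHP structure
#'
#' Builds the laterally periodic 2D refractive-index label map of one lateral
#' period by full stack height: keratin cortex on top, `n_layers` rows of
#' tilted melanin ellipses in a keratin matrix, keratin substrate below.
#' Material is sampled at cell centres; the lateral cell size is snapped to an
#' integer number of cells per period so the raster (and the FDTD domain built
#' from it) is exactly periodic.
#'
#' @param spec a [lattice_spec()].
#' @param delta target raster cell size, nm; must be at most `x/10` so the
#'   short axis spans at least 10 cells.
#' @return object of class `structure_geometry`: integer matrix `index_map`
#'   (rows = depth from the cortex surface, columns = lateral position; 1 =
#'   keratin, 2 = melanin), cell sizes `dx_nm`, `dy_nm`, `period_nm`,
#'   `height_nm`, band bounds, and the generating `spec`.
#' @export
build_achp_geometry <- function(spec, delta = 5) {
  stopifnot(inherits(spec, "lattice_spec"), is.numeric(delta), delta > 0)
  m <- spec$melanosome
  if (delta > m$x / 10)
    stop("raster cell ", delta, " nm too coarse: need delta <= x/10 = ",
         m$x / 10, " nm")
  period <- spec$period_nm
  nx <- max(4L, as.integer(round(period / delta)))
  dx <- period / nx
  ny <- as.integer(ceiling(spec$height_nm / delta))
  dy <- delta
  centres <- .lattice_centres(spec)
  phi <- m$tilt_deg * pi / 180
  a <- m$y / 2; b <- m$x / 2
  xg <- (seq_len(nx) - 0.5) * dx
  yg <- (seq_len(ny) - 0.5) * dy
  map <- matrix(1L, nrow = ny, ncol = nx)
  for (r in seq_len(nrow(centres))) {
    cx <- centres[r, 1]; cy <- centres[r, 2]
    jj <- which(abs(yg - cy) <= a + dy)       # rows that can intersect
    if (!length(jj)) next
    for (im in c(-1, 0, 1)) {                 # periodic images
      ox <- xg - (cx + im * period)
      ii <- which(abs(ox) <= a + dx)
      if (!length(ii)) next
      oy <- yg[jj] - cy
      u <- outer(oy, ox[ii], function(Y, X) X * cos(phi) + Y * sin(phi))
      v <- outer(oy, ox[ii], function(Y, X) -X * sin(phi) + Y * cos(phi))
      inside <- (u / a)^2 + (v / b)^2 <= 1
      sub <- map[jj, ii, drop = FALSE]
      sub[inside] <- 2L
      map[jj, ii] <- sub
    }
  }
  band_top <- spec$cortex_t
  band_bot <- spec$cortex_t + spec$band_nm
  structure(list(index_map = map, legend = c("keratin", "melanin"),
                 dx_nm = dx, dy_nm = dy,
                 period_nm = period, height_nm = ny * dy,
                 band_nm = c(top = band_top, bottom = band_bot),
                 spec = spec, incidence = "medium", exit = spec$substrate),
            class = "structure_geometry")
}

#' Raster melanin area fraction of the melanosome band
#' @param geom a [build_achp_geometry()] result.
#' @return pixel-counted melanin fraction between the cortex and substrate.
#' @export
raster_melanin_fraction <- function(geom) {
  stopifnot(inherits(geom, "structure_geometry"))
  yg <- (seq_len(nrow(geom$index_map)) - 0.5) * geom$dy_nm
  jj <- yg > geom$band_nm["top"] & yg < geom$band_nm["bottom"]
  mean(geom$index_map[jj, , drop = FALSE] == 2L)
}

#' Reduce a 2D structure to an effective 1D multilayer
#'
#' Slices the raster into horizontal sub-layers one raster row thick, assigns
#' each its melanin fill fraction, and merges adjacent sub-layers of equal
#' fraction. The result is the 1D multilayer equivalent of the lattice used by
#' the transfer-matrix solver; the per-layer complex index is formed at
#' evaluation time from the fill fraction by the chosen mixing rule
#' (index-weighted `volume_average`, default, or `maxwell_garnett` on the
#' dielectric function with melanin inclusions).
#'
#' @param geom a [build_achp_geometry()] result.
#' @param rule `"volume_average"` or `"maxwell_garnett"`.
#' @param materials material set, see [default_materials()].
#' @return a [layer_stack()].
#' @export
reduce_to_multilayer <- function(geom, rule = c("volume_average", "maxwell_garnett"),
                                 materials = default_materials()) {
  stopifnot(inherits(geom, "structure_geometry"))
  rule <- match.arg(rule)
  f <- rowMeans(geom$index_map == 2L)
  d <- rep(geom$dy_nm, length(f))
  # merge runs of equal fraction
  runs <- rle(f)
  thick <- runs$lengths * geom$dy_nm
  layer_stack(thickness_nm = thick, fraction_melanin = runs$values,
              rule = rule, materials = materials,
              incidence = "medium", exit = geom$spec$substrate,
              provenance = list(period_nm = geom$period_nm,
                                dy_nm = geom$dy_nm))
}

#' Construct a 1D layer stack
#'
#' The solver-facing description of a multilayer: ordered layer thicknesses
#' (top first) with per-layer melanin fill fractions, the mixing rule that
#' turns fractions into effective indices, and semi-infinite incidence and
#' exit media.
#'
#' @param thickness_nm positive layer thicknesses, nm, top first.
#' @param fraction_melanin melanin fill fraction per layer in `[0, 1]`
#'   (0 = pure keratin, 1 = pure melanin). Mutually exclusive with `material`.
#' @param material alternatively, a character vector naming the material of
#'   each layer directly (labels into `materials`), bypassing the mixing rule.
#' @param rule effective-index mixing rule.
#' @param materials material set.
#' @param incidence,exit labels into `materials` for the semi-infinite media.
#' @param provenance free-form metadata list.
#' @return object of class `layer_stack`.
#' @export
layer_stack <- function(thickness_nm, fraction_melanin = NULL,
                        material = NULL, rule = "volume_average",
                        materials = default_materials(),
                        incidence = "medium", exit = "keratin",
                        provenance = list()) {
  stopifnot(is.numeric(thickness_nm), all(thickness_nm > 0),
            incidence %in% names(materials), exit %in% names(materials))
  if (is.null(fraction_melanin) == is.null(material))
    stop("give exactly one of fraction_melanin or material")
  if (!is.null(fraction_melanin)) {
    stopifnot(length(thickness_nm) == length(fraction_melanin),
              all(fraction_melanin >= 0 & fraction_melanin <= 1))
    fraction_melanin <- as.numeric(fraction_melanin)
  } else {
    stopifnot(length(thickness_nm) == length(material),
              all(material %in% names(materials)))
  }
  structure(list(thickness_nm = as.numeric(thickness_nm),
                 fraction_melanin = fraction_melanin, material = material,
                 rule = rule, materials = materials,
                 incidence = incidence, exit = exit,
                 provenance = provenance),
            class = "layer_stack")
}

#' Effective complex indices of a layer stack
#'
#' @param stack a [layer_stack()].
#' @param lambda wavelengths, nm.
#' @return complex matrix, one row per layer, one column per wavelength.
#' @export
effective_index <- function(stack, lambda) {
  stopifnot(inherits(stack, "layer_stack"))
  if (!is.null(stack$material)) {
    rows <- lapply(stack$material,
                   function(nm) evaluate_index(stack$materials[[nm]], lambda))
    return(do.call(rbind, rows))
  }
  n_mel <- evaluate_index(stack$materials$melanin, lambda)
  n_ker <- evaluate_index(stack$materials$keratin, lambda)
  f <- stack$fraction_melanin
  if (stack$rule == "volume_average") {
    outer(f, n_mel) + outer(1 - f, n_ker)
  } else {  # maxwell_garnett: melanin inclusions in a keratin host
    em <- matrix(n_mel^2, nrow = length(f), ncol = length(lambda), byrow = TRUE)
    ek <- matrix(n_ker^2, nrow = length(f), ncol = length(lambda), byrow = TRUE)
    fm <- matrix(f, nrow = length(f), ncol = length(lambda))
    ee <- ek * (em + 2 * ek + 2 * fm * (em - ek)) /
               (em + 2 * ek - fm * (em - ek))
    sqrt(ee)
  }
}

#' @export
print.lattice_spec <- function(x, ...) {
  m <- x$melanosome
  cat("<lattice_spec> ACHP, ", x$n_layers, " rows\n", sep = "")
  cat(sprintf("  melanosome x=%g y=%g z=%g nm, tilt=%g deg\n",
              m$x, m$y, m$z, m$tilt_deg))
  cat(sprintf("  gap=%s nm, shear=%g  ->  period=%.1f nm, pitch=%.1f nm\n",
              paste(signif(unique(x$gap_g), 4), collapse = "/"), x$shear_s,
              x$period_nm, mean(x$pitch_nm)))
  cat(sprintf("  cortex %g nm, substrate %g nm (%s); total %.0f nm\n",
              x$cortex_t, x$substrate_t, x$substrate, x$height_nm))
  invisible(x)
}

#' @export
print.structure_geometry <- function(x, ...) {
  cat(sprintf("<structure_geometry> %d x %d cells (%.2f x %.2f nm), period %.1f nm, height %.0f nm\n",
              nrow(x$index_map), ncol(x$index_map), x$dy_nm, x$dx_nm,
              x$period_nm, x$height_nm))
  invisible(x)
}

#' Export a structure geometry as PNG + JSON sidecar
#'
#' Writes a grayscale label image (melanin dark) and a JSON file with the
#' lattice parameters needed to rebuild it.
#' @param geom a `structure_geometry`.
#' @param path_png,path_json output paths.
#' @return invisibly, the two paths.
#' @export
export_geometry <- function(geom, path_png, path_json) {
  stopifnot(inherits(geom, "structure_geometry"))
  img <- 1 - 0.8 * (geom$index_map == 2L)
  png::writePNG(img, path_png)
  sp <- geom$spec
  meta <- list(period_nm = geom$period_nm, height_nm = geom$height_nm,
               dx_nm = geom$dx_nm, dy_nm = geom$dy_nm,
               lattice = list(x = sp$melanosome$x, y = sp$melanosome$y,
                              z = sp$melanosome$z,
                              tilt_deg = sp$melanosome$tilt_deg,
                              gap_g = sp$gap_g, shear_s = sp$shear_s,
                              n_layers = sp$n_layers, cortex_t = sp$cortex_t,
                              substrate_t = sp$substrate_t))
  jsonlite::write_json(meta, path_json, auto_unbox = TRUE, digits = NA)
  invisible(c(path_png, path_json))
}

#' Export a layer stack as CSV
#' @param stack a [layer_stack()].
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
export_layer_stack <- function(stack, path) {
  df <- data.frame(thickness_nm = stack$thickness_nm,
                   fraction_melanin = stack$fraction_melanin)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
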
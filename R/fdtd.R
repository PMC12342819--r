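#' FDTD grid and run settings
#'
#' Numerical settings of the 2D finite-difference time-domain solver. The
#' stability ("Courant") setting is expressed as a fraction of the exact 2D
#' limit `1 / (c sqrt(1/dx^2 + 1/dy^2))`. The solver drives a single-frequency
#' plane wave, ramped on smoothly, and integrates until the demodulated
#' monitor phasors change by less than `convergence_tol` between successive
#' optical periods (or `max_periods` is reached, in which case the result is
#' flagged unconverged).
#'
#' @param delta cell size, nm (both directions; the lateral size is snapped to
#'   the structure period).
#' @param courant fraction of the 2D stability limit, in (0, 1).
#' @param pml_cells CPML thickness in cells on each stacking-direction
#'   boundary, at least 8.
#' @param max_periods time budget in optical periods.
#' @param convergence_tol steady-state relative phasor tolerance.
#' @param ramp_periods source turn-on ramp length, periods.
#' @param min_periods minimum settle time after the ramp before the
#'   convergence test may stop the run.
#' @return object of class `grid_spec`.
#' @export
grid_spec <- function(delta = 5, courant = 0.95, pml_cells = 12,
                      max_periods = 400, convergence_tol = 1e-3,
                      ramp_periods = 10, min_periods = 10) {
  if (!(courant > 0 && courant < 1))
    stop("courant must be a fraction of the stability limit in (0, 1)")
  if (pml_cells < 8) stop("pml_cells must be >= 8")
  structure(list(delta = delta, courant = courant, pml_cells = pml_cells,
                 max_periods = max_periods,
                 convergence_tol = convergence_tol,
                 ramp_periods = ramp_periods, min_periods = min_periods),
            class = "grid_spec")
}

#' Incidence condition
#'
#' One (plane, angle, polarization, wavelength) illumination condition.
#' s-polarized light has its electric field perpendicular to the plane of
#' incidence, p-polarized parallel to it. In the X-Y incidence plane
#' (perpendicular to the rod axis) s maps to the TE (out-of-plane E) 2D
#' problem and p to TM. Negative angles mean incidence mirrored about the
#' stack normal and are accepted for reciprocity checks.
#'
#' @param plane `"XY"` or `"YZ"`.
#' @param theta_deg incidence angle from the stack normal, degrees,
#'   `|theta| < 90`.
#' @param polarization `"s"` or `"p"`.
#' @param lambda wavelength, nm (visible band plus margins).
#' @return object of class `incidence_spec`.
#' @export
incidence_spec <- function(plane = c("XY", "YZ"), theta_deg, polarization = c("s", "p"),
                           lambda) {
  plane <- match.arg(plane)
  polarization <- match.arg(polarization)
  if (!(abs(theta_deg) < 90)) stop("|theta_deg| must be < 90")
  if (!(lambda >= 250 && lambda <= 1500))
    stop("wavelength ", lambda, " nm outside the supported 250-1500 nm band")
  structure(list(plane = plane, theta_deg = theta_deg,
                 polarization = polarization, lambda = lambda),
            class = "incidence_spec")
}

#' Homogeneous-slab test geometry
#'
#' Builds a laterally uniform `structure_geometry` from a list of horizontal
#' layers — the shape of input for which the transfer matrix is exact, used to
#' cross-validate the FDTD solver.
#'
#' @param material character vector of material labels, top layer first.
#' @param thickness_nm layer thicknesses, nm.
#' @param period_nm nominal lateral period (arbitrary for uniform layers).
#' @param delta cell size, nm.
#' @param incidence,exit labels of the semi-infinite media.
#' @return a `structure_geometry`.
#' @export
slab_geometry <- function(material, thickness_nm, period_nm = 100, delta = 5,
                          incidence = "medium", exit = "medium") {
  stopifnot(length(material) == length(thickness_nm), all(thickness_nm > 0))
  legend <- unique(c(material, exit))
  nx <- max(4L, as.integer(round(period_nm / delta)))
  rows_per <- pmax(1L, as.integer(round(thickness_nm / delta)))
  codes <- rep(match(material, legend), rows_per)
  map <- matrix(rep(codes, each = nx), nrow = length(codes), ncol = nx,
                byrow = TRUE)
  structure(list(index_map = map, legend = legend,
                 dx_nm = period_nm / nx, dy_nm = delta,
                 period_nm = period_nm, height_nm = length(codes) * delta,
                 band_nm = c(top = 0, bottom = length(codes) * delta),
                 spec = NULL, incidence = incidence, exit = exit),
            class = "structure_geometry")
}

# material label -> (epsr, sigma) maps at one wavelength
.material_eps_sigma <- function(name, lambda, materials) {
  if (!name %in% names(materials))
    stop("material '", name, "' not found in the material set")
  nc <- evaluate_index(materials[[name]], lambda)
  omega <- 2 * pi / lambda
  list(epsr = Re(nc)^2 - Im(nc)^2, sigma = omega * 2 * Re(nc) * Im(nc))
}

.geometry_media <- function(geom) {
  list(incidence = geom$incidence %||% "medium",
       exit = geom$exit %||% (geom$spec$substrate %||% "keratin"))
}

# Assemble the full simulation domain (air above, substrate below, PML pads)
# for one wavelength. Returns eps/sigma matrices plus 0-based special rows.
.build_fdtd_domain <- function(geom, lambda, grid, materials) {
  med <- .geometry_media(geom)
  nx <- ncol(geom$index_map)
  npml <- grid$pml_cells
  gapA <- 8L; gapB <- 10L; gapC <- 30L; gapD <- 30L; gapE <- 8L
  ny_g <- nrow(geom$index_map)
  ny <- 2L * npml + gapA + 1L + gapB + 1L + gapC + ny_g + gapD + 1L + gapE
  j_monR <- npml + gapA                      # 0-based rows for the kernel
  j_src <- j_monR + 1L + gapB
  js0 <- j_src + 1L + gapC
  j_monT <- js0 + ny_g + gapD
  epsr <- matrix(NA_real_, ny, nx); sigma <- matrix(NA_real_, ny, nx)
  m_in <- .material_eps_sigma(med$incidence, lambda, materials)
  m_out <- .material_eps_sigma(med$exit, lambda, materials)
  epsr[1:js0, ] <- m_in$epsr; sigma[1:js0, ] <- m_in$sigma
  lower <- (js0 + ny_g + 1L):ny
  epsr[lower, ] <- m_out$epsr; sigma[lower, ] <- m_out$sigma
  for (k in seq_along(geom$legend)) {
    cells <- geom$index_map == k
    if (!any(cells)) next
    mk <- .material_eps_sigma(geom$legend[k], lambda, materials)
    block_e <- epsr[(js0 + 1L):(js0 + ny_g), , drop = FALSE]
    block_s <- sigma[(js0 + 1L):(js0 + ny_g), , drop = FALSE]
    block_e[cells] <- mk$epsr; block_s[cells] <- mk$sigma
    epsr[(js0 + 1L):(js0 + ny_g), ] <- block_e
    sigma[(js0 + 1L):(js0 + ny_g), ] <- block_s
  }
  list(epsr = epsr, sigma = sigma, nx = nx, ny = ny,
       j_monR = j_monR, j_src = j_src, j_monT = j_monT,
       n_inc = sqrt(m_in$epsr))
}

.fdtd_ref_cache <- new.env(parent = emptyenv())

#' Clear the FDTD reference-run cache
#' @return invisibly, the number of entries removed.
#' @export
clear_fdtd_cache <- function() {
  n <- length(ls(.fdtd_ref_cache))
  rm(list = ls(.fdtd_ref_cache), envir = .fdtd_ref_cache)
  invisible(n)
}

.monitor_flux <- function(E, H, polarization, dx) {
  s <- 0.5 * sum(Re(E * Conj(H))) * dx
  if (polarization == "s") s else -s   # S_y = +Re(Ez Hx*)/2 | -Re(Ex Hz*)/2
}

#' Run one FDTD reflectance calculation
#'
#' Computes reflectance, transmittance and absorptance of a laterally
#' periodic structure for one continuous-wave oblique-incidence condition.
#' Bloch-periodic lateral boundaries carry the phase `exp(i kx period)` with
#' `kx = (2 pi / lambda) n_inc sin(theta)`; CPML terminates the stack
#' direction; the material index is frozen at the run wavelength (absorption
#' as electric conductivity). Fluxes are time-averaged Poynting fluxes
#' through monitor rows; the reflected flux is isolated by subtracting the
#' fields of an identical empty-domain (incidence-medium) reference run,
#' which also provides the incident-flux normalisation. Reference runs are
#' cached per condition within a session.
#'
#' Only the X-Y incidence plane is a 2D scattering problem; requests for the
#' Y-Z plane are refused here and served by the transfer-matrix reduction
#' (see [angle_sweep()]).
#'
#' @param geom a [build_achp_geometry()] or [slab_geometry()] result whose
#'   raster cell sizes set the grid.
#' @param inc an [incidence_spec()].
#' @param grid a [grid_spec()].
#' @param materials material set resolving every label used by `geom`.
#' @return object of class `flux_result`: `R`, `T`, `A`, `converged`,
#'   `periods`, plus the condition and grid.
#' @export
run_fdtd <- function(geom, inc, grid = grid_spec(),
                     materials = default_materials()) {
  stopifnot(inherits(geom, "structure_geometry"),
            inherits(inc, "incidence_spec"), inherits(grid, "grid_spec"))
  if (inc$plane != "XY")
    stop("run_fdtd solves the X-Y incidence plane; the Y-Z plane is served ",
         "by the transfer-matrix reduction (see angle_sweep)")
  lambda <- inc$lambda
  # resolution guard: >= 20 cells per wavelength in the densest material
  n_max <- max(vapply(materials, function(m) {
    rng <- m$lambda_range
    l <- min(max(lambda, rng[1]), rng[2])
    Re(evaluate_index(m, l))
  }, numeric(1)))
  if (max(geom$dx_nm, geom$dy_nm) > lambda / (20 * n_max))
    stop("grid too coarse at lambda = ", lambda, " nm: need delta <= ",
         signif(lambda / (20 * n_max), 3), " nm")
  dom <- .build_fdtd_domain(geom, lambda, grid, materials)
  dx <- geom$dx_nm; dy <- geom$dy_nm
  dt <- grid$courant / sqrt(1 / dx^2 + 1 / dy^2)
  omega <- 2 * pi / lambda
  kx <- omega * dom$n_inc * sin(inc$theta_deg * pi / 180)
  pol <- if (inc$polarization == "s") 0L else 1L
  key <- paste(signif(lambda, 10), signif(inc$theta_deg, 10), pol,
               dom$nx, signif(dx, 10), signif(dy, 10),
               signif(dom$n_inc, 10), grid$pml_cells, signif(dt, 10),
               sep = "|")
  # steep incidence needs a longer turn-on: spectral leakage of the ramp at
  # the grazing frequency kx*c scales with 1/((1 - sin theta) * ramp length)
  ramp <- max(grid$ramp_periods,
              ceiling(3.6 / (1 - abs(sin(inc$theta_deg * pi / 180)))))
  ref <- .fdtd_ref_cache[[key]]
  if (is.null(ref)) {
    # the reference (empty incidence medium) is run in a truncated domain:
    # the field above/at the source and the plane-wave flux are independent
    # of the domain height, so the rows below the source can be cut short
    npml <- grid$pml_cells
    ny_ref <- dom$j_src + 1L + 20L + 1L + 8L + npml
    j_monT_ref <- dom$j_src + 1L + 20L
    eps0 <- matrix(dom$epsr[1, 1], ny_ref, dom$nx)
    sig0 <- matrix(dom$sigma[1, 1], ny_ref, dom$nx)
    ref <- fdtd_run_kernel(eps0, sig0, dx, dy, dt, kx, omega, pol,
                           npml, dom$j_src, dom$j_monR, j_monT_ref,
                           ramp, grid$min_periods,
                           grid$max_periods, grid$convergence_tol)
    .fdtd_ref_cache[[key]] <- ref
  }
  out <- fdtd_run_kernel(dom$epsr, dom$sigma, dx, dy, dt, kx, omega, pol,
                         grid$pml_cells, dom$j_src, dom$j_monR, dom$j_monT,
                         ramp, grid$min_periods,
                         grid$max_periods, grid$convergence_tol)
  p_inc <- .monitor_flux(ref$E_T, ref$H_T, inc$polarization, dx)
  p_refl <- .monitor_flux(out$E_R - ref$E_R, out$H_R - ref$H_R,
                          inc$polarization, dx)
  p_trans <- .monitor_flux(out$E_T, out$H_T, inc$polarization, dx)
  R <- max(0, -p_refl / p_inc)
  T <- max(0, p_trans / p_inc)
  converged <- isTRUE(out$converged) && isTRUE(ref$converged)
  if (!converged)
    warning("FDTD run at lambda = ", lambda, " nm, theta = ", inc$theta_deg,
            " deg did not reach steady state within ", grid$max_periods,
            " periods (relative change ", signif(out$relchange, 2), ")")
  structure(list(R = R, T = T, A = 1 - R - T, condition = inc, grid = grid,
                 converged = converged, periods = out$periods),
            class = "flux_result")
}

#' FDTD reflectance spectrum
#'
#' One [run_fdtd()] call per wavelength under a fixed (plane, angle,
#' polarization) condition. Fails if more than 10% of the points did not
#' converge; individual unconverged points are flagged in the result.
#'
#' @param geom structure geometry.
#' @param plane incidence plane (must be `"XY"`).
#' @param theta_deg incidence angle, degrees.
#' @param polarization `"s"` or `"p"`.
#' @param lambda sorted wavelength grid, nm (>= 15 points for peak finding).
#' @param grid a [grid_spec()].
#' @param materials material set.
#' @return a [reflectance_spectrum()] with solver tag `"fdtd"`.
#' @export
sweep_spectrum <- function(geom, plane = "XY", theta_deg, polarization = "s",
                           lambda = seq(400, 800, by = 5),
                           grid = grid_spec(),
                           materials = default_materials()) {
  stopifnot(length(lambda) >= 15, !is.unsorted(lambda, strictly = TRUE))
  res <- lapply(lambda, function(l) {
    run_fdtd(geom, incidence_spec(plane, theta_deg, polarization, l),
             grid, materials)
  })
  R <- vapply(res, `[[`, numeric(1), "R")
  T <- vapply(res, `[[`, numeric(1), "T")
  conv <- vapply(res, `[[`, logical(1), "converged")
  if (mean(!conv) > 0.10)
    stop("FDTD sweep failed: ", sum(!conv), "/", length(conv),
         " wavelengths unconverged")
  reflectance_spectrum(lambda, R, T = T, converged = conv,
                       condition = list(plane = plane, theta_deg = theta_deg,
                                        polarization = polarization,
                                        solver = "fdtd"),
                       metadata = list(grid = unclass(grid)))
}

#' @export
print.flux_result <- function(x, ...) {
  cn <- x$condition
  cat(sprintf("<flux_result> lambda=%g nm theta=%g deg %s-pol: R=%.4f T=%.4f A=%.4f (%s, %d periods)\n",
              cn$lambda, cn$theta_deg, cn$polarization, x$R, x$T, x$A,
              if (x$converged) "converged" else "UNCONVERGED", x$periods))
  invisible(x)
}
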
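#' Transfer-matrix reflectance and transmittance of a 1D multilayer
#'
#' Exact plane-wave solution for a stack of homogeneous (possibly absorbing)
#' layers between semi-infinite incidence and exit media, by the standard
#' 2x2 characteristic-matrix product. Conventions: time dependence
#' `exp(-i w t)`; tilted admittances `eta_s = n cos(theta)` and
#' `eta_p = n / cos(theta)`; complex internal angles from Snell's law with the
#' principal square root of `1 - (n0 sin(theta0)/n)^2`, which handles
#' absorbing layers without branch errors.
#'
#' @param stack a [layer_stack()].
#' @param theta_deg incidence angle in the incidence medium, degrees,
#'   `0 <= theta < 90`.
#' @param polarization `"s"` (E perpendicular to the plane of incidence) or
#'   `"p"` (E parallel).
#' @param lambda wavelengths, nm.
#' @return `tmm_reflectance`: numeric vector of reflectance fractions `R`.
#'   `tmm_rt`: list with elements `R` and `T` (transmittance into the exit
#'   medium); `A = 1 - R - T` is the absorptance.
#' @export
tmm_reflectance <- function(stack, theta_deg, polarization = c("s", "p"),
                            lambda) {
  tmm_rt(stack, theta_deg, polarization, lambda)$R
}

#' @rdname tmm_reflectance
#' @export
tmm_rt <- function(stack, theta_deg, polarization = c("s", "p"), lambda) {
  polarization <- match.arg(polarization)
  stopifnot(inherits(stack, "layer_stack"), is.numeric(lambda))
  if (!(theta_deg >= 0 && theta_deg < 90))
    stop("incidence angle must satisfy 0 <= theta < 90 degrees")
  n0 <- evaluate_index(stack$materials[[stack$incidence]], lambda)
  nS <- evaluate_index(stack$materials[[stack$exit]], lambda)
  nl <- length(stack$thickness_nm)
  nmat <- if (nl > 0) effective_index(stack, lambda) else
    matrix(complex(0), 0, length(lambda))
  .tmm_core(n0, nS, nmat, stack$thickness_nm, theta_deg, polarization, lambda)
}

# Vectorized-over-lambda characteristic-matrix product.
# n0, nS: complex vectors over lambda; nmat: layers x lambda complex matrix.
.tmm_core <- function(n0, nS, nmat, d, theta_deg, polarization, lambda) {
  th0 <- theta_deg * pi / 180
  sin0 <- n0 * sin(th0)                     # conserved n*sin(theta)
  cos_of <- function(n) sqrt(1 - (sin0 / n)^2)
  eta_of <- function(n, cth)
    if (polarization == "s") n * cth else n / cth
  c0 <- cos_of(n0); cS <- cos_of(nS)
  eta0 <- eta_of(n0, c0); etaS <- eta_of(nS, cS)
  B <- rep(1 + 0i, length(lambda)); C <- etaS
  if (length(d) > 0) {
    for (j in rev(seq_along(d))) {          # multiply from exit side up
      nj <- nmat[j, ]
      cj <- cos_of(nj)
      etaj <- eta_of(nj, cj)
      delta <- 2 * pi * nj * cj * d[j] / lambda
      cd <- cos(delta); sd <- sin(delta)
      # e^{-i w t} convention: M = [[cos d, -i sin d / eta], [-i eta sin d, cos d]]
      B2 <- cd * B - 1i * sd / etaj * C
      C2 <- -1i * etaj * sd * B + cd * C
      B <- B2; C <- C2
    }
  }
  r <- (eta0 * B - C) / (eta0 * B + C)
  R <- pmin(Mod(r)^2, 1)
  T <- 4 * Re(eta0) * Re(etaS) / Mod(eta0 * B + C)^2
  list(R = as.numeric(R), T = as.numeric(T), r = r)
}

#' Reflectance spectrum of a layer stack
#'
#' Convenience wrapper returning a `reflectance_spectrum` object (the same
#' container the FDTD sweep produces, with solver tag `"tmm"`).
#'
#' @inheritParams tmm_reflectance
#' @param plane incidence-plane label carried in the condition metadata.
#' @return a [reflectance_spectrum()].
#' @export
tmm_spectrum <- function(stack, theta_deg, polarization = c("s", "p"),
                         lambda, plane = "XY") {
  polarization <- match.arg(polarization)
  rt <- tmm_rt(stack, theta_deg, polarization, lambda)
  reflectance_spectrum(lambda, rt$R, T = rt$T,
                       condition = list(plane = plane, theta_deg = theta_deg,
                                        polarization = polarization,
                                        solver = "tmm"))
}

#' First-order Bragg peak estimate for a periodic bilayer
#'
#' Closed-form constructive-interference condition
#' `lambda = 2 (n1 d1 cos(t1') + n2 d2 cos(t2'))` with internal angles from
#' Snell's law, used for calibration sanity checks only — the transfer matrix
#' is the quantitative solver.
#'
#' @param d1,d2 layer thicknesses, nm.
#' @param n1,n2 real layer indices at the wavelength of interest.
#' @param theta_deg incidence angle in the incidence medium, degrees.
#' @param n_inc incidence-medium index (default air).
#' @return first-order peak wavelength, nm.
#' @export
bragg_peak_estimate <- function(d1, n1, d2, n2, theta_deg, n_inc = 1) {
  s0 <- n_inc * sin(theta_deg * pi / 180)
  c1 <- sqrt(1 - (s0 / n1)^2)
  c2 <- sqrt(1 - (s0 / n2)^2)
  2 * (n1 * d1 * c1 + n2 * d2 * c2)
}
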
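#' Wavelength-dependent complex refractive index models
#'
#' A `material_dispersion` object holds the complex refractive index
#' \eqn{n(\lambda) + i k(\lambda)} of one optical material over a stated
#' wavelength validity range. Four models are supported:
#'
#' * `"constant"` — fixed `n`, `k` at every wavelength;
#' * `"cauchy_real"` — normal-dispersion Cauchy law \eqn{n(\lambda) = A + B/\lambda^2}
#'   with `k = 0`;
#' * `"cauchy_plus_exp_absorption"` — the Cauchy law for `n` plus a broadband
#'   absorption tail \eqn{k(\lambda) = a \exp(-\lambda/b)}, the usual description
#'   of eumelanin in feather optics;
#' * `"tabulated"` — linear interpolation of a measured \eqn{(\lambda, n, k)} table.
#'
#' Wavelengths are in nanometres throughout; `B` carries units of nm^2 and the
#' absorption decay constant `b` units of nm.
#'
#' @param name material label used in error messages and output metadata.
#' @param model one of `"constant"`, `"cauchy_real"`,
#'   `"cauchy_plus_exp_absorption"`, `"tabulated"`.
#' @param coefficients named numeric vector of model parameters: `n`, `k` for
#'   the constant model; `A`, `B` for the Cauchy models, plus `k_a`, `k_b` for
#'   the absorbing variant.
#' @param lambda_range length-2 numeric, wavelength validity interval in nm.
#' @param table data frame with columns `lambda_nm`, `n`, `k` (tabulated model
#'   only), `lambda_nm` strictly increasing.
#' @return An object of class `material_dispersion`.
#' @seealso [evaluate_index()], [load_dispersion_table()], [melanin_default()],
#'   [keratin_default()], [medium_default()]
#' @export
material_dispersion <- function(name, model, coefficients = NULL,
                                lambda_range = c(300, 1200), table = NULL) {
  model <- match.arg(model, c("constant", "cauchy_real",
                              "cauchy_plus_exp_absorption", "tabulated"))
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(lambda_range), length(lambda_range) == 2L,
            lambda_range[1] < lambda_range[2])
  if (model == "tabulated") {
    if (is.null(table))
      stop("tabulated dispersion for '", name, "' requires a table")
    if (!all(c("lambda_nm", "n", "k") %in% names(table)))
      stop("dispersion table needs columns lambda_nm, n, k")
    if (any(diff(table$lambda_nm) <= 0))
      stop("dispersion table for '", name, "': lambda_nm must be strictly increasing")
    if (any(table$k < 0))
      stop("dispersion table for '", name, "': k must be >= 0 (passive media)")
    lambda_range <- range(table$lambda_nm)
  } else {
    needed <- switch(model,
      constant = c("n", "k"),
      cauchy_real = c("A", "B"),
      cauchy_plus_exp_absorption = c("A", "B", "k_a", "k_b"))
    if (!all(needed %in% names(coefficients)))
      stop("model '", model, "' needs coefficients: ",
           paste(needed, collapse = ", "))
  }
  structure(list(name = name, model = model,
                 coefficients = coefficients,
                 lambda_range = as.numeric(lambda_range),
                 table = table),
            class = "material_dispersion")
}

#' Evaluate a complex refractive index
#'
#' Returns \eqn{n(\lambda) + i k(\lambda)} for one material at the requested
#' wavelengths. Evaluation outside the material's validity range is an error,
#' not an extrapolation.
#'
#' @param material a [material_dispersion()] object.
#' @param lambda numeric vector of wavelengths in nm.
#' @return complex vector, same length as `lambda`.
#' @examples
#' evaluate_index(keratin_default(), 500)  # 1.532 + 5890/500^2
#' @export
evaluate_index <- function(material, lambda) {
  stopifnot(inherits(material, "material_dispersion"), is.numeric(lambda))
  rng <- material$lambda_range
  if (any(lambda < rng[1] | lambda > rng[2]))
    stop("wavelength outside validity range [", rng[1], ", ", rng[2],
         "] nm of material '", material$name, "'")
  cf <- material$coefficients
  switch(material$model,
    constant = complex(real = rep(cf[["n"]], length(lambda)),
                       imaginary = rep(cf[["k"]], length(lambda))),
    cauchy_real = complex(real = cf[["A"]] + cf[["B"]] / lambda^2,
                          imaginary = rep(0, length(lambda))),
    cauchy_plus_exp_absorption = complex(
      real = cf[["A"]] + cf[["B"]] / lambda^2,
      imaginary = cf[["k_a"]] * exp(-lambda / cf[["k_b"]])),
    tabulated = {
      tb <- material$table
      nr <- stats::approx(tb$lambda_nm, tb$n, xout = lambda)$y
      ki <- stats::approx(tb$lambda_nm, tb$k, xout = lambda)$y
      complex(real = nr, imaginary = ki)
    })
}

#' Default keratin dispersion
#'
#' Cauchy model `n = 1.532 + 5890/lambda^2` (lambda in nm), non-absorbing —
#' the coefficients in routine use for feather beta-keratin. Override through
#' the `materials.keratin` config block when better data are available.
#' @param A,B Cauchy coefficients (B in nm^2).
#' @return a `material_dispersion`.
#' @export
keratin_default <- function(A = 1.532, B = 5890) {
  material_dispersion("keratin", "cauchy_real", c(A = A, B = B))
}

#' Default eumelanin dispersion
#'
#' Cauchy real part `n = 1.648 + 23700/lambda^2` with a broadband absorption
#' tail `k = 0.56 * exp(-lambda/270)` (lambda in nm), the literature-standard
#' description of eumelanin in structural-color modelling. All four numbers are
#' config-overridable and echoed into run metadata.
#' @param A,B Cauchy coefficients (B in nm^2).
#' @param k_a,k_b absorption amplitude and decay constant (nm).
#' @return a `material_dispersion`.
#' @export
melanin_default <- function(A = 1.648, B = 23700, k_a = 0.56, k_b = 270) {
  material_dispersion("melanin", "cauchy_plus_exp_absorption",
                      c(A = A, B = B, k_a = k_a, k_b = k_b))
}

#' Default ambient medium (air)
#' @param n real refractive index, default 1 (air above the barb surface).
#' @return a `material_dispersion`.
#' @export
medium_default <- function(n = 1.0) {
  material_dispersion("medium", "constant", c(n = n, k = 0))
}

#' Default material set
#'
#' Convenience bundle of the three materials of the barb model: melanin rods,
#' keratin matrix/cortex, ambient air.
#' @param melanin,keratin,medium individual [material_dispersion()] objects.
#' @return named list of `material_dispersion` objects.
#' @export
default_materials <- function(melanin = melanin_default(),
                              keratin = keratin_default(),
                              medium = medium_default()) {
  list(melanin = melanin, keratin = keratin, medium = medium)
}

#' Load a tabulated dispersion from a text file
#'
#' Reads a whitespace- or comma-separated 3-column table (`lambda_nm  n  k`)
#' with optional `#` comment lines, and returns a tabulated
#' [material_dispersion()] that interpolates linearly between nodes and
#' reproduces the table values exactly at the nodes.
#'
#' @param path file path.
#' @param name material label (default: file base name).
#' @return a `material_dispersion` with model `"tabulated"`.
#' @export
load_dispersion_table <- function(path, name = NULL) {
  if (is.null(name))
    name <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  rows <- which(keep)
  if (length(rows) < 2L)
    stop("dispersion table '", path, "': need at least 2 data rows")
  parse_row <- function(i) {
    fields <- strsplit(trimws(lines[i]), "[[:space:],]+")[[1]]
    vals <- suppressWarnings(as.numeric(fields))
    if (length(vals) != 3L || anyNA(vals))
      stop("dispersion table '", path, "', line ", i,
           ": expected 3 numeric fields, got '", lines[i], "'")
    vals
  }
  m <- t(vapply(rows, parse_row, numeric(3)))
  tb <- data.frame(lambda_nm = m[, 1], n = m[, 2], k = m[, 3])
  if (any(diff(tb$lambda_nm) <= 0)) {
    bad <- rows[which(diff(tb$lambda_nm) <= 0)[1] + 1L]
    stop("dispersion table '", path, "', line ", bad,
         ": lambda_nm not strictly increasing")
  }
  if (any(tb$k < 0)) {
    bad <- rows[which(tb$k < 0)[1]]
    stop("dispersion table '", path, "', line ", bad, ": negative k")
  }
  material_dispersion(name, "tabulated", table = tb)
}

#' @export
print.material_dispersion <- function(x, ...) {
  cat("<material_dispersion> ", x$name, " [", x$model, "]  lambda ",
      x$lambda_range[1], "-", x$lambda_range[2], " nm\n", sep = "")
  if (!is.null(x$coefficients)) {
    cat("  coefficients: ",
        paste(names(x$coefficients), signif(x$coefficients, 6),
              sep = "=", collapse = ", "), "\n", sep = "")
  }
  if (!is.null(x$table))
    cat("  table nodes: ", nrow(x$table), "\n", sep = "")
  invisible(x)
}
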
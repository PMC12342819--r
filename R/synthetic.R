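#' Melanosome population parameters
#'
#' Statistical description of a melanosome population for the synthetic
#' electron-microscopy generator: per-axis means with a common coefficient of
#' variation (truncated-normal draws), plus tilt dispersion. Defaults are the
#' measured fossil means with a 10% CV, the typical within-feather
#' variability of melanosome dimensions.
#'
#' @param mean_x,mean_y,mean_z axis means, nm.
#' @param cv coefficient of variation applied to each axis.
#' @param tilt_mean,tilt_sd cross-section tilt distribution, degrees.
#' @param n number of melanosomes.
#' @param seed integer RNG seed.
#' @return object of class `population_params`.
#' @export
population_params <- function(mean_x = 186, mean_y = 283, mean_z = 1774,
                              cv = 0.10, tilt_mean = 20, tilt_sd = 5,
                              n = 500, seed = 1L) {
  stopifnot(mean_x > 0, mean_y > 0, mean_z > 0, cv >= 0, n >= 0,
            tilt_sd >= 0)
  structure(list(mean_x = mean_x, mean_y = mean_y, mean_z = mean_z, cv = cv,
                 tilt_mean = tilt_mean, tilt_sd = tilt_sd,
                 n = as.integer(n), seed = as.integer(seed)),
            class = "population_params")
}

# evaluate expr under a local RNG seed without disturbing the global stream
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# positive truncated-normal draws (truncation at zero, by rejection)
.rtruncnorm_pos <- function(n, mean, sd) {
  if (n == 0) return(numeric(0))
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out <= 0)
  while (length(bad)) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] <= 0]
  }
  out
}

#' Sample a melanosome population
#'
#' Draws `n` independent melanosomes with truncated-normal axes (truncation
#' at zero) and normal tilts; draws violating the cross-section constraint
#' `x <= y` are redrawn pairwise. Reproducible under the stored seed.
#'
#' @param p a [population_params()].
#' @return object of class `melanosome_population`: data frame with columns
#'   `id`, `x_nm`, `y_nm`, `z_nm`, `tilt_deg` plus the generating params as
#'   attribute `params`.
#' @export
sample_population <- function(p) {
  stopifnot(inherits(p, "population_params"))
  df <- .with_seed(p$seed, {
    x <- .rtruncnorm_pos(p$n, p$mean_x, p$cv * p$mean_x)
    y <- .rtruncnorm_pos(p$n, p$mean_y, p$cv * p$mean_y)
    bad <- which(x > y)
    while (length(bad)) {
      x[bad] <- .rtruncnorm_pos(length(bad), p$mean_x, p$cv * p$mean_x)
      y[bad] <- .rtruncnorm_pos(length(bad), p$mean_y, p$cv * p$mean_y)
      bad <- bad[x[bad] > y[bad]]
    }
    z <- .rtruncnorm_pos(p$n, p$mean_z, p$cv * p$mean_z)
    tilt <- if (p$n > 0) stats::rnorm(p$n, p$tilt_mean, p$tilt_sd) else numeric(0)
    data.frame(id = seq_len(p$n), x_nm = x, y_nm = y, z_nm = z,
               tilt_deg = tilt)
  })
  attr(df, "params") <- p
  class(df) <- c("melanosome_population", "data.frame")
  df
}

#' Render a synthetic cross-section image
#'
#' Draws the sampled elliptical cross-sections as dark particles on a light
#' background at ACHP-like positions (rows at the lattice pitch, sheared row
#' offsets), adds Gaussian noise, and records the ground truth of every
#' rendered particle. Emulates the STEM cross-sections the morphometry is
#' designed for; it does not emulate staining gradients, charging, or section
#' compression.
#'
#' @param pop a [sample_population()] result.
#' @param lattice a [lattice_spec()] giving pitch/period/shear for the layout.
#' @param pixel_size nm per pixel; at most `mean_x / 10`.
#' @param noise_sigma additive Gaussian noise SD in gray levels (image range
#'   is 0-1, so 8/255 means 8 gray levels of an 8-bit image).
#' @param seed noise seed.
#' @param fg,bg particle and background gray levels.
#' @param max_px refuse layouts larger than this many pixels per side.
#' @return object of class `section_image`: `pixels` (matrix, rows = image y),
#'   `pixel_size`, `truth` data frame, `type = "cross"`.
#' @export
render_section <- function(pop, lattice = default_feather_lattice(),
                           pixel_size = 5, noise_sigma = 8 / 255, seed = 1L,
                           fg = 0.2, bg = 0.85, max_px = 6000L) {
  stopifnot(inherits(pop, "melanosome_population"), nrow(pop) >= 1)
  pars <- attr(pop, "params")
  if (!is.null(pars) && pixel_size > pars$mean_x / 10)
    stop("pixel_size must be <= mean_x / 10 for reliable morphometry")
  n <- nrow(pop)
  ncols <- ceiling(sqrt(n))
  nrows <- ceiling(n / ncols)
  period <- lattice$period_nm * 1.25      # slight layout loosening
  pitch <- mean(lattice$pitch_nm) * 1.35
  margin <- max(pop$y_nm)
  W <- ceiling((ncols * period + 2 * margin) / pixel_size)
  H <- ceiling((nrows * pitch + 2 * margin) / pixel_size)
  if (W > max_px || H > max_px)
    stop("layout of ", n, " particles needs a ", W, " x ", H,
         " px field, above the ", max_px, " px limit")
  img <- matrix(bg, nrow = H, ncol = W)
  row_i <- (seq_len(n) - 1) %/% ncols
  col_i <- (seq_len(n) - 1) %% ncols
  cx <- (margin + (col_i + 0.5 + (row_i * lattice$shear_s) %% 1) * period) / pixel_size
  cy <- (margin + (row_i + 0.5) * pitch) / pixel_size
  phi <- pop$tilt_deg * pi / 180
  a <- pop$y_nm / 2 / pixel_size   # semi-axes in px
  b <- pop$x_nm / 2 / pixel_size
  for (k in seq_len(n)) {
    ext <- a[k] + 1
    ii <- max(1, floor(cx[k] - ext)):min(W, ceiling(cx[k] + ext))
    jj <- max(1, floor(cy[k] - ext)):min(H, ceiling(cy[k] + ext))
    dxp <- ii - cx[k]; dyp <- jj - cy[k]
    u <- outer(dyp, dxp, function(Y, X) X * cos(phi[k]) + Y * sin(phi[k]))
    v <- outer(dyp, dxp, function(Y, X) -X * sin(phi[k]) + Y * cos(phi[k]))
    inside <- (u / a[k])^2 + (v / b[k])^2 <= 1
    blk <- img[jj, ii, drop = FALSE]
    blk[inside] <- fg
    img[jj, ii] <- blk
  }
  img <- .with_seed(seed, {
    pmin(pmax(img + stats::rnorm(length(img), 0, noise_sigma), 0), 1)
  })
  truth <- data.frame(id = pop$id, cx_px = cx, cy_px = cy,
                      x_nm = pop$x_nm, y_nm = pop$y_nm,
                      tilt_deg = pop$tilt_deg)
  structure(list(pixels = img, pixel_size = pixel_size, truth = truth,
                 type = "cross"),
            class = "section_image")
}

#' Render a synthetic longitudinal-section image
#'
#' Rods appear as dark rectangles of length `z` and width `x`, aligned with
#' the barb axis (image x direction), on a light background — the view used
#' to recover the rod long axis.
#'
#' @inheritParams render_section
#' @param gap_nm clear spacing between rods, nm.
#' @return a `section_image` with `type = "longitudinal"` and truth columns
#'   `z_nm`, `x_nm`.
#' @export
render_longitudinal <- function(pop, pixel_size = 5, noise_sigma = 8 / 255,
                                seed = 1L, gap_nm = 200, fg = 0.2, bg = 0.85,
                                max_px = 6000L) {
  stopifnot(inherits(pop, "melanosome_population"), nrow(pop) >= 1)
  n <- nrow(pop)
  cell_w <- max(pop$z_nm) + gap_nm
  cell_h <- max(pop$x_nm) + gap_nm
  ncols <- max(1, floor(sqrt(n * cell_h / cell_w)))
  nrows <- ceiling(n / ncols)
  W <- ceiling((ncols * cell_w + gap_nm) / pixel_size)
  H <- ceiling((nrows * cell_h + gap_nm) / pixel_size)
  if (W > max_px || H > max_px)
    stop("layout of ", n, " rods needs a ", W, " x ", H,
         " px field, above the ", max_px, " px limit")
  img <- matrix(bg, nrow = H, ncol = W)
  row_i <- (seq_len(n) - 1) %/% ncols
  col_i <- (seq_len(n) - 1) %% ncols
  cx <- (gap_nm + (col_i + 0.5) * cell_w) / pixel_size
  cy <- (gap_nm + (row_i + 0.5) * cell_h) / pixel_size
  hw <- pop$z_nm / 2 / pixel_size
  hh <- pop$x_nm / 2 / pixel_size
  for (k in seq_len(n)) {
    ii <- max(1, round(cx[k] - hw[k])):min(W, round(cx[k] + hw[k]))
    jj <- max(1, round(cy[k] - hh[k])):min(H, round(cy[k] + hh[k]))
    img[jj, ii] <- fg
  }
  img <- .with_seed(seed, {
    pmin(pmax(img + stats::rnorm(length(img), 0, noise_sigma), 0), 1)
  })
  truth <- data.frame(id = pop$id, cx_px = cx, cy_px = cy,
                      z_nm = pop$z_nm, x_nm = pop$x_nm)
  structure(list(pixels = img, pixel_size = pixel_size, truth = truth,
                 type = "longitudinal"),
            class = "section_image")
}

#' Measure melanosome morphometry from a section image
#'
#' Segments dark particles by thresholding (Otsu by default), discards
#' components touching the image border and components smaller than 25% of
#' the median component area, and fits each survivor with its
#' second-moment-equivalent ellipse. For longitudinal sections, the rod
#' length is measured as the pixel extent along the fitted major-axis
#' direction (moment axes overestimate the length of rectangles, extents do
#' not).
#'
#' @param img a [render_section()] or [render_longitudinal()] result.
#' @param threshold_rule `"otsu"` or `"fixed"`.
#' @param fixed_level threshold gray level when `threshold_rule = "fixed"`
#'   (pixels darker than this are particles).
#' @return object of class `morphometry_result`: `per_particle` data frame
#'   (`x_nm`, `y_nm`, `tilt_deg` for cross-sections; `z_nm`, `x_nm` for
#'   longitudinal), per-axis `mean` and `sd`, `n_measured`, `n_excluded`.
#' @export
measure_morphometry <- function(img, threshold_rule = c("otsu", "fixed"),
                                fixed_level = 0.5) {
  stopifnot(inherits(img, "section_image"))
  threshold_rule <- match.arg(threshold_rule)
  px <- img$pixels
  # histogram thresholding and connected components are orientation-free, so
  # the [row, col] matrix is passed to EBImage without transposition
  level <- if (threshold_rule == "otsu")
    EBImage::otsu(EBImage::Image(px), range = c(0, 1)) else fixed_level
  bw <- px < level
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(bw)))
  nlab <- max(lab)
  if (nlab == 0) stop("no particles found above threshold")
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  border <- setdiff(border, 0)
  # coordinate lists per label in one pass
  idx <- which(lab > 0)
  lv <- lab[idx]
  ys <- (idx - 1) %% nrow(lab) + 1
  xs <- (idx - 1) %/% nrow(lab) + 1
  coords <- split(seq_along(idx), lv)
  areas <- lengths(coords)
  keep <- setdiff(as.integer(names(coords)), border)
  if (length(keep)) {
    med_area <- stats::median(areas[as.character(keep)])
    keep <- keep[areas[as.character(keep)] >= 0.25 * med_area]
  }
  n_excluded <- nlab - length(keep)
  if (!length(keep)) stop("no particles survived the border/size filters")
  ps <- img$pixel_size
  fit_one <- function(id) {
    sel <- coords[[as.character(id)]]
    X <- xs[sel]; Y <- ys[sel]
    cxm <- mean(X); cym <- mean(Y)
    # second moments with the 1/12 variance of a unit pixel
    sxx <- mean((X - cxm)^2) + 1 / 12
    syy <- mean((Y - cym)^2) + 1 / 12
    sxy <- mean((X - cxm) * (Y - cym))
    ev <- eigen(matrix(c(sxx, sxy, sxy, syy), 2, 2), symmetric = TRUE)
    major <- 4 * sqrt(ev$values[1]); minor <- 4 * sqrt(ev$values[2])
    ang <- atan2(ev$vectors[2, 1], ev$vectors[1, 1]) * 180 / pi
    if (ang > 90) ang <- ang - 180
    if (ang <= -90) ang <- ang + 180
    # extent along the major axis (Feret-like), for rod lengths
    dirv <- ev$vectors[, 1]
    proj <- (X - cxm) * dirv[1] + (Y - cym) * dirv[2]
    extent <- diff(range(proj)) + 1
    c(major = major, minor = minor, tilt = ang, extent = extent)
  }
  fits <- t(vapply(keep, fit_one, numeric(4)))
  if (img$type == "cross") {
    per <- data.frame(x_nm = fits[, "minor"] * ps,
                      y_nm = fits[, "major"] * ps,
                      tilt_deg = fits[, "tilt"])
    mu <- c(x_nm = mean(per$x_nm), y_nm = mean(per$y_nm),
            tilt_deg = mean(per$tilt_deg))
    sdv <- c(x_nm = stats::sd(per$x_nm), y_nm = stats::sd(per$y_nm),
             tilt_deg = stats::sd(per$tilt_deg))
  } else {
    per <- data.frame(z_nm = fits[, "extent"] * ps,
                      x_nm = fits[, "minor"] * ps)
    mu <- c(z_nm = mean(per$z_nm), x_nm = mean(per$x_nm))
    sdv <- c(z_nm = stats::sd(per$z_nm), x_nm = stats::sd(per$x_nm))
  }
  structure(list(per_particle = per, mean = mu, sd = sdv,
                 n_measured = length(keep), n_excluded = n_excluded,
                 threshold = level, type = img$type),
            class = "morphometry_result")
}

#' @export
print.morphometry_result <- function(x, ...) {
  cat("<morphometry_result> ", x$type, " section: ", x$n_measured,
      " particles (", x$n_excluded, " excluded)\n", sep = "")
  m <- rbind(mean = x$mean, sd = x$sd)
  print(round(m, 1))
  invisible(x)
}

#' Export helpers for synthetic data
#'
#' `export_population` writes the sampled population as CSV;
#' `export_section_image` writes the image as PNG with a JSON truth sidecar.
#' @param pop a `melanosome_population`.
#' @param path,path_png,path_json output paths.
#' @param img a `section_image`.
#' @return invisibly, the written path(s).
#' @export
export_population <- function(pop, path) {
  utils::write.csv(as.data.frame(pop), path, row.names = FALSE)
  invisible(path)
}

#' @rdname export_population
#' @export
export_section_image <- function(img, path_png, path_json) {
  png::writePNG(img$pixels, path_png)
  jsonlite::write_json(list(pixel_size_nm = img$pixel_size, type = img$type,
                            truth = img$truth),
                       path_json, auto_unbox = TRUE, digits = NA)
  invisible(c(path_png, path_json))
}
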
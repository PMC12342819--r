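make_bump <- function(lam, centre, width, height) {
  height * exp(-0.5 * ((lam - centre) / width)^2)
}

test_that("peak finder recovers synthetic peak positions and reports none on monotone input", {
  lam <- seq(400, 800, by = 5)
  one <- reflectance_spectrum(lam, make_bump(lam, 550, 30, 0.4))
  pk <- find_peaks(one, prominence_min = 0.05)
  expect_equal(nrow(pk$peaks), 1)
  expect_lt(abs(pk$peaks$lambda_nm - 550), 5)
  expect_equal(pk$peaks$R, 0.4, tolerance = 1e-3)
  # FWHM of a Gaussian bump: 2*sqrt(2 ln 2)*sigma
  expect_equal(pk$peaks$fwhm_nm, 2 * sqrt(2 * log(2)) * 30, tolerance = 0.1)

  mono <- reflectance_spectrum(lam, seq(0.01, 0.5, length.out = length(lam)))
  expect_equal(nrow(find_peaks(mono, 0.05)$peaks), 0)
})

test_that("two bumps with a shallow saddle are both found, sorted by wavelength", {
  lam <- seq(400, 800, by = 5)
  R <- make_bump(lam, 480, 25, 0.3) + make_bump(lam, 650, 30, 0.5)
  pk <- find_peaks(reflectance_spectrum(lam, R), prominence_min = 0.05)
  expect_equal(nrow(pk$peaks), 2)
  expect_true(!is.unsorted(pk$peaks$lambda_nm))
  # brute-force maxima of the same sampled curve
  expect_lt(abs(pk$peaks$lambda_nm[1] - lam[which.max(R * (lam < 550))]), 5)
  expect_lt(abs(pk$peaks$lambda_nm[2] - lam[which.max(R * (lam > 550))]), 5)
  # a prominence threshold above the small bump suppresses it
  pk2 <- find_peaks(reflectance_spectrum(lam, R), prominence_min = 0.35)
  expect_equal(nrow(pk2$peaks), 1)
})

test_that("peak finder preconditions are enforced", {
  lam <- seq(400, 800, by = 5)
  sp <- reflectance_spectrum(lam, rep(0.1, length(lam)))
  expect_error(find_peaks(sp, lambda_band = c(300, 700)), "outside")
  expect_error(find_peaks(sp, lambda_band = c(600, 640)), "15 samples")
  expect_error(reflectance_spectrum(c(500, 450), c(0.1, 0.1)), "increasing")
})

test_that("hue bands map the characteristic wavelengths to their color words", {
  expect_equal(classify_hue(512), "green")
  expect_equal(classify_hue(578), "yellow")
  expect_equal(classify_hue(475), "deep blue")
  expect_equal(classify_hue(687), "red")
  expect_equal(classify_hue(c(449.9, 450, 600, 739.9, 750)),
               c("blue", "deep blue", "orange", "red", "dark/none"))
  expect_error(classify_hue(350), "380-780")
})

test_that("equal-energy white point and black limits of the colorimetry", {
  lam <- seq(380, 780, by = 5)
  white <- spectrum_to_swatch(reflectance_spectrum(lam, rep(1, length(lam))),
                              illuminant = "E")
  expect_equal(unname(white$xy), c(1, 1) / 3, tolerance = 0.01)
  expect_equal(unname(white$XYZ["Y"]), 1, tolerance = 1e-9)

  black <- spectrum_to_swatch(reflectance_spectrum(lam, rep(0, length(lam))),
                              illuminant = "E")
  expect_equal(unname(black$XYZ), c(0, 0, 0))
  expect_equal(black$hue_name, "dark/none")
  expect_true(all(black$sRGB == 0))
})

test_that("colorimetry is linear in the reflectance before gamma", {
  lam <- seq(380, 780, by = 5)
  R1 <- make_bump(lam, 480, 30, 0.3)
  R2 <- make_bump(lam, 640, 40, 0.4)
  s1 <- spectrum_to_swatch(reflectance_spectrum(lam, R1), "D65")
  s2 <- spectrum_to_swatch(reflectance_spectrum(lam, R2), "D65")
  s12 <- spectrum_to_swatch(reflectance_spectrum(lam, 0.5 * R1 + 0.5 * R2),
                            "D65")
  expect_equal(s12$XYZ, 0.5 * s1$XYZ + 0.5 * s2$XYZ, tolerance = 1e-9)
})

test_that("narrowband peaks render with the expected hue names", {
  lam <- seq(380, 780, by = 5)
  blue <- spectrum_to_swatch(
    reflectance_spectrum(lam, make_bump(lam, 475, 15, 0.5)))
  expect_equal(blue$hue_name, "deep blue")
  red <- spectrum_to_swatch(
    reflectance_spectrum(lam, make_bump(lam, 687, 15, 0.5)))
  expect_equal(red$hue_name, "red")
  dark <- spectrum_to_swatch(
    reflectance_spectrum(lam, rep(0.02, length(lam))))
  expect_equal(dark$hue_name, "dark/none")
})

test_that("angle sweep on the default model blue-shifts and goes dark at small angles", {
  geom <- build_achp_geometry(default_feather_lattice(), delta = 5)
  sw <- angle_sweep(geom, plane = "XY", polarization = "sp",
                    theta_list = c(0, 20, 40, 50, 60, 70),
                    lambda = seq(400, 800, by = 4), solver = "tmm")
  rep_df <- sweep_report(sw)
  pk4070 <- rep_df$peak_lambda_nm[rep_df$theta_deg >= 40]
  expect_true(all(is.finite(pk4070)))
  expect_true(all(diff(pk4070) < 0))     # strict blue-shift 40 -> 70
  expect_s3_class(sw$entries[[1]]$swatch, "color_swatch")
})

test_that("the Y-Z incidence plane is served by the multilayer reduction", {
  geom <- build_achp_geometry(default_feather_lattice(n_layers = 3), delta = 5)
  sw <- angle_sweep(geom, plane = "YZ", polarization = "s",
                    theta_list = 40, lambda = seq(400, 800, by = 10),
                    solver = "fdtd")
  expect_equal(sw$entries[[1]]$spectrum$condition$solver, "tmm")
})
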
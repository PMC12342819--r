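test_that("scenario application scales axes and is reproducible", {
  base <- default_feather_lattice(n_layers = 4)
  idsc <- taphonomy_scenario(scale_factor = 1, gap_jitter_sd = 0,
                             n_realizations = 1, seed = 1)
  same <- apply_scenario(base, idsc)[[1]]
  expect_equal(same$melanosome$x, base$melanosome$x)
  expect_equal(same$pitch_nm, base$pitch_nm)

  sc <- taphonomy_scenario(scale_factor = 1.10, gap_jitter_sd = 5,
                           n_realizations = 5, seed = 7)
  reals <- apply_scenario(base, sc)
  expect_length(reals, 5)
  expect_equal(reals[[1]]$melanosome$x, 186 * 1.10)   # 204.6 nm
  expect_equal(reals[[1]]$melanosome$x, 204.6)
  expect_identical(vapply(apply_scenario(base, sc), function(l) l$gap_g[1],
                          numeric(1)),
                   vapply(reals, function(l) l$gap_g[1], numeric(1)))
  # jitter varies between rows and realizations
  expect_gt(stats::sd(reals[[1]]$gap_g), 0)
})

test_that("peak matching reports identity, uniform shifts and dropouts", {
  lam <- seq(400, 800, by = 2)
  mk <- function(centres) {
    R <- Reduce(`+`, lapply(centres, function(c0) 0.4 * exp(-0.5 * ((lam - c0) / 20)^2)))
    find_peaks(reflectance_spectrum(lam, R), prominence_min = 0.05)
  }
  base <- list(mk(c(500, 650)))
  expect_equal(compare_peak_sets(base, base, 40)$matches$delta_nm, c(0, 0),
               tolerance = 1e-9)

  shifted <- list(mk(c(505, 655)))
  rep_s <- compare_peak_sets(base, shifted, 40, tol_nm = 20)
  expect_true(all(rep_s$matches$matched))
  expect_equal(rep_s$matches$delta_nm, c(5, 5), tolerance = 0.5)

  dropped <- list(mk(500))
  rep_d <- compare_peak_sets(base, dropped, 40, tol_nm = 20)
  expect_equal(rep_d$n_matched, 1)
  expect_equal(rep_d$n_unmatched, 1)
  expect_error(compare_peak_sets(base, list(), numeric(0)), "equal length")
})

test_that("the 110% enlargement keeps every baseline peak matched in the visible", {
  tp <- run_taphonomy(default_feather_lattice(),
                      taphonomy_scenario(scale_factor = 1.10,
                                         gap_jitter_sd = 10,
                                         n_realizations = 3, seed = 2),
                      theta_list = c(40, 50, 60, 70),
                      lambda = seq(400, 850, by = 4))
  m <- tp$match$matches
  strongest <- do.call(rbind, lapply(split(m, m$theta_deg), function(d)
    d[which.max(d$lambda_base), ]))   # first-order (reddest) peak per angle
  expect_true(all(strongest$matched))
  expect_true(all(abs(strongest$delta_nm) / strongest$lambda_base <= 0.12))
})

test_that("uniform 110% scaling red-shifts the dispersion-frozen model peak by ~10%", {
  # freeze dispersion: constant-index melanin/keratin at their 650 nm values
  mats <- default_materials()
  frozen <- list(
    melanin = material_dispersion("melanin", "constant",
      c(n = Re(evaluate_index(mats$melanin, 650)), k = 0)),
    keratin = material_dispersion("keratin", "constant",
      c(n = Re(evaluate_index(mats$keratin, 650)), k = 0)),
    medium = medium_default())
  lam <- seq(400, 1000, by = 2)
  peak_for <- function(f) {
    lat <- lattice_spec(melanosome = melanosome_spec(x = 186 * f, y = 283 * f,
                                                     z = 1774 * f),
                        gap_g = 39 * f, n_layers = 6)
    st <- reduce_to_multilayer(build_achp_geometry(lat, delta = 2.5),
                               materials = frozen)
    R <- tmm_reflectance(st, 40, "s", lam)
    pk <- find_peaks(reflectance_spectrum(lam, R), prominence_min = 0.05)
    max(pk$peaks$lambda_nm)   # first-order (reddest) peak
  }
  p1 <- peak_for(1); p2 <- peak_for(1.10)
  expect_equal(p2 / p1, 1.10, tolerance = 0.01)
})
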
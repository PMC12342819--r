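test_that("single-interface reflectance reproduces Fresnel exactly", {
  mats <- fixture_materials()
  st <- layer_stack(1, material = "glass", materials = mats, exit = "glass")
  expect_equal(tmm_reflectance(st, 0, "s", 550), 0.04, tolerance = 1e-12)
  expect_equal(tmm_reflectance(st, 0, "p", 550), 0.04, tolerance = 1e-12)
  for (th in c(20, 45, 70)) for (pol in c("s", "p"))
    expect_equal(tmm_reflectance(st, th, pol, 550),
                 fresnel_R(1.5, th, pol), tolerance = 1e-12)
})

test_that("matched media reflect nothing and Brewster kills p-polarization", {
  mats <- fixture_materials()
  matched <- layer_stack(50, material = "medium", materials = mats,
                         exit = "medium")
  expect_lt(tmm_reflectance(matched, 30, "s", 500), 1e-14)
  glass <- layer_stack(1, material = "glass", materials = mats, exit = "glass")
  brewster <- atan(1.5) * 180 / pi
  expect_lt(tmm_reflectance(glass, brewster, "p", 550), 1e-8)
})

test_that("an absorbing slab matches the Airy closed form, both polarizations", {
  mats <- fixture_materials()
  n1 <- 1.6 + 0.05i; n2 <- 1.5; d <- 500
  st <- layer_stack(d, material = "absglass", materials = mats, exit = "glass")
  for (th in c(0, 35)) for (pol in c("s", "p")) {
    s0 <- sin(th * pi / 180)
    c0 <- sqrt(1 - s0^2); c1 <- sqrt(1 - (s0 / n1)^2); c2 <- sqrt(1 - (s0 / n2)^2)
    if (pol == "s") {
      r01 <- (c0 - n1 * c1) / (c0 + n1 * c1)
      r12 <- (n1 * c1 - n2 * c2) / (n1 * c1 + n2 * c2)
    } else {
      r01 <- (n1 * c0 - c1) / (n1 * c0 + c1)
      r12 <- (n2 * c1 - n1 * c2) / (n2 * c1 + n1 * c2)
    }
    beta <- 2 * pi * n1 * d * c1 / 550
    r <- (r01 + r12 * exp(2i * beta)) / (1 + r01 * r12 * exp(2i * beta))
    expect_equal(tmm_reflectance(st, th, pol, 550), Mod(r)^2,
                 tolerance = 1e-10)
  }
})

test_that("lossless stacks conserve energy to 1e-10 and at normal incidence s equals p", {
  st <- fixture_bilayer_stack()
  lam <- seq(400, 800, by = 7)
  for (th in c(0, 25, 60)) for (pol in c("s", "p")) {
    rt <- tmm_rt(st, th, pol, lam)
    expect_lt(max(abs(rt$R + rt$T - 1)), 1e-10)
  }
  expect_equal(tmm_reflectance(st, 0, "s", lam),
               tmm_reflectance(st, 0, "p", lam), tolerance = 1e-12)
})

test_that("reflectance is invariant under subdividing a layer", {
  mats <- fixture_materials()
  whole <- layer_stack(c(186, 30, 186), material = c("hi", "lo", "hi"),
                       materials = mats, exit = "lo")
  split2 <- layer_stack(c(93, 93, 30, 100, 86),
                        material = c("hi", "hi", "lo", "hi", "hi"),
                        materials = mats, exit = "lo")
  lam <- seq(420, 760, by = 20)
  for (pol in c("s", "p"))
    expect_equal(tmm_reflectance(whole, 33, pol, lam),
                 tmm_reflectance(split2, 33, pol, lam), tolerance = 1e-12)
})

test_that("bilayer peak sits at the Bragg wavelength and blue-shifts with angle", {
  mats <- fixture_materials()
  lam <- seq(400, 900, by = 1)
  # quarter-wave stack in index-matched surroundings: brute-force argmax of
  # the TMM scan must land exactly on the design (Bragg) wavelength
  d1 <- 650 / (4 * 1.7428); d2 <- 650 / (4 * 1.55556)
  qw <- layer_stack(rep(c(d1, d2), 5), material = rep(c("hi", "lo"), 5),
                    materials = mats, incidence = "lo", exit = "lo")
  R0 <- tmm_reflectance(qw, 0, "s", lam)
  expect_equal(lam[which.max(R0)], 650)
  expect_equal(bragg_peak_estimate(d1, 1.7428, d2, 1.55556, 0), 650,
               tolerance = 1e-12)

  expect_equal(bragg_peak_estimate(100, 1.5, 100, 1.5, 0), 600)
  # cosine monotonicity: oblique peak always bluer
  for (th in c(20, 40, 60))
    expect_lt(bragg_peak_estimate(186, 1.7428, 30, 1.55556, th),
              bragg_peak_estimate(186, 1.7428, 30, 1.55556, th - 10))
  # estimate for the shipped lattice (melanin row / calibrated clearance at
  # their ~650 nm indices) against the reduced-stack TMM peak at 40 degrees
  n_mel <- Re(evaluate_index(mats$melanin, 650))
  n_ker <- Re(evaluate_index(mats$keratin, 650))
  est <- bragg_peak_estimate(186, n_mel, 39, n_ker, 40)
  stack <- reduce_to_multilayer(
    build_achp_geometry(default_feather_lattice(), delta = 5))
  R40 <- (tmm_reflectance(stack, 40, "s", lam) +
          tmm_reflectance(stack, 40, "p", lam)) / 2
  pk <- find_peaks(reflectance_spectrum(lam, R40), prominence_min = 0.05)$peaks
  expect_lt(abs(est - max(pk$lambda_nm)) / max(pk$lambda_nm), 0.05)
})

test_that("evanescent or out-of-range incidence is refused", {
  st <- fixture_bilayer_stack()
  expect_error(tmm_rt(st, 90, "s", 550), "theta")
  expect_error(tmm_rt(st, 95, "s", 550), "theta")
})

test_that("maxwell scale invariance: scaling a dispersion-frozen stack scales its peak", {
  mats <- fixture_materials()   # constant-index hi/lo pair
  lam <- seq(400, 1000, by = 1)
  base <- fixture_bilayer_stack(mats)
  f <- 1.10
  scaled <- layer_stack(rep(c(186, 30) * f, 5),
                        material = rep(c("hi", "lo"), 5),
                        materials = mats, exit = "lo")
  reddest <- function(st) {
    pk <- find_peaks(reflectance_spectrum(lam, tmm_reflectance(st, 40, "s", lam)),
                     prominence_min = 0.05)$peaks
    max(pk$lambda_nm)   # track the first order; argmax could hop orders
  }
  expect_equal(reddest(scaled) / reddest(base), f, tolerance = 0.01)
})
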
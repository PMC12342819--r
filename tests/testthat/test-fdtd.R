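# FDTD solver checks against exact electromagnetic oracles. Domains are kept
# small (thin stacks, short spectra) so the whole file runs in a few minutes.

test_that("grid and incidence specifications validate their invariants", {
  expect_error(grid_spec(courant = 1.2), "stability")
  expect_error(grid_spec(pml_cells = 4), ">= 8")
  expect_error(incidence_spec("XY", 95, "s", 550), "< 90")
  expect_error(incidence_spec("XY", 40, "s", 100), "band")
  expect_error(run_fdtd(slab_geometry("medium", 100),
                        incidence_spec("YZ", 40, "s", 550)),
               "transfer-matrix")
})

test_that("an empty domain is reflectionless and transmits all flux", {
  geom <- slab_geometry("medium", 300, period_nm = 100, delta = 5)
  for (th in c(0, 40, 60)) {
    f <- run_fdtd(geom, incidence_spec("XY", th, "s", 550))
    expect_lt(f$R, 0.005)
    expect_gt(f$T, 0.99)
  }
})

test_that("half-space reflectance matches Fresnel at normal and oblique incidence", {
  mats <- fixture_materials()
  geom <- slab_geometry("glass", 400, period_nm = 100, delta = 5,
                        exit = "glass")
  f0 <- run_fdtd(geom, incidence_spec("XY", 0, "s", 550), materials = mats)
  expect_equal(f0$R, 0.04, tolerance = 0.005)
  expect_true(f0$converged)
  for (th in c(40, 70)) for (pol in c("s", "p")) {
    f <- run_fdtd(geom, incidence_spec("XY", th, pol, 550), materials = mats)
    expect_lt(abs(f$R - fresnel_R(1.5, th, pol)), 0.005)
  }
})

test_that("energy is conserved for lossless media and grid refinement tightens it", {
  mats <- fixture_materials()
  geom <- slab_geometry(c("hi", "lo", "hi"), c(185, 90, 185),
                        period_nm = 100, delta = 5, exit = "glass")
  f <- run_fdtd(geom, incidence_spec("XY", 30, "s", 550), materials = mats)
  expect_lt(abs(1 - f$R - f$T), 0.01)
  geom2 <- slab_geometry(c("hi", "lo", "hi"), c(185, 90, 185),
                         period_nm = 100, delta = 2.5, exit = "glass")
  f2 <- run_fdtd(geom2, incidence_spec("XY", 30, "s", 550),
                 grid = grid_spec(delta = 2.5), materials = mats)
  expect_lt(abs(1 - f2$R - f2$T), abs(1 - f$R - f$T) + 1e-4)
  expect_lt(abs(1 - f2$R - f2$T), 0.003)
})

test_that("layered geometries agree with the transfer matrix within 0.02 absolute", {
  mats <- fixture_materials()
  layers <- rep(c("melanin", "keratin"), 3)
  d <- rep(c(185, 40), 3)
  geom <- slab_geometry(layers, d, period_nm = 100, delta = 5,
                        exit = "keratin")
  st <- layer_stack(d, material = layers, materials = mats, exit = "keratin")
  lam <- c(450, 550, 650, 750)
  for (th in c(0, 30, 60)) for (pol in c("s", "p")) {
    Rf <- vapply(lam, function(l)
      run_fdtd(geom, incidence_spec("XY", th, pol, l), materials = mats)$R,
      numeric(1))
    Rt <- tmm_reflectance(st, th, pol, lam)
    expect_lt(max(abs(Rf - Rt)), 0.02)
  }
})

test_that("thin-film fringes of a keratin slab match the transfer matrix", {
  mats <- fixture_materials()
  geom <- slab_geometry("keratin", 1000, period_nm = 100, delta = 5)
  st <- layer_stack(1000, material = "keratin", materials = mats,
                    exit = "medium")
  sp <- sweep_spectrum(geom, "XY", 0, "s", lambda = seq(400, 700, by = 20),
                       materials = mats)
  Rt <- tmm_reflectance(st, 0, "s", sp$lambda_nm)
  expect_lt(max(abs(sp$R - Rt)), 0.02)
  expect_true(all(sp$converged))
})

test_that("s and p coincide at normal incidence on a 2D-structured lattice", {
  geom <- build_achp_geometry(default_feather_lattice(n_layers = 2),
                              delta = 5)
  lam <- c(500, 600, 700)
  Rs <- vapply(lam, function(l)
    run_fdtd(geom, incidence_spec("XY", 0, "s", l))$R, numeric(1))
  Rp <- vapply(lam, function(l)
    run_fdtd(geom, incidence_spec("XY", 0, "p", l))$R, numeric(1))
  expect_lt(max(abs(Rs - Rp)), 0.01)
})

test_that("mirroring the lattice together with the incidence sign leaves R unchanged", {
  geom <- build_achp_geometry(default_feather_lattice(n_layers = 2),
                              delta = 5)
  mirror <- geom
  mirror$index_map <- geom$index_map[, rev(seq_len(ncol(geom$index_map)))]
  for (l in c(520, 660)) {
    a <- run_fdtd(geom, incidence_spec("XY", 35, "s", l))$R
    b <- run_fdtd(mirror, incidence_spec("XY", -35, "s", l))$R
    expect_equal(a, b, tolerance = 0.01)
  }
})
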
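test_that("melanosome axes and tilt are validated", {
  expect_error(melanosome_spec(x = 300, y = 283), "x <= y")
  expect_error(melanosome_spec(x = -1), "x <= y")
  expect_error(melanosome_spec(tilt_deg = 95), "< 90")
  m <- melanosome_spec()
  expect_equal(c(m$x, m$y, m$z), c(186, 283, 1774))
})

test_that("ellipse cross-section area matches pi*a*b and is tilt-invariant", {
  circ <- ellipse_cross_section(melanosome_spec(x = 200, y = 200, z = 200,
                                                tilt_deg = 0))
  expect_equal(circ$area, pi * 100 * 100, tolerance = 1e-12)
  expect_equal(circ$area, 31415.9, tolerance = 1e-5)

  ref <- ellipse_cross_section(melanosome_spec())
  expect_equal(ref$area, pi * 93 * 141.5, tolerance = 1e-12)
  expect_equal(ref$area, 41341.8, tolerance = 1e-5)

  rot <- ellipse_cross_section(melanosome_spec(tilt_deg = 85))
  expect_equal(rot$area, ref$area)
})

test_that("lattice invariants are enforced", {
  expect_error(lattice_spec(shear_s = 0), "strictly between")
  expect_error(lattice_spec(shear_s = 1.2), "strictly between")
  expect_error(lattice_spec(gap_g = -5))
  expect_error(lattice_spec(n_layers = 45), "10 um")
})

test_that("a single untilted touching row is exactly one short axis tall", {
  lat <- lattice_spec(melanosome = melanosome_spec(tilt_deg = 0),
                      gap_g = 0, shear_s = 0.5, n_layers = 1,
                      cortex_t = 0, substrate_t = 0)
  expect_equal(lat$height_nm, 186)
  # within-row period of untilted touching ellipses is the major axis
  expect_equal(lat$period_nm, 283)
})

test_that("raster is laterally periodic and purely deterministic", {
  lat <- default_feather_lattice(n_layers = 3)
  g1 <- build_achp_geometry(lat, delta = 5)
  g2 <- build_achp_geometry(lat, delta = 5)
  expect_identical(g1$index_map, g2$index_map)
  # periodicity: membership at x and x + period agree on a fresh raster row
  # (the raster stores one period; wrap is exercised via the image copies)
  expect_true(any(g1$index_map == 2L))
  expect_error(build_achp_geometry(lat, delta = 30), "too coarse")
})

test_that("raster melanin fraction converges to the analytic packing fraction", {
  lat <- default_feather_lattice(n_layers = 4)
  # unit-cell fraction (period x pitch) agrees within 2% at 5 nm cells
  expect_equal(raster_melanin_fraction(build_achp_geometry(lat, delta = 5)),
               packing_fraction(lat), tolerance = 0.02)
  # pixel counting converges to the exact band-area fraction as cells shrink
  target <- lat$n_layers * ellipse_cross_section(lat$melanosome)$area /
    (lat$period_nm * lat$band_nm)
  errs <- vapply(c(10, 5, 2.5), function(d) {
    abs(raster_melanin_fraction(build_achp_geometry(lat, delta = d)) - target)
  }, numeric(1))
  expect_lt(errs[3], errs[1])
  expect_lt(errs[3] / target, 0.005)
})

test_that("untilted regular-hex fraction matches the hand ellipse formula", {
  m <- melanosome_spec(tilt_deg = 1e-9)
  lat <- lattice_spec(melanosome = m, gap_g = 30, shear_s = 0.5, n_layers = 4)
  geom <- build_achp_geometry(lat, delta = 2.5)
  analytic <- 4 * pi * (186 / 2) * (283 / 2) / (lat$period_nm * lat$band_nm)
  expect_equal(raster_melanin_fraction(geom), analytic, tolerance = 0.02)
})

test_that("multilayer reduction reaches the homogeneous limits exactly", {
  mats <- default_materials()
  lat <- default_feather_lattice(n_layers = 2)
  geom <- build_achp_geometry(lat, delta = 5)
  stack <- reduce_to_multilayer(geom, materials = mats)
  idx <- effective_index(stack, 500)
  n_ker <- evaluate_index(mats$keratin, 500)
  # cortex band: fill fraction 0 -> keratin exactly
  expect_equal(stack$fraction_melanin[1], 0)
  expect_equal(idx[1, 1], n_ker)
  # hand-computed 50/50 volume average at 500 nm
  n_mel <- evaluate_index(mats$melanin, 500)
  half <- layer_stack(100, fraction_melanin = 0.5, materials = mats)
  expect_equal(effective_index(half, 500)[1, 1], (n_mel + n_ker) / 2)
  expect_equal(Re(effective_index(half, 500)[1, 1]), 1.64918, tolerance = 1e-5)
  expect_equal(Im(effective_index(half, 500)[1, 1]), Im(n_mel) / 2)
  # fraction 1 -> melanin exactly
  full <- layer_stack(100, fraction_melanin = 1, materials = mats)
  expect_equal(effective_index(full, 500)[1, 1], n_mel)
})

test_that("maxwell-garnett mixing matches its closed form and limits", {
  mats <- default_materials()
  st <- layer_stack(c(10, 10, 10), fraction_melanin = c(0, 0.3, 1),
                    rule = "maxwell_garnett", materials = mats)
  idx <- effective_index(st, 600)
  em <- evaluate_index(mats$melanin, 600)^2
  ek <- evaluate_index(mats$keratin, 600)^2
  f <- 0.3
  ee <- ek * (em + 2 * ek + 2 * f * (em - ek)) / (em + 2 * ek - f * (em - ek))
  expect_equal(idx[2, 1], sqrt(ee))
  expect_equal(idx[1, 1], sqrt(ek))
  expect_equal(idx[3, 1], sqrt(em))
})

test_that("widening the clearance dilutes the melanin fraction", {
  lat_tight <- default_feather_lattice(gap_g = 10, n_layers = 3)
  lat_loose <- default_feather_lattice(gap_g = 120, n_layers = 3)
  expect_gt(packing_fraction(lat_tight), packing_fraction(lat_loose))
  g <- build_achp_geometry(lat_loose, delta = 5)
  expect_lt(raster_melanin_fraction(g), 0.35)
})
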
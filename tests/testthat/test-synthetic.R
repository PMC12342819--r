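test_that("population sampling is reproducible, respects constraints and hits its moments", {
  expect_equal(nrow(sample_population(population_params(n = 0))), 0)

  p <- population_params(n = 200, seed = 11)
  a <- sample_population(p); b <- sample_population(p)
  expect_identical(a, b)
  expect_true(all(a$x_nm <= a$y_nm))
  expect_true(all(a$x_nm > 0))

  big <- sample_population(population_params(n = 10000, seed = 3))
  expect_equal(mean(big$y_nm), 283, tolerance = 0.01)       # within 1%
  expect_equal(sd(big$y_nm) / mean(big$y_nm), 0.10, tolerance = 0.10)
  expect_equal(mean(big$z_nm), 1774, tolerance = 0.01)
})

test_that("a noise-free single circle round-trips through rendering and measurement", {
  pop <- sample_population(population_params(
    mean_x = 200, mean_y = 200.0001, mean_z = 1000, cv = 0, tilt_sd = 0,
    n = 1, seed = 1))
  img <- render_section(pop, default_feather_lattice(), pixel_size = 2,
                        noise_sigma = 0, seed = 1)
  mm <- measure_morphometry(img)
  # equivalent diameter within one pixel of the true 200 nm
  expect_lt(abs(mm$mean[["x_nm"]] - 200), 2)
  expect_lt(abs(mm$mean[["y_nm"]] - 200), 2)
})

test_that("a noise-free tilted ellipse is recovered to 2 px and 2 degrees", {
  pop <- sample_population(population_params(cv = 0, tilt_mean = 20,
                                             tilt_sd = 0, n = 1, seed = 1))
  img <- render_section(pop, default_feather_lattice(), pixel_size = 2,
                        noise_sigma = 0, seed = 1)
  mm <- measure_morphometry(img)
  expect_lt(abs(mm$mean[["x_nm"]] - 186), 4)   # 2 px at 2 nm/px
  expect_lt(abs(mm$mean[["y_nm"]] - 283), 4)
  expect_lt(abs(mm$mean[["tilt_deg"]] - 20), 2)
})

test_that("rendering is deterministic and records one truth row per particle", {
  pop <- sample_population(population_params(n = 40, seed = 5))
  i1 <- render_section(pop, default_feather_lattice(), seed = 9)
  i2 <- render_section(pop, default_feather_lattice(), seed = 9)
  expect_identical(i1$pixels, i2$pixels)
  expect_equal(nrow(i1$truth), 40)
  i3 <- render_section(pop, default_feather_lattice(), seed = 10)
  expect_false(identical(i1$pixels, i3$pixels))
})

test_that("border-touching particles are excluded from the measurement", {
  pop <- sample_population(population_params(n = 1, cv = 0, tilt_sd = 0,
                                             seed = 2))
  img <- render_section(pop, default_feather_lattice(), pixel_size = 5,
                        noise_sigma = 0, seed = 1)
  # shift the particle onto the border by cropping the image at its centre
  cy <- round(img$truth$cy_px[1])
  img$pixels <- img$pixels[cy:nrow(img$pixels), ]
  expect_error(measure_morphometry(img), "survived")
})

test_that("noisy population measurement recovers the generator means within a few percent", {
  pop <- sample_population(population_params(n = 150, seed = 21))
  img <- render_section(pop, default_feather_lattice(), pixel_size = 5,
                        noise_sigma = 8 / 255, seed = 22)
  mm <- measure_morphometry(img)
  expect_gt(mm$n_measured, 120)
  expect_lt(abs(mm$mean[["y_nm"]] - 283) / 283, 0.03)
  expect_lt(abs(mm$mean[["x_nm"]] - 186) / 186, 0.03)

  lng <- render_longitudinal(pop, pixel_size = 5, noise_sigma = 8 / 255,
                             seed = 23)
  mm2 <- measure_morphometry(lng)
  expect_lt(abs(mm2$mean[["z_nm"]] - 1774) / 1774, 0.03)
})

test_that("parameter recovery holds across a grid of population shapes", {
  for (scale in c(0.7, 1.6)) {
    for (cv in c(0.05, 0.2)) {
      p <- population_params(mean_x = 186 * scale, mean_y = 283 * scale,
                             mean_z = 1774 * scale, cv = cv, n = 80,
                             seed = round(100 * scale + cv * 10))
      pop <- sample_population(p)
      lat <- lattice_spec(melanosome = melanosome_spec(
        x = 186 * scale, y = 283 * scale, z = 1774 * scale), gap_g = 40)
      img <- render_section(pop, lat, pixel_size = min(5, 186 * scale / 12),
                            noise_sigma = 8 / 255, seed = 3)
      mm <- measure_morphometry(img)
      expect_lt(abs(mm$mean[["y_nm"]] - 283 * scale) / (283 * scale), 0.05)
      expect_lt(abs(mm$mean[["x_nm"]] - 186 * scale) / (186 * scale), 0.05)
    }
  }
})
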
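test_that("lossless planar limit gives total reflectance of 1", {
  expect_equal(diffuse_reflectance(optical_properties(0, 1.0), 0), 1,
               tolerance = 1e-14)
  expect_equal(diffuse_reflectance(optical_properties(0, 0.3, 1.33), 0), 1,
               tolerance = 1e-14)
})

test_that("reflectance decreases in absorption and spatial frequency", {
  # operating domain: scattering-dominated media (mu_tr > 2 pi fx); at
  # frequencies beyond the transport scale the closed form genuinely folds
  mu_a <- exp(seq(log(0.001), log(0.5), length.out = 16))
  mu_s <- seq(0.5, 5, length.out = 16)
  fx <- seq(0, 0.15, length.out = 8)
  for (s in mu_s) {
    for (f in fx) {
      rd <- diffuse_reflectance(optical_properties(mu_a, s), f)
      expect_true(all(rd >= 0 & rd <= 1))
      expect_true(all(diff(rd) < 0))
    }
    for (a in mu_a[c(1, 8, 16)]) {
      rd <- diffuse_reflectance(optical_properties(a, s), fx)
      expect_true(all(diff(rd) <= 0))
    }
  }
})

test_that("invalid optical property inputs are rejected by field name", {
  expect_error(optical_properties(-0.01, 1), "mu_a")
  expect_error(optical_properties(0.01, 0), "mu_s_prime")
  expect_error(optical_properties(0.01, NA), "mu_s_prime")
  expect_error(optical_properties(0.01, 1, 0.9), "n_tissue")
  expect_error(diffuse_reflectance(optical_properties(0.01, 1), -0.1), "fx")
  expect_error(diffuse_reflectance(optical_properties(0.01, 1), Inf), "fx")
})

test_that("lookup tables hold the forward model on the grid and obey its order", {
  lut <- suppressWarnings(
    build_lut(c(0, 0.1), mu_a_range = c(0.005, 0.07),
              mu_s_range = c(0.5, 2), grid_sizes = c(8, 8)))
  expect_s3_class(lut, "sfdi_lut")
  # every entry equals the closed form at its node
  for (i in seq_along(lut$mu_a_grid))
    for (j in seq_along(lut$mu_s_grid)) {
      p <- optical_properties(lut$mu_a_grid[i], lut$mu_s_grid[j])
      expect_equal(lut$rd_low[i, j], diffuse_reflectance(p, 0))
      expect_equal(lut$rd_high[i, j], diffuse_reflectance(p, 0.1))
    }
  expect_true(all(lut$rd_low > 0 & lut$rd_low < 1))
  expect_true(all(lut$rd_high <= lut$rd_low))
  # strictly ordered in mu_a along every scattering column
  expect_true(all(apply(lut$rd_low, 2, function(col) all(diff(col) < 0))))
  # first mu_a row dominates all others
  expect_true(all(sweep(lut$rd_low[-1, ], 2, lut$rd_low[1, ], `<`)))
})

test_that("lookup table construction validates its ranges", {
  expect_error(build_lut(c(0.1, 0)), "ascending")
  expect_error(build_lut(mu_a_range = c(0.5, 0.001)), "ordered")
  expect_error(build_lut(grid_sizes = c(1, 8)), "grid_sizes")
  # marginal validity is recorded in the table metadata
  wide <- build_lut(mu_a_range = c(0.001, 0.5), mu_s_range = c(0.1, 5),
                    grid_sizes = c(4, 4))
  expect_match(wide$notes, "diffusion approximation")
  narrow <- build_lut(mu_a_range = c(0.005, 0.01), mu_s_range = c(0.5, 2),
                      grid_sizes = c(4, 4))
  expect_length(narrow$notes, 0)
})

test_that("lookup table archives round-trip losslessly", {
  lut <- suppressWarnings(build_lut(grid_sizes = c(16, 12)))
  path <- withr::local_tempfile(fileext = ".json")
  write_lut(lut, path)
  back <- read_lut(path)
  expect_equal(back$mu_a_grid, lut$mu_a_grid)
  expect_equal(back$mu_s_grid, lut$mu_s_grid)
  expect_equal(back$rd_low, lut$rd_low)
  expect_equal(back$rd_high, lut$rd_high)
  expect_identical(back$f_pair, lut$f_pair)
  expect_identical(back$model_tag, lut$model_tag)
})

test_that("photon Monte Carlo is seed-reproducible and rejects no scattering", {
  p <- optical_properties(0.01, 1.0)
  a <- monte_carlo_rd(p, c(0, 0.1), n_photons = 5000, seed = 7)
  b <- monte_carlo_rd(p, c(0, 0.1), n_photons = 5000, seed = 7)
  expect_identical(a$rd, b$rd)
  c2 <- monte_carlo_rd(p, c(0, 0.1), n_photons = 5000, seed = 8)
  expect_false(identical(a$rd, c2$rd))
  zero_scatter <- structure(list(mu_a = 0.01, mu_s_prime = 0, n_tissue = 1.4),
                            class = "sfdi_props")
  expect_error(monte_carlo_rd(zero_scatter, 0, n_photons = 5000),
               "random walk")
  expect_error(monte_carlo_rd(p, 0, n_photons = 10), "1000")
})

test_that("strong absorption drives Monte Carlo reflectance toward zero", {
  p <- optical_properties(20, 0.5)   # mu_a >> mu_s'
  est <- monte_carlo_rd(p, 0, n_photons = 5000, seed = 3)
  expect_lt(est$rd[1], 0.02)
})

test_that("Monte Carlo matches diffusion in the diffusive regime", {
  # single-node convergence check; the full grid runs in the acceptance suite
  p <- optical_properties(0.01, 1.0)
  est <- monte_carlo_rd(p, c(0, 0.1), n_photons = 2e5, seed = 5)
  dif <- diffuse_reflectance(p, c(0, 0.1))
  expect_lt(max(abs(est$rd - dif) / dif), 0.15)
})
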
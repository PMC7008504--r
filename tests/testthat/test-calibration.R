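test_that("phantom specs answer exact and interpolated property queries", {
  # single point: exact query only
  spec1 <- phantom_spec(800, 0.007, 0.93)
  p <- phantom_properties_at(spec1, 800)
  expect_equal(p$mu_a, 0.007)
  expect_equal(p$mu_s_prime, 0.93)
  expect_error(phantom_properties_at(spec1, 735), "exact-wavelength")

  # collinear absorption knots: spline reproduces the line
  wl <- c(660, 735, 865)
  mu_a_line <- 0.002 + 1e-5 * wl
  spec3 <- phantom_spec(wl, mu_a_line, 0.93 * (wl / 800)^-1.2)
  for (q in c(700, 760, 800))
    expect_equal(phantom_properties_at(spec3, q)$mu_a, 0.002 + 1e-5 * q,
                 tolerance = 1e-12)

  # scattering points generated from a power law are recovered exactly
  law_pts <- 0.93 * (wl / 800)^(-1.2)
  spec_pl <- phantom_spec(wl, rep(0.007, 3), law_pts)
  expect_equal(phantom_properties_at(spec_pl, 800)$mu_s_prime, 0.93,
               tolerance = 1e-10)
  # cross-check against a log-space linear fit oracle
  fit <- lm(log(law_pts) ~ log(wl / 800))
  expect_equal(phantom_properties_at(spec_pl, 750)$mu_s_prime,
               exp(unname(coef(fit)[1])) * (750 / 800)^unname(coef(fit)[2]),
               tolerance = 1e-10)

  expect_error(phantom_properties_at(spec3, 600), "span")
  expect_error(phantom_spec(c(800, 700), c(0.007, 0.01), 0.9),
               "increasing")
  expect_error(phantom_spec(800, -0.007, 0.93), "positive")
})

test_that("predicted phantom reflectance follows the forward model", {
  spec <- phantom_spec(800, 0.007, 0.93)
  expect_equal(predict_reference_rd(spec, 800, 0),
               diffuse_reflectance(optical_properties(0.007, 0.93), 0))
  expect_lt(predict_reference_rd(spec, 800, 0.1),
            predict_reference_rd(spec, 800, 0))
})

test_that("calibration ratio obeys identity and linearity", {
  m <- sfdi_map(flat_matrix(1200, c(8L, 8L)), wavelength = 800, fx = 0.1,
                kind = "modulation")
  pred <- 0.42
  expect_equal(calibrate(m, m, pred)$values, flat_matrix(pred, c(8L, 8L)),
               tolerance = 1e-14)
  m2 <- sfdi_map(2 * m$values, wavelength = 800, fx = 0.1)
  expect_equal(calibrate(m2, m, pred)$values,
               flat_matrix(2 * pred, c(8L, 8L)), tolerance = 1e-14)
})

test_that("cross-channel calibration is refused", {
  a <- sfdi_map(flat_matrix(1, c(4L, 4L)), wavelength = 800, fx = 0.1)
  b <- sfdi_map(flat_matrix(1, c(4L, 4L)), wavelength = 735, fx = 0.1)
  d <- sfdi_map(flat_matrix(1, c(4L, 4L)), wavelength = 800, fx = 0)
  expect_error(calibrate(a, b, 0.4), "channel mismatch")
  expect_error(calibrate(a, d, 0.4), "channel mismatch")
})

test_that("reference pixels at the noise floor are masked, not divided", {
  ref <- flat_matrix(1000, c(4L, 4L))
  ref[1, 1] <- 1e-9
  m_ref <- sfdi_map(ref, wavelength = 800, fx = 0)
  m_s <- sfdi_map(flat_matrix(500, c(4L, 4L)), wavelength = 800, fx = 0)
  out <- calibrate(m_s, m_ref, 0.5)
  expect_false(out$mask[1, 1])
  expect_true(all(out$mask[-1]))
  expect_true(is.na(out$values[1, 1]))
})

test_that("a shared gain map cancels exactly through calibration", {
  set.seed(11)
  shape <- c(24L, 24L)
  gain <- matrix(runif(prod(shape), 0.2, 3), shape[1], shape[2])
  inst <- instrument_model(gain_map = gain)
  scene <- flat_scene(0.02, 1.4, shape)
  phant <- phantom_spec(800, 0.007, 0.93)
  s_stack <- simulate_raw_stack(scene, inst, 800)
  r_stack <- simulate_reference_stack(phant, inst, 800, shape)
  mods_s <- demodulate_stack(s_stack)
  mods_r <- demodulate_stack(r_stack)
  for (f in c(0, 0.1)) {
    rd <- calibrate(modulation_map(mods_s, 800, f),
                    modulation_map(mods_r, 800, f),
                    predict_reference_rd(phant, 800, f))
    truth <- diffuse_reflectance(optical_properties(0.02, 1.4), f)
    expect_lt(max(abs(rd$values - truth)), 1e-10)
  }
})

test_that("phantom specs survive the CSV + JSON header round trip", {
  spec <- phantom_spec(c(660, 735, 865), c(0.008, 0.0075, 0.0072),
                       c(1.18, 1.05, 0.88), n_tissue = 1.37, name = "p9")
  csv <- withr::local_tempfile(fileext = ".csv")
  write_phantom_spec(spec, csv)
  back <- read_phantom_spec(csv)
  expect_equal(back$wavelength, spec$wavelength)
  expect_equal(back$mu_a, spec$mu_a)
  expect_equal(back$mu_s_prime, spec$mu_s_prime)
  expect_equal(attr(back, "n_tissue"), 1.37)
  expect_identical(attr(back, "name"), "p9")
})
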
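test_that("phase stepping recovers the fringe phase over a grid of offsets", {
  for (phi0 in seq(-2.8, 2.8, by = 0.7)) {
    fr <- lapply(c(0, 2 * pi / 3, 4 * pi / 3), function(p)
      flat_matrix(10 + 2 * cos(phi0 + p), c(6L, 6L)))
    pm <- extract_phase(fr[[1]], fr[[2]], fr[[3]])
    expect_true(all(pm$mask))
    expect_equal(pm$phase, flat_matrix(phi0, c(6L, 6L)), tolerance = 1e-10)
    # offset invariance
    pm2 <- extract_phase(fr[[1]] + 3, fr[[2]] + 3, fr[[3]] + 3)
    expect_equal(pm2$phase, pm$phase, tolerance = 1e-10)
  }
})

test_that("unmodulated pixels have undefined phase and are masked", {
  c7 <- flat_matrix(7, c(5L, 5L))
  pm <- extract_phase(c7, c7, c7)
  expect_false(any(pm$mask))
  expect_true(all(is.na(pm$phase)))
  expect_error(unwrap_phase(pm), "fully masked")
})

test_that("a wrapped linear ramp unwraps to the ramp modulo one global cycle", {
  shape <- c(8L, 1000L)
  truth <- matrix(rep(0.05 * (seq_len(shape[2]) - 1), each = shape[1]),
                  shape[1], shape[2])
  wrapped <- truth - 2 * pi * floor(truth / (2 * pi) + 0.5)
  pm <- structure(list(phase = wrapped,
                       quality = flat_matrix(1, shape),
                       mask = matrix(TRUE, shape[1], shape[2]),
                       wrapped = TRUE),
                  class = "sfdi_phase_map")
  un <- unwrap_phase(pm)
  resid <- un$phase - truth
  k <- round(resid[1, 1] / (2 * pi))
  expect_equal(resid, flat_matrix(2 * pi * k, shape), tolerance = 1e-9)
})

test_that("an already-continuous map is left unchanged", {
  set.seed(2)
  base <- matrix(cumsum(rnorm(30, 0, 0.05)), 5, 6)  # range well below 2*pi
  pm <- structure(list(phase = base, quality = flat_matrix(1, c(5L, 6L)),
                       mask = matrix(TRUE, 5, 6), wrapped = TRUE),
                  class = "sfdi_phase_map")
  expect_equal(unwrap_phase(pm)$phase, base, tolerance = 1e-12)
})

test_that("unwrapping a hemispheric phase leaves no residual jumps", {
  shape <- c(96L, 96L); pitch <- 0.3
  hemi <- make_hemisphere_scene(17.5, shape = shape, pixel_pitch = pitch)
  inst <- instrument_model(pixel_pitch = pitch, phase_height_gain = 2)
  flat <- flat_scene(0.01, 1.0, shape, pixel_pitch = pitch)
  fo <- stack_frames(simulate_raw_stack(hemi, inst, 800), 800, 0.1)
  fr <- stack_frames(simulate_raw_stack(flat, inst, 800), 800, 0.1)
  dphi <- phase_difference(extract_phase(fo[[1]], fo[[2]], fo[[3]]),
                           extract_phase(fr[[1]], fr[[2]], fr[[3]]))
  un <- unwrap_phase(dphi)
  jumps_r <- abs(diff(un$phase))          # along rows
  jumps_c <- abs(t(diff(t(un$phase))))    # along columns
  expect_lt(max(jumps_r, jumps_c), pi)
})

test_that("height calibration recovers a uniform gain exactly", {
  shape <- c(10L, 10L)
  mk <- function(phi, wrapped = FALSE)
    structure(list(phase = flat_matrix(phi, shape),
                   quality = flat_matrix(1, shape),
                   mask = matrix(TRUE, shape[1], shape[2]),
                   wrapped = wrapped),
              class = "sfdi_phase_map")
  # unwrapped maps, gain 0.5 mm/rad: phase = h / 0.5
  stacks <- lapply(c(0, 1, 2, 3), function(h)
    list(height = h, phase = mk(h / 0.5)))
  cal <- calibrate_height(stacks)
  expect_equal(cal$gain, flat_matrix(0.5, shape), tolerance = 1e-12)
  expect_equal(cal$reference_phase, flat_matrix(0, shape), tolerance = 1e-12)
  # two-point minimal input is an exact fit
  cal2 <- calibrate_height(list(list(height = 1, phase = mk(2)),
                                list(height = 3, phase = mk(6))))
  expect_equal(cal2$gain, flat_matrix(0.5, shape), tolerance = 1e-12)
  expect_error(calibrate_height(list(list(height = 1, phase = mk(2)))),
               ">= 2 heights")
  # zero phase spread masks the pixel
  calz <- calibrate_height(list(list(height = 0, phase = mk(1)),
                                list(height = 2, phase = mk(1))))
  expect_false(any(calz$mask))
})

test_that("height calibration tolerates seeded phase noise", {
  set.seed(13)
  shape <- c(40L, 40L)
  heights <- c(0, 1.5, 3, 4.5, 6)
  stacks <- lapply(heights, function(h) {
    phase <- flat_matrix(h / 2, shape) +
      matrix(rnorm(prod(shape), 0, 0.01), shape[1], shape[2])
    list(height = h,
         phase = structure(list(phase = phase,
                                quality = flat_matrix(1, shape),
                                mask = matrix(TRUE, shape[1], shape[2]),
                                wrapped = FALSE),
                           class = "sfdi_phase_map"))
  })
  cal <- calibrate_height(stacks)
  rel <- abs(cal$gain - 2) / 2
  expect_gte(mean(rel < 0.02), 0.99)
})

test_that("phase converts to height against the calibrated reference plane", {
  shape <- c(12L, 15L)
  cal <- structure(list(gain = flat_matrix(2, shape),
                        reference_phase = flat_matrix(0.3, shape),
                        mask = matrix(TRUE, shape[1], shape[2])),
                   class = "sfdi_height_cal")
  at_ref <- structure(list(phase = flat_matrix(0.3, shape),
                           quality = flat_matrix(1, shape),
                           mask = matrix(TRUE, shape[1], shape[2]),
                           wrapped = FALSE),
                      class = "sfdi_phase_map")
  expect_equal(phase_to_height(at_ref, cal)$values,
               flat_matrix(0, shape))
  # tilted plane: height = 0.1 * col in mm
  tilt <- matrix(rep(0.1 * seq_len(shape[2]), each = shape[1]),
                 shape[1], shape[2])
  pm <- at_ref; pm$phase <- 0.3 + tilt / 2
  hm <- phase_to_height(pm, cal)
  fit <- lm(as.vector(hm$values) ~ as.vector(col(hm$values)))
  expect_equal(unname(coef(fit)), c(0, 0.1), tolerance = 1e-10)
})

test_that("intensity-height correction is exact on its own linear model", {
  set.seed(21)
  shape <- c(9L, 9L)
  slope <- matrix(rnorm(prod(shape), -3, 0.5), shape[1], shape[2])
  base <- matrix(runif(prod(shape), 100, 200), shape[1], shape[2])
  stacks <- lapply(c(0, 2, 5), function(h)
    list(height = h, image = base + slope * h))
  model <- fit_intensity_height_model(stacks)
  expect_equal(model$slope, slope, tolerance = 1e-10)
  expect_equal(model$intercept, base, tolerance = 1e-10)
  h_map <- flat_matrix(3.7, shape)
  corrected <- apply_intensity_height_correction(base + slope * 3.7,
                                                 h_map, model)
  expect_lt(max(abs(corrected - base)), 1e-10)
  # zero height map: no-op
  expect_equal(apply_intensity_height_correction(base, flat_matrix(0, shape),
                                                 model), base)
  # null model: no-op for any height map
  model0 <- model; model0$slope <- flat_matrix(0, shape)
  expect_equal(apply_intensity_height_correction(base, h_map, model0), base)
  expect_error(fit_intensity_height_model(stacks[1]), ">= 2 heights")
  expect_error(apply_intensity_height_correction(base[1:3, ], h_map, model),
               "shape mismatch")
})

test_that("the hemisphere profile reconstructs within a tenth of a millimeter", {
  shape <- c(128L, 128L); pitch <- 0.3
  hemi <- make_hemisphere_scene(17.5, shape = shape, pixel_pitch = pitch)
  flat <- flat_scene(0.01, 1.0, shape, pixel_pitch = pitch)
  inst <- instrument_model(pixel_pitch = pitch, phase_height_gain = 2)
  ph_of <- function(scene) {
    fr <- stack_frames(simulate_raw_stack(scene, inst, 800), 800, 0.1)
    extract_phase(fr[[1]], fr[[2]], fr[[3]])
  }
  ph_ref <- ph_of(flat)
  cal <- calibrate_height(lapply(c(0, 2, 4), function(h) {
    sc <- flat_scene(0.01, 1.0, shape, height = h, pixel_pitch = pitch)
    list(height = h, phase = phase_difference(ph_of(sc), ph_ref))
  }))
  un <- unwrap_phase(phase_difference(ph_of(hemi), ph_ref))
  border <- matrix(FALSE, shape[1], shape[2]); border[1:8, ] <- TRUE
  hm <- phase_to_height(rebase_phase(un, border), cal)
  err <- hm$values - hemi$height_map
  expect_lt(sqrt(mean(err[hm$mask]^2)), 0.1)
})
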
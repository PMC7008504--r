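test_that("noiseless rendering demodulates back to the forward model", {
  scene <- flat_scene(0.015, 1.1, c(20L, 40L))
  inst <- instrument_model()
  stack <- simulate_raw_stack(scene, inst, 800)
  mods <- demodulate_stack(stack)
  p <- optical_properties(0.015, 1.1)
  expect_equal(modulation_map(mods, 800, 0)$values,
               flat_matrix(diffuse_reflectance(p, 0), c(20L, 40L)),
               tolerance = 1e-12)
  expect_equal(modulation_map(mods, 800, 0.1)$values,
               flat_matrix(0.8 * diffuse_reflectance(p, 0.1), c(20L, 40L)),
               tolerance = 1e-12)
})

test_that("noisy rendering is deterministic per seed and leaves R's RNG alone", {
  scene <- flat_scene(0.01, 1, c(12L, 12L))
  inst <- instrument_model(noise = "default", seed = 99)
  set.seed(1); before <- runif(1)
  set.seed(1)
  a <- simulate_raw_stack(scene, inst, 800)
  after <- runif(1)
  expect_identical(before, after)      # global stream untouched
  b <- simulate_raw_stack(scene, inst, 800)
  expect_identical(a$frames, b$frames)
  inst2 <- instrument_model(noise = "default", seed = 100)
  c2 <- simulate_raw_stack(scene, inst2, 800)
  expect_false(identical(a$frames, c2$frames))
})

test_that("frequencies beyond the sampling limit are refused", {
  scene <- flat_scene()
  inst <- instrument_model(frequencies = c(0, 2.0), pixel_pitch = 0.3)
  expect_error(simulate_raw_stack(scene, inst, 800), "Nyquist")
})

test_that("phantom grid scenes carry their stated range and bookkeeping", {
  scene <- make_phantom_grid_scene(3, 3, shape = c(60L, 60L))
  tr <- scene$truth
  expect_equal(nrow(tr), 9)
  corner_ll <- tr[tr$block_row == 1 & tr$block_col == 1, ]
  corner_ur <- tr[tr$block_row == 3 & tr$block_col == 3, ]
  expect_equal(c(corner_ll$mu_a, corner_ll$mu_s_prime), c(0.005, 0.5))
  expect_equal(c(corner_ur$mu_a, corner_ur$mu_s_prime), c(0.07, 2.0))
  # truth table and painted maps agree block by block
  for (i in seq_len(nrow(tr))) {
    r <- (tr$row0[i] + 1):tr$row1[i]; cc <- (tr$col0[i] + 1):tr$col1[i]
    expect_true(all(scene$mu_a[[1]][r, cc] == tr$mu_a[i]))
    expect_true(all(scene$mu_s_prime[[1]][r, cc] == tr$mu_s_prime[i]))
  }
  # degenerate grid sits at the midpoints
  one <- make_phantom_grid_scene(1, 1, shape = c(8L, 8L))
  expect_equal(one$truth$mu_a, 0.0375)
  expect_equal(one$truth$mu_s_prime, 1.25)
})

test_that("hemisphere scenes have the right apex, footprint and volume", {
  scene <- make_hemisphere_scene(17.5, shape = c(200L, 200L),
                                 pixel_pitch = 0.15)
  h <- scene$height_map
  expect_equal(max(h), 8.75, tolerance = 1e-3)
  # zero outside the disc footprint
  yc <- (200 + 1) / 2
  d <- sqrt(outer(((seq_len(200) - yc) * 0.15)^2,
                  ((seq_len(200) - yc) * 0.15)^2, `+`))
  expect_true(all(h[d > 8.75 + 0.3] == 0))
  # numerically integrated volume vs (2/3) pi r^3
  vol <- sum(h) * 0.15^2
  expect_equal(vol, 2 / 3 * pi * 8.75^3, tolerance = 0.01)
  expect_error(make_hemisphere_scene(100, shape = c(64L, 64L),
                                     pixel_pitch = 0.3),
               "field of view")
})

test_that("chromophore scenes realize the extinction model per wavelength", {
  tabx <- read_extinction_table()
  conc <- list(hbo2 = flat_matrix(22, c(6L, 6L)),
               hhb = flat_matrix(9, c(6L, 6L)))
  scene <- make_chromophore_scene(conc, c(660, 735, 865), tabx,
                                  scatter_a = 0.9, scatter_b = 1.1)
  E <- interpolate_extinction(tabx, c(660, 735, 865))
  for (i in 1:3) {
    wl <- c(660, 735, 865)[i]
    expect_equal(scene$mu_a[[as.character(wl)]][1, 1],
                 unname(E[i, "hbo2"] * 22 + E[i, "hhb"] * 9),
                 tolerance = 1e-12)
    expect_equal(scene$mu_s_prime[[as.character(wl)]][1, 1],
                 0.9 * (wl / 800)^(-1.1), tolerance = 1e-12)
  }
})

test_that("stack accessor names the offending channel on incomplete triplets", {
  scene <- flat_scene()
  stack <- simulate_raw_stack(scene, instrument_model(), 800)
  expect_error(stack_frames(stack, 800, 0.2), "800 nm, fx 0.2")
  stack$frames <- stack$frames[-1]
  stack$index <- stack$index[-1, ]
  expect_error(stack_frames(stack, 800, 0), "need 3")
})
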
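tab <- read_extinction_table()

test_that("the shipped extinction fixture is well formed", {
  expect_s3_class(tab, "sfdi_extinction")
  expect_true(all(diff(tab$wavelength) > 0))
  expect_true(all(tab$hbo2 > 0) && all(tab$hhb > 0))
  d <- tab$hbo2 - tab$hhb
  expect_true(all(d[tab$wavelength < 795] < 0))
  expect_true(all(d[tab$wavelength > 805] > 0))
})

test_that("extinction interpolation is exact at rows and linear between", {
  k <- 10
  at_row <- interpolate_extinction(tab, tab$wavelength[k])
  expect_equal(unname(at_row[1, ]), c(tab$hbo2[k], tab$hhb[k]))
  mid <- (tab$wavelength[k] + tab$wavelength[k + 1]) / 2
  at_mid <- interpolate_extinction(tab, mid)
  expect_equal(unname(at_mid[1, "hbo2"]), (tab$hbo2[k] + tab$hbo2[k + 1]) / 2)
  expect_equal(unname(at_mid[1, "hhb"]), (tab$hhb[k] + tab$hhb[k + 1]) / 2)
  expect_error(interpolate_extinction(tab, 500), "span")
})

test_that("interior extinction queries are bracketed by their neighbors", {
  set.seed(8)
  q <- runif(50, min(tab$wavelength), max(tab$wavelength))
  eps <- interpolate_extinction(tab, q)
  for (i in seq_along(q)) {
    k <- findInterval(q[i], tab$wavelength)
    k2 <- min(k + 1, nrow(tab))
    expect_gte(eps[i, "hbo2"], min(tab$hbo2[k], tab$hbo2[k2]) - 1e-15)
    expect_lte(eps[i, "hbo2"], max(tab$hbo2[k], tab$hbo2[k2]) + 1e-15)
  }
})

test_that("forward-constructed absorption unmixes to the true concentrations", {
  wls <- c(660, 735, 865)
  E <- interpolate_extinction(tab, wls)
  mu_a <- as.vector(E %*% c(10, 20))
  got <- fit_chromophores(mu_a, wls, tab)
  expect_equal(got$hbo2, 10, tolerance = 1e-8)
  expect_equal(got$hhb, 20, tolerance = 1e-8)
  expect_lt(got$residual, 1e-12)
  # zero absorption: null solution
  got0 <- fit_chromophores(rep(0, 3), wls, tab)
  expect_equal(unname(unlist(got0[1, c("hbo2", "hhb")])), c(0, 0))
  expect_equal(got0$residual, 0)
})

test_that("the unconstrained solve is scale equivariant", {
  wls <- c(660, 735, 865)
  E <- interpolate_extinction(tab, wls)
  mu_a <- as.vector(E %*% c(12, 7)) * (1 + c(0.03, -0.02, 0.01))
  c1 <- fit_chromophores(mu_a, wls, tab, nonnegative = FALSE)
  c2 <- fit_chromophores(2 * mu_a, wls, tab, nonnegative = FALSE)
  expect_equal(2 * c1$hbo2, c2$hbo2, tolerance = 1e-10)
  expect_equal(2 * c1$hhb, c2$hhb, tolerance = 1e-10)
})

test_that("nonnegative unmixing clamps at the constraint like a grid search", {
  wls <- c(660, 735, 865)
  E <- interpolate_extinction(tab, wls)
  mu_a <- as.vector(E %*% c(5, -1))
  un <- fit_chromophores(mu_a, wls, tab, nonnegative = FALSE)
  expect_lt(un$hhb, 0)
  nn <- fit_chromophores(mu_a, wls, tab, nonnegative = TRUE)
  expect_equal(nn$hhb, 0)
  expect_gt(nn$residual, 0)
  oracle <- nnls_grid_oracle(E, mu_a, cmax = 10, step = 0.001)
  expect_equal(nn$hbo2, oracle$coef[1], tolerance = 1e-3)
  expect_equal(nn$residual^2, oracle$rss, tolerance = 1e-6)
})

test_that("a pure-oxyhemoglobin pixel fits with zero residual", {
  wls <- c(660, 735, 865)
  E <- interpolate_extinction(tab, wls)
  got <- fit_chromophores(as.vector(E[, "hbo2"] * 25), wls, tab)
  expect_lt(got$residual, 1e-12)
  expect_equal(got$hbo2, 25, tolerance = 1e-8)
})

test_that("underdetermined or degenerate unmixing inputs are rejected", {
  expect_error(fit_chromophores(0.01, 800, tab), "underdetermined")
  expect_error(fit_chromophores(c(0.01, 0.01), c(735, 735), tab),
               "duplicate")
})

test_that("scatter power-law fits are exact on noiseless data", {
  wls <- c(660, 735, 865)
  law <- fit_scatter_power_law(1.0 * (wls / 800)^(-1.3), wls)
  expect_equal(law$a, 1.0, tolerance = 1e-12)
  expect_equal(law$b, 1.3, tolerance = 1e-12)
  flat <- fit_scatter_power_law(rep(0.93, 3), wls)
  expect_equal(flat$a, 0.93, tolerance = 1e-12)
  expect_equal(flat$b, 0, tolerance = 1e-12)
  expect_error(fit_scatter_power_law(c(1, -0.5, 0.8), wls), "positive")
  expect_error(fit_scatter_power_law(0.9, 800), "2 distinct")
  td <- tidy(law)
  expect_equal(td$estimate[td$term == "b"], 1.3, tolerance = 1e-12)
})

test_that("scatter power recovery stays tight under 5 percent noise", {
  # tolerance below was fixed by a 200-replicate simulation of this model
  set.seed(19)
  wls <- c(660, 735, 865)
  truth <- 1.1 * (wls / 800)^(-1.2)
  err_b <- replicate(200, {
    noisy <- truth * exp(rnorm(3, 0, 0.05))
    abs(fit_scatter_power_law(noisy, wls)$b - 1.2)
  })
  expect_lt(median(err_b), 0.35)
})

test_that("spline interpolation matches an independent tridiagonal solver", {
  wl <- c(621, 691, 731, 811, 851)
  mu_a <- 0.01 + 0.004 * sin(wl / 60)
  q <- c(660, 735, 800)
  got <- interpolate_mu_a_spline(wl, mu_a, q)
  oracle <- tridiag_natural_spline(wl, mu_a, q)
  expect_equal(as.numeric(got), oracle, tolerance = 1e-10)
  expect_identical(attr(got, "method"), "natural_spline")
  # knot identity and linear reproduction
  expect_equal(as.numeric(interpolate_mu_a_spline(wl, mu_a, wl)),
               mu_a, tolerance = 1e-12)
  line <- 0.001 * wl
  expect_equal(as.numeric(interpolate_mu_a_spline(wl, line, q)),
               0.001 * q, tolerance = 1e-10)
  # two knots fall back to linear, extrapolation refused
  two <- interpolate_mu_a_spline(c(700, 800), c(0.01, 0.02), 750)
  expect_identical(attr(two, "method"), "linear")
  expect_equal(as.numeric(two), 0.015)
  expect_error(interpolate_mu_a_spline(wl, mu_a, 900), "span")
})
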
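# shared builders for synthetic fixtures; all randomness is locally seeded

flat_matrix <- function(value, shape = c(32L, 32L)) {
  matrix(value, shape[1], shape[2])
}

flat_scene <- function(mu_a = 0.01, mu_s = 1.0, shape = c(32L, 32L),
                       height = NULL, pixel_pitch = 0.3) {
  sfdi_scene(flat_matrix(mu_a, shape), flat_matrix(mu_s, shape),
             height_map = if (!is.null(height)) flat_matrix(height, shape),
             pixel_pitch = pixel_pitch)
}

# ideal three-phase sinusoid triplet over a column coordinate
sinusoid_triplet <- function(offset, amplitude, fx = 0.1, pitch = 0.3,
                             phi0 = 0, shape = c(16L, 64L)) {
  x <- matrix(rep((seq_len(shape[2]) - 1) * pitch, each = shape[1]),
              shape[1], shape[2])
  lapply(c(0, 2 * pi / 3, 4 * pi / 3), function(p)
    offset + amplitude * cos(2 * pi * fx * x + phi0 + p))
}

# independent natural cubic spline: textbook tridiagonal solve for the
# second derivatives, then piecewise cubic evaluation (oracle for
# interpolate_mu_a_spline; shares no code with the implementation)
tridiag_natural_spline <- function(x, y, xout) {
  n <- length(x)
  h <- diff(x)
  # tridiagonal system for interior second derivatives m[2..n-1]; m1=mn=0
  # row k (knot i = k+1): h[i-1] m[i-1] + 2(h[i-1]+h[i]) m[i] + h[i] m[i+1]
  a <- if (n > 3) c(0, h[2:(n - 2)]) else 0   # sub-diagonal: h[k]
  b <- 2 * (h[-(n - 1)] + h[-1])
  cc <- c(h[-1])                              # super-diagonal: h[k+1]
  rhs <- 6 * ((y[-(1:2)] - y[-c(1, n)]) / h[-1] -
                (y[-c(1, n)] - y[-((n - 1):n)]) / h[-(n - 1)])
  ni <- n - 2
  m <- numeric(n)
  if (ni == 1) {
    m[2] <- rhs / b
  } else if (ni > 1) {
    # Thomas algorithm
    cp <- numeric(ni); dp <- numeric(ni)
    cp[1] <- cc[1] / b[1]; dp[1] <- rhs[1] / b[1]
    for (i in 2:ni) {
      den <- b[i] - a[i] * cp[i - 1]
      cp[i] <- if (i < ni) cc[i] / den else 0
      dp[i] <- (rhs[i] - a[i] * dp[i - 1]) / den
    }
    sol <- numeric(ni)
    sol[ni] <- dp[ni]
    if (ni > 1) for (i in (ni - 1):1) sol[i] <- dp[i] - cp[i] * sol[i + 1]
    m[2:(n - 1)] <- sol
  }
  vapply(xout, function(q) {
    i <- findInterval(q, x, rightmost.closed = TRUE)
    i <- min(max(i, 1), n - 1)
    t <- q - x[i]
    hi <- h[i]
    y[i] +
      t * ((y[i + 1] - y[i]) / hi - hi * (2 * m[i] + m[i + 1]) / 6) +
      t^2 * m[i] / 2 +
      t^3 * (m[i + 1] - m[i]) / (6 * hi)
  }, numeric(1))
}

# exhaustive nonnegative least squares over a concentration grid (oracle
# for the constrained chromophore solve, 2 chromophores)
nnls_grid_oracle <- function(E, b, cmax = 50, step = 0.05) {
  grid <- seq(0, cmax, by = step)
  best <- c(NA, NA); best_r <- Inf
  for (c1 in grid) {
    r1 <- b - E[, 1] * c1
    # optimal c2 >= 0 given c1 has closed form; grid only over c1
    c2 <- max(0, sum(E[, 2] * r1) / sum(E[, 2]^2))
    r <- sum((r1 - E[, 2] * c2)^2)
    if (r < best_r) { best_r <- r; best <- c(c1, c2) }
  }
  list(coef = best, rss = best_r)
}
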
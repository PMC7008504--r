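#' Extinction coefficient table
#'
#' Molar extinction coefficients of the fitted chromophores (by default
#' oxy- and deoxyhemoglobin) on a strictly increasing wavelength grid, in
#' mm^-1 per micromolar. Columns after `wavelength` are chromophore names;
#' for the hemoglobin pair the two spectra must cross near the 800 nm
#' isosbestic point (oxyhemoglobin below deoxyhemoglobin at shorter
#' wavelengths, above at longer).
#'
#' @param wavelength Wavelengths, nm, strictly increasing.
#' @param ... Named numeric vectors of extinction coefficients
#'   (mm^-1 uM^-1), one per chromophore, e.g. `hbo2 = ..., hhb = ...`.
#' @return An `sfdi_extinction` tibble.
#' @export
extinction_table <- function(wavelength, ...) {
  check_finite_numeric(wavelength, "wavelength")
  if (is.unsorted(wavelength, strictly = TRUE))
    stop("wavelengths must be strictly increasing", call. = FALSE)
  cols <- list(...)
  if (length(cols) < 1 || is.null(names(cols)) || any(names(cols) == ""))
    stop("supply named extinction columns", call. = FALSE)
  for (nm in names(cols)) {
    check_finite_numeric(cols[[nm]], nm)
    if (any(cols[[nm]] <= 0))
      stop("extinction coefficients must be > 0: ", nm, call. = FALSE)
    if (length(cols[[nm]]) != length(wavelength))
      stop("column length mismatch: ", nm, call. = FALSE)
  }
  if (all(c("hbo2", "hhb") %in% names(cols)) &&
      min(wavelength) < 800 && max(wavelength) > 800) {
    d <- cols$hbo2 - cols$hhb
    if (!(any(d[wavelength < 790] < 0) && any(d[wavelength > 810] > 0)))
      warning(paste("hemoglobin columns do not cross near the 800 nm",
                    "isosbestic point; check the table"), call. = FALSE)
  }
  out <- tibble::tibble(wavelength = wavelength, !!!cols)
  structure(out, class = c("sfdi_extinction", class(out)))
}

#' Load an extinction table from CSV
#'
#' Expected columns: `wavelength_nm` then one extinction column per
#' chromophore named `eps_<name>_per_mm_per_uM` (or any bare names). With no
#' path, loads the synthetic hemoglobin fixture shipped with the package
#' (660-900 nm in 5 nm steps; physically shaped oxy/deoxy spectra with the
#' isosbestic crossing near 800 nm, constructed for self-consistent testing
#' rather than copied from a literature compilation).
#'
#' @param path CSV path; default the shipped synthetic hemoglobin table.
#' @return An `sfdi_extinction` tibble.
#' @export
read_extinction_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "extinction_hb_synthetic.csv",
                        package = "sfdi", mustWork = TRUE)
  df <- read.csv(path)
  wl_col <- grep("^wavelength", names(df), value = TRUE)[1]
  if (is.na(wl_col)) stop("no wavelength column in ", path, call. = FALSE)
  eps <- df[setdiff(names(df), wl_col)]
  names(eps) <- gsub("^eps_|_per_mm_per_um$", "", tolower(names(eps)))
  do.call(extinction_table, c(list(wavelength = df[[wl_col]]), as.list(eps)))
}

#' Interpolate extinction coefficients
#'
#' Linear interpolation of every chromophore column at the measured
#' illumination wavelengths (LED center wavelengths vary between builds, so
#' coefficients are always evaluated at the characterized wavelength, never
#' the nominal one). Queries outside the table span are rejected.
#'
#' @param table An `sfdi_extinction`.
#' @param wavelength Query wavelengths, nm.
#' @return Matrix with one row per query wavelength and one named column
#'   per chromophore (mm^-1 uM^-1).
#' @export
interpolate_extinction <- function(table, wavelength) {
  stopifnot(inherits(table, "sfdi_extinction"))
  check_finite_numeric(wavelength, "wavelength")
  wl <- table$wavelength
  if (any(wavelength < min(wl)) || any(wavelength > max(wl)))
    stop(sprintf("query outside table span [%g, %g] nm", min(wl), max(wl)),
         call. = FALSE)
  chrom <- setdiff(names(table), "wavelength")
  out <- vapply(chrom, function(nm)
    approx(wl, table[[nm]], xout = wavelength)$y, numeric(length(wavelength)))
  matrix(out, nrow = length(wavelength), ncol = length(chrom),
         dimnames = list(NULL, chrom))
}

# exact small-k nonnegative least squares by active-set enumeration,
# vectorized over observations (columns of B); E is m x k with k small
nnls_enumerate <- function(E, B) {
  k <- ncol(E)
  n <- ncol(B)
  best_c <- matrix(0, k, n)
  best_r <- colSums(B^2)             # empty active set: c = 0
  subsets <- lapply(seq_len(2^k - 1), function(m)
    which(bitwAnd(m, bitwShiftL(1L, seq_len(k) - 1L)) > 0))
  for (S in subsets) {
    Es <- E[, S, drop = FALSE]
    cs <- qr.coef(qr(Es), B)
    cs <- matrix(cs, nrow = length(S))
    feas <- colSums(cs < -1e-12) == 0
    if (!any(feas)) next
    resid <- colSums((B - Es %*% cs)^2)
    take <- feas & (resid < best_r - 1e-300) & (resid <= best_r)
    if (any(take)) {
      best_r[take] <- resid[take]
      best_c[, take] <- 0
      best_c[S, take] <- cs[, take, drop = FALSE]
    }
  }
  list(coef = pmax(best_c, 0), rss = pmax(best_r, 0))
}

#' Unmix chromophore concentrations from absorption spectra
#'
#' Solves, per pixel, the linear system `E c = mu_a` relating the absorption
#' coefficients measured at several wavelengths to chromophore
#' concentrations through the extinction matrix `E` (wavelengths x
#' chromophores, mm^-1 uM^-1). The least-squares solution requires at least
#' as many wavelengths as chromophores; with the nonnegativity option on
#' (the default — concentrations are physical) pixels whose unconstrained
#' solution goes negative are re-solved exactly over the nonnegative
#' quadrant by active-set enumeration. The per-pixel residual norm is kept
#' as a fit diagnostic.
#'
#' @param mu_a Either a list of per-wavelength images (`sfdi_property_map`,
#'   [sfdi_map()] or plain matrices), a numeric matrix with one column per
#'   wavelength (rows = observations), or a numeric vector (one pixel).
#' @param wavelengths Measurement wavelengths, nm, one per image/column.
#' @param table Extinction table; default the shipped synthetic hemoglobin
#'   fixture.
#' @param nonnegative Constrain concentrations to be >= 0 (default TRUE).
#' @return For image input, an `sfdi_chromophore_map` (per-chromophore
#'   concentration matrices in uM, `residual` in mm^-1, `mask`); otherwise
#'   a tibble with one row per observation.
#' @examples
#' tab <- read_extinction_table()
#' E <- interpolate_extinction(tab, c(660, 735, 865))
#' fit_chromophores(as.vector(E %*% c(10, 20)), c(660, 735, 865), tab)
#' @export
fit_chromophores <- function(mu_a, wavelengths, table = NULL,
                             nonnegative = TRUE) {
  table <- table %||% read_extinction_table()
  check_finite_numeric(wavelengths, "wavelengths")
  if (anyDuplicated(wavelengths))
    stop("duplicate wavelengths make the extinction matrix singular",
         call. = FALSE)
  E <- interpolate_extinction(table, wavelengths)
  k <- ncol(E)
  if (length(wavelengths) < k)
    stop(sprintf(
      "underdetermined system: %d wavelength(s) for %d chromophores",
      length(wavelengths), k), call. = FALSE)

  shape <- NULL; mask <- NULL
  if (is.list(mu_a) && !is.data.frame(mu_a)) {
    if (length(mu_a) != length(wavelengths))
      stop("one mu_a image per wavelength required", call. = FALSE)
    imgs <- lapply(mu_a, function(m) {
      if (inherits(m, "sfdi_property_map")) m$mu_a
      else if (inherits(m, "sfdi_map")) m$values
      else m
    })
    masks <- lapply(mu_a, function(m) {
      if (inherits(m, c("sfdi_property_map", "sfdi_map"))) m$mask
      else matrix(TRUE, nrow(m), ncol(m))
    })
    do.call(check_same_shape, c(imgs, list(what = "mu_a images")))
    shape <- dim(imgs[[1]])
    mask <- Reduce(`&`, masks)
    M <- do.call(cbind, lapply(imgs, as.vector))   # npix x nwl
  } else if (is.matrix(mu_a)) {
    if (ncol(mu_a) != length(wavelengths))
      stop("one mu_a column per wavelength required", call. = FALSE)
    M <- mu_a
  } else {
    if (length(mu_a) != length(wavelengths))
      stop("one mu_a value per wavelength required", call. = FALSE)
    M <- matrix(mu_a, nrow = 1)
  }

  B <- t(M)                                        # nwl x nobs
  usable <- apply(is.finite(B), 2, all)
  coefs <- matrix(NA_real_, k, ncol(B),
                  dimnames = list(colnames(E), NULL))
  rss <- rep(NA_real_, ncol(B))
  if (any(usable)) {
    Bu <- B[, usable, drop = FALSE]
    qrE <- qr(E)
    cu <- matrix(qr.coef(qrE, Bu), nrow = k)
    ru <- colSums((Bu - E %*% cu)^2)
    if (nonnegative) {
      neg <- colSums(cu < -1e-12) > 0
      if (any(neg)) {
        nn <- nnls_enumerate(E, Bu[, neg, drop = FALSE])
        cu[, neg] <- nn$coef
        ru[neg] <- nn$rss
      }
      cu <- pmax(cu, 0)
    }
    coefs[, usable] <- cu
    rss[usable] <- ru
  }
  residual <- sqrt(pmax(rss, 0))

  if (!is.null(shape)) {
    conc <- lapply(seq_len(k), function(j)
      matrix(coefs[j, ], shape[1], shape[2]))
    names(conc) <- colnames(E)
    ok <- mask & matrix(usable, shape[1], shape[2])
    structure(
      list(concentrations = conc,
           residual = matrix(residual, shape[1], shape[2]),
           mask = ok, wavelengths = wavelengths,
           chromophores = colnames(E), nonnegative = nonnegative),
      class = "sfdi_chromophore_map")
  } else {
    out <- tibble::as_tibble(as.data.frame(t(coefs)))
    out$residual <- residual
    out
  }
}

#' @export
print.sfdi_chromophore_map <- function(x, ...) {
  cat(sprintf("<sfdi_chromophore_map> %dx%d px; chromophores: %s\n",
              nrow(x$residual), ncol(x$residual),
              paste(x$chromophores, collapse = ", ")))
  for (nm in x$chromophores) {
    v <- x$concentrations[[nm]][x$mask]
    cat(sprintf("  %s: median %.3g uM [%.3g, %.3g]\n", nm,
                median(v), min(v), max(v)))
  }
  invisible(x)
}

#' Fit the reduced-scattering power law
#'
#' Fits `mu_s'(lambda) = a (lambda/lambda0)^-b` (lambda0 = 800 nm) to a
#' measured scattering spectrum by ordinary least squares in log space,
#' which is exact on noiseless power-law data. `a` (mm^-1) is the reduced
#' scattering at the reference wavelength and `b` the dimensionless scatter
#' power.
#'
#' @param mu_s_prime Positive scattering values, mm^-1.
#' @param wavelengths Matching wavelengths, nm (>= 2 distinct).
#' @param lambda0 Reference wavelength, nm (fixed 800 by convention).
#' @return An `sfdi_power_law` with `a`, `b`, `lambda0`, fitted values and
#'   the underlying data; supports [tidy()], [glance()] and [autoplot()].
#' @examples
#' fit_scatter_power_law(c(1.28, 1.12, 0.90), c(660, 735, 865))
#' @export
fit_scatter_power_law <- function(mu_s_prime, wavelengths, lambda0 = 800) {
  check_finite_numeric(wavelengths, "wavelengths")
  if (!is.numeric(mu_s_prime) || any(!is.finite(mu_s_prime)) ||
      any(mu_s_prime <= 0))
    stop("mu_s_prime must be positive (log-space fit undefined otherwise)",
         call. = FALSE)
  if (length(unique(wavelengths)) < 2)
    stop("need >= 2 distinct wavelengths", call. = FALSE)
  x <- log(wavelengths / lambda0)
  y <- log(mu_s_prime)
  fit <- lm(y ~ x)
  a <- exp(unname(coef(fit)[1]))
  b <- -unname(coef(fit)[2])
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - sum(fit$residuals^2) / tss else 1
  structure(
    list(a = a, b = b, lambda0 = lambda0,
         wavelengths = wavelengths, mu_s_prime = mu_s_prime,
         fitted = a * (wavelengths / lambda0)^(-b),
         r_squared = r2),
    class = "sfdi_power_law")
}

#' @export
print.sfdi_power_law <- function(x, ...) {
  cat(sprintf(
    "<sfdi_power_law> mu_s'(lambda) = %.4g (lambda/%g)^-%.4g mm^-1\n",
    x$a, x$lambda0, x$b))
  invisible(x)
}

#' @export
tidy.sfdi_power_law <- function(x, ...) {
  tibble::tibble(term = c("a", "b"), estimate = c(x$a, x$b))
}

#' @export
glance.sfdi_power_law <- function(x, ...) {
  tibble::tibble(a = x$a, b = x$b, lambda0 = x$lambda0,
                 r.squared = x$r_squared, nobs = length(x$wavelengths))
}

#' @exportS3Method ggplot2::autoplot
autoplot.sfdi_power_law <- function(object, ...) {
  grid <- seq(min(object$wavelengths), max(object$wavelengths),
              length.out = 200)
  df <- data.frame(wavelength = object$wavelengths,
                   mu_s_prime = object$mu_s_prime)
  dfit <- data.frame(wavelength = grid,
                     mu_s_prime = object$a * (grid / object$lambda0)^(-object$b))
  ggplot2::ggplot(df, ggplot2::aes(.data$wavelength, .data$mu_s_prime)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = dfit) +
    ggplot2::labs(x = "wavelength (nm)", y = "mu_s' (mm^-1)",
                  title = sprintf("a = %.3g mm^-1, b = %.3g",
                                  object$a, object$b))
}

#' Natural cubic spline interpolation of an absorption spectrum
#'
#' Harmonizes absorption measured at one instrument's wavelengths onto
#' another's: a natural cubic spline is fit through the measured knots and
#' evaluated at the query wavelengths. At least three knots give the cubic
#' fit; with exactly two the interpolant falls back to linear (recorded in
#' the `"method"` attribute). Queries outside the knot span are rejected.
#'
#' @param wavelengths Knot wavelengths, nm (>= 2, distinct).
#' @param mu_a_values Absorption at the knots, mm^-1.
#' @param query_wavelengths Wavelengths to evaluate, nm.
#' @return Numeric vector of interpolated mu_a values with attribute
#'   `method` ("natural_spline" or "linear").
#' @export
interpolate_mu_a_spline <- function(wavelengths, mu_a_values,
                                    query_wavelengths) {
  check_finite_numeric(wavelengths, "wavelengths")
  check_finite_numeric(mu_a_values, "mu_a_values")
  check_finite_numeric(query_wavelengths, "query_wavelengths")
  if (length(wavelengths) < 2 || anyDuplicated(wavelengths))
    stop("need >= 2 distinct knots", call. = FALSE)
  if (any(query_wavelengths < min(wavelengths)) ||
      any(query_wavelengths > max(wavelengths)))
    stop(sprintf("query outside knot span [%g, %g] nm",
                 min(wavelengths), max(wavelengths)), call. = FALSE)
  if (length(wavelengths) >= 3) {
    y <- spline(wavelengths, mu_a_values, xout = query_wavelengths,
                method = "natural")$y
    attr(y, "method") <- "natural_spline"
  } else {
    y <- approx(wavelengths, mu_a_values, xout = query_wavelengths)$y
    attr(y, "method") <- "linear"
  }
  y
}
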
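#' Invert one reflectance pair to optical properties
#'
#' Recovers `(mu_a, mu_s')` from the diffuse reflectance measured at the
#' table's two spatial frequencies by inverse interpolation over the LUT
#' image: a damped Newton iteration on the bilinear interpolant of the two
#' forward surfaces, seeded at the nearest table node. The forward residual
#' at the solution is reported; pairs whose residual cannot be driven below
#' a relative tolerance (targets outside the image hull, including
#' nonphysical reflectance) come back flagged out-of-domain rather than
#' clamped to the table edge.
#'
#' @param rd_pair Numeric length-2: reflectance at `lut$f_pair[1]` and
#'   `lut$f_pair[2]`.
#' @param lut An `sfdi_lut` from [build_lut()] / [read_lut()].
#' @param rel_tol Relative forward-residual acceptance band (default 1e-3).
#' @return A list: `props` ([optical_properties()] or NA fields),
#'   `residual`, `in_domain`.
#' @examples
#' lut <- build_lut(grid_sizes = c(32, 32))
#' rd <- diffuse_reflectance(optical_properties(0.02, 1.2), lut$f_pair)
#' invert_pair(rd, lut)
#' @export
invert_pair <- function(rd_pair, lut, rel_tol = 1e-3) {
  stopifnot(inherits(lut, "sfdi_lut"), length(rd_pair) == 2L)
  res <- lut_invert_cpp(rd_pair[1], rd_pair[2],
                        lut$mu_a_grid, lut$mu_s_grid,
                        lut$rd_low, lut$rd_high, rel_tol)
  ok <- res[1, 4] > 0
  list(
    props = if (ok)
      optical_properties(res[1, 1], res[1, 2], lut$n_tissue)
    else
      structure(list(mu_a = NA_real_, mu_s_prime = NA_real_,
                     n_tissue = lut$n_tissue), class = "sfdi_props"),
    residual = res[1, 3],
    in_domain = ok)
}

#' Invert calibrated reflectance maps to property maps
#'
#' Pixel-by-pixel inversion of the two-frequency reflectance pair: each
#' pixel's `(Rd at f1, Rd at f2)` is looked up through the table's inverse
#' map. The output validity mask is the conjunction of both input masks and
#' the per-pixel in-domain flag; out-of-domain or masked pixels carry NA.
#'
#' @param rd_low,rd_high [sfdi_map()] reflectance maps at the table's low
#'   and high spatial frequency; must share wavelength and shape, and their
#'   `fx` must match `lut$f_pair`.
#' @param lut An `sfdi_lut`.
#' @param rel_tol Passed to the inverse interpolation (see [invert_pair()]).
#' @return An `sfdi_property_map`: matrices `mu_a`, `mu_s_prime` (mm^-1),
#'   `residual`, logical `mask`, plus `wavelength` and LUT provenance.
#' @export
invert_map <- function(rd_low, rd_high, lut, rel_tol = 1e-3) {
  stopifnot(inherits(rd_low, "sfdi_map"), inherits(rd_high, "sfdi_map"),
            inherits(lut, "sfdi_lut"))
  if (!isTRUE(all.equal(rd_low$wavelength, rd_high$wavelength)))
    stop("reflectance maps disagree on wavelength", call. = FALSE)
  check_same_shape(rd_low$values, rd_high$values, what = "reflectance maps")
  if (!isTRUE(all.equal(c(rd_low$fx, rd_high$fx), lut$f_pair)))
    stop(sprintf(
      "map frequencies (%g, %g) do not match LUT f_pair (%g, %g)",
      rd_low$fx, rd_high$fx, lut$f_pair[1], lut$f_pair[2]), call. = FALSE)

  shape <- dim(rd_low$values)
  in_mask <- rd_low$mask & rd_high$mask
  v1 <- rd_low$values; v2 <- rd_high$values
  v1[!in_mask] <- NA_real_; v2[!in_mask] <- NA_real_
  res <- lut_invert_cpp(as.vector(v1), as.vector(v2),
                        lut$mu_a_grid, lut$mu_s_grid,
                        lut$rd_low, lut$rd_high, rel_tol)
  ok <- matrix(res[, 4] > 0, shape[1], shape[2]) & in_mask
  mu_a <- matrix(res[, 1], shape[1], shape[2])
  mu_s <- matrix(res[, 2], shape[1], shape[2])
  mu_a[!ok] <- NA_real_; mu_s[!ok] <- NA_real_
  structure(
    list(mu_a = mu_a, mu_s_prime = mu_s,
         residual = matrix(res[, 3], shape[1], shape[2]),
         mask = ok, wavelength = rd_low$wavelength,
         lut_provenance = list(model_tag = lut$model_tag,
                               f_pair = lut$f_pair,
                               grid = c(length(lut$mu_a_grid),
                                        length(lut$mu_s_grid)))),
    class = "sfdi_property_map")
}

#' @export
print.sfdi_property_map <- function(x, ...) {
  cat(sprintf("<sfdi_property_map> %dx%d px", nrow(x$mu_a), ncol(x$mu_a)))
  if (!is.na(x$wavelength)) cat(sprintf(", %g nm", x$wavelength))
  cat(sprintf("\n  valid %d/%d\n", sum(x$mask), length(x$mask)))
  if (any(x$mask)) {
    cat(sprintf("  mu_a:  [%.4g, %.4g] mm^-1 (median %.4g)\n",
                min(x$mu_a[x$mask]), max(x$mu_a[x$mask]),
                median(x$mu_a[x$mask])))
    cat(sprintf("  mu_s': [%.4g, %.4g] mm^-1 (median %.4g)\n",
                min(x$mu_s_prime[x$mask]), max(x$mu_s_prime[x$mask]),
                median(x$mu_s_prime[x$mask])))
  }
  invisible(x)
}

#' Extract one quantity of a property map as an image map
#'
#' @param pmap An `sfdi_property_map`.
#' @param what `"mu_a"`, `"mu_s_prime"` or `"residual"`.
#' @return An [sfdi_map()].
#' @export
property_map_layer <- function(pmap, what = c("mu_a", "mu_s_prime",
                                              "residual")) {
  stopifnot(inherits(pmap, "sfdi_property_map"))
  what <- match.arg(what)
  sfdi_map(pmap[[what]], wavelength = pmap$wavelength, mask = pmap$mask,
           kind = what, units = if (what == "residual") "" else "mm^-1")
}
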
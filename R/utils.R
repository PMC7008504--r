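#' @useDynLib sfdi, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats approx coef lm median qt sd spline rnorm rpois runif
#' @importFrom utils read.csv write.csv
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# reject non-finite numeric input, naming the offending field
check_finite_numeric <- function(x, name) {
  if (!is.numeric(x) || length(x) == 0 || !all(is.finite(x)))
    stop(sprintf("`%s` must be finite numeric", name), call. = FALSE)
  invisible(x)
}

check_same_shape <- function(..., what = "images") {
  mats <- list(...)
  dims <- lapply(mats, dim)
  if (any(vapply(dims, is.null, logical(1))))
    stop(what, " must be matrices", call. = FALSE)
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1L)
    stop("shape mismatch among ", what, ": ",
         paste(vapply(dims, paste, character(1), collapse = "x"),
               collapse = " vs "), call. = FALSE)
  invisible(TRUE)
}

#' Per-pixel image map container
#'
#' Light wrapper used for every per-pixel product of the pipeline
#' (modulation amplitude, calibrated reflectance, phase, height): a numeric
#' matrix plus a logical validity mask and channel metadata. Invalid pixels
#' are flagged, never silently zeroed.
#'
#' @param values Numeric matrix.
#' @param wavelength Wavelength in nm (NA when not tied to a channel).
#' @param fx Spatial frequency in mm^-1 (NA when not applicable).
#' @param mask Logical matrix, `TRUE` where the pixel is valid; defaults to
#'   all valid.
#' @param kind Short label for what the values are ("modulation", "rd",
#'   "mu_a", "phase", "height", ...).
#' @param units Unit string for the values.
#' @return An `sfdi_map` object.
#' @export
sfdi_map <- function(values, wavelength = NA_real_, fx = NA_real_,
                     mask = NULL, kind = "map", units = "") {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(mask)) mask <- matrix(TRUE, nrow(values), ncol(values))
  stopifnot(is.logical(mask), all(dim(mask) == dim(values)))
  structure(
    list(values = values, mask = mask,
         wavelength = wavelength, fx = fx, kind = kind, units = units),
    class = "sfdi_map")
}

#' @export
dim.sfdi_map <- function(x) dim(x$values)

#' @export
print.sfdi_map <- function(x, ...) {
  v <- x$values[x$mask]
  cat(sprintf("<sfdi_map:%s> %dx%d px", x$kind, nrow(x$values), ncol(x$values)))
  if (!is.na(x$wavelength)) cat(sprintf(", %g nm", x$wavelength))
  if (!is.na(x$fx)) cat(sprintf(", fx = %g mm^-1", x$fx))
  cat(sprintf("\n  valid %d/%d; range [%.4g, %.4g] %s\n",
              sum(x$mask), length(x$mask),
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA,
              x$units))
  invisible(x)
}

#' Plot an image map
#'
#' Raster display of an [sfdi_map()] with invalid pixels left blank.
#'
#' @param object An `sfdi_map`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.sfdi_map <- function(object, ...) {
  v <- object$values
  v[!object$mask] <- NA
  df <- data.frame(
    col = rep(seq_len(ncol(v)), each = nrow(v)),
    row = rep(seq_len(nrow(v)), ncol(v)),
    value = as.vector(v))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::scale_fill_viridis_c(na.value = "grey80") +
    ggplot2::labs(fill = object$units,
                  title = sprintf("%s%s%s", object$kind,
                                  if (!is.na(object$wavelength))
                                    sprintf(" @ %g nm", object$wavelength) else "",
                                  if (!is.na(object$fx))
                                    sprintf(", fx = %g mm^-1", object$fx) else ""))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot .data
#' @export
ggplot2::autoplot
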
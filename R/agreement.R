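#' ROI mean and standard deviation
#'
#' Summarizes a rectangular region of interest of a per-pixel map over its
#' valid pixels only. ROI bounds follow the package convention: 0-based,
#' half-open `[row0, row1) x [col0, col1)` pixel indices. The sample
#' (n - 1) standard deviation is used.
#'
#' @param map An [sfdi_map()], an `sfdi_property_map` layer (see
#'   [property_map_layer()]) or a plain matrix.
#' @param roi Integer vector `c(row0, row1, col0, col1)`; default the whole
#'   image.
#' @return A tibble with `mean`, `sd`, `n`.
#' @export
roi_mean <- function(map, roi = NULL) {
  if (inherits(map, "sfdi_map")) {
    values <- map$values; mask <- map$mask
  } else {
    stopifnot(is.matrix(map))
    values <- map; mask <- matrix(TRUE, nrow(map), ncol(map))
  }
  roi <- roi %||% c(0L, nrow(values), 0L, ncol(values))
  stopifnot(length(roi) == 4)
  if (roi[1] < 0 || roi[3] < 0 || roi[2] > nrow(values) ||
      roi[4] > ncol(values) || roi[1] >= roi[2] || roi[3] >= roi[4])
    stop("roi out of map bounds or empty", call. = FALSE)
  r <- (roi[1] + 1):roi[2]; cc <- (roi[3] + 1):roi[4]
  sel <- mask[r, cc] & is.finite(values[r, cc])
  v <- values[r, cc][sel]
  if (length(v) == 0) stop("no valid pixels in roi", call. = FALSE)
  tibble::tibble(mean = mean(v), sd = if (length(v) > 1) sd(v) else 0,
                 n = length(v))
}

#' Paired percent difference
#'
#' Per-pair percent difference `100 (test - ref) / ref`, summarized as mean
#' and sample standard deviation — the accuracy statistic used to compare
#' an instrument under test against a reference instrument over a phantom
#' set.
#'
#' @param test,ref Paired numeric vectors; `ref` must be positive.
#' @return A tibble with `mean_pct`, `sd_pct`, `n`; per-pair differences in
#'   attribute `"pct"`.
#' @export
percent_difference <- function(test, ref) {
  check_finite_numeric(test, "test")
  check_finite_numeric(ref, "ref")
  if (length(test) != length(ref))
    stop("test and ref must be paired (equal length)", call. = FALSE)
  if (any(ref <= 0)) stop("reference values must be positive", call. = FALSE)
  pct <- 100 * (test - ref) / ref
  out <- tibble::tibble(mean_pct = mean(pct),
                        sd_pct = if (length(pct) > 1) sd(pct) else 0,
                        n = length(pct))
  attr(out, "pct") <- pct
  out
}

#' Bland-Altman agreement analysis
#'
#' Quantifies agreement between two methods measuring the same quantity:
#' with paired differences `d = x - y`, the bias is `mean(d)` and the
#' limits of agreement `mean(d) +/- 1.96 sd(d)` delimit the band expected
#' to contain about 95% of future paired differences (Gaussian
#' differences). The limits are themselves estimates; their standard error
#' `sqrt(3 sd^2 / n)`, scaled by the t quantile at `n - 1` degrees of
#' freedom, gives the confidence half-width reported alongside them.
#'
#' @param x,y Paired measurements (`x` the instrument under test, `y` the
#'   reference, so differences are oriented test - reference); `n >= 2`.
#' @param conf Confidence level for the limit uncertainty (default 0.95).
#' @return An `sfdi_bland_altman` object; see [tidy()], [glance()],
#'   [autoplot()] methods.
#' @examples
#' ba <- bland_altman(c(1, 2, 3, 4) + 0.1, c(1, 2, 3, 4))
#' tidy(ba)
#' @export
bland_altman <- function(x, y, conf = 0.95) {
  check_finite_numeric(x, "x")
  check_finite_numeric(y, "y")
  if (length(x) != length(y))
    stop("x and y must be paired (equal length)", call. = FALSE)
  n <- length(x)
  if (n < 2) stop("need n >= 2 pairs", call. = FALSE)
  d <- x - y
  m <- mean(d); s <- sd(d)
  half <- qt(1 - (1 - conf) / 2, n - 1) * sqrt(3 * s^2 / n)
  structure(
    list(mean_diff = m, sd_diff = s,
         loa_low = m - 1.96 * s, loa_high = m + 1.96 * s,
         loa_ci_halfwidth = half, n = n,
         differences = d, means = (x + y) / 2, conf = conf),
    class = "sfdi_bland_altman")
}

#' @export
print.sfdi_bland_altman <- function(x, ...) {
  cat(sprintf("<sfdi_bland_altman> n = %d\n", x$n))
  cat(sprintf("  bias %.4g; limits of agreement [%.4g, %.4g] (+/- %.4g)\n",
              x$mean_diff, x$loa_low, x$loa_high, x$loa_ci_halfwidth))
  invisible(x)
}

#' @export
tidy.sfdi_bland_altman <- function(x, ...) {
  tibble::tibble(
    term = c("mean_diff", "loa_low", "loa_high"),
    estimate = c(x$mean_diff, x$loa_low, x$loa_high),
    ci_halfwidth = c(qt(1 - (1 - x$conf) / 2, x$n - 1) * x$sd_diff / sqrt(x$n),
                     x$loa_ci_halfwidth, x$loa_ci_halfwidth))
}

#' @export
glance.sfdi_bland_altman <- function(x, ...) {
  tibble::tibble(mean_diff = x$mean_diff, sd_diff = x$sd_diff,
                 loa_low = x$loa_low, loa_high = x$loa_high,
                 loa_ci_halfwidth = x$loa_ci_halfwidth, n = x$n)
}

#' @exportS3Method ggplot2::autoplot
autoplot.sfdi_bland_altman <- function(object, ...) {
  df <- data.frame(mean = object$means, diff = object$differences)
  lines <- data.frame(
    y = c(object$mean_diff, object$loa_low, object$loa_high),
    type = c("bias", "loa", "loa"))
  ggplot2::ggplot(df, ggplot2::aes(.data$mean, .data$diff)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_hline(data = lines,
                        ggplot2::aes(yintercept = .data$y,
                                     linetype = .data$type)) +
    ggplot2::labs(x = "mean of the two instruments",
                  y = "difference (test - reference)") +
    ggplot2::guides(linetype = "none")
}

#' Write an agreement report
#'
#' Emits a Bland-Altman report both as JSON and as a one-row CSV.
#'
#' @param ba An `sfdi_bland_altman`.
#' @param json_path,csv_path Output paths (either may be NULL to skip).
#' @return Invisibly, the report as a list.
#' @export
write_agreement_report <- function(ba, json_path = NULL, csv_path = NULL) {
  stopifnot(inherits(ba, "sfdi_bland_altman"))
  rep <- list(mean_diff = ba$mean_diff, sd_diff = ba$sd_diff,
              loa_low = ba$loa_low, loa_high = ba$loa_high,
              loa_ci_halfwidth = ba$loa_ci_halfwidth, n = ba$n)
  if (!is.null(json_path))
    jsonlite::write_json(rep, json_path, auto_unbox = TRUE, digits = NA)
  if (!is.null(csv_path))
    write.csv(as.data.frame(rep), csv_path, row.names = FALSE)
  invisible(rep)
}

#' Drift summary of repeated measurements
#'
#' Stability statistics for a time series of ROI-mean optical properties
#' measured repeatedly on the same phantom: per wavelength, the sample
#' standard deviation of the series and the least-squares slope versus
#' time (a trend detector; near-zero slope with random scatter about the
#' mean indicates a drift-free instrument).
#'
#' @param data A data frame with columns `time`, `value` and optionally
#'   `wavelength` (a single series is assumed when absent). At least 3
#'   time points per series.
#' @return A tibble per wavelength: `sd`, `slope` (value units per time
#'   unit), `mean`, `n`.
#' @export
drift_summary <- function(data) {
  stopifnot(is.data.frame(data), all(c("time", "value") %in% names(data)))
  if (!"wavelength" %in% names(data)) data$wavelength <- NA_real_
  groups <- split(data, data$wavelength)
  if (length(groups) == 0) groups <- list(data)   # single unlabeled series
  out <- lapply(groups, function(d) {
    if (nrow(d) < 3)
      stop("need >= 3 time points per series", call. = FALSE)
    fit <- lm(value ~ time, data = d)
    tibble::tibble(wavelength = d$wavelength[1],
                   sd = sd(d$value),
                   slope = unname(coef(fit)[2]),
                   mean = mean(d$value), n = nrow(d))
  })
  do.call(rbind, unname(out))
}
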
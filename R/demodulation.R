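#' Three-phase AC demodulation
#'
#' Recovers the per-pixel modulation amplitude from three frames acquired
#' under sinusoidal illumination shifted by 120 degrees (phases 0, 2*pi/3,
#' 4*pi/3). For an ideal triplet `I_i = O + A cos(phi + p_i)` the estimator
#'
#'   `m_ac = (sqrt(2)/3) sqrt((I1-I2)^2 + (I2-I3)^2 + (I3-I1)^2)`
#'
#' returns exactly `A` at every pixel, independent of the spatial phase
#' `phi` and of any common offset; it is also invariant to reordering the
#' three frames.
#'
#' @param I1,I2,I3 Equally shaped intensity matrices (linear sensor counts).
#' @return Matrix of modulation amplitudes (same units as the input).
#' @examples
#' demodulate_ac(matrix(1.5), matrix(1.0), matrix(0.5))  # 1/sqrt(3)
#' @export
demodulate_ac <- function(I1, I2, I3) {
  check_same_shape(I1, I2, I3, what = "phase frames")
  sqrt(2) / 3 * sqrt((I1 - I2)^2 + (I2 - I3)^2 + (I3 - I1)^2)
}

#' Three-phase DC demodulation
#'
#' Companion planar (DC) estimator: the mean of the three phase frames,
#' which for an ideal 120-degree triplet recovers the offset `O` exactly.
#' Used when a planar channel is derived from the AC triplet rather than
#' from dedicated unmodulated frames.
#'
#' @inheritParams demodulate_ac
#' @return Matrix of DC amplitudes.
#' @export
demodulate_dc <- function(I1, I2, I3) {
  check_same_shape(I1, I2, I3, what = "phase frames")
  (I1 + I2 + I3) / 3
}

#' Demodulate a raw frame stack
#'
#' Applies three-phase demodulation to every (wavelength, spatial frequency)
#' triplet of a raw stack, producing one AC modulation map per channel plus
#' a DC map per wavelength. The DC channel comes from the dedicated planar
#' (fx = 0) triplet when the stack contains one; otherwise it falls back to
#' the DC estimator applied to the lowest-frequency AC triplet, and the
#' choice is recorded in the result. Pixels saturated at the sensor
#' bit-depth maximum in any contributing frame are masked invalid.
#'
#' @param stack An `sfdi_raw_stack` (see [simulate_raw_stack()] /
#'   [load_raw_stack()]).
#' @param dc_from `"planar"` (default: dedicated fx = 0 triplet, with
#'   fallback) or `"ac"` (always derive DC from the lowest AC triplet).
#' @return A list of class `sfdi_modulation_set`: `maps` is a list of
#'   [sfdi_map()] objects of kind "modulation" (one per wavelength and
#'   frequency, DC included), `dc_source` records where each DC map came
#'   from.
#' @export
demodulate_stack <- function(stack, dc_from = c("planar", "ac")) {
  stopifnot(inherits(stack, "sfdi_raw_stack"))
  dc_from <- match.arg(dc_from)
  idx <- stack$index
  sat_level <- if (isTRUE(stack$meta$bit_depth > 0))
    2^stack$meta$bit_depth - 1 else Inf

  maps <- list()
  dc_source <- character(0)
  for (wl in sort(unique(idx$wavelength))) {
    fxs <- sort(unique(idx$fx[idx$wavelength == wl]))
    for (f in fxs) {
      fr <- stack_frames(stack, wl, f)
      sat <- (fr[[1]] >= sat_level) | (fr[[2]] >= sat_level) |
        (fr[[3]] >= sat_level)
      if (f > 0) {
        m <- demodulate_ac(fr[[1]], fr[[2]], fr[[3]])
        maps[[channel_key(wl, f)]] <-
          sfdi_map(m, wavelength = wl, fx = f, mask = !sat,
                   kind = "modulation", units = "counts")
      }
    }
    # DC channel
    has_planar <- 0 %in% fxs
    use_planar <- dc_from == "planar" && has_planar
    src_fx <- if (use_planar) 0 else min(fxs[fxs > 0])
    fr <- stack_frames(stack, wl, src_fx)
    sat <- (fr[[1]] >= sat_level) | (fr[[2]] >= sat_level) |
      (fr[[3]] >= sat_level)
    m <- demodulate_dc(fr[[1]], fr[[2]], fr[[3]])
    maps[[channel_key(wl, 0)]] <-
      sfdi_map(m, wavelength = wl, fx = 0, mask = !sat,
               kind = "modulation", units = "counts")
    dc_source[as.character(wl)] <-
      if (use_planar) "planar" else sprintf("ac_triplet_fx=%g", src_fx)
  }
  structure(list(maps = maps, dc_source = dc_source),
            class = "sfdi_modulation_set")
}

channel_key <- function(wavelength, fx) sprintf("%gnm_fx%g", wavelength, fx)

#' @export
print.sfdi_modulation_set <- function(x, ...) {
  cat(sprintf("<sfdi_modulation_set> %d channel maps\n", length(x$maps)))
  for (k in names(x$maps)) cat("  ", k, "\n", sep = "")
  invisible(x)
}

#' Look up one channel of a modulation set
#'
#' @param mods An `sfdi_modulation_set` from [demodulate_stack()].
#' @param wavelength Wavelength, nm.
#' @param fx Spatial frequency, mm^-1 (0 for the DC map).
#' @return The requested [sfdi_map()].
#' @export
modulation_map <- function(mods, wavelength, fx) {
  key <- channel_key(wavelength, fx)
  m <- mods$maps[[key]]
  if (is.null(m))
    stop("no demodulated channel ", key, call. = FALSE)
  m
}
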
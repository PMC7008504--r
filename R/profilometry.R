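#' Extract wrapped phase from a three-step fringe triplet
#'
#' Phase-stepping profilometry: with sinusoidal fringes projected at phases
#' 0, 2*pi/3 and 4*pi/3 (`I_i = O + A cos(phi + p_i)`), the per-pixel
#' fringe phase is `phi = atan2(sqrt(3) (I3 - I2), 2 I1 - I2 - I3)`,
#' wrapped to (-pi, pi].
#' The local modulation amplitude serves as a quality/validity measure:
#' pixels with no modulation (e.g. equal frames) have undefined phase and
#' are masked.
#'
#' @param I1,I2,I3 Equally shaped intensity matrices.
#' @param mod_threshold Modulation amplitude below which a pixel is masked;
#'   default `1e-8 * max(DC)` so exactly unmodulated input is invalid while
#'   any real fringe signal survives.
#' @return An `sfdi_phase_map`: `phase` (radians), `quality` (modulation
#'   amplitude), logical `mask`, and `wrapped = TRUE`.
#' @export
extract_phase <- function(I1, I2, I3, mod_threshold = NULL) {
  check_same_shape(I1, I2, I3, what = "fringe frames")
  m_ac <- demodulate_ac(I1, I2, I3)
  dc <- demodulate_dc(I1, I2, I3)
  if (is.null(mod_threshold)) mod_threshold <- 1e-8 * max(dc, 0)
  phase <- atan2(sqrt(3) * (I3 - I2), 2 * I1 - I2 - I3)
  mask <- m_ac > mod_threshold
  phase[!mask] <- NA_real_
  structure(list(phase = phase, quality = m_ac, mask = mask, wrapped = TRUE),
            class = "sfdi_phase_map")
}

#' @export
print.sfdi_phase_map <- function(x, ...) {
  v <- x$phase[x$mask]
  cat(sprintf("<sfdi_phase_map> %dx%d px, %s; valid %d/%d; range [%.3f, %.3f] rad\n",
              nrow(x$phase), ncol(x$phase),
              if (x$wrapped) "wrapped" else "unwrapped",
              sum(x$mask), length(x$mask),
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
  invisible(x)
}

#' Unwrap a phase image
#'
#' Removes 2*pi ambiguities by quality-guided flood fill: unwrapping grows
#' outward from the highest-quality valid pixel (which keeps its wrapped
#' value), absorbing pixels in decreasing order of local modulation
#' amplitude so noisy or masked regions are reached last. Each absorbed
#' pixel is offset by the integer multiple of 2*pi that puts it within pi
#' of its solved neighbor, so the result is continuous across valid
#' 4-neighborhoods. Disconnected valid regions are unwrapped independently.
#'
#' @param pm A wrapped `sfdi_phase_map` from [extract_phase()].
#' @return The unwrapped `sfdi_phase_map` (`wrapped = FALSE`).
#' @export
unwrap_phase <- function(pm) {
  stopifnot(inherits(pm, "sfdi_phase_map"))
  if (!any(pm$mask)) stop("fully masked phase map", call. = FALSE)
  w <- pm$phase
  w[!pm$mask] <- 0          # placeholder; masked pixels never visited
  un <- unwrap_phase_cpp(w, pm$quality, pm$mask)
  structure(list(phase = un, quality = pm$quality, mask = pm$mask,
                 wrapped = FALSE),
            class = "sfdi_phase_map")
}

#' Rebase an unwrapped phase map to a reference region
#'
#' Quality-guided unwrapping fixes phase only up to one global 2*pi
#' multiple per connected region. When part of the scene is known to sit at
#' the reference plane (zero expected phase), this helper removes the
#' multiple of 2*pi closest to the median phase over that region.
#'
#' @param pm An unwrapped `sfdi_phase_map`.
#' @param region Logical matrix selecting reference pixels (default: all
#'   valid pixels).
#' @return The rebased `sfdi_phase_map`.
#' @export
rebase_phase <- function(pm, region = NULL) {
  stopifnot(inherits(pm, "sfdi_phase_map"), !pm$wrapped)
  region <- region %||% pm$mask
  sel <- region & pm$mask
  if (!any(sel)) stop("empty reference region", call. = FALSE)
  k <- round(median(pm$phase[sel]) / (2 * pi))
  pm$phase <- pm$phase - 2 * pi * k
  pm
}

#' Wrapped phase difference of two phase maps
#'
#' Pixelwise difference `a - b` wrapped back to (-pi, pi]. Subtracting the
#' flat reference-plane measurement from an object measurement removes the
#' projection carrier, leaving only the height-induced phase, which is then
#' spatially unwrapped.
#'
#' @param a,b Wrapped `sfdi_phase_map`s, co-registered.
#' @return A wrapped `sfdi_phase_map`; quality is the elementwise minimum
#'   of the two inputs, masks intersect.
#' @export
phase_difference <- function(a, b) {
  stopifnot(inherits(a, "sfdi_phase_map"), inherits(b, "sfdi_phase_map"))
  check_same_shape(a$phase, b$phase, what = "phase maps")
  d <- a$phase - b$phase
  d <- d - 2 * pi * floor(d / (2 * pi) + 0.5)   # wrap to (-pi, pi]
  mask <- a$mask & b$mask
  d[!mask] <- NA_real_
  structure(list(phase = d, quality = pmin(a$quality, b$quality),
                 mask = mask, wrapped = TRUE),
            class = "sfdi_phase_map")
}

#' Calibrate the per-pixel phase-to-height relation
#'
#' From fringe measurements of a flat phantom placed at two or more known
#' heights, fits at each pixel a straight line of unwrapped phase versus
#' height. The inverse slope is the phase-to-height gain (mm/radian) and
#' the intercept the reference phase at height zero. Pixels with no phase
#' spread across heights (or masked in any input) are masked.
#'
#' Maps may be supplied unwrapped (fitted as given) or wrapped: wrapped
#' maps are unwrapped temporally — heights are sorted and the per-pixel
#' phase accumulated through the wrapped successive differences, which is
#' exact provided consecutive height steps move the phase by less than pi
#' (steps smaller than `pi * gain` mm).
#'
#' @param phase_stacks A list of `list(height = <mm>, phase =
#'   <sfdi_phase_map>)` entries, co-registered; >= 2 distinct heights.
#' @return An `sfdi_height_cal`: `gain` (mm/rad), `reference_phase` (rad),
#'   logical `mask`.
#' @export
calibrate_height <- function(phase_stacks) {
  if (length(phase_stacks) < 2)
    stop("need >= 2 heights for the linear fit", call. = FALSE)
  h <- vapply(phase_stacks, function(s) s$height, numeric(1))
  if (length(unique(h)) < 2)
    stop("need >= 2 distinct heights", call. = FALSE)
  ord <- order(h)
  h <- h[ord]
  maps <- lapply(phase_stacks[ord], function(s) {
    stopifnot(inherits(s$phase, "sfdi_phase_map"))
    s$phase
  })
  do.call(check_same_shape, c(lapply(maps, `[[`, "phase"),
                              list(what = "phase maps")))
  mask <- Reduce(`&`, lapply(maps, `[[`, "mask"))
  if (any(vapply(maps, `[[`, logical(1), "wrapped"))) {
    # temporal unwrapping through wrapped successive differences,
    # anchored at the lowest height
    acc <- maps[[1]]
    acc$phase <- matrix(0, nrow(acc$phase), ncol(acc$phase))
    acc$wrapped <- FALSE
    rel <- vector("list", length(maps))
    rel[[1]] <- acc
    for (k in 2:length(maps)) {
      d <- phase_difference(maps[[k]], maps[[k - 1]])
      nxt <- rel[[k - 1]]
      nxt$phase <- nxt$phase + d$phase
      rel[[k]] <- nxt
    }
    maps <- rel
    mask <- mask & Reduce(`&`, lapply(maps, function(m) is.finite(m$phase)))
    for (k in seq_along(maps)) maps[[k]]$phase[!mask] <- 0
  }

  hbar <- mean(h)
  sxx <- sum((h - hbar)^2)
  Pbar <- Reduce(`+`, lapply(maps, `[[`, "phase")) / length(maps)
  sxy <- Reduce(`+`, Map(function(m, hk) (hk - hbar) * m$phase, maps, h))
  slope <- sxy / sxx                       # rad per mm
  ref <- Pbar - slope * hbar               # phase at height 0
  ok <- mask & is.finite(slope) & (abs(slope) > .Machine$double.eps^0.5)
  gain <- 1 / slope                        # mm per rad
  gain[!ok] <- NA_real_; ref[!ok] <- NA_real_
  structure(list(gain = gain, reference_phase = ref, mask = ok),
            class = "sfdi_height_cal")
}

#' Convert unwrapped phase to height
#'
#' `height = gain * (phase - reference_phase)` per pixel, in mm relative to
#' the calibration reference plane. Masks propagate.
#'
#' @param unwrapped An unwrapped `sfdi_phase_map`.
#' @param cal An `sfdi_height_cal` from [calibrate_height()].
#' @return An [sfdi_map()] of kind "height" (mm).
#' @export
phase_to_height <- function(unwrapped, cal) {
  stopifnot(inherits(unwrapped, "sfdi_phase_map"),
            inherits(cal, "sfdi_height_cal"))
  if (unwrapped$wrapped)
    stop("phase map must be unwrapped first", call. = FALSE)
  check_same_shape(unwrapped$phase, cal$gain, what = "phase/calibration maps")
  ok <- unwrapped$mask & cal$mask
  height <- cal$gain * (unwrapped$phase - cal$reference_phase)
  height[!ok] <- NA_real_
  sfdi_map(height, mask = ok, kind = "height", units = "mm")
}

#' Per-pixel intensity-versus-height correction
#'
#' `fit_intensity_height_model` fits, at every pixel, a straight line of
#' raw intensity against known height from measurements of a flat phantom
#' at two or more heights (slope in counts/mm, intercept = counts at the
#' reference plane). `apply_intensity_height_correction` then re-references
#' a measured image to the calibration plane by subtracting
#' `slope * height` pixelwise, compensating intensity changes caused by
#' parts of the sample sitting closer to or farther from the camera.
#'
#' @param images_at_heights A list of `list(height = <mm>, image =
#'   <matrix>)`; >= 2 distinct heights, co-registered.
#' @return An `sfdi_intensity_height_model` with matrices `slope` and
#'   `intercept`.
#' @export
fit_intensity_height_model <- function(images_at_heights) {
  if (length(images_at_heights) < 2)
    stop("need >= 2 heights for the linear fit", call. = FALSE)
  h <- vapply(images_at_heights, function(s) s$height, numeric(1))
  if (length(unique(h)) < 2)
    stop("need >= 2 distinct heights", call. = FALSE)
  imgs <- lapply(images_at_heights, `[[`, "image")
  do.call(check_same_shape, c(imgs, list(what = "calibration images")))
  hbar <- mean(h)
  sxx <- sum((h - hbar)^2)
  Ibar <- Reduce(`+`, imgs) / length(imgs)
  sxy <- Reduce(`+`, Map(function(m, hk) (hk - hbar) * m, imgs, h))
  slope <- sxy / sxx
  intercept <- Ibar - slope * hbar
  structure(list(slope = slope, intercept = intercept, heights = h),
            class = "sfdi_intensity_height_model")
}

#' @rdname fit_intensity_height_model
#' @param image Matrix of raw intensities to correct.
#' @param height_map [sfdi_map()] of heights (mm) or a plain matrix,
#'   co-registered with `image`.
#' @param model An `sfdi_intensity_height_model`.
#' @return `apply_intensity_height_correction` returns the corrected image
#'   matrix (`image - slope * height`).
#' @export
apply_intensity_height_correction <- function(image, height_map, model) {
  stopifnot(inherits(model, "sfdi_intensity_height_model"))
  hm <- if (inherits(height_map, "sfdi_map")) height_map$values else height_map
  check_same_shape(image, hm, model$slope, what = "image/height/model")
  image - model$slope * hm
}
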
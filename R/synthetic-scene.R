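#' Synthetic scene: ground-truth optical property maps
#'
#' A scene holds per-pixel ground truth from which raw camera frames are
#' rendered: absorption and reduced scattering maps (either one pair shared
#' by all wavelengths, or one pair per wavelength), an optional height map
#' for profilometry, and the medium refractive index. Scenes make every
#' downstream stage testable without hardware.
#'
#' @param mu_a,mu_s_prime Either single matrices (wavelength-flat scene) or
#'   named lists of matrices keyed by wavelength in nm; mm^-1, positive.
#' @param n_tissue Refractive index.
#' @param height_map Optional height matrix, mm.
#' @param pixel_pitch Sample-plane pixel size, mm/pixel.
#' @param truth Optional tibble of ground-truth bookkeeping (kept verbatim).
#' @return An `sfdi_scene`.
#' @export
sfdi_scene <- function(mu_a, mu_s_prime, n_tissue = 1.4, height_map = NULL,
                       pixel_pitch = 0.3, truth = NULL) {
  as_map_list <- function(x, nm) {
    if (is.matrix(x)) return(list(x))
    stopifnot(is.list(x), !is.null(names(x)))
    x
  }
  mu_a <- as_map_list(mu_a, "mu_a")
  mu_s_prime <- as_map_list(mu_s_prime, "mu_s_prime")
  if (length(mu_a) != length(mu_s_prime) ||
      !identical(names(mu_a), names(mu_s_prime)))
    stop("mu_a and mu_s_prime must cover the same wavelengths", call. = FALSE)
  all_maps <- c(mu_a, mu_s_prime, if (!is.null(height_map)) list(height_map))
  do.call(check_same_shape, c(all_maps, list(what = "scene maps")))
  for (m in mu_a) if (any(!is.finite(m)) || any(m < 0))
    stop("mu_a maps must be finite and >= 0", call. = FALSE)
  for (m in mu_s_prime) if (any(!is.finite(m)) || any(m <= 0))
    stop("mu_s_prime maps must be finite and > 0", call. = FALSE)
  structure(
    list(mu_a = mu_a, mu_s_prime = mu_s_prime, n_tissue = n_tissue,
         height_map = height_map, pixel_pitch = pixel_pitch,
         shape = dim(mu_a[[1]]), truth = truth),
    class = "sfdi_scene")
}

#' @export
print.sfdi_scene <- function(x, ...) {
  cat(sprintf("<sfdi_scene> %dx%d px @ %g mm/px; %s; height map: %s\n",
              x$shape[1], x$shape[2], x$pixel_pitch,
              if (is.null(names(x$mu_a)))
                "wavelength-flat properties"
              else paste0("wavelengths: ",
                          paste(names(x$mu_a), collapse = ", "), " nm"),
              if (is.null(x$height_map)) "none" else "yes"))
  invisible(x)
}

# property maps of a scene at a wavelength (flat scenes serve any query)
scene_props_at <- function(scene, wavelength) {
  if (is.null(names(scene$mu_a)))
    return(list(mu_a = scene$mu_a[[1]], mu_s_prime = scene$mu_s_prime[[1]]))
  key <- as.character(wavelength)
  if (!key %in% names(scene$mu_a))
    stop("scene has no properties at ", wavelength, " nm", call. = FALSE)
  list(mu_a = scene$mu_a[[key]], mu_s_prime = scene$mu_s_prime[[key]])
}

#' Block-tiled phantom grid scene
#'
#' Emulates an accuracy experiment over a set of homogeneous
#' tissue-mimicking phantoms: the image is tiled into `n_levels_a` x
#' `n_levels_s` rectangular blocks whose absorption levels span
#' `mu_a_range` (rows) and scattering levels span `mu_s_range` (columns),
#' covering the physiologically relevant range 0.005-0.07 mm^-1 in mu_a and
#' 0.5-2 mm^-1 in mu_s'. Each block's ground truth and pixel bounds are
#' recorded in the scene's `truth` table.
#'
#' @param n_levels_a,n_levels_s Number of distinct levels per property
#'   (>= 1; a single level sits at the range midpoint).
#' @param shape Image size `c(rows, cols)` in pixels.
#' @param mu_a_range,mu_s_range Property ranges, mm^-1.
#' @param n_tissue,pixel_pitch Passed to [sfdi_scene()].
#' @return An `sfdi_scene` whose `truth` tibble has one row per block:
#'   block indices, true properties, and half-open 0-based pixel bounds.
#' @export
make_phantom_grid_scene <- function(n_levels_a = 3, n_levels_s = 3,
                                    shape = c(256L, 256L),
                                    mu_a_range = c(0.005, 0.07),
                                    mu_s_range = c(0.5, 2.0),
                                    n_tissue = 1.4, pixel_pitch = 0.3) {
  stopifnot(n_levels_a >= 1, n_levels_s >= 1)
  levels_of <- function(rg, n)
    if (n == 1) mean(rg) else seq(rg[1], rg[2], length.out = n)
  la <- levels_of(mu_a_range, n_levels_a)
  ls <- levels_of(mu_s_range, n_levels_s)
  row_edges <- round(seq(0, shape[1], length.out = n_levels_a + 1))
  col_edges <- round(seq(0, shape[2], length.out = n_levels_s + 1))

  mu_a <- matrix(NA_real_, shape[1], shape[2])
  mu_s <- matrix(NA_real_, shape[1], shape[2])
  rows <- list()
  for (i in seq_len(n_levels_a)) {
    for (j in seq_len(n_levels_s)) {
      r <- (row_edges[i] + 1):row_edges[i + 1]
      cc <- (col_edges[j] + 1):col_edges[j + 1]
      mu_a[r, cc] <- la[i]
      mu_s[r, cc] <- ls[j]
      rows[[length(rows) + 1]] <- tibble::tibble(
        block_row = i, block_col = j, mu_a = la[i], mu_s_prime = ls[j],
        row0 = row_edges[i], row1 = row_edges[i + 1],
        col0 = col_edges[j], col1 = col_edges[j + 1])
    }
  }
  sfdi_scene(mu_a, mu_s, n_tissue = n_tissue, pixel_pitch = pixel_pitch,
             truth = do.call(rbind, rows))
}

#' Hemispheric cap scene for profilometry
#'
#' A hemispherical cap of the given diameter resting on a flat reference
#' plane at the image center, with homogeneous optical properties:
#' `height(x, y) = sqrt(r^2 - d^2)` inside the footprint, 0 outside. The
#' apex height equals the radius.
#'
#' @param diameter_mm Sphere diameter, mm (> 0 and within the field of
#'   view).
#' @param base_props [optical_properties()] of the (homogeneous) material.
#' @param shape Image size `c(rows, cols)`.
#' @param pixel_pitch mm/pixel.
#' @return An `sfdi_scene` with a `height_map`.
#' @export
make_hemisphere_scene <- function(diameter_mm = 17.5,
                                  base_props = optical_properties(0.01, 1.0),
                                  shape = c(256L, 256L), pixel_pitch = 0.3) {
  if (diameter_mm <= 0) stop("diameter must be > 0", call. = FALSE)
  field <- shape * pixel_pitch
  if (diameter_mm > min(field))
    stop(sprintf("diameter %g mm exceeds the %g x %g mm field of view",
                 diameter_mm, field[1], field[2]), call. = FALSE)
  r <- diameter_mm / 2
  yc <- (shape[1] + 1) / 2; xc <- (shape[2] + 1) / 2
  rowd <- (seq_len(shape[1]) - yc) * pixel_pitch
  cold <- (seq_len(shape[2]) - xc) * pixel_pitch
  d2 <- outer(rowd^2, cold^2, `+`)
  height <- sqrt(pmax(r^2 - d2, 0))
  mu_a <- matrix(base_props$mu_a[1], shape[1], shape[2])
  mu_s <- matrix(base_props$mu_s_prime[1], shape[1], shape[2])
  sfdi_scene(mu_a, mu_s, n_tissue = base_props$n_tissue[1],
             height_map = height, pixel_pitch = pixel_pitch,
             truth = tibble::tibble(diameter_mm = diameter_mm,
                                    apex_mm = r))
}

#' Scene from chromophore concentration maps
#'
#' Builds a multi-wavelength scene whose absorption follows from known
#' oxy/deoxyhemoglobin concentration maps through the extinction table
#' (`mu_a(lambda) = E(lambda) . c`, per pixel) and whose scattering follows
#' the power law `a (lambda/800)^-b`. Recovering the concentrations through
#' the full pipeline closes the chromophore validation loop.
#'
#' @param concentrations Named list of concentration matrices (uM), names
#'   matching the extinction table chromophores (e.g. `hbo2`, `hhb`).
#' @param wavelengths Wavelengths to realize, nm.
#' @param table Extinction table; default the shipped synthetic hemoglobin
#'   fixture.
#' @param scatter_a,scatter_b Power-law parameters (mm^-1 at 800 nm, and
#'   dimensionless power).
#' @param n_tissue,pixel_pitch Passed to [sfdi_scene()].
#' @return An `sfdi_scene` with per-wavelength property maps; `truth` keeps
#'   the concentration maps.
#' @export
make_chromophore_scene <- function(concentrations,
                                   wavelengths = c(660, 735, 865),
                                   table = NULL,
                                   scatter_a = 1.0, scatter_b = 1.3,
                                   n_tissue = 1.4, pixel_pitch = 0.3) {
  table <- table %||% read_extinction_table()
  stopifnot(is.list(concentrations), !is.null(names(concentrations)))
  E <- interpolate_extinction(table, wavelengths)
  if (!all(names(concentrations) %in% colnames(E)))
    stop("concentration names must match table chromophores: ",
         paste(colnames(E), collapse = ", "), call. = FALSE)
  do.call(check_same_shape, c(concentrations,
                              list(what = "concentration maps")))
  shape <- dim(concentrations[[1]])
  mu_a <- list(); mu_s <- list()
  for (i in seq_along(wavelengths)) {
    m <- matrix(0, shape[1], shape[2])
    for (nm in names(concentrations))
      m <- m + E[i, nm] * concentrations[[nm]]
    key <- as.character(wavelengths[i])
    mu_a[[key]] <- m
    mu_s[[key]] <- matrix(scatter_a * (wavelengths[i] / 800)^(-scatter_b),
                          shape[1], shape[2])
  }
  sfdi_scene(mu_a, mu_s, n_tissue = n_tissue, pixel_pitch = pixel_pitch,
             truth = tibble::tibble(
               chromophore = names(concentrations),
               map = I(unname(concentrations)),
               scatter_a = scatter_a, scatter_b = scatter_b))
}

#' Instrument model for the simulator
#'
#' Describes the virtual SFDI instrument that renders a scene into raw
#' frames: a per-pixel multiplicative gain map (the instrument response
#' function), projection modulation depth and phase set, spatial
#' frequencies, sample-plane pixel pitch, the sensor noise model and bit
#' depth, and the phase-to-height gain used to encode surface height into
#' fringe phase.
#'
#' @param gain_map Per-pixel gain matrix, or a scalar (default 1);
#'   must be positive.
#' @param modulation_depth Projection modulation depth in (0, 1].
#' @param phases Projection phases, radians (default 0, 2*pi/3, 4*pi/3).
#' @param frequencies Spatial frequencies, mm^-1 (include 0 for the planar
#'   channel).
#' @param pixel_pitch mm/pixel in the sample plane.
#' @param orientation `"columns"` (fringes vary along image columns,
#'   default) or `"rows"`.
#' @param noise `NULL` for noiseless rendering, `"default"` for the
#'   10-bit CMOS sensor model (exposure at 600 counts per unit reflectance,
#'   Poisson shot noise at 15 photoelectrons per count, Gaussian read noise
#'   sd 2 counts, 10-bit quantization), or a list
#'   `list(counts_per_rd =, electrons_per_count =, read_sd =)`.
#' @param bit_depth 0 to disable quantization, else 8..16. Quantization
#'   acts on sensor counts, so it applies only together with a noise model
#'   (which defines the counts scale).
#' @param phase_height_gain Height encoded as `phase = height / gain`,
#'   mm/radian, applied to AC channels when the scene has a height map.
#' @param seed Integer seed making noisy renders reproducible.
#' @return An `sfdi_instrument`.
#' @export
instrument_model <- function(gain_map = 1, modulation_depth = 0.8,
                             phases = c(0, 2 * pi / 3, 4 * pi / 3),
                             frequencies = c(0, 0.1), pixel_pitch = 0.3,
                             orientation = c("columns", "rows"),
                             noise = NULL, bit_depth = 0L,
                             phase_height_gain = 2, seed = 1L) {
  orientation <- match.arg(orientation)
  if (identical(noise, "default")) {
    noise <- list(counts_per_rd = 600, electrons_per_count = 15, read_sd = 2)
    if (bit_depth == 0L) bit_depth <- 10L
  }
  if (is.matrix(gain_map) && any(gain_map <= 0) ||
      !is.matrix(gain_map) && any(gain_map <= 0))
    stop("gain must be positive", call. = FALSE)
  if (modulation_depth <= 0 || modulation_depth > 1)
    stop("modulation_depth must be in (0, 1]", call. = FALSE)
  if (length(phases) != 3)
    stop("three projection phases required", call. = FALSE)
  if (!(bit_depth == 0 || (bit_depth >= 8 && bit_depth <= 16)))
    stop("bit_depth must be 0 (off) or 8..16", call. = FALSE)
  structure(
    list(gain_map = gain_map, modulation_depth = modulation_depth,
         phases = phases, frequencies = sort(unique(frequencies)),
         pixel_pitch = pixel_pitch, orientation = orientation,
         noise = noise, bit_depth = as.integer(bit_depth),
         phase_height_gain = phase_height_gain, seed = seed),
    class = "sfdi_instrument")
}

#' Render a scene into a raw frame stack
#'
#' Forward image formation: for every wavelength, spatial frequency and
#' projection phase `p_i`, the frame is
#'
#'   `I_i(x) = gain(x) [Rd(0; x) + m Rd(fx; x) cos(2 pi fx x_mm + p_i + phi_h(x))]`
#'
#' with per-pixel reflectance from the diffusion forward model, `m` the
#' modulation depth, and `phi_h = height / phase_height_gain` encoding the
#' scene's height map into AC fringe phase. Shot noise, read noise and
#' bit-depth quantization follow when enabled; each stage is skippable and
#' the render is deterministic for a fixed instrument seed (R's global RNG
#' state is untouched).
#'
#' @param scene An `sfdi_scene`.
#' @param instrument An [instrument_model()].
#' @param wavelengths Wavelengths to render; defaults to the scene's own
#'   (or 800 nm for a wavelength-flat scene).
#' @return An `sfdi_raw_stack`: `frames` (list of matrices), `index` tibble
#'   (wavelength, fx, phase_idx, phase, frame), and acquisition `meta`.
#' @export
simulate_raw_stack <- function(scene, instrument, wavelengths = NULL) {
  stopifnot(inherits(scene, "sfdi_scene"),
            inherits(instrument, "sfdi_instrument"))
  wavelengths <- wavelengths %||%
    (if (is.null(names(scene$mu_a))) 800 else as.numeric(names(scene$mu_a)))
  nyq <- 1 / (2 * instrument$pixel_pitch)
  if (any(instrument$frequencies >= nyq))
    stop(sprintf("fx beyond Nyquist (%g mm^-1) for pixel_pitch %g mm",
                 nyq, instrument$pixel_pitch), call. = FALSE)
  shape <- scene$shape
  gain <- if (is.matrix(instrument$gain_map)) instrument$gain_map
          else matrix(instrument$gain_map, shape[1], shape[2])
  check_same_shape(gain, scene$mu_a[[1]], what = "gain map and scene")

  coord <- if (instrument$orientation == "columns")
    matrix(rep((seq_len(shape[2]) - 1) * instrument$pixel_pitch,
               each = shape[1]), shape[1], shape[2])
  else
    matrix(rep((seq_len(shape[1]) - 1) * instrument$pixel_pitch,
               times = shape[2]), shape[1], shape[2])
  phi_h <- if (!is.null(scene$height_map))
    scene$height_map / instrument$phase_height_gain
  else matrix(0, shape[1], shape[2])

  # local RNG stream so renders are reproducible and side-effect free
  has_seed <- exists(".Random.seed", envir = globalenv())
  if (has_seed) old_seed <- get(".Random.seed", envir = globalenv())
  set.seed(instrument$seed)
  on.exit({
    if (has_seed) assign(".Random.seed", old_seed, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  })

  frames <- list(); idx <- list(); fr <- 0L
  for (wl in wavelengths) {
    pm <- scene_props_at(scene, wl)
    props <- optical_properties(as.vector(pm$mu_a), as.vector(pm$mu_s_prime),
                                scene$n_tissue)
    rd0 <- matrix(diffuse_reflectance(props, 0), shape[1], shape[2])
    for (f in instrument$frequencies) {
      rdf <- if (f == 0) rd0
             else matrix(diffuse_reflectance(props, f), shape[1], shape[2])
      ph <- if (f == 0) matrix(0, shape[1], shape[2]) else phi_h
      for (k in seq_along(instrument$phases)) {
        p <- instrument$phases[k]
        img <- gain * (rd0 + instrument$modulation_depth * rdf *
                         cos(2 * pi * f * coord + p + ph))
        if (!is.null(instrument$noise)) {
          # to sensor counts: shot noise at the photoelectron level
          # (epc electrons per count), read noise, then quantization
          sc <- instrument$noise$counts_per_rd
          epc <- instrument$noise$electrons_per_count %||% 1
          counts <- rpois(length(img),
                          pmax(as.vector(img) * sc * epc, 0)) / epc +
            rnorm(length(img), 0, instrument$noise$read_sd %||% 0)
          if (instrument$bit_depth > 0)
            counts <- pmin(pmax(round(counts), 0),
                           2^instrument$bit_depth - 1)
          else counts <- pmax(counts, 0)
          img <- matrix(counts, shape[1], shape[2])
        }
        fr <- fr + 1L
        frames[[fr]] <- img
        idx[[fr]] <- tibble::tibble(wavelength = wl, fx = f,
                                    phase_idx = k - 1L, phase = p,
                                    frame = fr)
      }
    }
  }
  structure(
    list(frames = frames, index = do.call(rbind, idx),
         meta = list(bit_depth = if (is.null(instrument$noise)) 0L
                     else instrument$bit_depth,
                     counts_per_rd = instrument$noise$counts_per_rd,
                     pixel_pitch = instrument$pixel_pitch,
                     orientation = instrument$orientation,
                     modulation_depth = instrument$modulation_depth,
                     phases = instrument$phases,
                     phase_height_gain = instrument$phase_height_gain,
                     noise = instrument$noise, seed = instrument$seed,
                     exposure = NA_real_)),
    class = "sfdi_raw_stack")
}

#' Render the calibration phantom into a reference stack
#'
#' Convenience wrapper for the calibration arm of a simulated experiment:
#' builds, per wavelength, a homogeneous flat scene with the phantom's
#' interpolated properties, and renders all of them into a single raw
#' stack with the same instrument (hence the same gain map / IRF) as the
#' sample measurement.
#'
#' @param phantom An [phantom_spec()].
#' @param instrument An [instrument_model()].
#' @param wavelengths Wavelengths to render, nm.
#' @param shape Image size `c(rows, cols)`.
#' @return An `sfdi_raw_stack`.
#' @export
simulate_reference_stack <- function(phantom, instrument, wavelengths,
                                     shape = c(256L, 256L)) {
  stopifnot(inherits(phantom, "sfdi_phantom_spec"))
  stacks <- lapply(wavelengths, function(wl) {
    p <- phantom_properties_at(phantom, wl)
    sc <- sfdi_scene(matrix(p$mu_a, shape[1], shape[2]),
                     matrix(p$mu_s_prime, shape[1], shape[2]),
                     n_tissue = p$n_tissue,
                     pixel_pitch = instrument$pixel_pitch)
    simulate_raw_stack(sc, instrument, wl)
  })
  out <- stacks[[1]]
  for (k in seq_along(stacks)[-1]) {
    idx <- stacks[[k]]$index
    idx$frame <- idx$frame + length(out$frames)
    out$frames <- c(out$frames, stacks[[k]]$frames)
    out$index <- rbind(out$index, idx)
  }
  out
}

#' @export
print.sfdi_raw_stack <- function(x, ...) {
  cat(sprintf("<sfdi_raw_stack> %d frames (%dx%d px)\n",
              length(x$frames), nrow(x$frames[[1]]), ncol(x$frames[[1]])))
  cat(sprintf("  wavelengths: %s nm; fx: %s mm^-1; %d phases\n",
              paste(unique(x$index$wavelength), collapse = ", "),
              paste(unique(x$index$fx), collapse = ", "),
              length(unique(x$index$phase_idx))))
  invisible(x)
}

#' Frames of one (wavelength, frequency) triplet
#'
#' @param stack An `sfdi_raw_stack`.
#' @param wavelength Wavelength, nm.
#' @param fx Spatial frequency, mm^-1.
#' @return List of three matrices in phase order.
#' @export
stack_frames <- function(stack, wavelength, fx) {
  sel <- stack$index$wavelength == wavelength & stack$index$fx == fx
  if (sum(sel) != 3L)
    stop(sprintf("stack has %d frame(s) for (%g nm, fx %g); need 3",
                 sum(sel), wavelength, fx), call. = FALSE)
  ord <- order(stack$index$phase_idx[sel])
  stack$frames[stack$index$frame[sel][ord]]
}

#' Per-block recovery summary for a phantom grid scene
#'
#' Joins a recovered property map against the scene's block ground truth:
#' per block, the mean and standard deviation of recovered mu_a and mu_s'
#' over the block interior (a guard band excludes pixels near block edges,
#' where demodulation mixes neighboring blocks) and the percent error
#' against truth.
#'
#' @param pmap An `sfdi_property_map` recovered by the pipeline.
#' @param scene The `sfdi_scene` from [make_phantom_grid_scene()].
#' @param guard Guard band width in pixels excluded at block borders
#'   (default 2).
#' @return A tibble, one row per block, with true and recovered properties
#'   and percent errors.
#' @export
scene_block_summary <- function(pmap, scene, guard = 2) {
  stopifnot(inherits(pmap, "sfdi_property_map"),
            inherits(scene, "sfdi_scene"), !is.null(scene$truth))
  tr <- scene$truth
  out <- lapply(seq_len(nrow(tr)), function(i) {
    r <- (tr$row0[i] + 1 + guard):(tr$row1[i] - guard)
    cc <- (tr$col0[i] + 1 + guard):(tr$col1[i] - guard)
    sel <- pmap$mask[r, cc]
    ma <- pmap$mu_a[r, cc][sel]
    ms <- pmap$mu_s_prime[r, cc][sel]
    tibble::tibble(
      block_row = tr$block_row[i], block_col = tr$block_col[i],
      mu_a_true = tr$mu_a[i], mu_s_true = tr$mu_s_prime[i],
      n_px = sum(sel),
      mu_a_mean = mean(ma), mu_a_sd = sd(ma),
      mu_s_mean = mean(ms), mu_s_sd = sd(ms),
      mu_a_pct_err = 100 * (mean(ma) - tr$mu_a[i]) / tr$mu_a[i],
      mu_s_pct_err = 100 * (mean(ms) - tr$mu_s_prime[i]) / tr$mu_s_prime[i])
  })
  do.call(rbind, out)
}
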
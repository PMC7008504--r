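#' Save / load a raw frame stack
#'
#' A stack is stored as a multi-page TIFF (one page per frame, 32-bit IEEE
#' float samples scaled into `[0, 1]` by a recorded per-file factor) with a
#' JSON sidecar index mapping each page to its (wavelength, spatial
#' frequency, phase) key and carrying the acquisition metadata. Loading
#' validates that page and index counts match and that every (wavelength,
#' frequency) key has its full three-phase triplet. Round-trip is lossless
#' to 32-bit float precision (exact for integer sensor counts).
#'
#' @param stack An `sfdi_raw_stack`.
#' @param tiff_path Multi-page TIFF path.
#' @param index_path JSON index path; defaults to `<tiff_path>.json`.
#' @return `write_raw_stack` returns `tiff_path` invisibly;
#'   `load_raw_stack` the restored stack.
#' @export
write_raw_stack <- function(stack, tiff_path,
                            index_path = paste0(tiff_path, ".json")) {
  stopifnot(inherits(stack, "sfdi_raw_stack"))
  scale <- max(vapply(stack$frames, max, numeric(1)), 1)
  tiff::writeTIFF(lapply(stack$frames, function(m) m / scale),
                  tiff_path, bits.per.sample = 32L)
  jsonlite::write_json(
    list(format = "sfdi_raw_stack", version = 1L, scale = scale,
         n_frames = length(stack$frames),
         index = stack$index, meta = stack$meta),
    index_path, digits = NA, auto_unbox = TRUE, dataframe = "columns")
  invisible(tiff_path)
}

#' @rdname write_raw_stack
#' @export
load_raw_stack <- function(tiff_path,
                           index_path = paste0(tiff_path, ".json")) {
  pages <- tiff::readTIFF(tiff_path, all = TRUE)
  idx <- jsonlite::read_json(index_path, simplifyVector = TRUE)
  if (!identical(idx$format, "sfdi_raw_stack"))
    stop("not an sfdi_raw_stack index: ", index_path, call. = FALSE)
  index <- tibble::as_tibble(idx$index)
  if (nrow(index) != length(pages))
    stop(sprintf("index lists %d frame(s) but TIFF has %d page(s)",
                 nrow(index), length(pages)), call. = FALSE)
  scale <- idx$scale %||% 1
  frames <- lapply(pages, function(p) p * scale)
  if (isTRUE(idx$meta$bit_depth > 0))
    frames <- lapply(frames, round)      # integer sensor counts
  key <- paste(index$wavelength, index$fx)
  bad <- names(which(table(key) != 3))
  if (length(bad))
    stop("incomplete phase triplet for (wavelength nm, fx mm^-1) key(s): ",
         paste(bad, collapse = "; "), call. = FALSE)
  meta <- idx$meta
  structure(list(frames = frames, index = index, meta = meta),
            class = "sfdi_raw_stack")
}

#' Save / load a per-pixel map
#'
#' An [sfdi_map()] (or one layer of a property map) is written as a
#' two-page 32-bit float TIFF — values (masked pixels as 0) and the
#' validity mask — plus a JSON sidecar with the scaling factor, channel
#' metadata (wavelength, fx, kind, units) and mask statistics, so the file
#' can be re-validated standalone.
#'
#' @param map An [sfdi_map()].
#' @param tiff_path Output TIFF path.
#' @param meta_path JSON sidecar; defaults to `<tiff_path>.json`.
#' @param extra Named list merged into the sidecar (e.g. provenance).
#' @return `write_map` returns `tiff_path` invisibly; `read_map` the
#'   restored map.
#' @export
write_map <- function(map, tiff_path, meta_path = paste0(tiff_path, ".json"),
                      extra = list()) {
  stopifnot(inherits(map, "sfdi_map"))
  v <- map$values
  v[!map$mask] <- 0
  lo <- min(v, 0); hi <- max(v, lo + 1)
  scale <- hi - lo
  tiff::writeTIFF(list((v - lo) / scale, map$mask * 1),
                  tiff_path, bits.per.sample = 32L)
  jsonlite::write_json(
    c(list(format = "sfdi_map", version = 1L, offset = lo, scale = scale,
           wavelength = map$wavelength, fx = map$fx, kind = map$kind,
           units = map$units,
           n_valid = sum(map$mask), n_pixels = length(map$mask)),
      extra),
    meta_path, digits = NA, auto_unbox = TRUE)
  invisible(tiff_path)
}

#' @rdname write_map
#' @export
read_map <- function(tiff_path, meta_path = paste0(tiff_path, ".json")) {
  pages <- tiff::readTIFF(tiff_path, all = TRUE)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (!identical(meta$format, "sfdi_map"))
    stop("not an sfdi_map sidecar: ", meta_path, call. = FALSE)
  mask <- pages[[2]] > 0.5
  values <- pages[[1]] * meta$scale + meta$offset
  values[!mask] <- NA_real_
  sfdi_map(values, wavelength = meta$wavelength %||% NA_real_,
           fx = meta$fx %||% NA_real_, mask = mask,
           kind = meta$kind %||% "map", units = meta$units %||% "")
}

#' Run configuration
#'
#' Reads and validates the JSON run configuration that ties the processing
#' chain together: wavelengths (nm), the two spatial frequencies (mm^-1),
#' projection phases, file paths (sample and reference stacks, phantom
#' spec, extinction table, lookup table, output directory), ROI bounds
#' (0-based half-open `[row0, row1) x [col0, col1)`), and options
#' (nonnegative unmixing, DC source, noise floor, seed).
#'
#' @param path JSON configuration file.
#' @return The configuration as a list, validated.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    stop("config file not found: ", path, call. = FALSE)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg$config_path <- path
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg Configuration list.
#' @export
validate_run_config <- function(cfg) {
  if (length(cfg$wavelengths %||% numeric(0)) < 1)
    stop("config: need >= 1 wavelength", call. = FALSE)
  if (length(cfg$frequencies %||% numeric(0)) < 2)
    stop("config: need >= 2 spatial frequencies for inversion",
         call. = FALSE)
  need <- c("raw", "reference", "phantom")
  for (key in need) {
    p <- cfg$paths[[key]]
    if (is.null(p))
      stop("config: missing path `", key, "`", call. = FALSE)
    if (!file.exists(p))
      stop("config: file not found for `", key, "`: ", p, call. = FALSE)
  }
  for (key in c("extinction", "lut")) {
    p <- cfg$paths[[key]]
    if (!is.null(p) && !file.exists(p))
      stop("config: file not found for `", key, "`: ", p, call. = FALSE)
  }
  cfg$options <- cfg$options %||% list()
  cfg
}

#' Run the full processing chain
#'
#' In-memory core of the pipeline: demodulate the sample and reference
#' stacks, remove the instrument response by phantom calibration per
#' (wavelength, frequency) channel, invert the two-frequency reflectance
#' pair to per-pixel optical properties, and (given >= 2 wavelengths and an
#' extinction table) unmix chromophore concentrations.
#'
#' @param sample_stack,ref_stack `sfdi_raw_stack` objects measured under
#'   identical channels (the reference being the calibration phantom).
#' @param phantom An [phantom_spec()] describing the reference phantom.
#' @param lut An `sfdi_lut` whose `f_pair` matches two stack frequencies.
#' @param extinction Optional extinction table for unmixing.
#' @param dc_from,noise_floor,nonnegative,rel_tol Stage options (see
#'   [demodulate_stack()], [calibrate()], [fit_chromophores()],
#'   [invert_map()]).
#' @return A list of class `sfdi_result`: `rd_maps` (per channel),
#'   `property_maps` (per wavelength), `chromophores` (or NULL), and
#'   processing metadata.
#' @export
process_stacks <- function(sample_stack, ref_stack, phantom, lut,
                           extinction = NULL,
                           dc_from = "planar", noise_floor = 1e-3,
                           nonnegative = TRUE, rel_tol = 1e-3) {
  stopifnot(inherits(sample_stack, "sfdi_raw_stack"),
            inherits(ref_stack, "sfdi_raw_stack"))
  mods_s <- demodulate_stack(sample_stack, dc_from = dc_from)
  mods_r <- demodulate_stack(ref_stack, dc_from = dc_from)
  wavelengths <- sort(unique(sample_stack$index$wavelength))

  rd_maps <- list(); property_maps <- list()
  for (wl in wavelengths) {
    rd_pair <- list()
    for (i in 1:2) {
      f <- lut$f_pair[i]
      m_s <- modulation_map(mods_s, wl, f)
      m_r <- modulation_map(mods_r, wl, f)
      pred <- predict_reference_rd(phantom, wl, f)
      rd <- calibrate(m_s, m_r, pred, noise_floor = noise_floor)
      rd_maps[[channel_key(wl, f)]] <- rd
      rd_pair[[i]] <- rd
    }
    property_maps[[as.character(wl)]] <-
      invert_map(rd_pair[[1]], rd_pair[[2]], lut, rel_tol = rel_tol)
  }

  chrom <- NULL
  if (!is.null(extinction) && length(wavelengths) >= 2) {
    chrom <- fit_chromophores(unname(property_maps), wavelengths,
                              table = extinction,
                              nonnegative = nonnegative)
  }
  structure(
    list(rd_maps = rd_maps, property_maps = property_maps,
         chromophores = chrom,
         meta = list(wavelengths = wavelengths, f_pair = lut$f_pair,
                     dc_source = mods_s$dc_source,
                     lut_provenance = lut$model_tag)),
    class = "sfdi_result")
}

#' @export
print.sfdi_result <- function(x, ...) {
  cat(sprintf(
    "<sfdi_result> %d wavelength(s), f_pair = (%g, %g) mm^-1, LUT: %s\n",
    length(x$property_maps), x$meta$f_pair[1], x$meta$f_pair[2],
    x$meta$lut_provenance))
  cat(sprintf("  chromophores: %s\n",
              if (is.null(x$chromophores)) "not fitted"
              else paste(x$chromophores$chromophores, collapse = ", ")))
  invisible(x)
}

#' File-level pipeline entry point
#'
#' Validates the run configuration first (before any computation), loads
#' every input, runs [process_stacks()], and writes all output maps as
#' 32-bit float TIFFs with JSON sidecars plus a machine-readable provenance
#' log (configuration, file checksums, LUT provenance, package version)
#' into the output directory. Any stage failure aborts with the stage name.
#'
#' @param config A configuration list (see [read_run_config()]) or a path
#'   to the JSON file.
#' @return The `sfdi_result`, invisibly; side effect: files under
#'   `config$paths$output_dir`.
#' @export
run_pipeline <- function(config) {
  cfg <- if (is.character(config)) read_run_config(config)
         else validate_run_config(config)
  opts <- cfg$options
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage `%s` failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  sample_stack <- stage("load_raw", load_raw_stack(cfg$paths$raw))
  ref_stack <- stage("load_reference", load_raw_stack(cfg$paths$reference))
  phantom <- stage("load_phantom", read_phantom_spec(cfg$paths$phantom))
  lut <- stage("lut", {
    if (!is.null(cfg$paths$lut)) read_lut(cfg$paths$lut)
    else build_lut(f_pair = sort(cfg$frequencies)[1:2])
  })
  extinction <- if (!is.null(cfg$paths$extinction))
    stage("load_extinction", read_extinction_table(cfg$paths$extinction))
  else NULL

  res <- stage("process", process_stacks(
    sample_stack, ref_stack, phantom, lut, extinction,
    dc_from = opts$dc_from %||% "planar",
    noise_floor = opts$noise_floor %||% 1e-3,
    nonnegative = opts$nonnegative %||% TRUE))

  out <- cfg$paths$output_dir %||% "."
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  prov <- list(
    package = "sfdi",
    version = as.character(utils::packageVersion("sfdi")),
    config = cfg[setdiff(names(cfg), "config_path")],
    config_md5 = if (!is.null(cfg$config_path))
      unname(tools::md5sum(cfg$config_path)) else NA,
    lut_provenance = lut$model_tag,
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE))
  for (key in names(res$rd_maps))
    write_map(res$rd_maps[[key]],
              file.path(out, paste0("rd_", key, ".tif")),
              extra = list(provenance = prov["version"]))
  for (wl in names(res$property_maps)) {
    pm <- res$property_maps[[wl]]
    for (layer in c("mu_a", "mu_s_prime", "residual"))
      write_map(property_map_layer(pm, layer),
                file.path(out, sprintf("%s_%snm.tif", layer, wl)),
                extra = list(lut = pm$lut_provenance))
  }
  if (!is.null(res$chromophores)) {
    ch <- res$chromophores
    for (nm in ch$chromophores)
      write_map(sfdi_map(ch$concentrations[[nm]], mask = ch$mask,
                         kind = paste0("conc_", nm), units = "uM"),
                file.path(out, sprintf("conc_%s.tif", nm)))
    write_map(sfdi_map(ch$residual, mask = ch$mask,
                       kind = "unmix_residual", units = "mm^-1"),
              file.path(out, "unmix_residual.tif"))
  }
  jsonlite::write_json(prov, file.path(out, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(res)
}
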
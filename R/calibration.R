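#' Calibration phantom specification
#'
#' Describes a characterized tissue-mimicking calibration phantom by its
#' tabulated optical properties at one or more reference wavelengths. The
#' phantom used to remove the instrument response function must be well
#' characterized; a typical silicone phantom is specified near 800 nm with
#' mu_a around 0.007 mm^-1 and mu_s' around 0.93 mm^-1.
#'
#' @param wavelength Reference wavelengths, nm, strictly increasing.
#' @param mu_a,mu_s_prime Positive properties at each wavelength, mm^-1.
#' @param n_tissue Phantom refractive index.
#' @param name Label carried into provenance metadata.
#' @return An `sfdi_phantom_spec`: a tibble of reference points with
#'   attributes `n_tissue` and `name`.
#' @examples
#' phantom_spec(800, 0.007, 0.93, name = "silicone-ref")
#' @export
phantom_spec <- function(wavelength, mu_a, mu_s_prime, n_tissue = 1.4,
                         name = "phantom") {
  check_finite_numeric(wavelength, "wavelength")
  check_finite_numeric(mu_a, "mu_a")
  check_finite_numeric(mu_s_prime, "mu_s_prime")
  if (length(wavelength) < 1) stop("need >= 1 reference point", call. = FALSE)
  if (is.unsorted(wavelength, strictly = TRUE))
    stop("wavelengths must be strictly increasing", call. = FALSE)
  if (any(mu_a <= 0) || any(mu_s_prime <= 0))
    stop("phantom properties must be positive", call. = FALSE)
  out <- tibble::tibble(wavelength = wavelength,
                        mu_a = rep_len(mu_a, length(wavelength)),
                        mu_s_prime = rep_len(mu_s_prime, length(wavelength)))
  structure(out, n_tissue = n_tissue, name = name,
            class = c("sfdi_phantom_spec", class(out)))
}

#' Interpolate phantom properties to a wavelength
#'
#' Spectral harmonization of the phantom characterization: absorption is
#' interpolated with a natural cubic spline through the reference points
#' (linear when only two points are given), while reduced scattering is
#' carried by a power law `mu_s'(lambda) = a (lambda/800)^-b` fitted to the
#' reference points in log space. A single-point specification only answers
#' exact-wavelength queries; queries outside the reference span are
#' rejected rather than extrapolated.
#'
#' @param spec An [phantom_spec()].
#' @param wavelength Query wavelength, nm (scalar).
#' @return [optical_properties()] at the query wavelength.
#' @export
phantom_properties_at <- function(spec, wavelength) {
  stopifnot(inherits(spec, "sfdi_phantom_spec"))
  check_finite_numeric(wavelength, "wavelength")
  stopifnot(length(wavelength) == 1L)
  wl <- spec$wavelength
  if (nrow(spec) == 1L) {
    if (!isTRUE(all.equal(wavelength, wl)))
      stop(sprintf(
        "single-point phantom spec permits only exact-wavelength queries (%g nm)",
        wl), call. = FALSE)
    return(optical_properties(spec$mu_a, spec$mu_s_prime,
                              attr(spec, "n_tissue")))
  }
  if (wavelength < min(wl) || wavelength > max(wl))
    stop(sprintf("wavelength %g nm outside phantom reference span [%g, %g] nm",
                 wavelength, min(wl), max(wl)), call. = FALSE)
  mu_a <- spline(wl, spec$mu_a, xout = wavelength, method = "natural")$y
  law <- fit_scatter_power_law(spec$mu_s_prime, wl)
  mu_s <- law$a * (wavelength / law$lambda0)^(-law$b)
  optical_properties(mu_a, mu_s, attr(spec, "n_tissue"))
}

#' Predicted phantom reflectance
#'
#' Theoretical diffuse reflectance of the calibration phantom at a given
#' wavelength and spatial frequency, obtained by feeding the interpolated
#' phantom properties through the diffusion forward model. This is the
#' reference value against which the phantom measurement is ratioed to
#' remove the instrument response function.
#'
#' @inheritParams phantom_properties_at
#' @param fx Spatial frequency, mm^-1.
#' @return Scalar predicted reflectance.
#' @export
predict_reference_rd <- function(spec, wavelength, fx) {
  diffuse_reflectance(phantom_properties_at(spec, wavelength), fx)
}

#' Remove the instrument response function
#'
#' Converts a demodulated sample map into calibrated diffuse reflectance by
#' ratioing against the phantom measurement acquired under the same channel
#' and scaling by the phantom's predicted reflectance:
#' `rd = (m_sample / m_ref) * rd_ref_pred`, per pixel. Because sample and
#' reference share the multiplicative instrument gain, the gain cancels
#' exactly. Reference pixels at or below the noise floor are masked invalid
#' rather than divided through.
#'
#' @param m_sample,m_ref [sfdi_map()] modulation maps sharing shape,
#'   wavelength and spatial frequency.
#' @param rd_ref_pred Predicted phantom reflectance for this channel (see
#'   [predict_reference_rd()]).
#' @param noise_floor Fraction of `max(m_ref)` below which reference pixels
#'   are considered unmeasured (default 1e-3).
#' @return An [sfdi_map()] of kind "rd" (dimensionless reflectance).
#' @export
calibrate <- function(m_sample, m_ref, rd_ref_pred, noise_floor = 1e-3) {
  stopifnot(inherits(m_sample, "sfdi_map"), inherits(m_ref, "sfdi_map"))
  same_chan <- function(a, b)
    (is.na(a) && is.na(b)) || isTRUE(all.equal(a, b))
  if (!same_chan(m_sample$wavelength, m_ref$wavelength) ||
      !same_chan(m_sample$fx, m_ref$fx))
    stop(sprintf(
      "channel mismatch: sample (%g nm, fx %g) vs reference (%g nm, fx %g)",
      m_sample$wavelength, m_sample$fx, m_ref$wavelength, m_ref$fx),
      call. = FALSE)
  check_same_shape(m_sample$values, m_ref$values, what = "modulation maps")
  check_finite_numeric(rd_ref_pred, "rd_ref_pred")

  floor_level <- noise_floor * max(m_ref$values)
  ok <- m_sample$mask & m_ref$mask & (m_ref$values > floor_level)
  rd <- (m_sample$values / m_ref$values) * rd_ref_pred
  rd[!ok] <- NA_real_
  sfdi_map(rd, wavelength = m_sample$wavelength, fx = m_sample$fx,
           mask = ok, kind = "rd", units = "")
}

#' Read / write a phantom specification
#'
#' CSV columns `wavelength_nm, mu_a_per_mm, mu_s_prime_per_mm`, with a JSON
#' sidecar header carrying `name` and `n_tissue`.
#'
#' @param spec An [phantom_spec()].
#' @param csv_path CSV path; the header defaults to `<csv_path>.json`.
#' @param header_path Optional explicit header path.
#' @return `write_phantom_spec` returns `csv_path` invisibly;
#'   `read_phantom_spec` the restored spec.
#' @export
write_phantom_spec <- function(spec, csv_path,
                               header_path = paste0(csv_path, ".json")) {
  stopifnot(inherits(spec, "sfdi_phantom_spec"))
  df <- data.frame(wavelength_nm = spec$wavelength,
                   mu_a_per_mm = spec$mu_a,
                   mu_s_prime_per_mm = spec$mu_s_prime)
  write.csv(df, csv_path, row.names = FALSE)
  jsonlite::write_json(list(name = attr(spec, "name"),
                            n_tissue = attr(spec, "n_tissue")),
                       header_path, auto_unbox = TRUE, digits = NA)
  invisible(csv_path)
}

#' @rdname write_phantom_spec
#' @export
read_phantom_spec <- function(csv_path,
                              header_path = paste0(csv_path, ".json")) {
  df <- read.csv(csv_path)
  hdr <- if (file.exists(header_path))
    jsonlite::read_json(header_path, simplifyVector = TRUE)
  else list(name = "phantom", n_tissue = 1.4)
  phantom_spec(df$wavelength_nm, df$mu_a_per_mm, df$mu_s_prime_per_mm,
               n_tissue = hdr$n_tissue %||% 1.4,
               name = hdr$name %||% "phantom")
}
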
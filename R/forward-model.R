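#' Optical properties of a turbid medium
#'
#' Bundles the absorption coefficient, reduced scattering coefficient and
#' refractive index that parameterize photon transport in a semi-infinite
#' homogeneous medium. Fields may be vectors (recycled to a common length),
#' so a single object can describe many media at once.
#'
#' @param mu_a Absorption coefficient, mm^-1 (>= 0).
#' @param mu_s_prime Reduced scattering coefficient, mm^-1 (> 0).
#' @param n_tissue Refractive index of the medium (>= 1). Default 1.4, the
#'   standard soft-tissue value.
#' @return An object of class `sfdi_props`: a list with vector fields
#'   `mu_a`, `mu_s_prime`, `n_tissue`.
#' @examples
#' optical_properties(0.01, 1.0)
#' @export
optical_properties <- function(mu_a, mu_s_prime, n_tissue = 1.4) {
  check_finite_numeric(mu_a, "mu_a")
  check_finite_numeric(mu_s_prime, "mu_s_prime")
  check_finite_numeric(n_tissue, "n_tissue")
  if (any(mu_a < 0)) stop("mu_a must be >= 0", call. = FALSE)
  if (any(mu_s_prime <= 0)) stop("mu_s_prime must be > 0", call. = FALSE)
  if (any(n_tissue < 1)) stop("n_tissue must be >= 1", call. = FALSE)
  n <- max(length(mu_a), length(mu_s_prime), length(n_tissue))
  structure(
    list(mu_a = rep_len(mu_a, n),
         mu_s_prime = rep_len(mu_s_prime, n),
         n_tissue = rep_len(n_tissue, n)),
    class = "sfdi_props")
}

#' @export
print.sfdi_props <- function(x, ...) {
  n <- length(x$mu_a)
  cat(sprintf("<sfdi_props> %d medium/media\n", n))
  show <- seq_len(min(n, 6L))
  cat(sprintf("  mu_a = %s mm^-1\n", paste(signif(x$mu_a[show], 4), collapse = ", ")))
  cat(sprintf("  mu_s' = %s mm^-1\n", paste(signif(x$mu_s_prime[show], 4), collapse = ", ")))
  cat(sprintf("  n = %s\n", paste(unique(signif(x$n_tissue[show], 4)), collapse = ", ")))
  invisible(x)
}

# internal: effective boundary reflection parameter from index mismatch
# (Groenhuis/Egan-Hilgeman polynomial in n, standard in the diffusion
# boundary condition for tissue optics)
boundary_A <- function(n_tissue) {
  r_eff <- 0.0636 * n_tissue + 0.668 + 0.710 / n_tissue - 1.440 / n_tissue^2
  (1 - r_eff) / (2 * (1 + r_eff))
}

#' Diffuse reflectance in the spatial frequency domain
#'
#' Closed-form diffusion-approximation forward model for the diffuse
#' reflectance `Rd` of a semi-infinite homogeneous medium illuminated by a
#' sinusoidal pattern of spatial frequency `fx` (mm^-1). This is the sample's
#' spatial modulation transfer function evaluated at one frequency. With
#' `mu_tr = mu_a + mu_s'`, `a' = mu_s'/mu_tr`, and scalar attenuation
#' `mu_eff'(fx) = sqrt(3 mu_a mu_tr + (2 pi fx)^2)`,
#'
#'   `Rd = 3 A a' / ((mu_eff'/mu_tr + 1) (mu_eff'/mu_tr + 3 A))`
#'
#' where `A` encodes the refractive-index-mismatch boundary condition. In the
#' lossless planar limit (`mu_a = 0`, `fx = 0`) the expression equals 1
#' exactly; it decreases monotonically in both `mu_a` and `fx`.
#'
#' @param props An [optical_properties()] object (fields may be vectors).
#' @param fx Spatial frequency in the sample plane, mm^-1 (>= 0). Recycled
#'   against the property vectors.
#' @return Dimensionless reflectance in `[0, 1]`, vectorized.
#' @examples
#' diffuse_reflectance(optical_properties(0.01, 1.0), fx = c(0, 0.1))
#' @export
diffuse_reflectance <- function(props, fx) {
  stopifnot(inherits(props, "sfdi_props"))
  check_finite_numeric(fx, "fx")
  if (any(fx < 0)) stop("fx must be >= 0", call. = FALSE)
  n <- max(length(props$mu_a), length(fx))
  mu_a <- rep_len(props$mu_a, n)
  mu_s <- rep_len(props$mu_s_prime, n)
  nt <- rep_len(props$n_tissue, n)
  fx <- rep_len(fx, n)
  mu_tr <- mu_a + mu_s
  a_p <- mu_s / mu_tr
  mu_eff <- sqrt(3 * mu_a * mu_tr + (2 * pi * fx)^2)
  A <- boundary_A(nt)
  x <- mu_eff / mu_tr
  3 * A * a_p / ((x + 1) * (x + 3 * A))
}

#' Build a two-frequency lookup table
#'
#' Precomputes diffuse reflectance over a (mu_a, mu_s') grid at the two
#' spatial frequencies used for inversion. By default mu_a nodes are
#' log-spaced (reflectance varies fastest at low absorption) and mu_s' nodes
#' linear. The table is the forward image used by [invert_pair()] /
#' [invert_map()] to recover optical properties per pixel.
#'
#' @param f_pair Two spatial frequencies, mm^-1, ascending.
#' @param mu_a_range,mu_s_range Positive `c(lo, hi)` bounds, mm^-1.
#' @param grid_sizes Nodes per axis `c(n_mu_a, n_mu_s)`, each >= 2.
#' @param model_tag `"diffusion"` (closed form, deterministic) or
#'   `"monte_carlo"` (photon simulation at each node; slow, seeded).
#' @param n_tissue Refractive index used for every node.
#' @param mu_a_spacing `"log"` or `"linear"` node spacing for the mu_a axis.
#' @param n_photons,seed Monte Carlo controls (ignored for diffusion).
#' @return An `sfdi_lut` with grid vectors, the two reflectance matrices
#'   (`rd_low`, `rd_high`; rows index mu_a, columns mu_s'), provenance and
#'   any validity notes.
#' @export
build_lut <- function(f_pair = c(0, 0.1),
                      mu_a_range = c(0.001, 0.5),
                      mu_s_range = c(0.1, 5),
                      grid_sizes = c(128L, 128L),
                      model_tag = c("diffusion", "monte_carlo"),
                      n_tissue = 1.4,
                      mu_a_spacing = c("log", "linear"),
                      n_photons = 1e5, seed = 1L) {
  model_tag <- match.arg(model_tag)
  mu_a_spacing <- match.arg(mu_a_spacing)
  if (length(f_pair) != 2L || any(f_pair < 0) || f_pair[1] >= f_pair[2])
    stop("f_pair must be two ascending nonnegative frequencies", call. = FALSE)
  for (rg in list(mu_a_range = mu_a_range, mu_s_range = mu_s_range)) {
    if (length(rg) != 2L || any(rg <= 0) || rg[1] >= rg[2])
      stop("property ranges must be positive and ordered (lo < hi)", call. = FALSE)
  }
  if (any(grid_sizes < 2)) stop("grid_sizes must be >= 2 per axis", call. = FALSE)

  mu_a_grid <- if (mu_a_spacing == "log") {
    exp(seq(log(mu_a_range[1]), log(mu_a_range[2]), length.out = grid_sizes[1]))
  } else {
    seq(mu_a_range[1], mu_a_range[2], length.out = grid_sizes[1])
  }
  mu_s_grid <- seq(mu_s_range[1], mu_s_range[2], length.out = grid_sizes[2])

  # validity bookkeeping: kept in the table's metadata, shown by print()
  notes <- character(0)
  if (mu_s_range[1] / mu_a_range[2] < 10) {
    notes <- c(notes, paste0(
      "grid includes nodes with mu_s'/mu_a < 10 where the diffusion ",
      "approximation degrades"))
  }

  g <- expand.grid(mu_a = mu_a_grid, mu_s = mu_s_grid)
  if (model_tag == "diffusion") {
    props <- optical_properties(g$mu_a, g$mu_s, n_tissue)
    rd_low <- matrix(diffuse_reflectance(props, f_pair[1]),
                     nrow = grid_sizes[1])
    rd_high <- matrix(diffuse_reflectance(props, f_pair[2]),
                      nrow = grid_sizes[1])
  } else {
    rd_low <- rd_high <- matrix(NA_real_, grid_sizes[1], grid_sizes[2])
    for (k in seq_len(nrow(g))) {
      est <- monte_carlo_rd(optical_properties(g$mu_a[k], g$mu_s[k], n_tissue),
                            fx = f_pair, n_photons = n_photons,
                            seed = seed + k)
      i <- (k - 1L) %% grid_sizes[1] + 1L
      j <- (k - 1L) %/% grid_sizes[1] + 1L
      rd_low[i, j] <- est$rd[1]
      rd_high[i, j] <- est$rd[2]
    }
  }

  structure(
    list(f_pair = as.numeric(f_pair),
         mu_a_grid = mu_a_grid, mu_s_grid = mu_s_grid,
         rd_low = rd_low, rd_high = rd_high,
         model_tag = model_tag, n_tissue = n_tissue,
         notes = notes,
         created = format(Sys.time(), tz = "UTC", usetz = TRUE)),
    class = "sfdi_lut")
}

#' @export
print.sfdi_lut <- function(x, ...) {
  cat(sprintf("<sfdi_lut> %dx%d grid, fx = (%g, %g) mm^-1, model = %s\n",
              length(x$mu_a_grid), length(x$mu_s_grid),
              x$f_pair[1], x$f_pair[2], x$model_tag))
  cat(sprintf("  mu_a in [%g, %g] mm^-1; mu_s' in [%g, %g] mm^-1; n = %g\n",
              min(x$mu_a_grid), max(x$mu_a_grid),
              min(x$mu_s_grid), max(x$mu_s_grid), x$n_tissue))
  if (length(x$notes)) cat("  note:", x$notes, sep = "\n  ")
  invisible(x)
}

#' Serialize / restore a lookup table
#'
#' The table is stored as a self-describing JSON archive (grid vectors, both
#' reflectance matrices at full double precision, frequency pair, provenance
#' tag and creation metadata), so tables generated elsewhere (for example a
#' true photon Monte Carlo run) can be dropped in. Round-trip is lossless.
#'
#' @param lut An `sfdi_lut`.
#' @param path File path for the JSON archive.
#' @return `write_lut` returns `path` invisibly; `read_lut` the restored
#'   `sfdi_lut`.
#' @export
write_lut <- function(lut, path) {
  stopifnot(inherits(lut, "sfdi_lut"))
  payload <- list(
    format = "sfdi_lut", version = 1L,
    f_pair = lut$f_pair,
    mu_a_grid = lut$mu_a_grid, mu_s_grid = lut$mu_s_grid,
    # matrices flattened column-major with explicit dims: unambiguous
    dim = dim(lut$rd_low),
    rd_low = as.vector(lut$rd_low), rd_high = as.vector(lut$rd_high),
    model_tag = if (lut$model_tag %in% c("diffusion", "monte_carlo"))
      lut$model_tag else "imported",
    n_tissue = lut$n_tissue, notes = lut$notes, created = lut$created)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_lut
#' @export
read_lut <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "sfdi_lut"))
    stop("not an sfdi_lut archive: ", path, call. = FALSE)
  dm <- as.integer(p$dim)
  structure(
    list(f_pair = as.numeric(p$f_pair),
         mu_a_grid = as.numeric(p$mu_a_grid),
         mu_s_grid = as.numeric(p$mu_s_grid),
         rd_low = matrix(as.numeric(p$rd_low), dm[1], dm[2]),
         rd_high = matrix(as.numeric(p$rd_high), dm[1], dm[2]),
         model_tag = p$model_tag, n_tissue = p$n_tissue,
         notes = as.character(p$notes %||% character(0)),
         created = p$created),
    class = "sfdi_lut")
}

#' Monte Carlo diffuse reflectance
#'
#' Photon random-walk estimate of the spatial-frequency-domain diffuse
#' reflectance of a semi-infinite homogeneous medium, used as an independent
#' cross-check on the diffusion closed form. Scattering follows the
#' Henyey-Greenstein phase function with anisotropy `g` at
#' `mu_s = mu_s' / (1 - g)`, so the reduced coefficient is preserved while
#' the sub-diffusive (short-pathlength) response keeps the forward-peaked
#' character of tissue scattering; `g = 0` degenerates to isotropic
#' scattering at the reduced coefficient. Absorption is handled by weight
#' attenuation with Russian roulette, and the refractive-index mismatch at
#' the surface applies unpolarized Fresnel reflection with total internal
#' reflection beyond the critical angle. Escaping photons are binned by exit
#' radius (0.1 mm bins to 50 mm) and `Rd(fx)` is the zeroth-order Bessel
#' (Hankel) transform of the radial reflectance profile.
#'
#' @param props [optical_properties()] of a single medium; `mu_s_prime` must
#'   be positive (the walk is undefined without scattering).
#' @param fx Spatial frequencies to evaluate, mm^-1 (vectorized: one walk
#'   serves all frequencies).
#' @param n_photons Number of photon packets (>= 1000).
#' @param seed Integer seed; runs are bitwise-reproducible per seed and do
#'   not touch R's global RNG state.
#' @param bin_width,r_max Radial binning of exiting photons, mm.
#' @param g Scattering anisotropy in `[0, 1)`; default 0.8 (soft tissue).
#' @return An `sfdi_mc_rd` list: `rd` and `se` (standard error) per
#'   frequency, the radial bin weights, and the call parameters.
#' @examples
#' monte_carlo_rd(optical_properties(0.01, 1), fx = c(0, 0.1),
#'                n_photons = 2000, seed = 7)
#' @export
monte_carlo_rd <- function(props, fx, n_photons = 1e5, seed = 1L,
                           bin_width = 0.1, r_max = 50, g = 0.8) {
  stopifnot(inherits(props, "sfdi_props"))
  if (length(props$mu_a) != 1L)
    stop("monte_carlo_rd expects a single medium", call. = FALSE)
  if (props$mu_s_prime <= 0)
    stop(paste("mu_s_prime must be > 0: the random walk is undefined under",
               "the reduced-scattering parameterization without scattering"),
         call. = FALSE)
  check_finite_numeric(fx, "fx")
  if (any(fx < 0)) stop("fx must be >= 0", call. = FALSE)
  if (n_photons < 1e3) stop("n_photons must be >= 1000", call. = FALSE)
  if (g < 0 || g >= 1) stop("g must be in [0, 1)", call. = FALSE)
  mu_s_full <- props$mu_s_prime / (1 - g)
  res <- mc_radial_rd_cpp(props$mu_a, mu_s_full, props$n_tissue,
                          as.numeric(fx), as.integer(n_photons),
                          as.numeric(seed), bin_width, r_max, g)
  structure(
    list(rd = as.numeric(res$rd), se = as.numeric(res$se), fx = as.numeric(fx),
         bin_weight = as.numeric(res$bin_weight), bin_width = bin_width,
         n_photons = as.integer(n_photons), seed = seed, g = g, props = props),
    class = "sfdi_mc_rd")
}

#' @export
print.sfdi_mc_rd <- function(x, ...) {
  cat(sprintf("<sfdi_mc_rd> %d photons, seed %s\n", x$n_photons,
              format(x$seed)))
  for (k in seq_along(x$fx))
    cat(sprintf("  Rd(fx = %g) = %.5f (se %.5f)\n", x$fx[k], x$rd[k], x$se[k]))
  invisible(x)
}
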
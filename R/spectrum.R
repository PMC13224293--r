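#' Spectrum objects
#'
#' An `ir_spectrum` holds intensities on an [ir_grid()]; a `raw_spectrum`
#' holds arbitrary (wavenumber, intensity) points, e.g. straight from a
#' dipole-trajectory Fourier transform or an instrument export, before
#' interpolation onto the common grid. Raw intensities may be negative
#' (numerical noise); gridded, preprocessed spectra never are.
#'
#' A spectrum flagged `normalized` has unit rectangle-rule area:
#' `sum(intensities) * step == 1` within 1e-9. Unit-area
#' ("probability-density-like") spectra are what all comparison metrics and
#' unmixing routines operate on.
#'
#' @param grid an [ir_grid()].
#' @param intensities numeric vector of length `grid$n_points`.
#' @param normalized logical; assert (and check) unit area.
#' @return An `ir_spectrum`.
#' @export
ir_spectrum <- function(grid, intensities, normalized = FALSE) {
  stopifnot(inherits(grid, "ir_grid"))
  intensities <- as.numeric(intensities)
  if (length(intensities) != grid$n_points)
    stop("`intensities` must have length grid$n_points", call. = FALSE)
  if (any(!is.finite(intensities)))
    stop("`intensities` must be finite", call. = FALSE)
  if (normalized) {
    if (any(intensities < 0))
      stop("a normalized spectrum cannot contain negative intensities",
           call. = FALSE)
    area <- sum(intensities) * grid$step
    if (abs(area - 1) > 1e-9)
      stop(sprintf("normalized = TRUE but area = %.12g (must be 1 +/- 1e-9)",
                   area), call. = FALSE)
  }
  structure(list(grid = grid, intensities = intensities,
                 normalized = isTRUE(normalized)),
            class = "ir_spectrum")
}

#' @export
print.ir_spectrum <- function(x, ...) {
  cat(sprintf("<ir_spectrum> %d points, %s, max intensity %.4g at %g cm^-1\n",
              x$grid$n_points,
              if (x$normalized) "unit-area" else "unnormalized",
              max(x$intensities),
              grid_wavenumbers(x$grid)[which.max(x$intensities)]))
  invisible(x)
}

#' @rdname ir_spectrum
#' @param wavenumber,intensity numeric vectors of equal length (>= 2
#'   points); wavenumbers strictly increasing.
#' @export
raw_spectrum <- function(wavenumber, intensity) {
  wavenumber <- as.numeric(wavenumber)
  intensity <- as.numeric(intensity)
  if (length(wavenumber) != length(intensity))
    stop("`wavenumber` and `intensity` must have equal length", call. = FALSE)
  if (length(wavenumber) < 2)
    stop("a raw spectrum needs at least 2 points", call. = FALSE)
  if (any(!is.finite(wavenumber)) || any(!is.finite(intensity)))
    stop("raw spectrum values must be finite", call. = FALSE)
  if (any(diff(wavenumber) <= 0))
    stop("wavenumbers must be strictly increasing", call. = FALSE)
  structure(list(wavenumber = wavenumber, intensity = intensity),
            class = "raw_spectrum")
}

#' Interpolate a raw spectrum onto a uniform grid
#'
#' Linear interpolation at each grid point; grid points outside the raw
#' spectrum's wavenumber range get intensity 0. The result is neither
#' clipped nor normalized — follow with [preprocess_spectrum()].
#'
#' @param raw a [raw_spectrum()].
#' @param grid an [ir_grid()]; defaults to the common 0--4996 cm^-1 grid.
#' @return An unnormalized `ir_spectrum`.
#' @export
regrid <- function(raw, grid = default_grid()) {
  if (!inherits(raw, "raw_spectrum"))
    stop("`raw` must be a raw_spectrum", call. = FALSE)
  nu <- grid_wavenumbers(grid)
  y <- stats::approx(raw$wavenumber, raw$intensity, xout = nu,
                     method = "linear", yleft = 0, yright = 0,
                     ties = "ordered")$y
  ir_spectrum(grid, y, normalized = FALSE)
}

#' Smooth, clip and normalize a spectrum
#'
#' The standard preprocessing applied to every spectrum before comparison
#' or unmixing, in this order: Gaussian smoothing (discrete convolution,
#' reflective edges, kernel truncated at 4 sigma), clipping of negative
#' intensities to zero, and unit-area normalization (division by
#' `sum * step`). Reflective edge handling conserves the total intensity
#' sum exactly, so smoothing never changes a spectrum's area.
#'
#' @param spec an `ir_spectrum`.
#' @param smooth_sigma Gaussian kernel width in cm^-1 (0 disables
#'   smoothing). The package default for noisy simulation output is 8
#'   cm^-1 (two grid steps on the default grid).
#' @param clip clip negative intensities to zero.
#' @param normalize scale to unit rectangle-rule area.
#' @return An `ir_spectrum`, `normalized` if requested.
#' @export
preprocess_spectrum <- function(spec, smooth_sigma = 0, clip = TRUE,
                                normalize = TRUE) {
  stopifnot(inherits(spec, "ir_spectrum"))
  if (!is.numeric(smooth_sigma) || length(smooth_sigma) != 1 ||
      smooth_sigma < 0)
    stop("`smooth_sigma` must be a single non-negative number", call. = FALSE)
  y <- spec$intensities
  if (smooth_sigma > 0)
    y <- gaussian_smooth(y, smooth_sigma / spec$grid$step)
  if (clip) y <- pmax(y, 0)
  if (normalize) {
    area <- sum(y) * spec$grid$step
    if (area <= 0)
      stop("degenerate spectrum: zero total intensity, cannot normalize",
           call. = FALSE)
    y <- y / area
  }
  ir_spectrum(spec$grid, y, normalized = normalize)
}

# Discrete Gaussian convolution, sigma in grid units. Half-sample symmetric
# (edge-repeated) reflection: index 0 -> 1, -1 -> 2, n+1 -> n. For a
# symmetric kernel this padding conserves the total intensity sum exactly
# (each source column of the implied smoothing matrix sums to 1).
gaussian_smooth <- function(y, sigma) {
  n <- length(y)
  r <- ceiling(4 * sigma)
  if (r < 1) return(y)
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  pad_left <- y[pmin(n, r:1)]
  pad_right <- y[pmax(1, n:(n - r + 1))]
  yp <- c(pad_left, y, pad_right)
  out <- stats::convolve(yp, rev(k), type = "filter")
  stopifnot(length(out) == n)
  out
}

#' Mean squared error between two spectra
#'
#' Mean over grid points of the squared intensity difference. Used both as
#' a fit metric and as the spectral distance that defines nearest
#' neighbours and true/false-positive pairing in misidentification
#' profiling.
#'
#' @param a,b `ir_spectrum` objects on the same grid.
#' @return A non-negative scalar.
#' @export
spectral_mse <- function(a, b) {
  stopifnot(inherits(a, "ir_spectrum"), inherits(b, "ir_spectrum"))
  check_same_grid(a, b)
  mean((a$intensities - b$intensities)^2)
}

#' Cumulative distribution of a unit-area spectrum
#'
#' Running rectangle-rule integral `cumsum(intensities) * step`. Requires a
#' normalized spectrum, so the result is non-decreasing and ends at 1.
#'
#' @param spec a normalized `ir_spectrum`.
#' @return Numeric vector in \[0, 1\], one value per grid point.
#' @export
spectrum_cdf <- function(spec) {
  stopifnot(inherits(spec, "ir_spectrum"))
  if (!spec$normalized)
    stop("spectrum_cdf requires a normalized spectrum", call. = FALSE)
  cumsum(spec$intensities) * spec$grid$step
}

#' Average CDF difference between two spectra
#'
#' The mean, over all grid points, of the difference between the two
#' spectra's cumulative distributions — a shift-sensitive comparison of
#' unit-area spectra. With `signed = TRUE` the sign carries direction: a
#' positive value means `a`'s intensity sits at lower wavenumbers than
#' `b`'s (`a` red-shifted relative to `b`). For a rigid on-grid shift of
#' \eqn{\delta} cm^-1 the signed value equals \eqn{\delta / \mathrm{span}}
#' with span = [grid_span()].
#'
#' @param a,b normalized `ir_spectrum` objects on one grid.
#' @param signed if `FALSE`, average the absolute CDF gap instead.
#' @return A scalar; in \[-1, 1\] for `signed`, \[0, 1\] otherwise.
#' @export
avg_cdf_difference <- function(a, b, signed = TRUE) {
  d <- spectrum_cdf(a) - spectrum_cdf(b)
  if (signed) mean(d) else mean(abs(d))
}

#' First moment (mean wavenumber) of a unit-area spectrum
#'
#' @param spec a normalized `ir_spectrum`.
#' @return Intensity-weighted mean wavenumber (cm^-1).
#' @export
mean_wavenumber <- function(spec) {
  stopifnot(inherits(spec, "ir_spectrum"))
  if (!spec$normalized)
    stop("mean_wavenumber requires a normalized spectrum", call. = FALSE)
  sum(grid_wavenumbers(spec$grid) * spec$intensities) * spec$grid$step
}
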
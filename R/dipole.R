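# speed of light in cm per femtosecond
C_CM_PER_FS <- 2.99792458e-5

#' Dipole-moment trajectory
#'
#' The total dipole moment \eqn{M(t)} of a simulation box sampled at a
#' fixed time step, the raw material for a simulated IR spectrum.
#'
#' @param timestep_fs sampling interval in femtoseconds, > 0.
#' @param dipoles numeric matrix, one row per sample, 3 columns (x, y, z
#'   dipole components in any consistent unit); at least 16 samples.
#' @param temperature optional simulation temperature in kelvin (metadata
#'   only; the combined quantum/field correction applied to spectra is the
#'   temperature-independent \eqn{\nu^2} form).
#' @return A `dipole_trajectory`.
#' @export
dipole_trajectory <- function(timestep_fs, dipoles, temperature = NULL) {
  if (!is.numeric(timestep_fs) || length(timestep_fs) != 1 ||
      timestep_fs <= 0)
    stop("`timestep_fs` must be a single positive number", call. = FALSE)
  dipoles <- as.matrix(dipoles)
  if (ncol(dipoles) != 3)
    stop("`dipoles` must have 3 columns (x, y, z)", call. = FALSE)
  if (nrow(dipoles) < 16)
    stop("a trajectory needs at least 16 samples", call. = FALSE)
  if (any(!is.finite(dipoles)))
    stop("dipole components must be finite", call. = FALSE)
  structure(list(timestep_fs = timestep_fs, dipoles = dipoles,
                 temperature = temperature),
            class = "dipole_trajectory")
}

#' @export
print.dipole_trajectory <- function(x, ...) {
  cat(sprintf(
    "<dipole_trajectory> %d samples at %g fs (%.3g ps), Nyquist %.0f cm^-1\n",
    nrow(x$dipoles), x$timestep_fs,
    nrow(x$dipoles) * x$timestep_fs / 1000,
    1 / (2 * C_CM_PER_FS * x$timestep_fs)))
  invisible(x)
}

#' Dipole autocorrelation function
#'
#' \eqn{C(\tau_k) = \langle M(t) \cdot M(t + \tau_k) \rangle}, the
#' ensemble average over all valid time origins of the dot product between
#' the total dipole and its lagged copy. The unbiased estimator (division
#' by the number of valid origins at each lag) is used; lag-products are
#' accumulated with an FFT so long trajectories stay cheap.
#'
#' @param traj a [dipole_trajectory()].
#' @param max_lag largest lag index (in samples), `0 < max_lag <` sample
#'   count; default half the trajectory.
#' @return Numeric vector of length `max_lag + 1` (lags 0..max_lag).
#' @export
dipole_autocorrelation <- function(traj, max_lag = NULL) {
  stopifnot(inherits(traj, "dipole_trajectory"))
  n <- nrow(traj$dipoles)
  if (is.null(max_lag)) max_lag <- n %/% 2
  if (!is.numeric(max_lag) || length(max_lag) != 1 ||
      max_lag != round(max_lag) || max_lag <= 0 || max_lag >= n)
    stop("`max_lag` must be an integer in (0, sample count)", call. = FALSE)
  # FFT-based raw lag sums per cartesian component, then unbiased scaling
  nfft <- 2^ceiling(log2(2 * n))
  raw <- numeric(max_lag + 1)
  for (d in 1:3) {
    x <- traj$dipoles[, d]
    fx <- stats::fft(c(x, numeric(nfft - n)))
    s <- Re(stats::fft(Mod(fx)^2, inverse = TRUE)) / nfft
    raw <- raw + s[seq_len(max_lag + 1)]
  }
  raw / (n - 0:max_lag)
}

#' IR spectrum from a dipole trajectory
#'
#' The classical line shape is the Fourier transform \eqn{\tilde C(\nu)}
#' of the dipole autocorrelation function; the combined field-coupling and
#' quantum correction turns it into the absorbance spectrum
#' \deqn{S_{qm}(\nu) = \tilde C(\nu)\,\nu^2.}
#' The autocorrelation (optionally Hann-windowed to suppress truncation
#' ringing) is evenly extended and transformed; the frequency axis is
#' converted to wavenumber via \eqn{\nu[\mathrm{cm}^{-1}] = f / c} and the
#' result is interpolated onto `grid`, clipped and unit-area normalized.
#'
#' @param traj a [dipole_trajectory()].
#' @param grid target [ir_grid()]; its maximum wavenumber must lie below
#'   the Nyquist limit \eqn{1 / (2 c\, \Delta t)}.
#' @param max_lag autocorrelation length (default: half the trajectory;
#'   sets the frequency resolution \eqn{1/(2\,\mathrm{max\_lag}\,\Delta t
#'   \,c)} in cm^-1).
#' @param window `"hann"` (default) or `"none"`.
#' @param smooth_sigma Gaussian smoothing passed to
#'   [preprocess_spectrum()] (cm^-1; default 0).
#' @return A normalized `ir_spectrum` on `grid`.
#' @export
spectrum_from_dipole <- function(traj, grid = default_grid(),
                                 max_lag = NULL,
                                 window = c("hann", "none"),
                                 smooth_sigma = 0) {
  window <- match.arg(window)
  stopifnot(inherits(traj, "dipole_trajectory"), inherits(grid, "ir_grid"))
  if (all(traj$dipoles == 0))
    stop("degenerate spectrum: all-zero dipole trajectory", call. = FALSE)
  nyquist <- 1 / (2 * C_CM_PER_FS * traj$timestep_fs)
  nu_max <- grid$start + (grid$n_points - 1) * grid$step
  if (nu_max >= nyquist)
    stop(sprintf(
      "grid extends to %.0f cm^-1 but the trajectory Nyquist limit is %.0f cm^-1 (aliasing)",
      nu_max, nyquist), call. = FALSE)
  a <- dipole_autocorrelation(traj, max_lag)
  L <- length(a) - 1L
  if (window == "hann")
    a <- a * 0.5 * (1 + cos(pi * (0:L) / L))
  # even extension (C(-tau) = C(tau)) -> real, symmetric transform
  ext <- c(a, rev(a[2:L]))
  ctil <- Re(stats::fft(ext))[1:(L + 1)]
  nu <- (0:L) / (2 * L * traj$timestep_fs) / C_CM_PER_FS
  s_qm <- ctil * nu^2
  spec <- regrid(raw_spectrum(nu, s_qm), grid)
  preprocess_spectrum(spec, smooth_sigma = smooth_sigma, clip = TRUE,
                      normalize = TRUE)
}
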
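## frequency conversion: 1 fs^-1 in cm^-1 (1e15 / c with c in cm/s)
CM1_PER_INV_FS <- 1e15 / 2.99792458e10

#' Estimate velocities from a position track
#'
#' Central differences at interior points, one-sided differences at the two
#' ends; the series length is preserved.
#'
#' @param track Numeric matrix (n x 3) or vector of ordered positions
#'   (Angstrom).
#' @param dt Sampling interval (fs), > 0.
#' @return Velocities in Angstrom/fs, same shape as `track`.
#' @export
estimate_velocity <- function(track, dt) {
  if (is.vector(track)) track <- matrix(track, ncol = 1L)
  n <- nrow(track)
  if (n < 3L) stop("need at least 3 positions to estimate velocities")
  if (!is.finite(dt) || dt <= 0) stop("dt must be > 0 (fs)")
  v <- matrix(0, n, ncol(track))
  v[1L, ] <- (track[2L, ] - track[1L, ]) / dt
  v[n, ] <- (track[n, ] - track[n - 1L, ]) / dt
  v[2:(n - 1L), ] <- (track[3:n, , drop = FALSE] -
                        track[1:(n - 2L), , drop = FALSE]) / (2 * dt)
  v
}

#' Velocity autocorrelation function
#'
#' `C(tau) = < v(0) . v(tau) >`, averaged over all time origins.
#'
#' @param velocities Numeric matrix (n x d) or vector of ordered velocities.
#' @param max_lag Largest lag (in samples), < series length.
#' @return Numeric vector of length `max_lag + 1` (lags 0..max_lag).
#' @export
vacf <- function(velocities, max_lag) {
  if (is.vector(velocities)) velocities <- matrix(velocities, ncol = 1L)
  n <- nrow(velocities)
  if (max_lag >= n) stop("max_lag must be smaller than the series length")
  vapply(0:max_lag, function(tau) {
    idx <- seq_len(n - tau)
    mean(rowSums(velocities[idx, , drop = FALSE] *
                   velocities[idx + tau, , drop = FALSE]))
  }, numeric(1))
}

#' Excess-charge IR spectrum from CEC velocities
#'
#' One-sided power spectrum of the (tapered) velocity autocorrelation
#' function, reported on a cm^-1 grid in arbitrary units. A Hann taper on
#' the VACF is applied by default to suppress spectral leakage. No
#' frequency-dependent prefactor and no quantum correction are applied;
#' set `omega2_weight = TRUE` for an optional omega^2 weighting.
#'
#' @param velocities Numeric matrix (n x d) or vector; n >= 64.
#' @param dt Sampling interval (fs).
#' @param window `"hann"` (default) or `"none"`.
#' @param max_lag Largest VACF lag (default `floor(n/2)`).
#' @param omega2_weight Multiply intensities by frequency squared
#'   (default `FALSE`).
#' @return Object of class `cec_spectrum`: `frequency` (cm^-1, strictly
#'   increasing), `intensity` (non-negative, arbitrary units), and
#'   `resolution` (grid spacing, cm^-1).
#' @export
ir_spectrum <- function(velocities, dt, window = c("hann", "none"),
                        max_lag = NULL, omega2_weight = FALSE) {
  window <- match.arg(window)
  if (is.vector(velocities)) velocities <- matrix(velocities, ncol = 1L)
  n <- nrow(velocities)
  if (n < 64L) stop("need at least 64 velocity samples")
  L <- if (is.null(max_lag)) n %/% 2L else as.integer(max_lag)
  cv <- vacf(velocities, L)
  taper <- switch(window,
                  hann = 0.5 * (1 + cos(pi * (0:L) / L)),
                  none = rep(1, L + 1L))
  cw <- cv * taper
  ## even extension C(-tau) = C(tau), then a real FFT gives the one-sided
  ## cosine transform on bins 0..L
  x <- c(cw, rev(cw[2:L]))
  I <- Re(stats::fft(x))[1:(L + 1L)]
  freq <- (0:L) / (2 * L * dt) * CM1_PER_INV_FS
  if (omega2_weight) I <- I * freq^2
  structure(list(frequency = freq, intensity = pmax(I, 0),
                 resolution = freq[2L] - freq[1L], window = window,
                 n_fft = 2L * L),
            class = "cec_spectrum")
}

#' Total one-sided spectral power
#'
#' With an untapered transform this equals the zero-lag VACF (a discrete
#' Parseval identity), which makes it a useful normalization check.
#'
#' @param spec A `cec_spectrum`.
#' @return Scalar power in the VACF's units.
#' @export
spectrum_power <- function(spec) {
  I <- spec$intensity
  L <- length(I) - 1L
  (I[1L] + 2 * sum(I[2:L]) + I[L + 1L]) / spec$n_fft
}

#' @export
print.cec_spectrum <- function(x, ...) {
  pk <- x$frequency[which.max(x$intensity)]
  cat(sprintf("CEC spectrum: %d bins, 0-%.0f cm^-1 (res %.2f), max at %.0f cm^-1\n",
              length(x$frequency), max(x$frequency), x$resolution, pk))
  invisible(x)
}

#' Running-average smoothing of a spectrum
#'
#' Boxcar running mean over a window of the stated spectral width (default
#' 33 cm^-1); edge bins are averaged over the part of the window that fits.
#'
#' @param spec A `cec_spectrum`.
#' @param window_cm Window width in cm^-1, at least one grid spacing.
#' @return A `cec_spectrum` with smoothed intensities.
#' @export
smooth_spectrum <- function(spec, window_cm = 33) {
  if (window_cm < spec$resolution)
    stop("smoothing window (", window_cm,
         " cm^-1) is below the grid spacing (", spec$resolution, " cm^-1)")
  half <- floor(window_cm / spec$resolution / 2)
  n <- length(spec$intensity)
  if (half == 0L) return(spec)
  cs <- cumsum(c(0, spec$intensity))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  spec$intensity <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  spec$smoothed_window_cm <- window_cm
  spec
}

#' Spectrum of a CEC position track
#'
#' Convenience wrapper: velocity estimation, tapered VACF transform and the
#' running-average smoothing in one call.
#'
#' @param track n x 3 matrix of CEC positions (Angstrom).
#' @param dt Sampling interval (fs).
#' @param window_cm Smoothing window (cm^-1); `NULL` to skip smoothing.
#' @param ... Passed to [ir_spectrum()].
#' @return A `cec_spectrum`; when smoothing is requested the raw
#'   intensities are kept in field `intensity_raw`.
#' @export
track_spectrum <- function(track, dt, window_cm = 33, ...) {
  vel <- estimate_velocity(track, dt)
  spec <- ir_spectrum(vel, dt, ...)
  if (!is.null(window_cm)) {
    raw <- spec$intensity
    spec <- smooth_spectrum(spec, window_cm)
    spec$intensity_raw <- raw
  }
  spec
}
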
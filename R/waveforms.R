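#' RF waveform
#'
#' A complex B1 waveform on a uniform time grid.
#'
#' @param samples Complex (or numeric) vector of B1 samples in microtesla.
#' @param dt Sample interval in ms.
#' @return An object of class `rf_waveform` with elements `samples` and `dt`.
#' @export
rf_waveform <- function(samples, dt) {
  stopifnot(is.numeric(dt), length(dt) == 1, dt > 0, length(samples) >= 1)
  structure(list(samples = as.complex(samples), dt = as.numeric(dt)),
            class = "rf_waveform")
}

#' Gradient waveform
#'
#' A real gradient waveform on a uniform time grid.
#'
#' @param samples Numeric vector of gradient samples in mT/m.
#' @param dt Sample interval in ms.
#' @return An object of class `gradient_waveform`.
#' @export
gradient_waveform <- function(samples, dt) {
  stopifnot(is.numeric(samples), is.numeric(dt), length(dt) == 1, dt > 0)
  structure(list(samples = as.numeric(samples), dt = as.numeric(dt)),
            class = "gradient_waveform")
}

#' Waveform duration in ms
#'
#' Duration is the number of samples times the dwell: each sample occupies
#' one dwell interval (hard-pulse convention).
#'
#' @param w An `rf_waveform` or `gradient_waveform`.
#' @return Duration in ms.
#' @export
wf_duration <- function(w) length(w$samples) * w$dt

#' Slew rate of a gradient waveform
#'
#' First differences divided by the dwell, in mT/m/ms. Has one fewer element
#' than the waveform.
#'
#' @param g A `gradient_waveform`.
#' @return Numeric vector of slew values.
#' @export
slew_rate <- function(g) {
  stopifnot(inherits(g, "gradient_waveform"))
  diff(g$samples) / g$dt
}

#' Peak |B1| of an RF waveform in microtesla
#' @param rf An `rf_waveform`.
#' @export
rf_peak <- function(rf) max(Mod(rf$samples))

#' Sample-midpoint time axis of a waveform (ms)
#'
#' Sample j is centred at (j - 1/2) * dt, so the axis is symmetric about
#' half the duration for any length.
#'
#' @param w An `rf_waveform` or `gradient_waveform`.
#' @export
wf_times <- function(w) (seq_along(w$samples) - 0.5) * w$dt

#' Resample a waveform to a new number of samples (same duration)
#'
#' Band-limited (Fourier) interpolation on the sample-midpoint time axis:
#' the spectrum is zero-padded (or truncated) and a half-sample phase ramp
#' aligns the midpoint grids. Exact for waveforms resolved on the original
#' grid - band edges are preserved and no spectral replicas are introduced,
#' which matters when a coarsely designed pulse is moved to the fine working
#' grid. `method = "spline"` falls back to cubic splines.
#'
#' @param w An `rf_waveform` or `gradient_waveform`.
#' @param n New sample count.
#' @param method "fourier" (default) or "spline".
#' @return A waveform of the same class with `n` samples and dwell
#'   `wf_duration(w)/n`.
#' @export
resample_waveform <- function(w, n, method = c("fourier", "spline")) {
  method <- match.arg(method)
  Tdur <- wf_duration(w)
  dt_new <- Tdur / n
  if (method == "fourier") {
    interp <- function(x) fourier_resample(x, n, Tdur, w$dt, dt_new)
    if (inherits(w, "rf_waveform"))
      return(rf_waveform(interp(as.complex(w$samples)), dt_new))
    return(gradient_waveform(Re(interp(as.complex(w$samples))), dt_new))
  }
  t_old <- wf_times(w)
  t_new <- (seq_len(n) - 0.5) * dt_new
  interp1 <- function(y) {
    stats::spline(t_old, y, xout = pmin(pmax(t_new, t_old[1]),
                                        t_old[length(t_old)]))$y
  }
  if (inherits(w, "rf_waveform")) {
    s <- complex(real = interp1(Re(w$samples)),
                 imaginary = interp1(Im(w$samples)))
    rf_waveform(s, dt_new)
  } else {
    gradient_waveform(interp1(w$samples), dt_new)
  }
}

# zero-pad / truncate the DFT and shift by half the dwell difference so the
# midpoint-sample conventions of the two grids coincide
fourier_resample <- function(x, n_new, Tdur, dt_old, dt_new) {
  n_old <- length(x)
  X <- stats::fft(x) / n_old
  m_old <- dft_freqs(n_old)
  Xf <- rep(0 + 0i, n_new)
  m_new <- dft_freqs(n_new)
  idx <- match(m_old, m_new)
  ok <- !is.na(idx)
  Xf[idx[ok]] <- X[ok]
  # half-Nyquist bin of an even-length input: split symmetrically
  if (n_old %% 2 == 0 && n_new > n_old) {
    nyq <- n_old / 2
    i_pos <- match(nyq, m_new)
    i_neg <- match(-nyq, m_new)
    Xf[i_pos] <- Xf[i_neg] / 2
    Xf[i_neg] <- Xf[i_neg] / 2
  }
  delta <- (dt_new - dt_old) / 2
  Xf <- Xf * exp(2i * pi * m_new * delta / Tdur)
  stats::fft(Xf, inverse = TRUE)
}

dft_freqs <- function(n) {
  if (n %% 2 == 0) c(0:(n / 2 - 1), -(n / 2):-1) else
    c(0:((n - 1) / 2), -((n - 1) / 2):-1)
}

#' @export
print.rf_waveform <- function(x, ...) {
  cat(sprintf("<rf_waveform> %d samples, dt %.4g ms, duration %.4g ms, peak %.4g uT\n",
              length(x$samples), x$dt, wf_duration(x), max(Mod(x$samples))))
  invisible(x)
}

#' @export
print.gradient_waveform <- function(x, ...) {
  cat(sprintf("<gradient_waveform> %d samples, dt %.4g ms, peak %.4g mT/m\n",
              length(x$samples), x$dt, max(abs(x$samples))))
  invisible(x)
}

#' RF pulse energy
#'
#' Integral of the squared B1 magnitude, in uT^2 ms (proportional to the
#' deposited RF energy).
#'
#' @param rf An `rf_waveform`.
#' @return Energy in uT^2 ms.
#' @export
rf_energy <- function(rf) {
  stopifnot(inherits(rf, "rf_waveform"))
  sum(Mod(rf$samples)^2) * rf$dt
}
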
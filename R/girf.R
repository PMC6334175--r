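#' Gradient impulse response function (GIRF)
#'
#' Complex transfer function of a gradient chain, sampled on a frequency
#' grid. Applied to a demanded gradient waveform it predicts the waveform
#' the system actually plays out.
#'
#' @param freq_khz Frequency axis in kHz (uniform, may be one-sided; a
#'   one-sided table is Hermitian-extended on use).
#' @param response Complex response values: a vector (single axis) or a
#'   matrix with one column per axis.
#' @param axes Character vector of axis names (subset of "x","y","z").
#' @return Object of class `girf`.
#' @export
girf <- function(freq_khz, response, axes = "z") {
  response <- as.matrix(response)
  stopifnot(length(freq_khz) == nrow(response),
            ncol(response) == length(axes),
            all(axes %in% c("x", "y", "z")))
  if (!any(freq_khz == 0) && min(abs(freq_khz)) > diff(range(freq_khz)) / 1e6)
    stop("GIRF must be defined at (or very near) zero frequency")
  dc <- Mod(response[which.min(abs(freq_khz)), ])
  if (any(dc < 0.95 | dc > 1.05))
    warning("GIRF magnitude at DC outside [0.95, 1.05]", call. = FALSE)
  colnames(response) <- axes
  structure(list(freq_khz = as.numeric(freq_khz), response = response,
                 axes = axes), class = "girf")
}

#' @export
print.girf <- function(x, ...) {
  cat(sprintf("<girf> axes %s, %d frequencies, %.4g..%.4g kHz\n",
              paste(x$axes, collapse = ","), length(x$freq_khz),
              min(x$freq_khz), max(x$freq_khz)))
  invisible(x)
}

#' Synthetic GIRF with Gaussian or Butterworth low-pass magnitude
#'
#' Emulates the measured behaviour of whole-body gradient chains: a low-pass
#' magnitude response (full width at half maximum `fwhm`) and an
#' approximately linear phase corresponding to a constant group delay.
#'
#' @param fwhm Magnitude FWHM in kHz (Inf gives an identity response).
#' @param delay Group delay in microseconds.
#' @param shape "gaussian" or "butterworth".
#' @param order Butterworth order (ignored for gaussian).
#' @param fmax Frequency-axis half-range in kHz (default 2000, beyond the
#'   Nyquist rate of any dwell used here).
#' @param df Frequency resolution in kHz.
#' @param axes Axis names the response applies to.
#' @return A [girf()].
#' @export
make_synthetic_girf <- function(fwhm, delay = 0, shape = c("gaussian",
                                                           "butterworth"),
                                order = 4, fmax = 2000, df = 1, axes = "z") {
  shape <- match.arg(shape)
  stopifnot(fwhm > 0)
  f <- seq(-fmax, fmax, by = df)
  mag <- if (!is.finite(fwhm)) rep(1, length(f))
  else if (shape == "gaussian") exp(-4 * log(2) * (f / fwhm)^2)
  else 1 / sqrt(1 + (2 * f / fwhm)^(2 * order))
  ph <- -2 * pi * f * delay * 1e-3   # delay us -> ms; f kHz
  resp <- mag * exp(1i * ph)
  g <- girf(f, matrix(rep(resp, length(axes)), ncol = length(axes)),
            axes = axes)
  g$fwhm <- fwhm; g$delay <- delay; g$shape <- shape
  g
}

#' Identity GIRF (perfect gradient chain)
#' @export
identity_girf <- function() make_synthetic_girf(Inf)

#' Predict the realized gradient through a GIRF
#'
#' Linear time-invariant prediction G_actual = G_target * h by
#' frequency-domain multiplication. The waveform is padded to at least twice
#' its length (edge-hold padding) to suppress circular wrap-around, and the
#' GIRF is linearly interpolated onto the waveform's frequency grid; beyond
#' the measured band the last value is held (flat extrapolation), with a
#' warning when the held magnitude is non-negligible.
#'
#' @param g_target A [gradient_waveform()].
#' @param girf A [girf()].
#' @param axis Which axis response to use.
#' @return A [gradient_waveform()] on the same grid as the input.
#' @export
apply_girf <- function(g_target, girf, axis = "z") {
  stopifnot(inherits(g_target, "gradient_waveform"), inherits(girf, "girf"))
  if (!axis %in% girf$axes) stop("axis not present in GIRF")
  x <- g_target$samples
  n <- length(x)
  npad <- 2^ceiling(log2(2 * n))
  head_pad <- (npad - n) %/% 2
  xp <- c(rep(x[1], head_pad), x, rep(x[n], npad - n - head_pad))
  fk <- c(0:(npad / 2), -(npad / 2 - 1):-1) / (npad * g_target$dt)  # kHz
  ftab <- girf$freq_khz
  rtab <- girf$response[, axis]
  if (min(ftab) >= 0) {   # Hermitian extension of a one-sided table
    ftab <- c(-rev(ftab[ftab > 0]), ftab)
    rtab <- c(Conj(rev(rtab[girf$freq_khz > 0])), rtab)
  }
  if (max(abs(fk)) > max(ftab)) {
    edge_mag <- max(Mod(rtab[c(1, length(rtab))]))
    if (edge_mag > 1e-3)
      warning(sprintf(
        "GIRF band (%.3g kHz) narrower than waveform Nyquist (%.3g kHz); holding edge value",
        max(ftab), max(abs(fk))), call. = FALSE)
  }
  Hr <- stats::approx(ftab, Re(rtab), xout = fk, rule = 2)$y
  Hi <- stats::approx(ftab, Im(rtab), xout = fk, rule = 2)$y
  Y <- stats::fft(xp) * complex(real = Hr, imaginary = Hi)
  y <- Re(stats::fft(Y, inverse = TRUE)) / npad
  gradient_waveform(y[head_pad + seq_len(n)], g_target$dt)
}

#' Write / read a GIRF as CSV plus JSON sidecar
#'
#' CSV columns: freq_khz, then re_<axis>, im_<axis> per axis. The sidecar
#' (same path with ".json" appended) records resolution and axes.
#'
#' @param girf A [girf()].
#' @param path CSV file path.
#' @export
write_girf <- function(girf, path) {
  df <- data.frame(freq_khz = girf$freq_khz)
  for (ax in girf$axes) {
    df[[paste0("re_", ax)]] <- Re(girf$response[, ax])
    df[[paste0("im_", ax)]] <- Im(girf$response[, ax])
  }
  utils::write.csv(format(df, digits = 17, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  meta <- list(axes = girf$axes,
               resolution_khz = if (length(girf$freq_khz) > 1)
                 diff(girf$freq_khz[1:2]) else NA,
               n_freq = length(girf$freq_khz),
               provenance = if (!is.null(girf$shape))
                 sprintf("synthetic (%s, fwhm %g kHz, delay %g us)",
                         girf$shape, girf$fwhm, girf$delay)
               else "unspecified")
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_girf
#' @export
read_girf <- function(path) {
  df <- utils::read.csv(path)
  axes <- sub("^re_", "", grep("^re_", names(df), value = TRUE))
  resp <- sapply(axes, function(ax)
    complex(real = df[[paste0("re_", ax)]],
            imaginary = df[[paste0("im_", ax)]]))
  girf(df$freq_khz, resp, axes = axes)
}
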
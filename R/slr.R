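#' Filter specification for SLR beta-polynomial design
#'
#' Describes a refocusing beta filter: profile ripples are given on the
#' refocusing (beta^2) profile and are mapped internally to beta-profile
#' ripples with the standard SLR spin-echo relations d1_beta = d1/4,
#' d2_beta = sqrt(d2) (crusher-gradient convention).
#'
#' @param n_samples Number of time samples the designed pulse is resampled to
#'   (default 2048; the design itself runs at `n_taps`).
#' @param tbp Dimensionless time-bandwidth product.
#' @param ripple_pass In-slice ripple on the beta^2 profile (fraction).
#' @param ripple_stop Out-of-slice ripple on the beta^2 profile (fraction).
#' @param phase_type One of "linear", "minimum", "quadratic".
#' @param n_taps Number of filter taps used for the FIR design. Defaults to
#'   128, which is enough for any feasible spec: the Parks-McClellan length
#'   estimate equals `n_taps` identically in this parameterization because the
#'   transition width scales with 1/n_taps.
#' @return An object of class `slr_filter_spec`.
#' @export
slr_filter_spec <- function(n_samples = 2048, tbp, ripple_pass = 0.01,
                            ripple_stop = 0.01, phase_type = "linear",
                            n_taps = 128) {
  phase_type <- match.arg(phase_type, c("linear", "minimum", "quadratic"))
  stopifnot(tbp > 0, ripple_pass > 0, ripple_pass < 1,
            ripple_stop > 0, ripple_stop < 1, n_samples >= 64)
  structure(list(n_samples = as.integer(n_samples), tbp = tbp,
                 ripple_pass = ripple_pass, ripple_stop = ripple_stop,
                 phase_type = phase_type, pulse_type = "refocusing",
                 n_taps = as.integer(n_taps)),
            class = "slr_filter_spec")
}

# SLR spin-echo ripple mapping (with crushers): ripples requested on the
# beta^2 profile map to beta ripples d1/4 (pass) and sqrt(d2) (stop).
slr_ripple_map <- function(spec) {
  list(d1 = spec$ripple_pass / 4, d2 = sqrt(spec$ripple_stop))
}

# Fractional transition width (relative to the slice bandwidth) from the
# Parks-McClellan filter-length estimate.
dinf <- function(d1, d2) {
  a <- c(5.309e-3, 7.114e-2, -4.761e-1, -2.66e-3, -5.941e-1, -4.278e-1)
  l1 <- log10(d1); l2 <- log10(d2)
  (a[1] * l1^2 + a[2] * l1 + a[3]) * l2 + (a[4] * l1^2 + a[5] * l1 + a[6])
}

#' Weighted least-squares FIR design with Lawson re-weighting
#'
#' Designs an odd-length type-I (real, symmetric) FIR filter whose amplitude
#' response approximates 1 on a set of passbands and 0 elsewhere, with
#' transition bands excluded from the fit. Iterative Lawson re-weighting
#' pushes the weighted least-squares solution toward the equiripple solution,
#' so realized ripples meet `d1`/`d2`-style specs like a Parks-McClellan
#' design would, but without its convergence failures on very narrow bands.
#'
#' @param n Filter length (odd).
#' @param centers Passband centre frequencies in cycles/sample (may be
#'   negative; only the magnitude is used for this real design).
#' @param bw Full passband width in cycles/sample.
#' @param wtrans Fractional transition width (transition half-width =
#'   `wtrans * bw / 2` on each band edge).
#' @param d1,d2 Target passband/stopband ripples (used as inverse weights).
#' @param lawson Number of Lawson re-weighting iterations.
#' @param grid_mult Frequency-grid density multiplier.
#' @return Numeric vector of `n` filter taps.
#' @export
firls_lawson <- function(n, centers, bw, wtrans, d1, d2, lawson = 12,
                         grid_mult = 16) {
  if (n %% 2 == 0) stop("filter length must be odd")
  M <- (n - 1) / 2
  f <- seq(0, 0.5, length.out = grid_mult * n)
  D <- rep(0, length(f)); W <- rep(1 / d2, length(f))
  use <- rep(TRUE, length(f))
  for (fc in unique(abs(centers))) {
    inpass <- abs(f - fc) <= (1 - wtrans) * bw / 2
    intrans <- abs(f - fc) < (1 + wtrans) * bw / 2 & !inpass
    D[inpass] <- 1; W[inpass] <- 1 / d1; use[intrans] <- FALSE
  }
  f <- f[use]; D <- D[use]; W <- W[use]
  if (!any(D > 0)) stop("no passband grid points: spec infeasible for this n")
  C <- cbind(1, 2 * cos(2 * pi * outer(f, seq_len(M))))
  lw <- W^2
  a <- NULL
  for (it in seq_len(lawson)) {
    sw <- sqrt(lw)
    a <- qr.solve(C * sw, D * sw)
    err <- abs(as.vector(C %*% a) - D) * W
    if (it < lawson) lw <- lw * (0.2 + err / max(err))
  }
  c(rev(a[-1]), a[1], a[-1])
}

# Measure realized passband/stopband ripple of a (possibly complex) filter
# on a dense frequency grid. Ripples are measured about the passband
# mid-level (the nominal gain), matching how design specs are stated.
measure_ripples <- function(h, centers, bw, wtrans, ngrid = 40000) {
  f <- seq(0, 0.5, length.out = ngrid)
  A <- Mod(polyval_unit(h, f))
  inpass <- rep(FALSE, length(f)); intrans <- rep(FALSE, length(f))
  for (fc in unique(abs(centers))) {
    inpass <- inpass | abs(f - fc) <= (1 - wtrans) * bw / 2
    intrans <- intrans | abs(f - fc) < (1 + wtrans) * bw / 2
  }
  mid <- (max(A[inpass]) + min(A[inpass])) / 2
  list(pass = (max(A[inpass]) - min(A[inpass])) / 2 / mid,
       stop = max(A[!inpass & !intrans]) / mid,
       scale = mid)
}

# Evaluate a polynomial sum c_j e^{-2 pi i f j} at frequencies f
# (cycles/sample) via Horner.
polyval_unit <- function(cf, f) {
  z <- exp(-2i * pi * f)
  v <- rep(0 + 0i, length(z))
  for (k in rev(seq_along(cf))) v <- v * z + cf[k]
  v
}

# Dense response of a coefficient vector on the m-point DFT grid
# (forward FFT of the zero-padded coefficients).
dft_response <- function(cf, m) {
  stats::fft(c(cf, rep(0 + 0i, m - length(cf))))
}

#' Design an SLR beta filter
#'
#' Returns the beta-profile FIR filter for a refocusing pulse. For
#' `phase_type = "linear"` this is a symmetric filter meeting the mapped
#' ripples; for `"minimum"` (and `"quadratic"`, which starts minimum-phase)
#' the magnitude-squared prototype is designed first and spectrally factored
#' with the cepstral method.
#'
#' @param spec An [slr_filter_spec()].
#' @return List with elements `coef` (filter taps, possibly complex), `bw`
#'   (band width, cycles/sample), `wtrans`, `d1`, `d2` (mapped beta ripples)
#'   and `spec`.
#' @export
design_beta_filter <- function(spec) {
  stopifnot(inherits(spec, "slr_filter_spec"))
  rp <- slr_ripple_map(spec)
  wtr <- dinf(rp$d1, rp$d2) / spec$tbp
  if (wtr >= 1) stop("transition width exceeds band: spec infeasible")
  # very loose ripples give a near-zero (or negative) length estimate;
  # a finite transition band is still needed for the fit to be well posed
  wtr <- min(max(wtr, 0.1), 0.95)
  n <- spec$n_taps
  if (n %% 2 == 0) n <- n + 1L
  bw <- spec$tbp / n
  if ((1 + wtr) * bw / 2 >= 0.5)
    stop("transition band reaches Nyquist: n_taps too small for this tbp")
  if (spec$phase_type == "linear") {
    coef <- firls_lawson(n, 0, bw, wtr, rp$d1, rp$d2)
  } else {
    # magnitude-squared prototype: pass ripple 2*d1, stop ripple d2^2/2,
    # lifted to be nonnegative, then cepstral spectral factorization
    n2 <- 2L * n - 1L
    d2q <- rp$d2^2 / 2
    q <- firls_lawson(n2, 0, bw, wtr, 2 * rp$d1, d2q)
    m <- 2^ceiling(log2(max(64 * n2, 8192)))
    P <- Re(dft_response(as.complex(q), m) *
              exp(2i * pi * (0:(m - 1)) / m * ((n2 - 1) / 2)))
    P <- (P + d2q) / (1 + d2q)
    P[P < 0] <- 0
    coef <- mag2mp_cpp(sqrt(P), n)
  }
  mr <- measure_ripples(coef, 0, bw, wtr)
  if (mr$pass > rp$d1 * 1.5 || mr$stop > rp$d2 * 1.5)
    stop(sprintf(
      "filter design failed ripple contract (pass %.3g vs %.3g, stop %.3g vs %.3g)",
      mr$pass, rp$d1, mr$stop, rp$d2))
  list(coef = coef, bw = bw, wtrans = wtr, d1 = rp$d1, d2 = rp$d2,
       n = n, spec = spec, ripples = mr)
}

#' Forward SLR transform
#'
#' Computes the hard-pulse Cayley-Klein polynomials (alpha, beta) of an RF
#' waveform. Unitarity |alpha|^2 + |beta|^2 = 1 holds on the unit circle to
#' numerical precision.
#'
#' @param rf An [rf_waveform()].
#' @return An object of class `ck_polys`: list with complex coefficient
#'   vectors `alpha` and `beta` (ascending powers of z^-1).
#' @export
forward_slr <- function(rf) {
  stopifnot(inherits(rf, "rf_waveform"))
  ang <- .GAMMA * rf$dt * rf$samples
  res <- slr_forward_cpp(as.complex(ang))
  structure(list(alpha = as.complex(res$A), beta = as.complex(res$B)),
            class = "ck_polys")
}

#' Inverse SLR transform
#'
#' Builds the RF pulse whose spin-domain beta polynomial is the given filter,
#' scaled so its peak response is sin(flip/2). The alpha polynomial is the
#' minimum-phase spectral factor of 1 - |beta|^2.
#'
#' @param beta Complex or numeric beta filter coefficients.
#' @param flip Target flip angle in radians (pi for refocusing).
#' @param dur Pulse duration in ms (sets the dwell and the B1 scale).
#' @param m DFT grid size used for the factorization (default 8x the
#'   coefficient count, rounded up to a power of two).
#' @return An [rf_waveform()] with `length(beta)` samples.
#' @export
inverse_slr <- function(beta, flip = pi, dur = 1, m = NULL) {
  n <- length(beta)
  # a large factorization grid keeps the cepstral truncation error of the
  # alpha polynomial well below the design ripples (linear-phase designs
  # then come out amplitude-symmetric to ~1e-10)
  if (is.null(m)) m <- 2^ceiling(log2(max(512 * n, 4096)))
  b <- as.complex(beta)
  pk <- max(Mod(dft_response(b, m)))
  if (pk == 0) return(rf_waveform(rep(0 + 0i, n), dur / n))
  target <- min(sin(flip / 2), 1 - 1e-7)
  b <- b * (target / pk)
  rfang <- beta_to_rf_cpp(b, as.integer(m))
  dt <- dur / n
  rf_waveform(rfang / (.GAMMA * dt), dt)
}

#' Quadratic-phase pulse from a minimum-phase design
#'
#' Takes a minimum-phase SLR pulse, finds the roots of its beta polynomial,
#' and reflects those in the lower half of the z-plane across the unit circle
#' (r -> 1/conj(r)). The beta magnitude response is preserved; the
#' through-slice phase becomes approximately quadratic and the peak RF
#' amplitude drops because energy is spread in time.
#'
#' @param min_phase_rf An [rf_waveform()] produced from a minimum-phase beta.
#' @return An [rf_waveform()] of the same duration.
#' @export
quadratic_phase_pulse <- function(min_phase_rf) {
  stopifnot(inherits(min_phase_rf, "rf_waveform"))
  ck <- forward_slr(min_phase_rf)
  b <- ck$beta
  n <- length(b)
  r <- poly_roots_cpp(b)
  if (any(!is.finite(Re(r)) | !is.finite(Im(r))))
    stop("root finding failed on beta polynomial; try fewer samples")
  sel <- Im(r) < 0 & abs(Mod(r) - 1) < 0.5
  if (!any(sel)) return(min_phase_rf)
  r[sel] <- polish_roots(b, r[sel])
  m <- 2^ceiling(log2(max(512 * n, 4096)))
  bnew <- allpass_flip(b, r[sel], m)
  # match the original peak response, then rebuild the pulse
  pk0 <- max(Mod(dft_response(b, m)))
  bnew <- bnew * (pk0 / max(Mod(dft_response(bnew, m))))
  rfang <- beta_to_rf_cpp(bnew, as.integer(m))
  out <- rf_waveform(rfang / (.GAMMA * min_phase_rf$dt), min_phase_rf$dt)
  attr(out, "beta") <- bnew
  out
}

# Newton-polish polynomial roots; stable on both sides of the unit circle
# (|r| > 1 handled through the reversed polynomial at 1/r).
polish_roots <- function(cf, r, iters = 8) {
  cf <- as.complex(cf)
  n <- length(cf)
  dcf <- cf[-1] * seq_len(n - 1)
  rcf <- rev(cf); drcf <- rcf[-1] * seq_len(n - 1)
  horner <- function(co, z) {
    v <- rep(0 + 0i, length(z))
    for (k in rev(seq_along(co))) v <- v * z + co[k]
    v
  }
  for (i in seq_len(iters)) {
    inside <- Mod(r) <= 1
    rn <- r
    if (any(inside)) {
      z <- r[inside]
      rn[inside] <- z - horner(cf, z) / horner(dcf, z)
    }
    if (any(!inside)) {
      u <- 1 / r[!inside]
      un <- u - horner(rcf, u) / horner(drcf, u)
      rn[!inside] <- 1 / un
    }
    bad <- !is.finite(rn)
    rn[bad] <- r[bad]
    r <- rn
  }
  r
}

# Replace roots r_i of polynomial b by 1/conj(r_i), computed by evaluating
# the all-pass factors (z - 1/conj(r))/(z - r) on an m-point DFT grid and
# inverse-transforming. Exact for degree < m; avoids the catastrophic
# cancellation of multiplying monomial factors at high degree.
allpass_flip <- function(b, roots_to_flip, m) {
  n <- length(b)
  zg <- exp(-2i * pi * (0:(m - 1)) / m)
  Bg <- dft_response(as.complex(b), m)
  fac <- rep(1 + 0i, m)
  for (ri in roots_to_flip) fac <- fac * (zg - 1 / Conj(ri)) / (zg - ri)
  cf <- stats::fft(Bg * fac, inverse = TRUE) / m
  cf[seq_len(n)]
}

#' Design a singleband SLR refocusing pulse
#'
#' Full design pipeline: beta filter, inverse SLR, resampling to the working
#' time grid, and the matching constant slice-select gradient.
#'
#' @param tbp Time-bandwidth product.
#' @param thickness Slice thickness in mm.
#' @param duration Pulse duration in ms (sets bandwidth = tbp/duration).
#' @param phase_type "linear", "minimum" or "quadratic".
#' @param ripple_pass,ripple_stop Profile ripples (fractions, on beta^2).
#' @param n_samples Working sample count after resampling.
#' @param n_taps Design filter length.
#' @return Object of class `sb_pulse`: list with `rf` ([rf_waveform()]),
#'   `grad` (constant [gradient_waveform()]), `G` (mT/m), `filter` (the beta
#'   design), `tbp`, `thickness`, `phase_type`.
#' @export
design_sb_pulse <- function(tbp, thickness, duration = 1,
                            phase_type = "linear",
                            ripple_pass = 0.01, ripple_stop = 0.01,
                            n_samples = 2048, n_taps = 128) {
  spec <- slr_filter_spec(n_samples = n_samples, tbp = tbp,
                          ripple_pass = ripple_pass,
                          ripple_stop = ripple_stop,
                          phase_type = if (phase_type == "quadratic")
                            "minimum" else phase_type,
                          n_taps = n_taps)
  filt <- design_beta_filter(spec)
  rf <- inverse_slr(filt$coef, flip = pi, dur = duration)
  n <- filt$n
  m <- 2^ceiling(log2(max(8 * n, 1024)))
  beta <- as.complex(filt$coef) *
    (min(1, 1 - 1e-7) / max(Mod(dft_response(as.complex(filt$coef), m))))
  if (phase_type == "quadratic") {
    rf <- quadratic_phase_pulse(rf)
    beta <- attr(rf, "beta")
  }
  rf_fine <- resample_waveform(rf, n_samples)
  bw_khz <- tbp / duration
  G <- bw_khz / (gamma_bar() * 1e-3 * thickness)  # mT/m
  grad <- gradient_waveform(rep(G, n_samples), rf_fine$dt)
  structure(list(rf = rf_fine, rf_design = rf, grad = grad, G = G,
                 filter = filt, beta = beta, tbp = tbp,
                 thickness = thickness,
                 duration = duration, phase_type = phase_type),
            class = "sb_pulse")
}

#' @export
print.sb_pulse <- function(x, ...) {
  cat(sprintf("<sb_pulse> %s phase, tbp %.3g, %.3g mm slice, %.4g ms, G %.4g mT/m, peak %.4g uT\n",
              x$phase_type, x$tbp, x$thickness, wf_duration(x$rf), x$G,
              rf_peak(x$rf)))
  invisible(x)
}
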
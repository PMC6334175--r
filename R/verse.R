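#' Hardware limits for pulse design
#'
#' @param b1_max Peak RF amplitude in uT.
#' @param g_max Peak gradient amplitude in mT/m.
#' @param slew_max Peak gradient slew rate in mT/m/ms.
#' @return Object of class `hardware_limits`.
#' @export
hardware_limits <- function(b1_max = 13, g_max = 40, slew_max = 200) {
  stopifnot(b1_max > 0, g_max > 0, slew_max > 0)
  structure(list(b1_max = b1_max, g_max = g_max, slew_max = slew_max),
            class = "hardware_limits")
}

#' Time-optimal VERSE
#'
#' Given an RF pulse and a (positive, possibly constant) slice-select
#' gradient, returns the minimum-duration RF/gradient pair that produces the
#' same on-resonance profile, subject to peak-B1, gradient-amplitude and
#' slew-rate limits. The pulse is reparameterized by position along the
#' excitation k-trajectory; the per-position gradient cap is
#' min(g_max, b1_max * g/|rf| at matched k), and the minimum-time traversal
#' is found by slew-limited forward-backward integration of
#' d(g^2)/ds <= 2 S_max / gamma.
#'
#' The output gradient may start and end at nonzero values; ramps to zero
#' live outside the RF window and are not counted in the duration.
#'
#' @param rf An [rf_waveform()].
#' @param g A [gradient_waveform()] on the same grid, or a single positive
#'   number for a constant gradient.
#' @param lim A [hardware_limits()].
#' @param ns_factor Arc-grid density: number of arc samples = `ns_factor`
#'   times the input sample count.
#' @param dt_out Output dwell in ms (default: duration / max(input n, 2048),
#'   i.e. at least as fine as the input grid).
#' @param max_phase_rate Largest per-sample precession rate to resolve, in
#'   rad/ms (e.g. gamma * g_max * outermost position for a multiband pulse);
#'   when given, the output dwell is capped so the per-sample phase
#'   increment stays below pi/8.
#' @return Object of class `versed_pulse`: list with `rf`, `grad`,
#'   `duration` (ms) and `info` (arc-domain solution).
#' @export
time_optimal_verse <- function(rf, g, lim, ns_factor = 2, dt_out = NULL,
                               max_phase_rate = NULL) {
  stopifnot(inherits(rf, "rf_waveform"), inherits(lim, "hardware_limits"))
  n <- length(rf$samples)
  if (is.numeric(g) && length(g) == 1) g <- gradient_waveform(rep(g, n), rf$dt)
  stopifnot(inherits(g, "gradient_waveform"))
  if (length(g$samples) != n || abs(g$dt - rf$dt) > 1e-12 * rf$dt)
    stop("RF and gradient are not on the same time grid")
  gs <- g$samples
  if (any(gs < 0) && any(gs > 0))
    stop("unsupported trajectory: gradient changes sign")
  if (all(gs <= 0)) { gs <- -gs }   # traverse k in the positive sense
  tiny <- 1e-9 * max(Mod(rf$samples), 1e-12)
  if (any(gs <= 0 & Mod(rf$samples) > tiny))
    stop("nonzero RF on a zero-gradient segment cannot be VERSE'd")
  if (any(gs <= 0))
    stop("gradient must be strictly positive over the pulse")
  # arc positions (rad/mm) at sample midpoints
  area <- cumsum(gs * g$dt)
  s_in <- .GAMMA * (area - gs * g$dt / 2)
  S <- .GAMMA * area[n]
  if (S <= 0) stop("gradient area is zero")
  w <- rf$samples / gs                      # uT per (mT/m), fixed along k
  ns <- max(ns_factor * n, 1024)
  s_grid <- seq(s_in[1], s_in[n], length.out = ns)
  wr <- stats::approx(s_in, Re(w), xout = s_grid, rule = 2)$y
  wi <- stats::approx(s_in, Im(w), xout = s_grid, rule = 2)$y
  wmag <- sqrt(wr^2 + wi^2)
  cap <- pmin(lim$g_max, ifelse(wmag > 0, lim$b1_max / wmag, Inf))
  cap <- pmin(cap, lim$g_max)
  ds <- s_grid[2] - s_grid[1]
  sol <- verse_fb_cpp(cap, ds, lim$slew_max, .GAMMA)
  gv <- sol$g; tv <- sol$t
  # account for the half-arc segments before the first and after the last
  # midpoint (traversed at the boundary speeds)
  t_head <- (s_in[1]) / (.GAMMA * gv[1])
  t_tail <- (S - s_in[n]) / (.GAMMA * gv[ns])
  Tdur <- tv[ns] + t_head + t_tail
  if (is.null(dt_out)) dt_out <- Tdur / max(n, 2048)
  if (!is.null(max_phase_rate))
    dt_out <- min(dt_out, (pi / 8) / max_phase_rate)
  n_out <- max(2L, round(Tdur / dt_out))
  dt_out <- Tdur / n_out
  t_mid <- (seq_len(n_out) - 0.5) * dt_out
  s_of_t <- stats::approx(tv + t_head, s_grid, xout = t_mid, rule = 2)$y
  g_out <- stats::approx(s_grid, gv, xout = s_of_t, rule = 2)$y
  w_out <- complex(real = stats::approx(s_grid, wr, xout = s_of_t, rule = 2)$y,
                   imaginary = stats::approx(s_grid, wi, xout = s_of_t, rule = 2)$y)
  rf_out <- w_out * g_out
  # guard against interpolation overshoot of the active B1 constraint
  pk <- Mod(rf_out)
  over <- pk > lim$b1_max
  if (any(over)) rf_out[over] <- rf_out[over] * (lim$b1_max / pk[over])
  # renormalize gradient area exactly (quadrature of the resampling)
  g_out <- g_out * (S / .GAMMA) / sum(g_out * dt_out)
  structure(list(rf = rf_waveform(rf_out, dt_out),
                 grad = gradient_waveform(g_out, dt_out),
                 duration = Tdur,
                 info = list(s = s_grid, g_arc = gv, t_arc = tv,
                             cap = cap, k_extent = S)),
            class = "versed_pulse")
}

#' @export
print.versed_pulse <- function(x, ...) {
  cat(sprintf("<versed_pulse> %.4g ms, peak B1 %.4g uT, peak G %.4g mT/m\n",
              x$duration, rf_peak(x$rf), max(abs(x$grad$samples))))
  invisible(x)
}

#' Uniformly stretch an RF/gradient pair to a target duration
#'
#' Dilation by lambda = target/T scales B1 and G by 1/lambda and preserves
#' the on-resonance profile exactly.
#'
#' @param rf An [rf_waveform()].
#' @param g A [gradient_waveform()] or constant gradient value (mT/m).
#' @param target_T Target duration in ms (must be >= current duration).
#' @return A `versed_pulse` (rf, grad, duration).
#' @export
stretch_to_duration <- function(rf, g, target_T) {
  stopifnot(inherits(rf, "rf_waveform"))
  n <- length(rf$samples)
  if (is.numeric(g) && length(g) == 1) g <- gradient_waveform(rep(g, n), rf$dt)
  Tcur <- wf_duration(rf)
  if (target_T < Tcur * (1 - 1e-12))
    stop("target duration shorter than the pulse; use time_optimal_verse")
  lam <- target_T / Tcur
  structure(list(rf = rf_waveform(rf$samples / lam, rf$dt * lam),
                 grad = gradient_waveform(g$samples / lam, g$dt * lam),
                 duration = target_T,
                 info = list(lambda = lam)),
            class = "versed_pulse")
}

#' VERSE after multiband modulation (MBv)
#'
#' Applies time-optimal VERSE directly to an already-modulated multiband
#' pulse under the full B1 limit.
#'
#' @param mb_rf Modulated multiband [rf_waveform()].
#' @param G Constant design gradient in mT/m.
#' @param lim [hardware_limits()].
#' @param ... Passed to [time_optimal_verse()].
#' @return A `versed_pulse`.
#' @export
make_mbv <- function(mb_rf, G, lim, ...) {
  time_optimal_verse(mb_rf, G, lim, ...)
}

#' VERSE before multiband modulation (vMB)
#'
#' Applies time-optimal VERSE to the singleband pulse under the reduced
#' B1 limit of the multiband amplitude constraint, then modulates with the
#' time-variable-gradient modulation function. Because the modulation peak
#' depends on the VERSE'd k-trajectory, which depends on the B1 limit, the
#' limit is iterated to a fixed point (damping 0.5, tolerance 1e-3 on
#' peak * limit vs B1max, at most `max_iter` iterations).
#'
#' @param sb_rf Singleband [rf_waveform()].
#' @param G Constant design gradient in mT/m.
#' @param lim [hardware_limits()].
#' @param spec [modulation_spec()] with the phase offsets to use.
#' @param max_iter,tol,damping Fixed-point controls.
#' @param ... Passed to [time_optimal_verse()].
#' @return A `versed_pulse` whose `rf` is the modulated multiband waveform;
#'   `info` additionally carries `b1_limit`, `f_peak`, `iterations`.
#' @export
make_vmb <- function(sb_rf, G, lim, spec, max_iter = 20, tol = 1e-3,
                     damping = 0.5, ...) {
  stopifnot(inherits(spec, "modulation_spec"))
  if (spec$n_slices == 1 && all(spec$positions == 0))
    return(make_mbv(sb_rf, G, lim, ...))
  # initial guess from the constant-gradient modulation peak
  tc <- wf_times(sb_rf) - wf_duration(sb_rf) / 2
  pk <- max(Mod(modulation_function(.GAMMA * G * tc, spec)))
  L <- lim$b1_max / pk
  v <- NULL; fN <- NULL
  for (it in seq_len(max_iter)) {
    lim_red <- hardware_limits(L, lim$g_max, lim$slew_max)
    v <- time_optimal_verse(sb_rf, G, lim_red, ...)
    k <- k_trajectory(v$grad)
    kref <- (k$k[1] + k$k[length(k$k)]) / 2   # k-extent centre
    fN <- modulation_function(k$k - kref, spec)
    pk <- max(Mod(fN))
    if (abs(L * pk - lim$b1_max) <= tol * lim$b1_max) break
    if (it == max_iter)
      stop(sprintf(
        "vMB B1-limit fixed point did not converge: L=%.5g, peak=%.5g", L, pk))
    L <- L + damping * (lim$b1_max / pk - L)
  }
  rf_mb <- rf_waveform(v$rf$samples * fN, v$rf$dt)
  structure(list(rf = rf_mb, grad = v$grad, duration = v$duration,
                 info = c(v$info, list(b1_limit = L, f_peak = pk,
                                       iterations = it,
                                       sb_rf = v$rf))),
            class = "versed_pulse")
}
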
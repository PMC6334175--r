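#' PINS pulse design
#'
#' Power Independent of Number of Slices: the singleband envelope is
#' undersampled into hard RF subpulses interleaved with gradient blips, so
#' the excitation is periodic in the slice direction with period equal to
#' the slice separation. RF blips are made as short as the B1 limit allows
#' (per-blip duration dictated by the subpulse area), and each gradient blip
#' is the shortest triangular - or, when amplitude-limited, trapezoidal -
#' lobe of area 2*pi/(gamma*separation), i.e. one k-space step of the
#' periodic pattern. RF and gradient are never on simultaneously.
#'
#' @param sb An `sb_pulse` (from [design_sb_pulse()]); its envelope and
#'   time-bandwidth product define the subpulse weights.
#' @param separation Slice separation (period) in mm.
#' @param lim [hardware_limits()].
#' @param dwell Sampling time in microseconds (defaults: 1.21 for tbp <= 2,
#'   3.37 otherwise, matching short-blip operation).
#' @param area_scale Scale factor applied to the subpulse areas (used by
#'   MultiPINS mixing; 1 for pure PINS).
#' @param offset Spatial offset of the periodic slice pattern in mm
#'   (implemented as a linear phase across the subpulses); used to centre the
#'   pattern on a slice pack with an even number of slices.
#' @return Object of class `pins_design`: `rf`, `grad` (same grid),
#'   `n_subpulses`, `mixing_ratio`, `separation`, plus bookkeeping.
#' @export
design_pins <- function(sb, separation, lim, dwell = NULL, area_scale = 1,
                        offset = 0) {
  stopifnot(inherits(sb, "sb_pulse"), separation > sb$thickness)
  if (is.null(dwell)) dwell <- if (sb$tbp <= 2) 1.21 else 3.37
  dws <- dwell * 1e-3   # ms
  n_sub <- ceiling(sb$tbp * separation / sb$thickness)
  # subpulse areas: integrate the SB envelope over n_sub equal segments
  rfs <- sb$rf$samples
  n <- length(rfs)
  seg <- ceiling(seq_len(n) / (n / n_sub))
  areas <- as.complex(tapply(rfs * sb$rf$dt, seg, sum)) * area_scale
  if (offset != 0) {
    kj <- (seq_len(n_sub) - (n_sub + 1) / 2) * 2 * pi / separation
    areas <- areas * exp(1i * kj * offset)
  }
  # RF blips: duration per blip set by B1max, rounded up to the dwell
  nsamp_rf <- pmax(1L, ceiling(Mod(areas) / lim$b1_max / dws))
  # gradient blip: area = one k step of the periodic pattern
  Ag <- 2 * pi / (.GAMMA * separation)   # mT/m * ms
  tau_tri <- 2 * sqrt(Ag / lim$slew_max)
  if (lim$slew_max * tau_tri / 2 <= lim$g_max) {
    n_g <- max(2L, ceiling(tau_tri / dws))
    ramp <- ceiling(n_g / 2)
    shape <- c(seq_len(ramp), rev(seq_len(n_g - ramp)))
  } else {
    ramp_t <- lim$g_max / lim$slew_max
    flat_t <- Ag / lim$g_max - ramp_t
    n_r <- max(1L, ceiling(ramp_t / dws))
    n_f <- max(1L, ceiling(flat_t / dws))
    shape <- c(seq_len(n_r) / n_r, rep(1, n_f), rev(seq_len(n_r)) / n_r)
    n_g <- length(shape)
  }
  shape <- shape / (sum(shape) * dws) * Ag   # exact blip area
  if (max(shape) > lim$g_max * (1 + 1e-9))
    stop("gradient blip amplitude exceeds g_max: area unreachable under limits")
  if (max(abs(diff(c(0, shape, 0)))) / dws > lim$slew_max * (1 + 0.5))
    stop("gradient blip slew exceeds limit: area unreachable under limits")
  rf_out <- complex(0)
  g_out <- numeric(0)
  rf_list <- vector("list", 2 * n_sub - 1)
  g_list <- vector("list", 2 * n_sub - 1)
  for (j in seq_len(n_sub)) {
    amp <- areas[j] / (nsamp_rf[j] * dws)
    rf_list[[2 * j - 1]] <- rep(amp, nsamp_rf[j])
    g_list[[2 * j - 1]] <- rep(0, nsamp_rf[j])
    if (j < n_sub) {
      rf_list[[2 * j]] <- rep(0 + 0i, n_g)
      g_list[[2 * j]] <- shape
    }
  }
  rf_out <- unlist(rf_list)
  g_out <- unlist(g_list)
  # representative sample index (mid-blip) of each RF subpulse
  lens <- lengths(rf_list)
  starts <- cumsum(c(0, lens[-length(lens)]))
  sub_idx <- starts[seq(1, 2 * n_sub - 1, by = 2)] +
    ceiling(nsamp_rf / 2)
  if (max(Mod(rf_out)) > lim$b1_max * (1 + 1e-9))
    stop("RF blip amplitude exceeds B1max")
  structure(list(rf = rf_waveform(rf_out, dws),
                 grad = gradient_waveform(g_out, dws),
                 duration = length(rf_out) * dws,
                 n_subpulses = n_sub, mixing_ratio = 0,
                 separation = separation, thickness = sb$thickness,
                 sb = sb, areas = areas, blip_area = Ag,
                 nsamp_rf = nsamp_rf, blip_shape = shape, dwell_us = dwell,
                 sub_idx = sub_idx),
            class = "pins_design")
}

#' @export
print.pins_design <- function(x, ...) {
  cat(sprintf("<pins_design> %d subpulses, M %.3g, sep %.3g mm, %.4g ms\n",
              x$n_subpulses, x$mixing_ratio, x$separation, x$duration))
  invisible(x)
}

#' MultiPINS pulse design
#'
#' Mixes a VERSE-reshaped multiband pulse into a PINS pulse with mixing
#' ratio M: RF = M * RF_MB + (1-M) * RF_PINS. The MB component is the same
#' singleband envelope modulated without phase optimization and reshaped
#' onto the blipped PINS gradient (RF proportional to the instantaneous
#' gradient at matched k-position), so it plays during the gradient blips
#' while the PINS blips play at zero gradient. Larger M means smaller PINS
#' subpulse areas and therefore shorter B1-limited RF blips; the pulse gets
#' shorter until the MB component hits the B1 ceiling.
#'
#' @param sb An `sb_pulse`.
#' @param spec [modulation_spec()] (phases are forced to zero).
#' @param lim [hardware_limits()].
#' @param M Mixing ratio in `[0, 1]`.
#' @param dwell Sampling time in microseconds (see [design_pins()]).
#' @param offset Pattern offset in mm (see [design_pins()]).
#' @return A `pins_design` with `mixing_ratio = M`.
#' @export
design_multipins <- function(sb, spec, lim, M, dwell = NULL, offset = 0) {
  stopifnot(inherits(spec, "modulation_spec"), M >= 0, M <= 1)
  p <- design_pins(sb, slice_sep(spec), lim,
                   dwell = dwell, area_scale = 1 - M, offset = offset)
  if (M == 0) return(p)
  sep <- p$separation
  # k-position along the blipped gradient, referenced to the centre of the
  # subpulse comb (RF blips play at constant k, so this is well defined even
  # though blip durations vary)
  k <- k_trajectory(p$grad)
  ns <- p$n_subpulses
  kref <- if (ns %% 2 == 1) k$k[p$sub_idx[(ns + 1) / 2]]
  else mean(k$k[p$sub_idx[c(ns / 2, ns / 2 + 1)]])
  karg <- k$k - kref
  # singleband envelope as a function of k (constant-gradient mapping)
  ksb <- .GAMMA * p$sb$G *
    (wf_times(p$sb$rf) - wf_duration(p$sb$rf) / 2)
  spec0 <- modulation_spec(spec$n_slices, spec$positions,
                           phases = rep(0, spec$n_slices),
                           am_only = spec$am_only)
  # deposit per sample the exact k-integral of the modulated envelope over
  # the sample's k-span (rotation angle = integral of (b1/g) dk), rather
  # than a midpoint sample - the blips sweep k quickly and midpoint sampling
  # would misplace RF area
  kfine <- seq(min(karg) - 0.5, max(karg) + 0.5, length.out = 16384)
  wr <- stats::approx(ksb, Re(p$sb$rf$samples), xout = kfine, rule = 2)$y
  wi <- stats::approx(ksb, Im(p$sb$rf$samples), xout = kfine, rule = 2)$y
  wk <- complex(real = wr, imaginary = wi) *
    modulation_function(kfine, spec0) / p$sb$G
  Wcum <- c(0, cumsum((wk[-1] + wk[-length(wk)]) / 2 * diff(kfine)))
  # k at sample boundaries (same reference as karg)
  gs <- p$grad$samples * p$grad$dt
  k_edges <- .GAMMA * c(0, cumsum(gs)) - .GAMMA * sum(gs) +
    (karg[length(karg)] + .GAMMA * gs[length(gs)] / 2)
  Wi <- stats::approx(kfine, Re(Wcum), xout = k_edges, rule = 2)$y +
    1i * stats::approx(kfine, Im(Wcum), xout = k_edges, rule = 2)$y
  rf_mb <- diff(Wi) / (.GAMMA * p$rf$dt)
  rf_mix <- M * rf_mb + p$rf$samples   # PINS part already scaled by (1-M)
  pk <- max(Mod(rf_mix))
  if (pk > lim$b1_max * (1 + 1e-9))
    stop(sprintf("MultiPINS peak %.4g uT exceeds B1max %.4g uT at M=%.3g",
                 pk, lim$b1_max, M))
  p$rf <- rf_waveform(rf_mix, p$rf$dt)
  p$mixing_ratio <- M
  p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

slice_sep <- function(spec) {
  if (spec$n_slices < 2) stop("separation undefined for a single slice")
  d <- diff(sort(spec$positions))
  if (max(abs(d - d[1])) > 1e-9 * d[1])
    stop("MultiPINS requires equidistant slices")
  d[1]
}

#' Largest feasible MultiPINS mixing ratio
#'
#' Scans M over a grid from 0 to 1 (step `step`) and returns the largest M
#' for which the mixed pulse stays within the B1 limit. Duration is
#' non-increasing in M over the feasible range.
#'
#' @param sb An `sb_pulse`.
#' @param spec [modulation_spec()].
#' @param lim [hardware_limits()].
#' @param step Grid step (default 0.005).
#' @param dwell Sampling time in microseconds.
#' @param offset Pattern offset in mm (see [design_pins()]).
#' @return Largest feasible M (numeric), with attribute `duration_ms`.
#' @export
max_mixing_ratio <- function(sb, spec, lim, step = 0.005, dwell = NULL,
                             offset = 0) {
  ok <- function(M) {
    d <- tryCatch(design_multipins(sb, spec, lim, M, dwell = dwell,
                                   offset = offset),
                  error = function(e) NULL)
    d
  }
  if (is.null(ok(0))) stop("pure PINS (M = 0) infeasible under these limits")
  grid <- seq(0, 1, by = step)
  best <- 0; bestd <- NULL
  for (M in grid) {
    d <- ok(M)
    if (is.null(d)) break
    best <- M; bestd <- d
  }
  structure(best, duration_ms = bestd$duration)
}
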
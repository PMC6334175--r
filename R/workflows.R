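the_design_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  v <- the_design_cache[[key]]
  if (is.null(v)) {
    v <- force(expr)
    the_design_cache[[key]] <- v
  }
  v
}

#' Clear the internal design cache
#' @export
clear_design_cache <- function() {
  rm(list = ls(the_design_cache), envir = the_design_cache)
  invisible(NULL)
}

# Dilation helper (lambda may be < 1, unlike the public stretch operation).
dilate_pulse <- function(rf, g, lambda) {
  n <- length(rf$samples)
  if (is.numeric(g) && length(g) == 1) g <- gradient_waveform(rep(g, n), rf$dt)
  structure(list(rf = rf_waveform(rf$samples / lambda, rf$dt * lambda),
                 grad = gradient_waveform(g$samples / lambda, g$dt * lambda),
                 duration = wf_duration(rf) * lambda,
                 info = list(lambda = lambda)),
            class = "versed_pulse")
}

# Minimum constant-gradient duration: peak-B1-limited stretch, also bounded
# by the maximum gradient needed to reach the slice bandwidth.
const_gradient_duration <- function(rf_ref, tbp, thickness, lim) {
  t_ref <- wf_duration(rf_ref)
  t_b1 <- t_ref * max(Mod(rf_ref$samples)) / lim$b1_max
  t_g <- tbp / (gamma_bar() * 1e-3 * thickness * lim$g_max)
  max(t_b1, t_g)
}

#' Design a multiband refocusing pulse with any of the supported methods
#'
#' Methods: `MB` (constant gradient, linear phase, peak-limited stretch),
#' `MBv` (multiband modulation then time-optimal VERSE), `vMB` (VERSE on the
#' singleband pulse under the reduced B1 limit, then modulation), `nlMB`
#' (constant-gradient root-flipped), `nlMBv` (root-flipped then VERSE),
#' `nlvMB` (quadratic-phase singleband, VERSE, then modulation), `PINS`,
#' `MultiPINS`.
#'
#' @param method Method name (see above).
#' @param n_slices Number of slices N.
#' @param tbp Time-bandwidth product.
#' @param thickness Slice thickness, mm.
#' @param separation Slice separation, mm (fixed-separation geometry).
#' @param fov Imaging FOV, mm (fixed-FOV geometry: separation = fov/N).
#'   Exactly one of `separation`, `fov` must be given.
#' @param lim [hardware_limits()].
#' @param am_only Restrict modulation to signed AM.
#' @param ga Genetic-algorithm settings for root-flipped methods.
#' @param dwell PINS sampling time, microseconds.
#' @param t_ref Reference design duration, ms.
#' @param n_samples Working sample count.
#' @return Object of class `mb_design`: `method`, `rf`, `grad`, `duration`
#'   (ms), geometry fields, `target_b` (function(z) -> complex ideal beta
#'   response) and method-specific metadata in `meta`.
#' @export
design_pulse <- function(method, n_slices, tbp, thickness = 2,
                         separation = NULL, fov = NULL,
                         lim = hardware_limits(), am_only = FALSE,
                         ga = list(), dwell = NULL, t_ref = 1,
                         n_samples = 2048) {
  method <- match.arg(method, c("MB", "MBv", "vMB", "nlMB", "nlMBv",
                                "nlvMB", "PINS", "MultiPINS"))
  if (is.null(separation) == is.null(fov))
    stop("give exactly one of separation or fov")
  geometry <- if (is.null(separation)) "fixed_fov" else "fixed_sep"
  if (is.null(separation)) separation <- fov / n_slices
  fov_used <- if (geometry == "fixed_fov") fov else n_slices * separation
  if (separation <= thickness) stop("separation must exceed the thickness")
  N <- as.integer(n_slices)
  sb <- cached(sprintf("sb_lin_%g_%g_%g_%d", tbp, thickness, t_ref, n_samples),
               design_sb_pulse(tbp, thickness, duration = t_ref,
                               n_samples = n_samples))
  phases <- if (N >= 2) optimize_phase_offsets(N, am_only = am_only) else 0
  spec <- modulation_spec(N, slice_positions(N, separation), phases, am_only)
  th <- thickness
  # Exact effective beta response of the constant-gradient modulated parent:
  # forward SLR of the modulated pulse at a resolution that (a) keeps the
  # outermost modulation band clear of Nyquist and (b) makes the polynomial
  # response cover the whole 3x-FOV evaluation window. This captures all
  # large-tip cross-band effects, so it is the reference that the VERSE
  # machinery must preserve.
  n_alias <- 2.3 * tbp * (max(abs(slice_positions(N, separation))) / th + 1)
  n_cover <- 2 * tbp * (1.5 * fov_used + 5) / th
  n_tgt <- min(4096, 2^ceiling(log2(max(n_alias, n_cover, 512))))
  parent_beta <- function(rf_src, modulated) {
    key <- sprintf("tgt_%s_%g_%g_%d_%g_%d_%d_%d",
                   substr(digest_rf(rf_src), 1, 8),
                   tbp, th, N, separation, isTRUE(am_only), n_tgt, modulated)
    cached(key, {
      par_rf <- resample_waveform(rf_src, n_tgt)
      if (modulated) par_rf <- modulate_constant(par_rf, spec, sb$G)
      forward_slr(par_rf)$beta
    })
  }
  b_mb_lin <- function(z)
    band_limited_response(parent_beta(sb$rf, TRUE), z / th, tbp / n_tgt)
  pins_offset <- if (N %% 2 == 0) separation / 2 else 0
  meta <- list(spec = spec, sb = sb)
  # output dwell fine enough that the fastest multiband component advances
  # less than pi/8 per sample
  phr <- .GAMMA * lim$g_max * (max(abs(spec$positions)) + 3 * th)
  res <- switch(method,
    MB = {
      rf_mod <- modulate_constant(sb$rf, spec, sb$G)
      Tc <- const_gradient_duration(rf_mod, tbp, th, lim)
      v <- dilate_pulse(rf_mod, sb$G, Tc / t_ref)
      list(rf = v$rf, grad = v$grad, duration = v$duration,
           target_b = b_mb_lin)
    },
    MBv = {
      rf_mod <- modulate_constant(sb$rf, spec, sb$G)
      v <- make_mbv(rf_mod, sb$G, lim, max_phase_rate = phr)
      list(rf = v$rf, grad = v$grad, duration = v$duration,
           target_b = b_mb_lin, verse = v)
    },
    vMB = {
      v <- make_vmb(sb$rf, sb$G, lim, spec, max_phase_rate = phr)
      list(rf = v$rf, grad = v$grad, duration = v$duration,
           target_b = b_mb_lin, verse = v)
    },
    nlMB = {
      mb <- cached(sprintf("rf_mb_%g_%g_%d_%g_%d", tbp, th, N, separation,
                           isTRUE(am_only)),
                   root_flip_mb(tbp, spec, th, duration = t_ref, ga = ga,
                                n_samples = n_samples))
      Tc <- const_gradient_duration(mb$rf, tbp, th, lim)
      v <- dilate_pulse(mb$rf, mb$G, Tc / t_ref)
      list(rf = v$rf, grad = v$grad, duration = v$duration,
           target_b = function(z)
             band_limited_response(parent_beta(mb$rf, FALSE), z / th,
                                   tbp / n_tgt),
           mb = mb)
    },
    nlMBv = {
      mb <- cached(sprintf("rf_mb_%g_%g_%d_%g_%d", tbp, th, N, separation,
                           isTRUE(am_only)),
                   root_flip_mb(tbp, spec, th, duration = t_ref, ga = ga,
                                n_samples = n_samples))
      v <- make_mbv(mb$rf, mb$G, lim, max_phase_rate = phr)
      list(rf = v$rf, grad = v$grad, duration = v$duration,
           target_b = function(z)
             band_limited_response(parent_beta(mb$rf, FALSE), z / th,
                                   tbp / n_tgt),
           mb = mb, verse = v)
    },
    nlvMB = {
      sbq <- cached(sprintf("sb_quad_%g_%g_%g_%d", tbp, th, t_ref, n_samples),
                    design_sb_pulse(tbp, th, duration = t_ref,
                                    phase_type = "quadratic",
                                    n_samples = n_samples))
      v <- make_vmb(sbq$rf, sbq$G, lim, spec, max_phase_rate = phr)
      list(rf = v$rf, grad = v$grad, duration = v$duration,
           target_b = function(z)
             band_limited_response(parent_beta(sbq$rf, TRUE), z / th, tbp / n_tgt),
           sbq = sbq, verse = v)
    },
    PINS = {
      p <- design_pins(sb, separation, lim, dwell = dwell,
                       offset = pins_offset)
      tb <- kspace_target_beta(p, sb, NULL, 0, fov_used)
      list(rf = p$rf, grad = p$grad, duration = p$duration,
           target_b = function(z) polyval_unit(tb$beta, -z * tb$dk / (2 * pi)),
           pins = p)
    },
    MultiPINS = {
      spec0 <- modulation_spec(N, spec$positions, rep(0, N), am_only)
      M <- max_mixing_ratio(sb, spec0, lim, dwell = dwell,
                            offset = pins_offset)
      Mv <- as.numeric(M)
      p <- design_multipins(sb, spec0, lim, Mv, dwell = dwell,
                            offset = pins_offset)
      tb <- kspace_target_beta(p, sb, spec0, Mv, fov_used)
      list(rf = p$rf, grad = p$grad, duration = p$duration,
           target_b = function(z) polyval_unit(tb$beta, -z * tb$dk / (2 * pi)),
           pins = p, mixing_ratio = Mv)
    })
  structure(c(res,
              list(method = method, n_slices = N, tbp = tbp,
                   thickness = th, separation = separation,
                   fov = fov_used, geometry = geometry, lim = lim,
                   meta = meta)),
            class = "mb_design")
}

band_limited_response <- function(beta, pos_th, bw) {
  # the simulator's free-precession sign convention maps position +z to
  # digital frequency -z * bw / thickness of the beta polynomial
  f <- -pos_th * bw
  out <- rep(0 + 0i, length(f))
  ok <- abs(f) <= 0.5
  if (any(ok)) out[ok] <- polyval_unit(beta, f[ok])
  out
}

# Exact k-space design target for PINS/MultiPINS. RF blips play at zero
# gradient (pure rotations) and gradient blips are pure precession, so the
# pulse is exactly a hard-pulse SLR chain on the k axis: the PINS subpulses
# are delta rotations at the comb positions and the MB component deposits
# RF in proportion to the gradient at matched k. Discretizing k uniformly
# and running the forward SLR recursion gives the design's own beta
# response, valid over the whole evaluation window.
kspace_target_beta <- function(p, sb, spec0, M, fov_used) {
  dk_comb <- 2 * pi / p$separation
  K <- p$n_subpulses * dk_comb
  # grid spacing divides the comb spacing exactly, so the delta rotations
  # land on grid points (no quantization dephasing at large |z|)
  r <- 2 * ceiling(max(K * (1.5 * fov_used + 5) / pi, 512) /
                     (2 * p$n_subpulses))
  n_k <- p$n_subpulses * r
  dk <- dk_comb / r
  kg <- -K / 2 + (seq_len(n_k) - 1) * dk
  ang <- rep(0 + 0i, n_k)
  # PINS delta rotations at the comb positions
  kj <- (seq_len(p$n_subpulses) - (p$n_subpulses + 1) / 2) * dk_comb
  idx <- as.integer(round((kj - kg[1]) / dk)) + 1L
  stopifnot(max(abs((kj - kg[idx]))) < 1e-9 * dk_comb)
  ang[idx] <- ang[idx] + .GAMMA * p$areas
  if (M > 0) {
    ksb <- .GAMMA * sb$G * (wf_times(sb$rf) - wf_duration(sb$rf) / 2)
    wr <- stats::approx(ksb, Re(sb$rf$samples), xout = kg, rule = 2)$y
    wi <- stats::approx(ksb, Im(sb$rf$samples), xout = kg, rule = 2)$y
    env <- complex(real = wr, imaginary = wi)
    fN <- modulation_function(kg, spec0)
    dep <- M * (env * fN / sb$G) * dk
    # the blipped gradient only sweeps k between the first and last comb
    # positions; no MB energy can be deposited outside that interval
    dep[kg < kj[1] | kg > kj[length(kj)]] <- 0
    ang <- ang + dep
  }
  list(beta = slr_forward_cpp(ang)$B, dk = dk)
}

# cheap content hash for cache keys
digest_rf <- function(rf) {
  s <- rf$samples
  paste0(format(sum(Re(s) * seq_along(s)) + 1i * sum(Mod(s)), digits = 15),
         length(s))
}

#' @export
print.mb_design <- function(x, ...) {
  cat(sprintf("<mb_design> %s, N %d, tbp %.3g, sep %.3g mm (%s), %.4g ms, peak %.4g uT, energy %.4g uT^2 ms\n",
              x$method, x$n_slices, x$tbp, x$separation, x$geometry,
              x$duration, rf_peak(x$rf), rf_energy(x$rf)))
  invisible(x)
}

#' Ideal flip-angle target profile of a design
#'
#' Evaluates the design's own beta response on a z grid and converts to flip
#' angle; this is the reference for design-fidelity checks.
#'
#' @param design An `mb_design`.
#' @param z Positions (mm).
#' @return A [slice_profile()].
#' @export
target_profile <- function(design, z) {
  B <- design$target_b(z)
  th <- 2 * asin(pmin(Mod(B), 1))
  slice_profile(z, th, NULL, fov = design$fov)
}

#' Design fidelity under an ideal gradient
#'
#' Simulates the pulse with the demanded gradient and compares against the
#' analytic design target.
#'
#' @param design An `mb_design`.
#' @param pts_per_slice Spatial sampling density.
#' @return `c(eps_inside, eps_outside)`.
#' @export
design_fidelity_eps <- function(design, pts_per_slice = 16) {
  z <- profile_grid(design$fov, design$thickness, pts_per_slice)
  prof <- evaluate_profile(design$rf, design$grad, z, design$fov)
  nrmse_regions(prof, target_profile(design, z))
}

#' Slice-profile distortion caused by a GIRF
#'
#' Simulates the pulse with the demanded gradient (target profile) and with
#' the GIRF-distorted gradient (actual profile) and returns the region-wise
#' NRMSE, as used for epsilon_inside / epsilon_outside.
#'
#' @param design An `mb_design`.
#' @param girf A [girf()].
#' @param pts_per_slice Spatial sampling density.
#' @param axis GIRF axis.
#' @return `c(eps_inside, eps_outside)`.
#' @export
girf_distortion_eps <- function(design, girf, pts_per_slice = 16,
                                axis = "z") {
  z <- profile_grid(design$fov, design$thickness, pts_per_slice)
  tgt <- evaluate_profile(design$rf, design$grad, z, design$fov)
  g_act <- apply_girf(design$grad, girf, axis = axis)
  act <- evaluate_profile(design$rf, g_act, z, design$fov)
  nrmse_regions(act, tgt)
}

#' Run a design/evaluation sweep
#'
#' Designs the requested methods for each number of slices and tabulates
#' duration, RF energy and (optionally) GIRF distortion metrics.
#' Deterministic for fixed seeds; per-design failures are recorded as rows
#' with a non-"ok" status and the sweep continues.
#'
#' @param config A list with elements `methods` (character), `n_slices`
#'   (integer vector), `tbp`, `thickness`, and one of `fov` / `separation`;
#'   optional `lim` ([hardware_limits()]), `girf` ([girf()] or NULL),
#'   `ga_seed`, `am_only`, `pts_per_slice`, `dwell`.
#' @param out_csv Optional path: write the result table as CSV.
#' @return A data.frame of class `sweep_result`.
#' @export
run_sweep <- function(config, out_csv = NULL) {
  cfg <- utils::modifyList(list(methods = c("MB", "MBv", "vMB"),
                                n_slices = 2:4, tbp = 4, thickness = 2,
                                fov = NULL, separation = NULL,
                                lim = hardware_limits(), girf = NULL,
                                ga_seed = 1, am_only = FALSE,
                                pts_per_slice = 16, dwell = NULL), config)
  girf_id <- if (is.null(cfg$girf)) "none"
  else if (!is.null(cfg$girf$shape))
    sprintf("%s_fwhm%g_delay%g", cfg$girf$shape, cfg$girf$fwhm, cfg$girf$delay)
  else "custom"
  rows <- list()
  for (N in cfg$n_slices) {
    for (meth in cfg$methods) {
      row <- data.frame(method = meth, n_slices = N, tbp = cfg$tbp,
                        geometry = if (is.null(cfg$fov)) "fixed_sep"
                        else "fixed_fov",
                        separation = if (is.null(cfg$fov)) cfg$separation
                        else cfg$fov / N,
                        duration_ms = NA_real_, energy = NA_real_,
                        eps_inside = NA_real_, eps_outside = NA_real_,
                        girf_id = girf_id, status = "ok",
                        stringsAsFactors = FALSE)
      d <- tryCatch(
        design_pulse(meth, N, cfg$tbp, cfg$thickness,
                     separation = cfg$separation, fov = cfg$fov,
                     lim = cfg$lim, am_only = cfg$am_only,
                     ga = list(seed = cfg$ga_seed), dwell = cfg$dwell),
        error = function(e) e)
      if (inherits(d, "error")) {
        row$status <- conditionMessage(d)
      } else {
        row$duration_ms <- d$duration
        row$energy <- rf_energy(d$rf)
        if (!is.null(cfg$girf)) {
          eps <- tryCatch(girf_distortion_eps(d, cfg$girf,
                                              cfg$pts_per_slice),
                          error = function(e) c(NA, NA))
          row$eps_inside <- eps[1]
          row$eps_outside <- eps[2]
        }
      }
      rows[[length(rows) + 1]] <- row
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("sweep_result", "data.frame")
  if (!is.null(out_csv))
    utils::write.csv(out, out_csv, row.names = FALSE)
  out
}

#' Load a sweep configuration from YAML
#'
#' @param path YAML file. Recognised keys mirror the `config` argument of
#'   [run_sweep()]; `lim` may be a mapping with b1_max/g_max/slew_max and
#'   `girf` a mapping with fwhm/delay/shape.
#' @export
read_sweep_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$lim)) y$lim <- do.call(hardware_limits, y$lim)
  if (!is.null(y$girf)) y$girf <- do.call(make_synthetic_girf, y$girf)
  y
}

#' Duration metrics of the fixed-FOV method comparison
#'
#' Designs the linear and (optionally) non-linear method variants for each
#' number of slices at fixed FOV and returns the duration summary statistics
#' of the comparison: the mean percentage duration excess of vMB over MBv
#' (linear and non-linear), the mean pre-VERSE linear-vs-root-flipped gap of
#' the constant-gradient pulses, the post-VERSE gaps, and the mean VERSE
#' speed-up factor of MBv over the constant-gradient linear baseline.
#'
#' @param n_range Numbers of slices (default 2:12).
#' @param tbp Time-bandwidth product.
#' @param fov Imaging FOV in mm.
#' @param thickness Slice thickness in mm.
#' @param lim [hardware_limits()].
#' @param ga Genetic-algorithm settings for the root-flipped designs.
#' @param nonlinear Include the root-flipped / quadratic-phase variants.
#' @return List with `durations` (data.frame per N) and the summary metrics
#'   `mean_vmb_excess`, `mean_nl_vmb_excess`, `pre_verse_gap`,
#'   `post_verse_gap_mbv`, `post_verse_gap_vmb`, `verse_speedup`.
#' @export
duration_metrics_sweep <- function(n_range = 2:12, tbp = 4, fov = 200,
                                   thickness = 2, lim = hardware_limits(),
                                   ga = list(), nonlinear = TRUE) {
  rows <- lapply(n_range, function(N) {
    out <- data.frame(
      N = N,
      MB = design_pulse("MB", N, tbp, thickness, fov = fov, lim = lim)$duration,
      MBv = design_pulse("MBv", N, tbp, thickness, fov = fov,
                         lim = lim)$duration,
      vMB = design_pulse("vMB", N, tbp, thickness, fov = fov,
                         lim = lim)$duration)
    if (nonlinear) {
      out$nlMB <- design_pulse("nlMB", N, tbp, thickness, fov = fov,
                               lim = lim, ga = ga)$duration
      out$nlMBv <- design_pulse("nlMBv", N, tbp, thickness, fov = fov,
                                lim = lim, ga = ga)$duration
      out$nlvMB <- design_pulse("nlvMB", N, tbp, thickness, fov = fov,
                                lim = lim, ga = ga)$duration
    }
    out
  })
  d <- do.call(rbind, rows)
  res <- list(
    durations = d,
    mean_vmb_excess = mean(100 * (d$vMB - d$MBv) / d$MBv),
    verse_speedup = mean(d$MB / d$MBv))
  if (nonlinear) {
    res$mean_nl_vmb_excess <- mean(100 * (d$nlvMB - d$nlMBv) / d$nlMBv)
    res$pre_verse_gap <- mean(100 * (d$MB - d$nlMB) / d$nlMB)
    res$post_verse_gap_mbv <- mean(100 * (d$MBv - d$nlMBv) / d$nlMBv)
    res$post_verse_gap_vmb <- mean(100 * (d$vMB - d$nlvMB) / d$nlvMB)
  }
  res
}
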
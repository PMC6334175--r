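#' Multiband modulation specification
#'
#' @param n_slices Number of simultaneously excited slices N.
#' @param positions Slice centre positions x_n in mm (length N).
#' @param phases Per-slice phase offsets phi_n in radians (length N).
#' @param am_only If TRUE the modulation is restricted to a real-valued
#'   (signed AM) function, i.e. phases in {0, pi} with conjugate symmetry.
#' @return Object of class `modulation_spec`.
#' @export
modulation_spec <- function(n_slices, positions, phases = NULL,
                            am_only = FALSE) {
  n_slices <- as.integer(n_slices)
  if (is.null(phases)) phases <- rep(0, n_slices)
  stopifnot(length(positions) == n_slices, length(phases) == n_slices)
  structure(list(n_slices = n_slices, positions = as.numeric(positions),
                 phases = as.numeric(phases), am_only = isTRUE(am_only)),
            class = "modulation_spec")
}

#' Slice positions for a symmetric slice pack
#'
#' Centres N slices symmetrically about z = 0 with the given centre-to-centre
#' separation.
#'
#' @param n_slices N.
#' @param separation Centre-to-centre separation in mm.
#' @return Numeric vector of N positions (mm).
#' @export
slice_positions <- function(n_slices, separation) {
  (seq_len(n_slices) - (n_slices + 1) / 2) * separation
}

#' Excitation k-trajectory of a gradient waveform
#'
#' k(t) = -gamma * integral_t^T G(s) ds, so k at the end of the pulse is zero.
#' Units: rad/mm. Evaluated at sample midpoints by trapezoidal quadrature of
#' the sample-and-hold gradient (each sample contributes g*dt exactly).
#'
#' @param g A [gradient_waveform()].
#' @return Object of class `k_trajectory`: list with `k` (rad/mm, one value
#'   per gradient sample, evaluated at the sample midpoint), `k_end = 0`,
#'   `dt`.
#' @export
k_trajectory <- function(g) {
  stopifnot(inherits(g, "gradient_waveform"))
  # area remaining after the midpoint of sample i:
  # g_i*dt/2 + sum_{j>i} g_j*dt
  gs <- g$samples * g$dt
  tail_area <- rev(cumsum(rev(gs))) - gs / 2
  structure(list(k = -.GAMMA * tail_area, dt = g$dt), class = "k_trajectory")
}

#' Multiband modulation for a constant gradient
#'
#' Multiplies a singleband pulse by f_N(t) = sum_n exp(i(gamma G x_n t +
#' phi_n)). Time is measured from the pulse centre so that linear-phase
#' designs stay symmetric.
#'
#' @param sb An [rf_waveform()].
#' @param spec A [modulation_spec()].
#' @param G Constant gradient amplitude in mT/m.
#' @return An [rf_waveform()] of the same length and dwell.
#' @export
modulate_constant <- function(sb, spec, G) {
  stopifnot(inherits(sb, "rf_waveform"), inherits(spec, "modulation_spec"),
            G > 0)
  tc <- wf_times(sb) - wf_duration(sb) / 2
  f <- modulation_function(.GAMMA * G * tc, spec)
  rf_waveform(sb$samples * f, sb$dt)
}

#' Multiband modulation for a time-variable gradient
#'
#' Multiplies a (typically VERSE'd) singleband pulse by
#' f_N^v(t) = sum_n exp(i(k(t) x_n + phi_n)), with k referenced to the pulse
#' centre by default so the constant-gradient case reduces to
#' [modulate_constant()] up to a spatially linear phase.
#'
#' @param sb An [rf_waveform()] on the same grid as `k`.
#' @param k A [k_trajectory()].
#' @param spec A [modulation_spec()].
#' @param reference "center" (default) or "end": k value subtracted before
#'   modulation.
#' @return An [rf_waveform()].
#' @export
modulate_verse <- function(sb, k, spec, reference = c("center", "end")) {
  stopifnot(inherits(sb, "rf_waveform"), inherits(k, "k_trajectory"),
            inherits(spec, "modulation_spec"))
  reference <- match.arg(reference)
  if (length(k$k) != length(sb$samples) || abs(k$dt - sb$dt) > 1e-12 * sb$dt)
    stop("RF and k-trajectory are not on the same time grid")
  # "center" = midpoint of the k extent (NOT the time midpoint: the two
  # coincide only for time-symmetric pulses, and the k-extent centre is what
  # reduces exactly to the constant-gradient modulation on a constant G)
  kref <- if (reference == "center")
    (k$k[1] + k$k[length(k$k)]) / 2 else 0
  f <- modulation_function(k$k - kref, spec)
  rf_waveform(sb$samples * f, sb$dt)
}

# f_N evaluated at given spatial-frequency arguments (rad/mm * mm = rad)
modulation_function <- function(karg, spec) {
  f <- rep(0 + 0i, length(karg))
  for (n in seq_len(spec$n_slices))
    f <- f + exp(1i * (karg * spec$positions[n] + spec$phases[n]))
  if (spec$am_only) f <- complex(real = Re(f), imaginary = 0)
  f
}

#' Reduced peak-B1 constraint for VERSE-before-modulation designs
#'
#' When VERSE is applied to the singleband pulse first, the later modulation
#' multiplies the RF by f_N^v, so the B1 limit handed to VERSE must shrink to
#' B1max / max_t |f_N^v(t)|.
#'
#' @param b1_max System peak B1 (uT).
#' @param f_vals Complex samples of the modulation function.
#' @return Reduced limit in uT.
#' @export
vmb_b1_limit <- function(b1_max, f_vals) {
  pk <- max(Mod(f_vals))
  if (pk == 0) stop("modulation function is identically zero")
  b1_max / pk
}

# ---- phase-offset optimization -------------------------------------------

the_phase_cache <- new.env(parent = emptyenv())

#' Optimize multiband phase offsets
#'
#' Minimizes the peak magnitude of the modulation function for N equidistant
#' slices (the peak depends only on N and the slice spacing pattern, not on
#' the physical separation). Multi-start Nelder-Mead with a fixed internal
#' seed and a quadratic-phase-schedule start, so results are deterministic
#' for a given N. With `am_only = TRUE` the phases are restricted to {0, pi}
#' and found by exhaustive enumeration.
#'
#' @param n_slices N (>= 1).
#' @param am_only Restrict to signed-AM modulation.
#' @param symmetric Constrain the offsets to conjugate symmetry about the
#'   pack centre (phi_n = -phi_(N+1-n)), which makes the modulation function
#'   Hermitian; off by default (the unconstrained optimum is at least as
#'   good).
#' @param n_starts Number of random restarts (>= 32 recommended).
#' @param use_cache Reuse previously computed offsets for this N.
#' @return Numeric vector of N phases (first phase 0), with attribute
#'   `peak` = achieved peak |f_N|.
#' @export
optimize_phase_offsets <- function(n_slices, am_only = FALSE,
                                   symmetric = FALSE, n_starts = 64,
                                   use_cache = TRUE) {
  n_slices <- as.integer(n_slices)
  stopifnot(n_slices >= 1)
  if (n_slices == 1) return(structure(0, peak = 1))
  key <- sprintf("N%d_am%d_sym%d", n_slices, as.integer(am_only),
                 as.integer(symmetric))
  if (use_cache && !is.null(the_phase_cache[[key]]))
    return(the_phase_cache[[key]])
  u <- seq_len(n_slices) - (n_slices + 1) / 2   # slice index pattern
  tau <- seq(0, 2, length.out = 4096)           # two fundamental periods
  E <- exp(2i * pi * outer(tau, u))
  if (symmetric && !am_only) {
    # free parameters: phases of the first floor(N/2) slices; the mirror
    # slices get the negated phase (middle slice of an odd pack fixed at 0)
    half <- n_slices %/% 2
    expand <- function(p) {
      full <- numeric(n_slices)
      full[seq_len(half)] <- p
      full[n_slices + 1 - seq_len(half)] <- -p
      full
    }
    obj <- function(p) max(Mod(E %*% exp(1i * expand(p))))
    old <- local_seed(20270 + n_slices)
    on.exit(restore_seed(old), add = TRUE)
    best <- NULL; bestv <- Inf
    for (i in seq_len(n_starts)) {
      s <- if (i == 1) (pi * u^2 / n_slices)[seq_len(half)]
      else stats::runif(half, 0, 2 * pi)
      fit <- if (half == 1)
        list(par = stats::optimize(obj, c(0, 2 * pi), tol = 1e-10)$minimum)
      else stats::optim(s, obj, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-9))
      v <- obj(fit$par)
      if (v < bestv) { bestv <- v; best <- fit$par }
    }
    out <- structure(expand(best), peak = bestv)
    the_phase_cache[[key]] <- out
    return(out)
  }
  peak_of <- function(ph) max(Mod(E %*% exp(1i * ph)))
  if (am_only) {
    best <- NULL; bestv <- Inf
    for (code in 0:(2^(n_slices - 1) - 1)) {
      ph <- c(0, pi * as.integer(intToBits(code))[seq_len(n_slices - 1)])
      v <- max(abs(Re(E %*% exp(1i * ph))))
      if (v < bestv) { bestv <- v; best <- ph }
    }
    out <- structure(best, peak = bestv)
  } else {
    obj <- function(ph) peak_of(c(0, ph))
    if (n_slices == 2) {
      # one-dimensional: golden-section search on the single relative phase
      fit <- stats::optimize(obj, c(0, 2 * pi), tol = 1e-10)
      out <- structure(c(0, fit$minimum), peak = fit$objective)
      the_phase_cache[[key]] <- out
      return(out)
    }
    starts <- list(pi * u^2 / n_slices)          # quadratic phase schedule
    starts[[1]] <- (starts[[1]] - starts[[1]][1])[-1]
    old <- local_seed(20170 + n_slices)
    on.exit(restore_seed(old), add = TRUE)
    for (i in seq_len(n_starts - 1))
      starts[[i + 1]] <- stats::runif(n_slices - 1, 0, 2 * pi)
    best <- NULL; bestv <- Inf
    for (s in starts) {
      fit <- stats::optim(s, obj, method = "Nelder-Mead",
                          control = list(maxit = 2000, reltol = 1e-9))
      if (fit$value < bestv) { bestv <- fit$value; best <- fit$par }
    }
    # polish the winner: restarted simplex plus small perturbations
    for (i in 1:8) {
      s <- best + if (i == 1) 0 else stats::rnorm(n_slices - 1, 0, 0.1)
      fit <- stats::optim(s, obj, method = "Nelder-Mead",
                          control = list(maxit = 4000, reltol = 1e-12))
      if (fit$value < bestv) { bestv <- fit$value; best <- fit$par }
    }
    out <- structure(c(0, best %% (2 * pi)), peak = bestv)
  }
  the_phase_cache[[key]] <- out
  out
}

# save/restore the global RNG state so optimization is deterministic without
# disturbing the caller's stream
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  old
}
restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Persist / load phase-offset tables
#'
#' Phase offsets depend only on (N, am_only); tables are stored as JSON.
#'
#' @param path File path.
#' @param n_max Largest N to include when writing.
#' @export
write_phase_table <- function(path, n_max = 12) {
  tab <- list()
  for (N in 2:n_max) {
    for (am in c(FALSE, TRUE)) {
      ph <- optimize_phase_offsets(N, am_only = am)
      tab[[sprintf("N%d_am%d_sym0", N, as.integer(am))]] <-
        list(n_slices = N, am_only = am, phases = as.numeric(ph),
             peak = attr(ph, "peak"))
    }
  }
  jsonlite::write_json(tab, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_phase_table
#' @export
read_phase_table <- function(path) {
  tab <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (key in names(tab)) {
    the_phase_cache[[key]] <- structure(as.numeric(tab[[key]]$phases),
                                        peak = tab[[key]]$peak)
  }
  invisible(names(tab))
}

# ---- root-flipped multiband design ---------------------------------------

#' Design the multiband beta filter for root-flipping
#'
#' Direct multiband FIR design (weighted least squares with Lawson
#' re-weighting) with one passband per slice. The filter length is chosen so
#' the outermost band edge stays below 70% of Nyquist.
#'
#' @param tbp Time-bandwidth product.
#' @param pos_th Slice centre positions in units of the slice thickness.
#' @param ripple_pass,ripple_stop beta^2 profile ripples.
#' @return As [design_beta_filter()], plus `centers` (cycles/sample) and
#'   `pos_th`.
#' @export
design_mb_beta_filter <- function(tbp, pos_th, ripple_pass = 0.01,
                                  ripple_stop = 0.01) {
  d1 <- ripple_pass / 4; d2 <- sqrt(ripple_stop)
  wtr <- dinf(d1, d2) / tbp
  n <- ceiling((max(abs(pos_th)) + (1 + wtr) / 2) * tbp / 0.35)
  n <- max(257L, as.integer(n))
  if (n %% 2 == 0) n <- n + 1L
  bw <- tbp / n
  centers <- pos_th * bw
  coef <- firls_lawson(n, centers, bw, wtr, d1, d2)
  mr <- measure_ripples(coef, centers, bw, wtr)
  list(coef = coef, bw = bw, wtrans = wtr, d1 = d1, d2 = d2, n = n,
       centers = centers, pos_th = pos_th, ripples = mr)
}

#' Root-flipped multiband refocusing pulse
#'
#' Finds the roots of the multiband beta polynomial, identifies the passband
#' roots, and searches (genetic algorithm over conjugate-symmetric flip
#' patterns) for the pattern that minimizes the peak RF amplitude. Flipping a
#' root across the unit circle leaves |beta| unchanged, so the slice-profile
#' magnitude equals the unflipped design; the through-slice phase becomes
#' non-linear.
#'
#' @param tbp Time-bandwidth product.
#' @param spec A [modulation_spec()] (positions used; phases ignored —
#'   the flip pattern plays the role of phase optimization).
#' @param thickness Slice thickness in mm.
#' @param duration Nominal pulse duration in ms.
#' @param ga Genetic-algorithm settings: list with `pop`, `generations`,
#'   `seed`, `early_stop`, `mutation` (NULL = 1/n_bits).
#' @param ripple_pass,ripple_stop Profile ripples.
#' @param n_samples Working sample count after resampling.
#' @return Object of class `mb_pulse`: `rf` (fine grid), `rf_design`, `G`,
#'   `grad`, `filter`, `pattern` (best flip pattern), `peak_history`.
#' @export
root_flip_mb <- function(tbp, spec, thickness, duration = 1,
                         ga = list(), ripple_pass = 0.01, ripple_stop = 0.01,
                         n_samples = 2048) {
  stopifnot(inherits(spec, "modulation_spec"))
  ga <- utils::modifyList(list(pop = 64L, generations = 200L, seed = 1L,
                               early_stop = 40L, mutation = NULL,
                               conjugate_pairs = FALSE), ga)
  pos_th <- spec$positions / thickness
  filt <- design_mb_beta_filter(tbp, pos_th, ripple_pass, ripple_stop)
  n <- filt$n
  b0 <- as.complex(filt$coef)
  r <- poly_roots_cpp(b0)
  # passband roots: angular position inside a band, radius near the circle
  ang <- Arg(r) / (2 * pi)
  inband <- rep(FALSE, length(r))
  for (fc in filt$centers)
    inband <- inband | abs(ang - fc) < (1 + filt$wtrans) * filt$bw / 2
  inband <- inband & abs(Mod(r) - 1) < 0.3
  r[inband] <- polish_roots(b0, r[inband])
  # flip unit: individual passband roots (default, as in root-flipped
  # refocusing designs - the resulting beta is complex and the pulse
  # FM-like), or conjugate pairs (keeps the filter real)
  idx <- which(inband)
  if (isTRUE(ga$conjugate_pairs)) {
    pos_idx <- idx[Im(r[idx]) > 1e-12]
    neg_idx <- idx[Im(r[idx]) < -1e-12]
    real_idx <- setdiff(idx, c(pos_idx, neg_idx))
    groups <- lapply(pos_idx, function(i) {
      j <- neg_idx[which.min(Mod(r[neg_idx] - Conj(r[i])))]
      c(i, j)
    })
    groups <- c(groups, as.list(real_idx))
  } else {
    groups <- as.list(idx)
  }
  nbits <- length(groups)
  if (nbits == 0) stop("no passband roots found")
  m <- 2^ceiling(log2(max(8 * n, 2048)))
  zg <- exp(-2i * pi * (0:(m - 1)) / m)
  Bg <- dft_response(b0, m)
  # per-group all-pass factor on the DFT grid
  fac <- matrix(0 + 0i, m, nbits)
  for (gi in seq_len(nbits)) {
    v <- rep(1 + 0i, m)
    for (ri in r[groups[[gi]]]) v <- v * (zg - 1 / Conj(ri)) / (zg - ri)
    fac[, gi] <- v
  }
  target <- 1 - 1e-7
  eval_pattern <- function(bits) {
    Bn <- Bg
    for (gi in which(bits)) Bn <- Bn * fac[, gi]
    Bn <- Bn * (target / max(Mod(Bn)))
    bnew <- (stats::fft(Bn, inverse = TRUE) / m)[seq_len(n)]
    rfang <- beta_to_rf_cpp(bnew, as.integer(m))
    list(peak = max(Mod(rfang)), rfang = rfang, beta = bnew)
  }
  # genetic search with memoised fitness
  memo <- new.env(parent = emptyenv())
  fitness <- function(bits) {
    key <- paste(as.integer(bits), collapse = "")
    v <- memo[[key]]
    if (is.null(v)) {
      v <- eval_pattern(bits)$peak
      memo[[key]] <- v
    }
    v
  }
  old <- local_seed(ga$seed)
  on.exit(restore_seed(old), add = TRUE)
  pmut <- if (is.null(ga$mutation)) 1 / nbits else ga$mutation
  pop <- matrix(stats::runif(ga$pop * nbits) < 0.5, ga$pop, nbits)
  pop[1, ] <- FALSE                       # keep the linear-phase pattern in
  fit <- apply(pop, 1, fitness)
  best_hist <- numeric(0)
  stale <- 0L
  for (gen in seq_len(ga$generations)) {
    o <- order(fit)
    elite <- pop[o[1:2], , drop = FALSE]
    newpop <- matrix(FALSE, ga$pop, nbits)
    newpop[1:2, ] <- elite
    for (i in 3:ga$pop) {
      # tournament selection of two parents
      p1 <- o[min(sample.int(ga$pop, 2))]
      p2 <- o[min(sample.int(ga$pop, 2))]
      cross <- stats::runif(nbits) < 0.5
      child <- ifelse(cross, pop[p1, ], pop[p2, ])
      flip <- stats::runif(nbits) < pmut
      child[flip] <- !child[flip]
      newpop[i, ] <- child
    }
    pop <- newpop
    fit <- apply(pop, 1, fitness)
    if (length(best_hist) && min(fit) >= min(best_hist) - 1e-12)
      stale <- stale + 1L else stale <- 0L
    best_hist <- c(best_hist, min(fit))
    if (stale >= ga$early_stop) break
  }
  best_bits <- pop[which.min(fit), ]
  sol <- eval_pattern(best_bits)
  dt <- duration / n
  rf <- rf_waveform(sol$rfang / (.GAMMA * dt), dt)
  rf_fine <- resample_waveform(rf, n_samples)
  bw_khz <- tbp / duration
  G <- bw_khz / (gamma_bar() * 1e-3 * thickness)
  structure(list(rf = rf_fine, rf_design = rf, G = G,
                 grad = gradient_waveform(rep(G, n_samples), rf_fine$dt),
                 filter = filt, beta = sol$beta, pattern = best_bits,
                 peak_history = best_hist, tbp = tbp, thickness = thickness,
                 duration = duration, spec = spec),
            class = "mb_pulse")
}

#' @export
print.mb_pulse <- function(x, ...) {
  cat(sprintf("<mb_pulse> root-flipped, N %d, tbp %.3g, peak %.4g uT, %d flip bits\n",
              x$spec$n_slices, x$tbp, rf_peak(x$rf), length(x$pattern)))
  invisible(x)
}
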
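lim0 <- hardware_limits(13, 40, 200)

test_that("already-optimal input is returned unchanged in duration", {
  # peak exactly at b1max on g exactly at g_max: no speed-up possible
  n <- 512
  rf <- rf_waveform(13 * exp(-((seq_len(n) - n / 2) / (n / 6))^2) * 0 + 13, 0.002)
  v <- time_optimal_verse(rf, 40, lim0)
  expect_equal(v$duration, wf_duration(rf), tolerance = 1e-3)
  expect_lt(max(Mod(v$rf$samples)), 13 * (1 + 1e-6))
})

test_that("half-amplitude input on half gradient speeds up twofold", {
  n <- 512
  rf <- rf_waveform(rep(6.5, n), 0.002)
  v <- time_optimal_verse(rf, 20, hardware_limits(13, 40, 1e5))
  expect_equal(v$duration, wf_duration(rf) / 2, tolerance = 0.01)
  expect_equal(max(v$grad$samples), 40, tolerance = 0.01)
})

test_that("duration matches the dynamic-programming traversal oracle", {
  set.seed(123)
  gam <- mbverse:::.GAMMA
  for (trial in 1:5) {
    n <- 40
    # random smooth cap profile (as would come from b1max/|w|); both solvers
    # see the same 10x-refined arc discretization of it
    cap <- pmin(40, 5 + 35 * abs(sin(seq(0, pi * runif(1, 1, 3),
                                         length.out = n)) +
                                   0.3 * runif(n)))
    ds <- 0.05
    refine <- 10
    capr <- approx(seq_len(n), cap,
                   xout = seq(1, n, length.out = (n - 1) * refine + 1))$y
    sol <- mbverse:::verse_fb_cpp(capr, ds / refine, 200, gam)
    t_fb <- sol$t[length(capr)]
    t_dp <- verse_dp_oracle(cap, ds, 200, gam, refine = refine)
    expect_lt(abs(t_fb - t_dp) / t_dp, 0.02)
  }
})

test_that("VERSE outputs satisfy every hardware constraint", {
  sb <- sb_tbp4()
  v <- time_optimal_verse(sb$rf, sb$G, lim0)
  expect_lt(max(Mod(v$rf$samples)), lim0$b1_max * (1 + 1e-6))
  expect_lt(max(abs(v$grad$samples)), lim0$g_max * (1 + 1e-6))
  expect_lt(max(abs(slew_rate(v$grad))), lim0$slew_max * (1 + 1e-3))
})

test_that("gradient area is conserved through VERSE", {
  sb <- sb_tbp4()
  v <- time_optimal_verse(sb$rf, sb$G, lim0)
  a0 <- sum(sb$grad$samples) * sb$grad$dt
  a1 <- sum(v$grad$samples) * v$grad$dt
  expect_lt(abs(a1 - a0) / a0, 1e-6)
})

test_that("no uniform speed-up of the output remains feasible", {
  sb <- sb_tbp4()
  v <- time_optimal_verse(sb$rf, sb$G, lim0)
  lam <- 1 / (1 + 1e-3)
  sped <- mbverse:::dilate_pulse(v$rf, v$grad, lam)
  viol <- max(Mod(sped$rf$samples)) > lim0$b1_max * (1 + 1e-6) ||
    max(abs(sped$grad$samples)) > lim0$g_max * (1 + 1e-6) ||
    max(abs(slew_rate(sped$grad))) > lim0$slew_max * (1 + 1e-3)
  expect_true(viol)
})

test_that("on-resonance profile is preserved through VERSE", {
  sb <- sb_tbp4()
  v <- time_optimal_verse(sb$rf, sb$G, lim0)
  z <- seq(-9, 9, by = 0.05)
  p0 <- evaluate_profile(sb$rf, sb$grad, z, fov = 6)
  p1 <- evaluate_profile(v$rf, v$grad, z, fov = 6)
  expect_lt(nrmse_regions(p1, p0)[["eps_inside"]], 0.01)
  expect_lt(nrmse_regions(p1, p0)[["eps_outside"]], 0.01)
})

test_that("unsupported trajectories are rejected", {
  n <- 64
  rf <- rf_waveform(rep(1, n), 0.01)
  g_sign <- gradient_waveform(c(rep(10, n / 2), rep(-10, n / 2)), 0.01)
  expect_error(time_optimal_verse(rf, g_sign, lim0), "sign")
  g_zero <- gradient_waveform(c(rep(10, n / 2), rep(0, n / 2)), 0.01)
  expect_error(time_optimal_verse(rf, g_zero, lim0), "zero-gradient")
})

test_that("stretching scales amplitudes and preserves the profile", {
  sb <- sb_tbp4()
  T0 <- wf_duration(sb$rf)
  s <- stretch_to_duration(sb$rf, sb$grad, 2 * T0)
  expect_equal(s$duration, 2 * T0)
  expect_equal(rf_energy(s$rf), rf_energy(sb$rf) / 2, tolerance = 1e-9)
  expect_identical(stretch_to_duration(sb$rf, sb$grad, T0)$rf$samples,
                   sb$rf$samples)
  expect_error(stretch_to_duration(sb$rf, sb$grad, T0 / 2), "shorter")
  z <- seq(-6, 6, by = 0.05)
  p0 <- flip_profile(spin_domain_sim(sb$rf, sb$grad, z))
  p1 <- flip_profile(spin_domain_sim(s$rf, s$grad, z))
  expect_lt(sqrt(mean((p1 - p0)^2)) / sqrt(mean(p0^2)), 1e-5)
})

test_that("MBv and vMB coincide for a single slice", {
  sb <- sb_tbp4()
  s1 <- modulation_spec(1, 0, 0)
  v1 <- make_mbv(sb$rf, sb$G, lim0)
  v2 <- make_vmb(sb$rf, sb$G, lim0, s1)
  expect_equal(v1$duration, v2$duration, tolerance = 1e-12)
})

test_that("vMB output peak sits at the B1 ceiling when B1-limited", {
  sb <- sb_tbp4()
  spec <- modulation_spec(3, slice_positions(3, 28),
                          optimize_phase_offsets(3))
  v <- make_vmb(sb$rf, sb$G, lim0, spec)
  pk <- max(Mod(v$rf$samples))
  expect_lte(pk, lim0$b1_max * (1 + 1e-3))
  expect_gte(pk, 0.9 * lim0$b1_max)
  # expected ordering: vMB is somewhat longer than MBv
  mbv <- make_mbv(modulate_constant(sb$rf, spec, sb$G), sb$G, lim0)
  expect_gte(v$duration, mbv$duration)
})
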
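test_that("spin-domain trivial cases", {
  # zero RF: no excitation, unit |alpha|
  ck <- spin_domain_sim(rf_waveform(rep(0, 64), 0.01), 20, c(-5, 0, 5))
  expect_equal(max(Mod(ck$beta)), 0)
  expect_equal(Mod(ck$alpha), rep(1, 3), tolerance = 1e-12)
  expect_equal(flip_profile(ck), rep(0, 3))
  # on-resonance 90-degree hard pulse with no gradient
  gam <- mbverse:::.GAMMA
  ck90 <- spin_domain_sim(rf_waveform(rep((pi / 2) / (gam * 0.64), 1), 0.64),
                          0, 0)
  expect_equal(flip_profile(ck90) * 180 / pi, 90, tolerance = 1e-6)
  # |beta| = 1 -> theta = pi
  expect_equal(flip_profile(list(beta = 1 + 0i)), pi)
})

test_that("spin-domain engine matches a rotation-matrix integrator", {
  sb <- sb_tbp4()
  rf_small <- resample_waveform(sb$rf, 128)   # keep the oracle affordable
  set.seed(9)
  z <- sort(runif(50, -6, 6))
  ck <- spin_domain_sim(rf_small, sb$G, z, df = 37)
  M <- bloch_matrix_sim(rf_small, sb$G, z, df = 37)
  mz_sd <- 1 - 2 * Mod(ck$beta)^2
  mxy_sd <- 2 * Conj(ck$alpha) * ck$beta
  expect_lt(max(abs(mz_sd - M[3, ])), 1e-8)
  expect_lt(max(Mod(mxy_sd - complex(real = M[1, ], imaginary = M[2, ]))),
            1e-8)
  # unitarity
  expect_lt(max(abs(Mod(ck$alpha)^2 + Mod(ck$beta)^2 - 1)), 1e-9)
})

test_that("refocusing profile identities and symmetry", {
  sb <- sb_tbp4()
  z <- seq(-5, 5, by = 0.05)
  ck <- spin_domain_sim(sb$rf, sb$grad, z)
  b2 <- refocus_profile(ck)
  expect_equal(Mod(b2), Mod(ck$beta)^2, tolerance = 1e-12)
  th <- flip_profile(ck)
  expect_lt(max(abs(th - rev(th))), 1e-6)
  expect_true(all(th >= 0 & th <= pi))
})

test_that("NRMSE regions: ghost fixture and scaling linearity", {
  fov <- 40
  z <- seq(-60, 60, by = 0.25)
  # target: one boxcar slice inside the FOV
  tflip <- ifelse(abs(z) < 2, pi, 0)
  tgt <- slice_profile(z, tflip, NULL, fov)
  expect_equal(nrmse_regions(tgt, tgt), c(eps_inside = 0, eps_outside = 0))
  # profile with a ghost copy of the slice outside the FOV
  ghost <- 0.2 * pi * (abs(z - 40) < 2)
  prof <- slice_profile(z, tflip + ghost, NULL, fov)
  eps1 <- nrmse_regions(prof, tgt)
  expect_equal(eps1[["eps_inside"]], 0)
  # direct summation oracle
  inside <- abs(z) <= fov / 2
  outside <- abs(z) > fov / 2 & abs(z) <= 1.5 * fov
  oracle <- sqrt(mean(ghost[outside]^2)) / sqrt(mean(tflip[inside]^2))
  expect_equal(eps1[["eps_outside"]], oracle, tolerance = 1e-12)
  # doubling the ghost amplitude doubles eps_outside
  prof2 <- slice_profile(z, tflip + 2 * ghost, NULL, fov)
  expect_equal(nrmse_regions(prof2, tgt)[["eps_outside"]],
               2 * eps1[["eps_outside"]], tolerance = 1e-9)
  # zero target errors out
  ztgt <- slice_profile(z, 0 * z, NULL, fov)
  expect_error(nrmse_regions(prof, ztgt), "zero")
})

test_that("simulation grid convergence: halving dz barely moves eps", {
  d <- tcached("mbv3", design_pulse("MBv", 3, 4, 2, separation = 28))
  e24 <- design_fidelity_eps(d, pts_per_slice = 24)
  e48 <- design_fidelity_eps(d, pts_per_slice = 48)
  expect_lt(abs(e48[["eps_inside"]] - e24[["eps_inside"]]) /
              e24[["eps_inside"]], 0.02 + 1e-6)
  expect_lt(abs(e48[["eps_outside"]] - e24[["eps_outside"]]) /
              max(e24[["eps_outside"]], 1e-6), 0.02 + 1e-6)
})

test_that("phase deviation: identity and pure-delay cases vanish", {
  sb <- sb_tbp4()
  z <- seq(-4, 4, by = 0.05)
  expect_lt(phase_deviation(sb$rf, sb$grad, identity_girf(), z), 1e-6)
  # a pure delay on a constant gradient is a common linear phase roll,
  # removed by construction
  gd <- make_synthetic_girf(fwhm = Inf, delay = 5, df = 0.2)
  expect_lt(phase_deviation(sb$rf, sb$grad, gd, z), 0.25)
})

test_that("synthetic quadratic phase perturbation is quantified correctly", {
  # hand-built fixture: phases measured directly, no simulation
  z <- seq(-1, 1, by = 0.01)
  amp <- 3 * pi / 180
  dphi <- amp * (2 * z^2 - 1)     # quadratic, zero-mean-ish over the slice
  fit <- stats::lm.fit(cbind(1, z), dphi)
  got <- mean(abs(fit$residuals)) * 180 / pi
  # direct computation oracle: mean |quadratic residual| after removing the
  # best linear fit; for a*T2(z) on [-1,1] the residual is the centred
  # parabola itself
  resid <- dphi - (fit$coefficients[1] + fit$coefficients[2] * z)
  expect_equal(got, mean(abs(resid)) * 180 / pi, tolerance = 1e-12)
  expect_gt(got, 0.5 * 3 * 2 / pi)   # same order as the 3-degree amplitude
  expect_lt(got, 3)
})

test_that("off-resonance shift follows the chemical-shift closed form", {
  sb <- sb_tbp4()
  res <- offres_analysis(sb$rf, sb$grad, slice_center = 0, window = 10,
                         df_grid = c(0, 100, 200), dz = 0.02)
  expect_equal(res$shift_mm[1], 0, tolerance = 1e-9)
  expect_equal(res$distortion_nrmse[1], 0, tolerance = 1e-9)
  # shift = df / (gamma_bar * G) mm
  pred <- 100 * 1e-3 / (gamma_bar() * 1e-3 * sb$G)
  expect_equal(abs(res$shift_mm[2]), pred, tolerance = 0.05)
  expect_equal(abs(res$shift_mm[3]), 2 * pred, tolerance = 0.05)
})

test_that("longer pulses shift more off-resonance", {
  sb <- sb_tbp4()
  stretched <- stretch_to_duration(sb$rf, sb$grad, 2)
  r1 <- offres_analysis(sb$rf, sb$grad, 0, 10, c(0, 200), dz = 0.02)
  r2 <- offres_analysis(stretched$rf, stretched$grad, 0, 10, c(0, 200),
                        dz = 0.02)
  expect_gte(abs(r2$shift_mm[2]), abs(r1$shift_mm[2]))
})
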
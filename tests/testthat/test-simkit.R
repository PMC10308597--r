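test_that("baseline spectrum matches closed-form limits and direct evaluation", {
  # purely resistive limit
  ap0 <- aperture_model(R_f = 1e4, C_p = 0, L_s = 0)
  z <- baseline_spectrum(ap0, DEFAULT_FREQS)
  expect_equal(Mod(z), rep(1e4, 6))
  expect_equal(Arg(z), rep(0, 6))

  # RC corner identity: |Z| = R/sqrt(2), phase -45 degrees
  ap <- aperture_model(R_f = 1e4, C_p = 1e-11, L_s = 0)
  fc <- 1 / (2 * pi * ap$R_f * ap$C_p)
  zc <- baseline_spectrum(ap, fc)
  expect_equal(Mod(zc), 1e4 / sqrt(2), tolerance = 1e-12)
  expect_equal(Arg(zc) * 180 / pi, -45, tolerance = 1e-10)

  # direct complex-arithmetic evaluation per frequency
  apl <- aperture_model(R_f = 1e4, C_p = 1e-11, L_s = 1e-6)
  w <- 2 * pi * DEFAULT_FREQS
  expected <- 1i * w * 1e-6 + 1e4 / (1 + 1i * w * 1e4 * 1e-11)
  expect_equal(baseline_spectrum(apl, DEFAULT_FREQS), expected,
               tolerance = 1e-14)
  expect_error(baseline_spectrum(apl, c(1e3, -1)), "positive")
})

test_that("baseline phase is resistive at DC, capacitive at the corner, inductive far above", {
  ap <- aperture_model()
  expect_lt(abs(Arg(baseline_spectrum(ap, 1))), 1e-4)
  fc <- 1 / (2 * pi * ap$R_f * ap$C_p)
  expect_lt(Arg(baseline_spectrum(ap, fc)), 0)
  # far above the LC resonance the series inductance dominates
  expect_gt(Arg(baseline_spectrum(ap, 5e8)), 0)
})

test_that("Coulter amplitude follows the DeBlois-Bean form", {
  ap <- aperture_model()
  expect_equal(coulter_delta_r(0, ap), 0)
  # frozen value for the 8.2 um working bead in 0.625 ohm m fluid
  expect_equal(coulter_delta_r(8.2e-6, ap), 337.98, tolerance = 1e-4)
  # ordering over the measured bead sizes
  dr <- coulter_delta_r(c(3.9e-6, 5.6e-6, 8.2e-6), ap)
  expect_true(all(diff(dr) > 0))
  expect_error(coulter_delta_r(40e-6, ap), "smaller")
})

test_that("small-bead amplitude scales as d^3 and tracks the slab integral", {
  ap <- aperture_model()
  Deff <- 2 * ap$side_length / sqrt(pi)
  rho <- 1 / ap$fluid_conductivity
  for (d in c(Deff / 40, Deff / 20, Deff / 10)) {
    expect_equal(coulter_delta_r(2 * d, ap) / coulter_delta_r(d, ap), 8,
                 tolerance = 0.05)
    # independent slab-resistance discretization shares the d^3 scaling
    expect_equal(slab_delta_r(2 * d, Deff, rho) / slab_delta_r(d, Deff, rho),
                 8, tolerance = 0.05)
  }
})

test_that("bead element reduces to the resistive pulse without a shell", {
  ap <- aperture_model()
  b <- bead_model(8.2e-6, m_density = 0, aperture = ap)
  dB <- bead_element(b, ap, DEFAULT_FREQS)
  expect_equal(dB, rep(complex(real = b$delta_R), 6))
  # near-DC limit equals delta_R for any bead kind
  bm <- bead_model(8.2e-6, m_density = 0.8, aperture = ap)
  expect_lt(Mod(bead_element(bm, ap, 1e-5) - bm$delta_R), 1e-6)
})

test_that("metal shell flips the pulse sign only in the mid band", {
  ap <- aperture_model()
  b <- bead_model(8.2e-6, m_density = 1, aperture = ap)
  dB <- bead_element(b, ap, DEFAULT_FREQS)
  expect_gt(Re(dB[1]), 0)   # 45 kHz: interface capacitance still blocks
  expect_lt(Re(dB[4]), 0)   # 2 MHz: shell shunts the displaced slab
  # conformal conductive layer (C_sh -> Inf): negative at every frequency
  bc <- b
  bc$C_sh <- Inf
  dBc <- bead_element(bc, ap, DEFAULT_FREQS)
  expect_true(all(Re(dBc) < 0))
  # shell-removal limit: huge R_sh converges to the nonmetallized element
  br <- b
  br$R_sh <- 1e12
  br$C_sh <- 1e-20
  dBr <- bead_element(br, ap, DEFAULT_FREQS)
  expect_equal(Re(dBr), rep(b$delta_R, 6), tolerance = 1e-6)
})

test_that("total impedance interpolates between baseline and full insertion", {
  ap <- aperture_model(R_f = 1e4, C_p = 1e-11, L_s = 1e-6)
  b <- bead_model(8.2e-6, m_density = 0.5, aperture = ap)
  dB <- bead_element(b, ap, DEFAULT_FREQS)
  expect_equal(total_impedance(ap, dB, 0, DEFAULT_FREQS, C_b = b$C_b),
               baseline_spectrum(ap, DEFAULT_FREQS), tolerance = 1e-14)
  # s = 1, C_p = 0, L_s = 0, no bead capacitance: plain series sum
  ap0 <- aperture_model(R_f = 1e4, C_p = 0, L_s = 0)
  dB0 <- bead_element(b, ap0, DEFAULT_FREQS)
  expect_equal(total_impedance(ap0, dB0, 1, DEFAULT_FREQS),
               ap0$R_f + dB0, tolerance = 1e-12)
  # intermediate s: direct independent evaluation of the composition
  s <- 0.5
  w <- 2 * pi * DEFAULT_FREQS
  inner <- ap$R_f + s * dB
  C <- ap$C_p + s * b$C_b
  shunt <- 1 / (1i * w * C)
  expected <- 1i * w * ap$L_s + inner * shunt / (inner + shunt)
  expect_equal(total_impedance(ap, dB, s, DEFAULT_FREQS, C_b = b$C_b),
               expected, tolerance = 1e-12)
  expect_error(total_impedance(ap, dB, 1.5, DEFAULT_FREQS), "0, 1")
})

test_that("metallization-to-shell link is monotone with correct endpoints", {
  ap <- aperture_model()
  expect_equal(metallization_to_shell(0, ap), list(R_sh = Inf, C_sh = 0))
  full <- metallization_to_shell(1, ap, R0 = 625, C0 = 6e-11)
  expect_equal(full$R_sh, 625)
  expect_equal(full$C_sh, 6e-11)
  m <- seq(0.05, 1, by = 0.05)
  Rs <- vapply(m, function(mi) metallization_to_shell(mi, ap)$R_sh, 1)
  Cs <- vapply(m, function(mi) metallization_to_shell(mi, ap)$C_sh, 1)
  expect_true(all(diff(Rs) < 0))
  expect_true(all(diff(Cs) > 0))
  expect_error(metallization_to_shell(1.2, ap), "<= 1")
})

test_that("binding curve maps dose to metallization with 4PL symmetry", {
  p <- list(floor = 0.01, ceiling = 0.85, c50 = 30, hill = 1.2)
  expect_equal(dose_to_metallization(0, p), 0.01)
  expect_equal(dose_to_metallization(1e9, p), 0.85, tolerance = 1e-3)
  expect_equal(dose_to_metallization(30, p), (0.01 + 0.85) / 2)
  expect_error(dose_to_metallization(-1, p), "non-negative")
})

test_that("a single noise-free transit reproduces the circuit peak response", {
  ap <- aperture_model()
  spec <- nonmetallized_spec(seed = 5, n_beads = 1, amp_scale_sd = 0)
  sim <- synthesize_trial(spec, ap, quiet_acq(duration = 0.2, seed = 5))
  ref <- sim$ts$mag[, 1] - Mod(baseline_spectrum(ap, DEFAULT_FREQS))[1]
  # exactly one strict local maximum above half the pulse height
  apexes <- brute_peaks(ref, threshold = 100, min_sep = 1)
  expect_length(apexes, 1)
  b <- bead_model(spec$bead_diameter, 0, ap)
  expected <- bead_peak_response(b, ap, DEFAULT_FREQS)$dZp[1]
  # the apex sample sits within half a sample of the continuous-time peak,
  # bounding the sampling loss at exp(-(0.5/(sigma*fs))^2/2) ~ 0.6%
  expect_equal(max(ref), expected, tolerance = 0.01)
})

test_that("synthesis is a pure, reproducible function of its seeds", {
  spec <- trial_spec(n_beads = 10, probe_concentration = 50, seed = 9)
  acq <- acquisition_config(duration = 0.5, seed = 9)
  s1 <- synthesize_trial(spec, aperture_model(), acq)
  s2 <- synthesize_trial(spec, aperture_model(), acq)
  expect_identical(s1$ts$mag, s2$ts$mag)
  expect_identical(s1$ts$phase, s2$ts$phase)
  expect_identical(s1$truth, s2$truth)
  # caller RNG state is untouched
  set.seed(123)
  before <- .Random.seed
  invisible(synthesize_trial(spec, aperture_model(), acq))
  expect_identical(.Random.seed, before)
  # different seed changes the draw
  spec2 <- trial_spec(n_beads = 10, probe_concentration = 50, seed = 10)
  s3 <- synthesize_trial(spec2, aperture_model(), acq)
  expect_false(identical(s1$truth$t0, s3$truth$t0))
})

test_that("event placement fails loudly when the trial is too short", {
  spec <- trial_spec(n_beads = 500, seed = 1, min_spacing = 0.01)
  expect_error(synthesize_trial(spec, aperture_model(),
                                acquisition_config(duration = 0.3)),
               "duration")
})

test_that("nonmetallized pulses are positive at all six carriers and grow with size", {
  ap <- aperture_model()
  resp <- bead_peak_response(bead_model(8.2e-6, 0, ap), ap, DEFAULT_FREQS)
  expect_true(all(resp$dZp > 0))
  # 45 kHz amplitude strictly increasing over the measured 3.9-20.1 um range
  sizes <- c(3.9, 5.6, 8.2, 10, 15, 20.1) * 1e-6
  dz45 <- vapply(sizes, function(d)
    bead_peak_response(bead_model(d, 0, ap), ap, 45e3)$dZp, 1)
  expect_true(all(diff(dz45) > 0))
})
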
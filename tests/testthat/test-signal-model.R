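test_that("spgr_factor matches the closed form and its limits", {
  ## frozen closed-form evaluation: E1 = exp(-14.7/339), a = 8 deg
  e1 <- exp(-14.7 / 339)
  expected <- sin(8 * pi / 180) * (1 - e1) / (1 - e1 * cos(8 * pi / 180))
  expect_equal(spgr_factor(339, 14.7, 8), expected, tolerance = 1e-12)
  expect_equal(expected, 0.1141138, tolerance = 1e-6)
  ## T1 -> 0 gives sin(alpha); saturation gives 1
  expect_equal(spgr_factor(1e-6, 14.7, 8), sin(8 * pi / 180), tolerance = 1e-9)
  expect_equal(spgr_factor(339, 1e6, 90), 1.0, tolerance = 1e-9)
  expect_error(spgr_factor(-1, 14.7, 8), "positive")
  expect_error(spgr_factor(339, 14.7, 200), "180")
})

test_that("dixon_signal reduces to known special cases", {
  pr <- liver_protocol
  t_s <- pr$te / 1000
  ## water only: mono-exponential magnitude
  s <- dixon_signal(tissue_params(f = 0, r2s = 50, phi = 0), pr)
  ew <- spgr_factor(339, pr$tr, pr$fa)
  expect_equal(Mod(s), ew * exp(-50 * t_s), tolerance = 1e-12)
  ## pure single-peak fat: phase evolves at 2*pi*(f1 - phi)*t
  sp1 <- fat_spectrum(shift_ppm = -3.4, amplitude = 1)
  s2 <- dixon_signal(tissue_params(f = 1, r2s = 0, phi = 12), pr,
                     spectrum = sp1)
  f1 <- fat_frequencies(sp1, pr$b0)
  expect_equal(Arg(s2), ((2 * pi * (f1 - 12) * t_s + pi) %% (2 * pi)) - pi,
               tolerance = 1e-9)
  ## empty protocol errors
  expect_error(acq_protocol(te = numeric(0), tr = 10, fa = 8), "echo")
})

test_that("fat magnitude fraction at an in-phase time equals F when T1s match", {
  pr <- liver_protocol
  f0 <- 0.37
  sp1 <- fat_spectrum(shift_ppm = -3.30, amplitude = 1)
  te_in <- inphase_opposed_te(pr$b0)$te_in_ms
  pr_ip <- acq_protocol(te = c(te_in, 2 * te_in), tr = 3 * te_in, fa = 8,
                        b0 = pr$b0)
  p <- tissue_params(f = f0, r2s = 0, phi = 0, t1_water = 300, t1_fat = 300)
  s <- dixon_signal(p, pr_ip, spectrum = sp1)
  ## oracle: direct summation of the model terms at the in-phase time
  e <- spgr_factor(300, pr_ip$tr, 8)
  fm <- sum(sp1$amplitude *
              exp(2i * pi * fat_frequencies(sp1, pr$b0) * te_in / 1000))
  direct <- e * ((1 - f0) + f0 * fm)
  expect_equal(s[1], direct, tolerance = 1e-12)
  ## at the in-phase time the fat phasor is aligned with water, so the
  ## magnitude fraction of the fat term is exactly F
  fat_part <- e * f0 * Mod(fm)
  expect_equal(fat_part / (fat_part + e * (1 - f0)), f0, tolerance = 1e-9)
  ## with the multi-peak spectrum the minor peaks remain dephased and the
  ## fraction falls short of F
  s7 <- dixon_signal(p, pr_ip)
  fm7 <- sum(seven_peak$amplitude *
               exp(2i * pi * fat_frequencies(seven_peak, pr$b0) *
                     te_in / 1000))
  expect_lt(Mod(fm7), 1)
})

test_that("in-phase / opposed-phase echo times match the 0.55 T values", {
  te <- inphase_opposed_te(0.55, 3.30)
  expect_equal(round(te$te_in_ms, 2), 12.94)
  expect_equal(round(te$te_op_ms, 2), 6.47)
  ## doubling the shift halves both
  te2 <- inphase_opposed_te(0.55, 6.60)
  expect_equal(te2$te_in_ms, te$te_in_ms / 2, tolerance = 1e-12)
  ## frozen hand evaluation at 1.5 T: 1/(3.3e-6 * 42.577e6 * 1.5) s
  expect_equal(inphase_opposed_te(1.5, 3.30)$te_in_ms, 4.744820,
               tolerance = 1e-6)
  expect_error(inphase_opposed_te(0.55, 0), "non-zero")
})

test_that("signal model invariants: rho linearity, conjugate symmetry, seeds", {
  pr <- liver_protocol
  base <- tissue_params(f = 0.3, r2s = 60, phi = -40, rho = 1)
  s1 <- dixon_signal(base, pr)
  s3 <- dixon_signal(tissue_params(f = 0.3, r2s = 60, phi = -40, rho = 3.7),
                     pr)
  expect_equal(s3, 3.7 * s1, tolerance = 1e-12)
  ## negating phi and all fat shifts conjugates the signal
  neg_spec <- fat_spectrum(-seven_peak$shift_ppm, seven_peak$amplitude)
  s_neg <- dixon_signal(tissue_params(f = 0.3, r2s = 60, phi = 40), pr,
                        spectrum = neg_spec)
  expect_equal(s_neg, Conj(s1), tolerance = 1e-12)
  ## seeded noise is bit-reproducible and has the right variance
  nm <- noise_model(sigma = 0.5, seed = 42)
  expect_identical(dixon_signal(base, pr, noise = nm),
                   dixon_signal(base, pr, noise = nm))
  big <- dixon_signal(tissue_params(f = 0, r2s = 0, phi = 0, rho = 0),
                      acq_protocol(te = seq_len(50000) * 0.01,
                                   tr = 600, fa = 8),
                      noise = noise_model(0.5, seed = 8))
  expect_lt(abs(var(Re(big)) / 0.25 - 1), 0.03)
  expect_lt(abs(var(Im(big)) / 0.25 - 1), 0.03)
})

test_that("spectrum and protocol files round-trip", {
  sp_file <- file.path(tempdir(), "spectrum.csv")
  write_spectrum(seven_peak, sp_file)
  sp2 <- read_spectrum(sp_file)
  expect_equal(sp2$shift_ppm, seven_peak$shift_ppm)
  expect_equal(sp2$amplitude, seven_peak$amplitude, tolerance = 1e-12)
  pr_file <- file.path(tempdir(), "protocol.cfg")
  write_protocol(liver_protocol, pr_file)
  pr2 <- read_protocol(pr_file)
  expect_equal(pr2$te, liver_protocol$te)
  expect_equal(pr2$tr, liver_protocol$tr)
  expect_equal(pr2$fa, liver_protocol$fa)
  ## spectrum invariants enforced
  expect_error(fat_spectrum(c(1, 2), c(0.5, -0.1)), "non-negative")
  expect_error(fat_spectrum(c(1, Inf), c(0.5, 0.5)), "finite")
})
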
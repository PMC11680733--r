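test_that("noiseless voxel fit recovers the generating parameters", {
  pr <- liver_protocol
  p <- tissue_params(f = 0.20, r2s = 40, phi = 30)
  s <- dixon_signal(p, pr)
  ## with T1 correction the fraction itself is recovered
  ft <- fit_voxel(s, pr, t1_correction = c(339, 187))
  expect_lt(abs(ft$f - 0.20), 1e-3)
  expect_lt(abs(ft$r2s - 40), 0.1)
  expect_lt(abs(ft$phi - 30), 0.1)
  expect_lt(ft$residual, 1e-8)
  ## without correction the apparent fraction carries the closed-form
  ## SPGR T1-weighting bias
  ew <- spgr_factor(339, pr$tr, pr$fa)
  ef <- spgr_factor(187, pr$tr, pr$fa)
  f_app <- 0.2 * ef / (0.8 * ew + 0.2 * ef)
  ft2 <- fit_voxel(s, pr)
  expect_lt(abs(ft2$f - f_app), 1e-6)
  ## water-only: PDFF 0, R2* exact
  s0 <- dixon_signal(tissue_params(f = 0, r2s = 55, phi = -20), pr)
  ft0 <- fit_voxel(s0, pr)
  expect_equal(ft0$pdff, 0, tolerance = 1e-6)
  expect_lt(abs(ft0$r2s - 55), 1e-3)
  ## all-zero signal is flagged unreliable
  ftz <- fit_voxel(rep(0 + 0i, 6), pr)
  expect_false(ftz$reliable)
  expect_true(is.na(ftz$pdff))
  expect_error(fit_voxel(c(1 + 0i, 1), pr), "echoes")
})

test_that("water-fat exchange symmetry resolves to the lower-residual basin", {
  pr <- liver_protocol
  ## fat-dominant voxel must not be mirrored to 100 - PDFF
  s <- dixon_signal(tissue_params(f = 0.9, r2s = 30, phi = 0,
                                  t1_water = 300, t1_fat = 300), pr)
  ft <- fit_voxel(s, pr)
  expect_gt(ft$pdff, 80)
  ## and a water-dominant voxel stays water-dominant
  s2 <- dixon_signal(tissue_params(f = 0.1, r2s = 30, phi = 0,
                                   t1_water = 300, t1_fat = 300), pr)
  expect_lt(fit_voxel(s2, pr)$pdff, 20)
})

test_that("estimates are Fisher-consistent as noise vanishes", {
  pr <- liver_protocol
  p <- tissue_params(f = 0.3, r2s = 60, phi = 25,
                     t1_water = 300, t1_fat = 300)
  s0 <- dixon_signal(p, pr)
  sig <- 0.02 * Mod(s0[1])
  errs <- sapply(1:4, function(k) {
    sgk <- sig / 2^(k - 1)
    ek <- with_seed_test(100 + k, {
      reps <- replicate(40, {
        ft <- fit_voxel(s0 + complex(real = rnorm(6, 0, sgk),
                                     imaginary = rnorm(6, 0, sgk)), pr)
        abs(ft$f - 0.3) + abs(ft$r2s - 60) / 100 + abs(ft$phi - 25) / 100
      })
      mean(reps)
    })
    ek
  })
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[4], errs[1] / 4)
})

test_that("pdff stays in [0,100] and r2s in the box on random inputs", {
  pr <- liver_protocol
  set.seed(41)
  s_mat <- rcnorm_mat(6, 200, 0.1)
  ft <- pdffmap:::fit_signal_matrix(s_mat, pr, seven_peak)
  expect_true(all(ft$pdff >= 0 & ft$pdff <= 100, na.rm = TRUE))
  expect_true(all(ft$r2s >= 0 & ft$r2s <= 1000))
})

test_that("fit_maps matches voxelwise fits and fixes planted swaps", {
  pr <- liver_protocol
  ph <- small_phantom()
  clean <- simulate_acquisition(ph, pr, n_coils = 1, sigma = 0,
                                sensitivities = array(1 + 0i, c(ph$dims, 1)))
  img <- coil_combine(clean, method = "known",
                      sensitivities = array(1 + 0i, c(ph$dims, 1)))
  ## noiseless phantom: vial ROI means equal the apparent truth closely
  maps <- fit_maps(img, pr, mask = ph$object)
  rois <- phantom_rois(ph)
  st <- roi_stats(maps, rois)
  ew <- spgr_factor(339, pr$tr, pr$fa); ef <- spgr_factor(187, pr$tr, pr$fa)
  for (i in seq_len(nrow(ph$vials))) {
    v <- ph$vials[i, ]
    if (v$r2s > 200) next  # decay too fast for this echo train
    f_app <- 100 * v$f * ef / ((1 - v$f) * ew + v$f * ef)
    got <- st$pdff_mean[st$label == v$label]
    expect_lt(abs(got - f_app), 0.1)
    expect_lt(abs(st$r2s_mean[st$label == v$label] - v$r2s), 0.5)
  }
  ## composition: without the consistency passes the map equals the
  ## independent voxelwise fits
  maps_raw <- fit_maps(img, pr, mask = ph$object, refine_swaps = FALSE)
  vox <- which(ph$object)[c(3, 50, 200)]
  x <- unclass(img)
  for (v in vox) {
    co <- arrayInd(v, ph$dims)
    s <- x[co[1], co[2], co[3], ]
    ft <- fit_voxel(s, pr)
    expect_equal(maps_raw$pdff[v], ft$pdff, tolerance = 1e-6)
    expect_equal(maps_raw$r2s[v], ft$r2s, tolerance = 1e-3)
  }
  ## maps outside the mask are NA
  expect_true(all(is.na(maps$pdff[!ph$object])))
})

test_that("mono-exponential reference fit and its reliability flag", {
  te12 <- ref_protocol12$te
  ## exact recovery on noiseless data
  mags <- 100 * exp(-50 * te12 / 1000)
  ft <- fit_monoexp_r2s(mags, te12)
  expect_equal(ft$s0, 100, tolerance = 1e-9)
  expect_equal(ft$r2s, 50, tolerance = 1e-9)
  expect_true(ft$reliable)
  ## log-linear and refined estimates agree on noiseless data
  expect_lt(abs(ft$r2s - ft$r2s_loglin), 1e-6)
  expect_lt(abs(ft$s0 - ft$s0_loglin), 1e-6)
  ## T2* = 1 ms cannot be sampled by this echo train -> unreliable
  fast <- 100 * exp(-1000 * te12 / 1000)
  expect_false(fit_monoexp_r2s(fast, te12)$reliable)
  ## T2* < 4 ms under the twelve-echo protocol is flagged
  ft300 <- fit_monoexp_r2s(100 * exp(-300 * te12 / 1000), te12)
  expect_false(ft300$reliable)
  ## zero signal is unreliable
  expect_false(fit_monoexp_r2s(rep(0, 12), te12)$reliable)
  expect_error(fit_monoexp_r2s(c(1, 2), c(1, 2)), "3 echoes")
})
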
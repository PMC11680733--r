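test_that("lambda_m calibration is deterministic, linear in sigma_s, and converged", {
  c1 <- calibrate_lambda_m(125, 6, sigma_s = 1, n_samples = 200, seed = 5)
  c2 <- calibrate_lambda_m(125, 6, sigma_s = 1, n_samples = 200, seed = 5)
  expect_identical(c1$lambda_m, c2$lambda_m)
  c3 <- calibrate_lambda_m(125, 6, sigma_s = 2.5, n_samples = 200, seed = 5)
  expect_equal(c3$lambda_m, 2.5 * c1$lambda_m, tolerance = 1e-12)
  ## frozen large-sample oracle: median smallest singular value of 1e5
  ## complex Gaussian 125x6 samples (per-component SD 1) = 13.25482
  cal <- calibrate_lambda_m(125, 6, sigma_s = 1, n_samples = 500)
  expect_lt(abs(cal$lambda_m / 13.25482 - 1), 0.02)
  expect_error(calibrate_lambda_m(4, 6), "p >= q")
})

test_that("RLLR noise estimator: rank-deficient, homogeneous, and unbiased", {
  cal <- calibrate_lambda_m(60, 4, n_samples = 300, seed = 9)
  set.seed(10)
  ## exactly rank-deficient noiseless matrix -> sigma_hat = 0
  a <- rcnorm_mat(60, 2)
  mn <- a %*% rcnorm_mat(2, 4)
  expect_lt(estimate_noise_rllr(mn, cal)$sigma_hat, 1e-10)
  ## homogeneity in the data
  b <- rcnorm_mat(60, 4)
  expect_equal(estimate_noise_rllr(3 * b, cal)$sigma_hat,
               3 * estimate_noise_rllr(b, cal)$sigma_hat, tolerance = 1e-12)
  expect_error(estimate_noise_rllr(rcnorm_mat(10, 4), cal), "calibration")
  ## pure-noise patches of SD 2 recover sigma ~ 2 on average (validates the
  ## SD reading of the smallest-singular-value ratio)
  cal125 <- calibrate_lambda_m(125, 6, n_samples = 500)
  est <- replicate(400, estimate_noise_rllr(rcnorm_mat(125, 6, 2),
                                            cal125)$sigma_hat)
  expect_lt(abs(mean(est) / 2 - 1), 0.05)
})

test_that("SURE is an unbiased risk estimate and thresholding behaves", {
  set.seed(11)
  m <- 12; n <- 5; sigma <- 0.1
  u <- rcnorm_mat(m, 1); v <- rcnorm_mat(n, 1)
  x0 <- u %*% Conj(t(v))
  x0 <- x0 / sqrt(sum(Mod(x0)^2)) * 2
  lams <- c(0.05, 0.2, 0.5)
  nrep <- 800
  sure <- matrix(0, nrep, 3); risk <- matrix(0, nrep, 3)
  for (r in seq_len(nrep)) {
    x <- x0 + rcnorm_mat(m, n, sigma)
    sv <- svd(x)
    for (k in 1:3) {
      dnew <- pmax(sv$d - lams[k], 0)
      xh <- sv$u %*% (dnew * Conj(t(sv$v)))
      risk[r, k] <- sum(Mod(xh - x0)^2)
      sure[r, k] <- pdffmap:::sure_svt_risk(sv$d, m, n, sigma, lams[k],
                                            complex_data = TRUE)
    }
  }
  expect_lt(max(abs(colMeans(sure) / colMeans(risk) - 1)), 0.05)
  ## sigma = 0 is a fixed point
  x <- rcnorm_mat(6, 4)
  expect_equal(sure_svt(x, 0), x, ignore_attr = TRUE)
  ## strong rank-1 signal survives thresholding: the top direction is kept
  ## (alignment ~1) and soft thresholding costs only the ~lambda/s_top
  ## amplitude fraction (energy retention ~0.91 for this spike, measured
  ## against the clean oracle; assert with margin)
  sig <- 0.05
  spike <- 20 * sig * sqrt(12 + 5)
  u1 <- u / sqrt(sum(Mod(u)^2)); v1 <- v / sqrt(sum(Mod(v)^2))
  x0s <- spike * u1 %*% Conj(t(v1))
  stats <- replicate(50, {
    noisy <- x0s + rcnorm_mat(m, n, sig)
    den <- sure_svt(noisy, sig)
    sv <- svd(den)
    c(energy = sum(Mod(den)^2) / sum(Mod(x0s)^2),
      align = Mod(Conj(t(u1)) %*% sv$u[, 1]),
      better = sum(Mod(den - x0s)^2) < sum(Mod(noisy - x0s)^2))
  })
  expect_gt(mean(stats["energy", ]), 0.85)
  expect_gt(min(stats["align", ]), 0.98)
  expect_true(all(stats["better", ] == 1))
  ## pure noise is crushed
  crush <- replicate(50, {
    den <- sure_svt(rcnorm_mat(m, n, sig), sig)
    sqrt(sum(Mod(den)^2) / sum(Mod(rcnorm_mat(m, n, sig))^2))
  })
  expect_lt(mean(crush), 0.25)
})

test_that("rllr_denoise: low-rank fixed point, C++/R agreement, noise wins", {
  ## spatially constant object is rank 1: output equals input
  img <- tiny_me_image(c(7, 7, 5), sigma = 0)
  den <- rllr_denoise(img)
  expect_lt(max(Mod(unclass(den) - unclass(img))) / max(Mod(unclass(img))),
            1e-6)
  ## C++ patch loop agrees with the R reference pipeline
  set.seed(12)
  imgn <- tiny_me_image(c(7, 6, 5), sigma = 0.01, seed = 3)
  cal <- calibrate_lambda_m(125, 6)
  ps <- extract_patches(imgn, c(5, 5, 5), mode = "echo_only")
  mats <- lapply(seq_len(ps$n_patch), function(i) {
    mn <- patch_matrix(ps, i)
    sg <- estimate_noise_rllr(mn, cal)$sigma_hat
    unclass(sure_svt(mn, sg))
  })
  ref <- aggregate_patches(mats, ps)
  den2 <- rllr_denoise(imgn)
  expect_lt(max(Mod(ref - unclass(den2))), 1e-10)
  ## NRMSE against ground truth strictly improves at several noise levels
  clean <- tiny_me_image(c(10, 10, 5), sigma = 0)
  s1 <- Mod(unclass(clean)[1, 1, 1, 1])
  for (asnr in c(5, 10, 15)) {
    noisy <- tiny_me_image(c(10, 10, 5), sigma = s1 / asnr, seed = asnr)
    den3 <- rllr_denoise(noisy)
    err_in <- sqrt(sum(Mod(unclass(noisy) - unclass(clean))^2))
    err_out <- sqrt(sum(Mod(unclass(den3) - unclass(clean))^2))
    expect_lt(err_out, err_in)
  }
  ## global complex-scale equivariance when sigma_s is scaled accordingly
  cc <- complex(real = 1.3, imaginary = -0.7)
  d1 <- rllr_denoise(imgn, sigma_s = 1)
  x2 <- unclass(imgn) * cc
  d2 <- rllr_denoise(multi_echo_image(x2), sigma_s = Mod(cc))
  expect_lt(max(Mod(unclass(d2) - cc * unclass(d1))) / max(Mod(x2)), 1e-6)
  ## nuclear norm never increases per patch
  mn <- patch_matrix(ps, 1)
  den_m <- sure_svt(mn, 0.02)
  expect_lte(sum(svd(den_m)$d), sum(svd(mn)$d) + 1e-10)
  expect_error(rllr_denoise(tiny_me_image(c(6, 6, 5))[, , , 1, drop = FALSE]),
               "echoes")
})
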
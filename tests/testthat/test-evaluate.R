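test_that("concordance correlation: known values and Lin's inequality", {
  expect_equal(ccc(c(1, 2, 3), c(1, 2, 3)), 1.0)
  expect_equal(ccc(c(1, 2, 3), c(2, 3, 4)), 4 / 7, tolerance = 1e-12)
  expect_equal(ccc(c(1, 2, 3), c(5, 5, 5)), 0.0)
  expect_error(ccc(c(1, 1), c(1, 1)), "undefined")
  expect_error(ccc(1, 1:2), "equal length")
  ## |ccc| <= |pearson| on random inputs
  set.seed(61)
  for (i in 1:25) {
    x <- rnorm(30); y <- 0.5 * x + rnorm(30, sd = runif(1, 0.1, 2)) +
      runif(1, -3, 3)
    expect_lte(abs(ccc(x, y)), abs(cor(x, y)) + 1e-12)
  }
})

test_that("Bland-Altman: offsets, antisymmetry, and normal-limit check", {
  x <- c(1, 2, 3, 4)
  expect_equal(unlist(bland_altman(x, x)[, 1:3]),
               c(md = 0, loa_low = 0, loa_high = 0))
  ba <- bland_altman(x, x + 2.5)
  expect_equal(ba$md, 2.5)
  expect_equal(ba$loa_low, 2.5)
  set.seed(62)
  y <- rnorm(20); z <- rnorm(20)
  expect_equal(bland_altman(y, z)$md, -bland_altman(z, y)$md,
               tolerance = 1e-12)
  d <- rnorm(1e5)
  ba2 <- bland_altman(rep(0, 1e5), d)
  expect_lt(abs(ba2$loa_high - 1.96), 0.04)
  expect_lt(abs(ba2$loa_low + 1.96), 0.04)
})

test_that("aSNR definition, scale invariance, and the Rayleigh background", {
  vol <- array(0, c(20, 20, 2))
  vol[1:5, 1:5, ] <- 10
  set.seed(63)
  bg_mask <- array(FALSE, dim(vol)); bg_mask[10:20, 10:20, ] <- TRUE
  sig_mask <- array(FALSE, dim(vol)); sig_mask[1:5, 1:5, ] <- TRUE
  vol[bg_mask] <- abs(rnorm(sum(bg_mask)))   # magnitude image background
  expect_equal(asnr(vol, sig_mask, bg_mask), mean(vol[sig_mask]) /
                 sd(vol[bg_mask]))
  expect_equal(asnr(3.3 * vol, sig_mask, bg_mask),
               asnr(vol, sig_mask, bg_mask), tolerance = 1e-12)
  expect_error(asnr(vol, sig_mask, sig_mask), "overlap")
  ## complex volume: Rayleigh background, A/(sigma*sqrt(2 - pi/2)) oracle
  a <- 8; sg <- 0.5
  cvol <- array(complex(real = rnorm(4e4, 0, sg),
                        imaginary = rnorm(4e4, 0, sg)), c(200, 200, 1))
  cvol[1:40, 1:40, 1] <- a
  smask <- array(FALSE, dim(cvol)); smask[1:40, 1:40, 1] <- TRUE
  bmask <- array(FALSE, dim(cvol)); bmask[100:200, 100:200, 1] <- TRUE
  expect_lt(abs(asnr(cvol, smask, bmask) /
                  (a / (sg * sqrt(2 - pi / 2))) - 1), 0.05)
  ## zero-background flag
  zvol <- array(c(rep(1, 10), rep(0, 10)), c(20, 1, 1))
  expect_warning(v <- asnr(zvol, 1:10, 11:20), "infinite")
  expect_true(is.infinite(v))
})

test_that("roi_stats: constants, single voxels, checkerboard", {
  ph <- small_phantom()
  maps <- structure(list(pdff = ph$f * 100, r2s = ph$r2s,
                         mask = ph$object), class = "quant_maps")
  rois <- phantom_rois(ph)
  st <- roi_stats(maps, rois)
  expect_equal(st$pdff_sd, rep(0, nrow(st)))
  expect_equal(st$pdff_mean[st$label == "pdff_30"], 30)
  one <- roi_stats(maps, list(single = which(ph$object)[1]))
  expect_equal(one$n, 1L)
  expect_equal(one$pdff_sd, 0)
  ## checkerboard 0/100: mean 50, sample SD = 50*sqrt(n/(n-1))
  n <- 64
  chk <- structure(list(pdff = array(rep(c(0, 100), n / 2), c(n, 1, 1)),
                        r2s = array(0, c(n, 1, 1)),
                        mask = array(TRUE, c(n, 1, 1))),
                   class = "quant_maps")
  st2 <- roi_stats(chk, list(all = 1:n))
  expect_equal(st2$pdff_mean, 50)
  expect_equal(st2$pdff_sd, 50 * sqrt(n / (n - 1)), tolerance = 1e-12)
  ## voxel ordering does not matter
  st3 <- roi_stats(chk, list(all = sample(1:n)))
  expect_equal(st3$pdff_sd, st2$pdff_sd)
  expect_warning(roi_stats(chk, list(empty = integer(0))), "empty")
})

test_that("agreement report combines ccc, regression and Bland-Altman", {
  set.seed(64)
  x <- seq(0, 100, length.out = 15)
  y <- 1.02 * x - 0.5 + rnorm(15, 0, 1)
  rep <- agreement_report(x, y)
  expect_gt(rep$rho_c, 0.99)
  expect_equal(rep$slope, coef(lm(y ~ x))[[2]], tolerance = 1e-12)
  expect_equal(rep$md, mean(y - x), tolerance = 1e-12)
  td <- tidy(rep)
  expect_equal(td$estimate[td$term == "rho_c"], rep$rho_c)
  gl <- glance(rep)
  expect_equal(gl$n, 15L)
  ## method comparison wrappers run the standard tests
  dat <- data.frame(value = c(rnorm(10, 1), rnorm(10, 1.5), rnorm(10, 3)),
                    method = rep(c("a", "b", "c"), each = 10),
                    id = rep(1:10, 3))
  cmp <- compare_methods(dat)
  expect_s3_class(cmp$kruskal, "htest")
  expect_equal(nrow(cmp$wilcoxon), 3L)
  expect_true(all(cmp$wilcoxon$p_bonferroni >= cmp$wilcoxon$p_raw))
})
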
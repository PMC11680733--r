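make_mc_noise <- function(dims, nc, ne, sigma = 1, psi = NULL) {
  arr <- array(complex(real = rnorm(prod(dims) * nc * ne, 0, sigma),
                       imaginary = rnorm(prod(dims) * nc * ne, 0, sigma)),
               c(dims, nc, ne))
  if (!is.null(psi)) {
    l <- pdffmap:::chol_complex(psi)
    arr <- pdffmap:::apply_coil_transform(arr, l)
  }
  multi_coil_image(arr, noise_cov = psi)
}

test_that("prewhitening identities and empirical covariance", {
  set.seed(31)
  ## identity covariance leaves data unchanged
  img <- make_mc_noise(c(4, 4, 2), nc = 3, ne = 2)
  out <- prewhiten(img, diag(3))
  expect_equal(unclass(out), unclass(img), tolerance = 1e-12,
               ignore_attr = TRUE)
  ## diagonal scaling halves the over-weighted coil
  img2 <- make_mc_noise(c(2, 2, 1), nc = 2, ne = 1)
  out2 <- prewhiten(img2, diag(c(4, 1)))
  expect_equal(unclass(out2)[, , , 1, ], unclass(img2)[, , , 1, ] / 2,
               tolerance = 1e-12)
  expect_equal(unclass(out2)[, , , 2, ], unclass(img2)[, , , 2, ],
               tolerance = 1e-12)
  ## correlated noise -> prewhitened empirical covariance ~ identity
  rho <- 0.6
  psi <- outer(1:3, 1:3, function(i, j) rho^abs(i - j)) * c(1, 2, 0.5)^0 *
    2.0
  img3 <- make_mc_noise(c(40, 40, 16), nc = 3, ne = 4, psi = psi)
  wh <- prewhiten(img3)
  m <- matrix(aperm(unclass(wh), c(1, 2, 3, 5, 4)), ncol = 3)
  emp <- (Conj(t(m)) %*% m) / nrow(m) / 2  # per-component covariance
  expect_lt(max(Mod(emp - diag(3))), 0.05)
  ## unwhiten inverts
  back <- unwhiten(wh)
  expect_equal(unclass(back), unclass(img3), tolerance = 1e-9,
               ignore_attr = TRUE)
  ## non-PD covariance is refused with the offending pivot reported
  bad <- matrix(c(1, 1, 1, 1), 2, 2)
  img4 <- make_mc_noise(c(2, 2, 1), nc = 2, ne = 1)
  expect_error(prewhiten(img4, bad), "positive-definite")
})

test_that("g-factor normalization is an involution and flattens noise", {
  set.seed(32)
  dims <- c(12, 12, 4)
  g <- array(runif(prod(dims), 0.8, 2.5), dims)
  img <- make_mc_noise(dims, nc = 2, ne = 3)
  noisy <- unclass(img) * array(g, c(dims, 2, 3))   # sigma scales with g
  img_g <- multi_coil_image(noisy, gmap = g)
  fwd <- gfactor_normalize(img_g, direction = "forward")
  ## voxelwise noise SD uniform after normalization: split voxels by g
  v <- matrix(unclass(fwd), nrow = prod(dims))
  sds <- apply(cbind(Re(v), Im(v)), 1, sd)
  hi <- g > median(g)
  expect_lt(abs(mean(sds[hi]) / mean(sds[!hi]) - 1), 0.05)
  back <- gfactor_normalize(fwd, direction = "inverse")
  expect_equal(unclass(back), noisy, tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(gfactor_normalize(img_g, gmap = -g), "positive")
  ## gmap of ones is the identity
  ones <- gfactor_normalize(multi_coil_image(noisy, gmap = array(1, dims)),
                            direction = "forward")
  expect_equal(unclass(ones), noisy, tolerance = 1e-15, ignore_attr = TRUE)
})

test_that("patch extraction shapes and aggregate/extract identity", {
  set.seed(33)
  img <- tiny_me_image(c(7, 6, 5), sigma = 0.05, seed = 1)
  ps <- extract_patches(img, c(5, 5, 5), mode = "echo_only")
  expect_equal(dim(patch_matrix(ps, 1)), c(125L, 6L))
  expect_equal(ps$n_patch, (7 - 4) * (6 - 4) * (5 - 4))
  ## round trip reproduces the image exactly
  agg <- aggregate_patches(NULL, ps)
  expect_equal(agg, unclass(img), tolerance = 1e-14, ignore_attr = TRUE)
  ## echo_coil_realimag: 125 x 2*Ne*Nc real matrix
  mc <- make_mc_noise(c(5, 5, 5), nc = 12, ne = 6)
  ps2 <- extract_patches(mc, c(5, 5, 5), mode = "echo_coil_realimag")
  expect_equal(ps2$n_patch, 1L)
  expect_equal(dim(patch_matrix(ps2, 1)), c(125L, 144L))
  expect_true(is.numeric(patch_matrix(ps2, 1)))
  expect_error(extract_patches(img, c(9, 5, 5)), "larger than image")
  ## zeroing one patch only changes voxels it covers, weighted by coverage
  mats <- lapply(seq_len(ps$n_patch), function(i) patch_matrix(ps, i))
  mats[[2]] <- mats[[2]] * 0
  agg2 <- aggregate_patches(mats, ps)
  counts <- integer(prod(dim(img)[1:3]))
  for (i in seq_len(ps$n_patch)) {
    counts[ps$index[, i]] <- counts[ps$index[, i]] + 1L
  }
  inside <- ps$index[, 2]
  outside <- setdiff(which(counts > 0), inside)
  x0 <- matrix(unclass(img), ncol = 6)
  expect_equal(agg2[, , , 1][outside], unclass(img)[, , , 1][outside],
               tolerance = 1e-12)
  expected_inside <- x0[inside, 1] * (counts[inside] - 1) / counts[inside]
  expect_equal(agg2[, , , 1][inside], expected_inside, tolerance = 1e-12)
})

test_that("coil combination recovers the source image and SNR", {
  set.seed(34)
  dims <- c(10, 10, 4)
  ne <- 3; nc <- 5
  src <- array(complex(real = rnorm(prod(dims) * ne),
                       imaginary = rnorm(prod(dims) * ne)), c(dims, ne))
  sens <- pdffmap:::synthetic_sensitivities(dims, nc)
  dat <- array(0i, c(dims, nc, ne))
  for (c_i in seq_len(nc)) for (e_i in seq_len(ne)) {
    dat[, , , c_i, e_i] <- sens[, , , c_i] * src[, , , e_i]
  }
  mc <- multi_coil_image(dat)
  ## known sensitivities: exact recovery
  comb <- coil_combine(mc, method = "known", sensitivities = sens)
  expect_lt(max(Mod(unclass(comb) - src)) / max(Mod(src)), 1e-9)
  ## single coil with unit sensitivity is the identity
  one <- multi_coil_image(array(src, c(dims, 1, ne)))
  comb1 <- coil_combine(one, method = "known",
                        sensitivities = array(1 + 0i, c(dims, 1)))
  expect_equal(unclass(comb1), src, tolerance = 1e-12, ignore_attr = TRUE)
  ## matched-filter noise never exceeds RSS combination noise (pure noise)
  noise <- make_mc_noise(dims, nc = nc, ne = ne)
  cm <- coil_combine(noise, method = "known", sensitivities = sens)
  rss <- sqrt(apply(Mod(unclass(noise))^2, c(1, 2, 3, 5), sum))
  expect_lt(sd(Mod(unclass(cm))), sd(rss))
  ## all-zero input warns and returns zeros
  zero <- multi_coil_image(array(0i, c(dims, nc, ne)))
  expect_warning(z <- coil_combine(zero), "degenerate")
  expect_true(all(unclass(z) == 0))
})
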
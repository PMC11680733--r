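#' Calibrate the median smallest singular value of pure-noise matrices
#'
#' Draws `n_samples` random `p x q` matrices with i.i.d. complex Gaussian
#' entries (per-component SD `sigma_s`) and returns the median of their
#' smallest singular values, `lambda_m`. A patch matrix whose smallest
#' singular value is `P(Mn)` then has estimated noise SD
#' `sigma_hat = P(Mn) / lambda_m * sigma_s` (see [estimate_noise_rllr()]).
#' Results are cached per `(p, q, sigma_s, n_samples, seed)`.
#'
#' @param p,q Matrix dimensions (`p >= q >= 1`).
#' @param sigma_s Per-component SD of the calibration noise (default 1).
#' @param n_samples Number of random matrices (default 500).
#' @param seed RNG seed for the calibration draw (default 20240817).
#' @return A list of class `rllr_calibration` with fields `p`, `q`,
#'   `sigma_s`, `lambda_m`, `n_samples`, `seed`.
#' @export
calibrate_lambda_m <- function(p, q, sigma_s = 1, n_samples = 500,
                               seed = 20240817L) {
  if (p < q || q < 1) stop_invalid("need p >= q >= 1")
  if (n_samples < 1) stop_invalid("need at least one calibration sample")
  key <- paste("lm", p, q, format(sigma_s, digits = 12), n_samples, seed,
               sep = "_")
  hit <- .pdffmap_env[[key]]
  if (!is.null(hit)) return(hit)
  smin <- with_seed(seed, {
    vapply(seq_len(n_samples), function(i) {
      m <- matrix(complex(real = rnorm(p * q, 0, sigma_s),
                          imaginary = rnorm(p * q, 0, sigma_s)), p, q)
      min(svd(m, nu = 0, nv = 0)$d)
    }, numeric(1))
  })
  out <- structure(list(p = p, q = q, sigma_s = sigma_s,
                        lambda_m = median(smin), n_samples = n_samples,
                        seed = seed),
                   class = "rllr_calibration")
  .pdffmap_env[[key]] <- out
  out
}

#' Estimate patch noise level from the smallest singular value
#'
#' Compares the smallest singular value of a patch matrix to the calibrated
#' median smallest singular value of pure-noise matrices of the same shape:
#' `sigma_hat = smin(Mn) / lambda_m * sigma_s`.
#'
#' @param mn Complex patch matrix (`p x q`, matching the calibration).
#' @param calibration A [calibrate_lambda_m()] result.
#' @return A list with `sigma_hat` (per-component noise SD, >= 0) and
#'   `smin` (the smallest singular value observed).
#' @export
estimate_noise_rllr <- function(mn, calibration) {
  stopifnot(inherits(calibration, "rllr_calibration"))
  if (nrow(mn) != calibration$p || ncol(mn) != calibration$q) {
    stop_invalid("patch matrix is ", nrow(mn), "x", ncol(mn),
                 " but calibration is for ", calibration$p, "x", calibration$q)
  }
  smin <- min(svd(mn, nu = 0, nv = 0)$d)
  list(sigma_hat = smin / calibration$lambda_m * calibration$sigma_s,
       smin = smin)
}

#' SURE-optimal singular-value soft thresholding
#'
#' Soft-thresholds the singular values of a matrix at the threshold that
#' minimizes Stein's unbiased risk estimate (SURE) for singular-value soft
#' thresholding, using the closed-form divergence of spectral functions.
#' Candidate thresholds are the observed singular values plus zero (the risk
#' is piecewise smooth between singular values). For complex input the noise
#' is taken as complex Gaussian with per-component variance `sigma^2` and
#' the risk is evaluated on the complex Frobenius norm.
#'
#' @param x Numeric or complex matrix.
#' @param sigma Noise standard deviation (per real component). `sigma = 0`
#'   returns `x` unchanged.
#' @return Matrix of the same shape with thresholded singular values;
#'   attributes `threshold` (chosen lambda) and `sure` (risk at optimum).
#' @export
sure_svt <- function(x, sigma) {
  if (sigma < 0) stop_invalid("`sigma` must be non-negative")
  if (sigma == 0) {
    attr(x, "threshold") <- 0
    return(x)
  }
  sv <- svd(x)
  lam <- sure_svt_threshold(sv$d, nrow(x), ncol(x), sigma,
                            complex_data = is.complex(x))
  dnew <- pmax(sv$d - lam$lambda, 0)
  out <- sv$u %*% (dnew * Conj(t(sv$v)))
  attr(out, "threshold") <- lam$lambda
  attr(out, "sure") <- lam$sure
  out
}

## SURE risk of soft-thresholding singular values `d` of an m x n matrix at
## threshold `lambda`; `complex_data` switches the divergence constants
## (2mn real coordinates, diagonal weight 2|m-n|+1, cross-term factor 4).
sure_svt_risk <- function(d, m, n, sigma, lambda, complex_data = TRUE) {
  mm <- max(m, n); nn <- min(m, n)
  resid <- sum(pmin(d, lambda)^2)
  keep <- d > lambda
  shrunk <- pmax(d - lambda, 0)
  if (complex_data) {
    diagw <- 2 * (mm - nn) + 1
    crossf <- 4
    ncoord <- 2 * mm * nn
  } else {
    diagw <- mm - nn
    crossf <- 2
    ncoord <- mm * nn
  }
  div <- sum(keep) + diagw * sum(ifelse(d > 0, shrunk / d, 0))
  if (nn > 1) {
    d2 <- d^2
    num <- d * shrunk
    cross <- 0
    for (i in seq_len(nn)) {
      if (shrunk[i] > 0) {
        dif <- d2[i] - d2[-i]
        dif[abs(dif) < 1e-300] <- 1e-300
        cross <- cross + sum(num[i] / dif)
      }
    }
    div <- div + crossf * cross
  }
  -ncoord * sigma^2 + resid + 2 * sigma^2 * div
}

## Minimize the SURE risk over candidate thresholds {0, singular values}.
sure_svt_threshold <- function(d, m, n, sigma, complex_data = TRUE) {
  cand <- sort(unique(c(0, d)))
  risks <- vapply(cand, function(l) sure_svt_risk(d, m, n, sigma, l,
                                                  complex_data),
                  numeric(1))
  i <- which.min(risks)
  list(lambda = cand[i], sure = risks[i],
       candidates = cand, risks = risks)
}

#' Robust locally low-rank denoising of coil-combined multi-echo images
#'
#' For every stride-1 `(px, py, pz)` spatial patch, builds the complex
#' `[px*py*pz x Ne]` matrix, estimates the patch noise level by comparing
#' its smallest singular value to the calibrated pure-noise median
#' ([calibrate_lambda_m()]), applies SURE-optimal singular-value soft
#' thresholding ([sure_svt()]), and averages all overlapping denoised
#' patches into the output image.
#'
#' @param image A [multi_echo_image()] (coil-combined complex stack) or a
#'   4-D complex array.
#' @param patch Patch size `(px, py, pz)`, default `c(5, 5, 5)`.
#' @param mask Optional logical array `(x,y,z)`: only patches containing at
#'   least one masked voxel are denoised; uncovered voxels pass through.
#' @param sigma_s,n_samples,seed Calibration options, see
#'   [calibrate_lambda_m()].
#' @return A `multi_echo_image` of the input dimensions with attributes
#'   `sigma_map` (voxelwise aggregated noise-SD estimates) and
#'   `mean_sigma_hat` (mean per-patch estimate).
#' @export
rllr_denoise <- function(image, patch = c(5, 5, 5), mask = NULL, sigma_s = 1,
                         n_samples = 500, seed = 20240817L) {
  if (!inherits(image, "multi_echo_image")) image <- multi_echo_image(image)
  d <- dim(image)
  ne <- d[4]
  if (ne < 2) stop_invalid("need at least two echoes for low-rank denoising")
  calib <- calibrate_lambda_m(p = prod(patch), q = ne, sigma_s = sigma_s,
                              n_samples = n_samples, seed = seed)
  ps <- extract_patches(image, patch, mode = "echo_only")
  process <- NULL
  if (!is.null(mask)) {
    m <- as.logical(array(mask, d[1:3]))
    process <- colSums(matrix(m[ps$index], nrow(ps$index))) > 0
  }
  res <- rllr_core_cpp(ps$values, ps$index - 1L, calib$lambda_m,
                       calib$sigma_s, process)
  out <- patch_values_to_array(res$out, ps)
  out <- multi_echo_image(out, te = attr(image, "te"))
  attr(out, "sigma_map") <- array(res$sigma_map, d[1:3])
  attr(out, "mean_sigma_hat") <- mean(res$sigma_patch)
  out
}
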
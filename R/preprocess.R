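#' Multi-coil and coil-combined image containers
#'
#' `multi_coil_image()` wraps a complex array indexed `(x, y, z, coil, echo)`
#' together with optional noise metadata; `multi_echo_image()` wraps a
#' coil-combined complex array `(x, y, z, echo)`.
#'
#' @param data Complex array with the stated dimension order.
#' @param te Echo times in ms (length must match the echo dimension).
#' @param noise_cov Optional coil noise covariance (Nc x Nc, Hermitian
#'   positive-definite).
#' @param gmap Optional g-factor map, array `(x, y, z)`, strictly positive.
#' @return An array of class `multi_coil_image` / `multi_echo_image` with
#'   attributes `te`, `noise_cov`, `gmap`.
#' @export
multi_coil_image <- function(data, te = NULL, noise_cov = NULL, gmap = NULL) {
  if (length(dim(data)) != 5) stop_invalid("`data` must be a 5-D (x,y,z,coil,echo) array")
  if (!is.complex(data)) storage.mode(data) <- "complex"
  if (!is.null(te) && length(te) != dim(data)[5]) {
    stop_invalid("length(te) must equal the echo dimension")
  }
  if (!is.null(noise_cov)) check_psi(noise_cov, dim(data)[4])
  if (!is.null(gmap)) {
    if (!all(dim(gmap) == dim(data)[1:3])) stop_invalid("g-map dimensions must match image")
    if (any(gmap <= 0)) stop_invalid("g-map must be strictly positive")
  }
  structure(data, te = te, noise_cov = noise_cov, gmap = gmap,
            class = "multi_coil_image")
}

#' @rdname multi_coil_image
#' @export
multi_echo_image <- function(data, te = NULL) {
  if (length(dim(data)) != 4) stop_invalid("`data` must be a 4-D (x,y,z,echo) array")
  if (!is.complex(data)) storage.mode(data) <- "complex"
  if (!is.null(te) && length(te) != dim(data)[4]) {
    stop_invalid("length(te) must equal the echo dimension")
  }
  structure(data, te = te, class = "multi_echo_image")
}

check_psi <- function(psi, nc) {
  if (!is.matrix(psi) || nrow(psi) != nc || ncol(psi) != nc) {
    stop_invalid("noise covariance must be ", nc, " x ", nc)
  }
  if (max(Mod(psi - Conj(t(psi)))) > 1e-8 * max(Mod(psi))) {
    stop_invalid("noise covariance must be Hermitian")
  }
  ev <- eigen(psi, symmetric = TRUE, only.values = TRUE)$values
  if (min(Re(ev)) <= 0) {
    stop_invalid("noise covariance is not positive-definite (smallest eigenvalue ",
                 format(min(Re(ev))), ")")
  }
  invisible(TRUE)
}

## Lower-triangular Cholesky factor L (L L^H = a) of a Hermitian
## positive-definite matrix; base chol() is real-only.
chol_complex <- function(a) {
  n <- nrow(a)
  l <- matrix(0i, n, n)
  for (j in seq_len(n)) {
    jj <- seq_len(j - 1L)
    s <- Re(a[j, j]) - sum(Mod(l[j, jj])^2)
    if (s <= 0) {
      stop_invalid("covariance not positive-definite at pivot ", j,
                   " (remaining value ", format(s), ")")
    }
    l[j, j] <- sqrt(s)
    if (j < n) {
      for (i in (j + 1L):n) {
        l[i, j] <- (a[i, j] - sum(l[i, jj] * Conj(l[j, jj]))) / l[j, j]
      }
    }
  }
  l
}

## Apply an Nc x Nc matrix across the coil dimension of (x,y,z,coil,echo).
apply_coil_transform <- function(data, w) {
  d <- dim(data)
  m <- matrix(aperm(unclass(data), c(1, 2, 3, 5, 4)), ncol = d[4])
  m <- m %*% t(w)
  out <- aperm(array(m, c(d[1:3], d[5], d[4])), c(1, 2, 3, 5, 4))
  out
}

#' Prewhiten multi-coil data (coil decorrelation)
#'
#' Transforms the coil dimension by the inverse Cholesky factor of the noise
#' covariance so that the transformed channel noise is i.i.d. with identity
#' covariance. The applied whitener is stored in attribute `whitener` so the
#' transform can be inverted with [unwhiten()] after denoising.
#'
#' @param data A [multi_coil_image()].
#' @param psi Coil noise covariance (defaults to the image's `noise_cov`
#'   attribute). Must be Hermitian positive-definite.
#' @return A `multi_coil_image` with decorrelated coils, identity
#'   `noise_cov`, and the whitening matrix in `attr(, "whitener")`.
#' @export
prewhiten <- function(data, psi = attr(data, "noise_cov")) {
  stopifnot(inherits(data, "multi_coil_image"))
  nc <- dim(data)[4]
  if (is.null(psi)) psi <- diag(nc)
  check_psi(psi, nc)
  l <- chol_complex(psi)            # lower-triangular, psi = L L^H
  w <- solve(l)                     # L^{-1}
  out <- apply_coil_transform(data, w)
  out <- multi_coil_image(out, te = attr(data, "te"),
                          noise_cov = diag(nc), gmap = attr(data, "gmap"))
  attr(out, "whitener") <- w
  out
}

#' @rdname prewhiten
#' @export
unwhiten <- function(data) {
  stopifnot(inherits(data, "multi_coil_image"))
  w <- attr(data, "whitener")
  if (is.null(w)) return(data)
  out <- apply_coil_transform(data, solve(w))
  multi_coil_image(out, te = attr(data, "te"), gmap = attr(data, "gmap"))
}

#' Normalize spatially varying noise with a g-factor map
#'
#' `direction = "forward"` divides every coil/echo voxel by the g-factor so
#' that parallel-imaging noise amplification is removed before denoising;
#' `"inverse"` multiplies it back. The two directions compose to the
#' identity up to floating-point round-off.
#'
#' @param data A `multi_coil_image` or `multi_echo_image`.
#' @param gmap Positive array matching the spatial dimensions (defaults to
#'   the image's `gmap` attribute).
#' @param direction `"forward"` or `"inverse"`.
#' @return Image of the same class and dimensions.
#' @export
gfactor_normalize <- function(data, gmap = attr(data, "gmap"),
                              direction = c("forward", "inverse")) {
  direction <- match.arg(direction)
  if (is.null(gmap)) stop_invalid("no g-factor map supplied")
  d <- dim(data)
  if (!all(dim(gmap) == d[1:3])) stop_invalid("g-map dimensions must match image")
  if (any(!is.finite(gmap)) || any(gmap <= 0)) stop_invalid("g-map must be strictly positive")
  g <- as.vector(gmap)
  if (direction == "forward") g <- 1 / g
  out <- unclass(data) * array(g, d)   # g varies along x,y,z, recycled over trailing dims
  attributes(out) <- attributes(data)
  out
}

#' Extract sliding-window patch matrices
#'
#' Slides a `(px, py, pz)` window with stride 1 over the spatial dimensions
#' (valid positions only, no padding) and represents each patch as a 2-D
#' matrix: in mode `"echo_only"` a complex `[px*py*pz x Ne]` matrix (one
#' column per echo); in mode `"echo_coil_realimag"` a real
#' `[px*py*pz x 2*Ne*Nc]` matrix whose columns are the real and imaginary
#' parts of every (echo, coil) image.
#'
#' The returned object holds index bookkeeping rather than materialized
#' matrices; use [patch_matrix()] to realize one patch, and
#' [aggregate_patches()] to average modified patches back into an image.
#'
#' @param data A `multi_echo_image` (mode `"echo_only"`) or
#'   `multi_coil_image` (mode `"echo_coil_realimag"`).
#' @param patch Patch dimensions `(px, py, pz)`; default `c(5, 5, 5)`.
#' @param mode Patch matrix layout (see above).
#' @return A list of class `patch_set` with elements `index`
#'   (`p x n_patch` matrix of spatial voxel indices), `values`
#'   (`n_voxel x n_col` patch-column source matrix), `dims`, `patch`,
#'   `mode`, `n_patch`.
#' @export
extract_patches <- function(data, patch = c(5, 5, 5),
                            mode = c("echo_only", "echo_coil_realimag")) {
  mode <- match.arg(mode)
  d <- dim(data)
  sp <- d[1:3]
  patch <- as.integer(patch)
  if (length(patch) != 3 || any(patch < 1)) stop_invalid("`patch` must be three positive sizes")
  if (any(patch > sp)) {
    stop_invalid("patch (", paste(patch, collapse = "x"),
                 ") larger than image (", paste(sp, collapse = "x"), ")")
  }
  idx <- patch_index_matrix(sp, patch)
  x <- unclass(data)
  if (mode == "echo_only") {
    if (length(d) != 4) stop_invalid("echo_only mode expects a 4-D (x,y,z,echo) array")
    values <- matrix(x, nrow = prod(sp), ncol = d[4])
  } else {
    if (length(d) != 5) stop_invalid("echo_coil_realimag mode expects a 5-D (x,y,z,coil,echo) array")
    m <- matrix(x, nrow = prod(sp), ncol = d[4] * d[5])
    values <- cbind(Re(m), Im(m))
  }
  structure(list(index = idx, values = values, dims = d, patch = patch,
                 mode = mode, n_patch = ncol(idx)),
            class = "patch_set")
}

## p x n_patch matrix of linear spatial indices for all valid stride-1
## window positions, columns ordered by window origin (x fastest).
patch_index_matrix <- function(sp, patch) {
  nx <- sp[1] - patch[1] + 1L
  ny <- sp[2] - patch[2] + 1L
  nz <- sp[3] - patch[3] + 1L
  within <- as.vector(outer(
    outer(seq_len(patch[1]) - 1L, (seq_len(patch[2]) - 1L) * sp[1], `+`),
    (seq_len(patch[3]) - 1L) * sp[1] * sp[2], `+`))
  origin <- as.vector(outer(
    outer(seq_len(nx), (seq_len(ny) - 1L) * sp[1], `+`),
    (seq_len(nz) - 1L) * sp[1] * sp[2], `+`))
  vapply(origin, function(o) o + within, integer(length(within)))
}

#' @rdname extract_patches
#' @param ps A `patch_set`.
#' @param i Patch number in `1:ps$n_patch`.
#' @export
patch_matrix <- function(ps, i) {
  stopifnot(inherits(ps, "patch_set"))
  ps$values[ps$index[, i], , drop = FALSE]
}

#' Average (possibly modified) patches back into an image
#'
#' Every voxel is the arithmetic mean of its value over all patches that
#' contain it; near image borders voxels are covered by fewer patches.
#' With unmodified patch matrices this reproduces the input exactly.
#'
#' @param mats List of patch matrices (as from [patch_matrix()], possibly
#'   modified), or `NULL` to aggregate `ps$values` itself (identity).
#' @param ps The `patch_set` bookkeeping from [extract_patches()].
#' @return An array with the dimensions of the original image.
#' @export
aggregate_patches <- function(mats, ps) {
  stopifnot(inherits(ps, "patch_set"))
  nvox <- prod(ps$dims[1:3])
  ncols <- ncol(ps$values)
  if (is.null(mats)) {
    mats <- lapply(seq_len(ps$n_patch), function(i) patch_matrix(ps, i))
  }
  if (length(mats) != ps$n_patch) {
    stop_invalid("got ", length(mats), " matrices for ", ps$n_patch, " patches")
  }
  acc <- matrix(if (is.complex(ps$values)) 0i else 0, nvox, ncols)
  cnt <- numeric(nvox)
  p <- nrow(ps$index)
  for (i in seq_len(ps$n_patch)) {
    m <- mats[[i]]
    if (!all(dim(m) == c(p, ncols))) stop_invalid("patch matrix ", i, " has wrong shape")
    v <- ps$index[, i]
    acc[v, ] <- acc[v, ] + m
    cnt[v] <- cnt[v] + 1
  }
  covered <- cnt > 0
  acc[covered, ] <- acc[covered, ] / cnt[covered]
  acc[!covered, ] <- ps$values[!covered, ]
  patch_values_to_array(acc, ps)
}

## Reshape an n_voxel x n_col value matrix back to the source array layout.
patch_values_to_array <- function(values, ps) {
  d <- ps$dims
  if (ps$mode == "echo_only") {
    array(values, d)
  } else {
    k <- d[4] * d[5]
    array(complex(real = values[, seq_len(k)],
                  imaginary = values[, k + seq_len(k)]), d)
  }
}

#' Combine coil images into a single complex image
#'
#' Matched-filter coil combination with sensitivities estimated from a
#' smoothed calibration of the first echo: relative coil phases are taken
#' from `smooth(x_c * Conj(x_ref))` (the voxelwise product with a reference
#' coil, which cancels the shared object phase), magnitudes from the
#' smoothed root-sum-of-squares profile. Sensitivities are normalized to
#' unit sum-of-squares per voxel so the combined noise level equals the
#' per-coil noise level. With `method = "known"` the supplied sensitivities
#' are used directly; `method = "rss"` returns the root-sum-of-squares
#' magnitude combination (phase discarded).
#'
#' @param data A [multi_coil_image()].
#' @param method `"adaptive"` (default), `"known"` or `"rss"`.
#' @param sensitivities Complex array `(x, y, z, coil)`, required for
#'   `method = "known"`.
#' @param smooth_sigma Gaussian smoothing width (voxels) for calibration.
#' @return A [multi_echo_image()] `(x, y, z, echo)`.
#' @export
coil_combine <- function(data, method = c("adaptive", "known", "rss"),
                         sensitivities = NULL, smooth_sigma = 3) {
  stopifnot(inherits(data, "multi_coil_image"))
  method <- match.arg(method)
  d <- dim(data)
  nc <- d[4]; ne <- d[5]
  x <- unclass(data)
  if (all(Mod(x) == 0)) {
    warning("all-zero coil data: degenerate sensitivities, returning zeros")
    return(multi_echo_image(array(0i, c(d[1:3], ne)), te = attr(data, "te")))
  }
  if (method == "rss") {
    comb <- sqrt(apply(Mod(x)^2, c(1, 2, 3, 5), sum))
    return(multi_echo_image(array(complex(real = comb), c(d[1:3], ne)),
                            te = attr(data, "te")))
  }
  sens <- if (method == "known") {
    if (is.null(sensitivities)) stop_invalid("method = \"known\" needs `sensitivities`")
    sensitivities
  } else {
    estimate_sensitivities(x, smooth_sigma)
  }
  ss <- apply(Mod(sens)^2, c(1, 2, 3), sum)
  ss[ss == 0] <- Inf                      # no sensitivity -> combined zero
  num <- array(0i, c(d[1:3], ne))
  for (c_i in seq_len(nc)) {
    w <- Conj(sens[, , , c_i])
    for (e_i in seq_len(ne)) {
      num[, , , e_i] <- num[, , , e_i] + w * x[, , , c_i, e_i]
    }
  }
  multi_echo_image(num / array(ss, c(d[1:3], ne)), te = attr(data, "te"))
}

## Sensitivity calibration from the first echo: phase relative to the
## strongest coil, magnitude from smoothed per-coil profiles, normalized to
## unit root-sum-of-squares where signal exists.
estimate_sensitivities <- function(x, smooth_sigma) {
  d <- dim(x)
  nc <- d[4]
  cal <- x[, , , , 1, drop = TRUE]                 # (x,y,z,coil) first echo
  if (nc == 1) dim(cal) <- c(d[1:3], 1L)
  energy <- apply(Mod(cal)^2, 4, sum)
  ref <- which.max(energy)
  sens <- array(0i, c(d[1:3], nc))
  for (c_i in seq_len(nc)) {
    sens[, , , c_i] <- smooth_gauss3(cal[, , , c_i] * Conj(cal[, , , ref]),
                                     smooth_sigma)
  }
  rss <- sqrt(apply(Mod(sens)^2, c(1, 2, 3), sum))
  rss[rss == 0] <- 1
  sens / array(rss, c(d[1:3], nc))
}

## Separable Gaussian smoothing of a 3-D array (complex supported). Edges
## are renormalized by the smoothed indicator so borders keep unit gain.
smooth_gauss3 <- function(a, sigma) {
  if (sigma <= 0) return(a)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  conv_dim <- function(a, dim_i) {
    d <- dim(a)
    perm <- c(dim_i, setdiff(1:3, dim_i))
    m <- matrix(aperm(a, perm), nrow = d[dim_i])
    n <- nrow(m)
    pad <- matrix(0, r, ncol(m))
    mp <- rbind(pad, m, pad)
    out <- matrix(0, n, ncol(m))
    for (j in seq_along(k)) {
      out <- out + k[j] * mp[(j - 1) + seq_len(n), , drop = FALSE]
    }
    aperm(array(out, d[perm]), order(perm))
  }
  wt_dim <- function(w, dim_i) conv_dim(w, dim_i)
  out <- a
  wt <- array(1, dim(a))
  for (i in 1:3) {
    if (dim(a)[i] > 1) {
      out <- conv_dim(out, i)
      wt <- wt_dim(wt, i)
    }
  }
  out / wt
}
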
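#' Lin's concordance correlation coefficient
#'
#' Agreement between paired measurements combining correlation with scale
#' and location shift:
#' `rho_c = 2 cov(x, y) / (var(x) + var(y) + (mean(x) - mean(y))^2)`, with
#' population (1/n) moments.
#'
#' @param x,y Numeric vectors of equal length (n >= 2).
#' @return Scalar in `[-1, 1]`; exactly 1 iff `y == x` elementwise (with
#'   variation present).
#' @export
#' @examples
#' ccc(c(1, 2, 3), c(2, 3, 4))  # 4/7
ccc <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2) {
    stop_invalid("`x` and `y` must have equal length >= 2")
  }
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 2) stop_invalid("need at least 2 finite pairs")
  mx <- mean(x); my <- mean(y)
  vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
  cxy <- mean((x - mx) * (y - my))
  denom <- vx + vy + (mx - my)^2
  if (denom == 0) stop_invalid("concordance undefined: zero variance and equal means")
  2 * cxy / denom
}

#' Bland-Altman agreement analysis
#'
#' Mean difference `MD = mean(y - x)` and 95% limits of agreement
#' `MD +/- 1.96 * SD(y - x)` (sample SD).
#'
#' @param x,y Paired measurements (n >= 2).
#' @return A one-row tibble: `md`, `loa_low`, `loa_high`, `sd_diff`, `n`.
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2) {
    stop_invalid("`x` and `y` must have equal length >= 2")
  }
  d <- y - x
  ok <- is.finite(d)
  d <- d[ok]
  if (length(d) < 2) stop_invalid("need at least 2 finite pairs")
  md <- mean(d); s <- sd(d)
  tibble::tibble(md = md, loa_low = md - 1.96 * s, loa_high = md + 1.96 * s,
                 sd_diff = s, n = length(d))
}

#' Apparent SNR of a magnitude image
#'
#' Signal mean in a signal region of interest divided by the SD of the
#' magnitude in a background (air) region, both on magnitude images with no
#' Rayleigh correction — the raw ratio.
#'
#' @param volume Numeric or complex array (complex input is taken Mod()).
#' @param signal_roi,background_roi Logical arrays matching `volume` or
#'   integer index vectors; must be non-empty and disjoint.
#' @return Scalar aSNR (`Inf` with a warning when the background SD is 0).
#' @export
asnr <- function(volume, signal_roi, background_roi) {
  v <- Mod(volume)
  sig <- v[signal_roi]
  bg <- v[background_roi]
  if (length(sig) == 0 || length(bg) < 2) stop_invalid("ROIs must be non-empty")
  si <- to_index(signal_roi, length(v))
  bi <- to_index(background_roi, length(v))
  if (length(intersect(si, bi)) > 0) stop_invalid("signal and background ROIs overlap")
  s <- sd(bg)
  if (s == 0) {
    warning("zero background SD: aSNR is infinite")
    return(Inf)
  }
  mean(sig) / s
}

to_index <- function(roi, n) {
  if (is.logical(roi)) which(roi) else as.integer(roi)
}

#' Circular evaluation ROIs for a digital phantom
#'
#' One circular ROI per vial, concentric at 60% of the vial radius,
#' spanning all slices.
#'
#' @param phantom A [make_phantom()] result.
#' @param frac ROI radius as a fraction of the vial radius (default 0.6).
#' @return A named list of integer voxel indices, one element per vial.
#' @export
phantom_rois <- function(phantom, frac = 0.6) {
  stopifnot(inherits(phantom, "digital_phantom"))
  dims <- phantom$dims
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  xg <- matrix(seq_len(nx), nx, ny)
  yg <- matrix(seq_len(ny), nx, ny, byrow = TRUE)
  out <- list()
  for (i in seq_len(nrow(phantom$vials))) {
    v <- phantom$vials[i, ]
    inside <- which((xg - v$cx)^2 + (yg - v$cy)^2 <= (frac * v$radius)^2)
    idx <- as.vector(outer(inside, (seq_len(nz) - 1L) * nx * ny, `+`))
    out[[v$label]] <- idx
  }
  out
}

#' Per-ROI statistics of quantitative maps
#'
#' @param maps A `quant_maps` object from [fit_maps()].
#' @param rois Named list of voxel index vectors (or logical arrays).
#' @return A tibble: `label`, `n`, `pdff_mean`, `pdff_sd`, `r2s_mean`,
#'   `r2s_sd`. Empty ROIs are skipped with a warning.
#' @export
roi_stats <- function(maps, rois) {
  stopifnot(inherits(maps, "quant_maps"))
  rows <- purrr::imap(rois, function(roi, label) {
    idx <- to_index(roi, length(maps$pdff))
    if (length(idx) == 0) {
      warning("ROI ", label, " is empty; skipped")
      return(NULL)
    }
    p <- maps$pdff[idx]; r <- maps$r2s[idx]
    tibble::tibble(label = label, n = length(idx),
                   pdff_mean = mean(p, na.rm = TRUE),
                   pdff_sd = if (sum(is.finite(p)) > 1) sd(p, na.rm = TRUE) else 0,
                   r2s_mean = mean(r, na.rm = TRUE),
                   r2s_sd = if (sum(is.finite(r)) > 1) sd(r, na.rm = TRUE) else 0)
  })
  dplyr::bind_rows(purrr::compact(rows))
}

#' Agreement report: measured versus reference values
#'
#' Combines Lin's concordance correlation, ordinary least-squares
#' regression of measurement on reference (`y = a x + b`), the mean
#' difference, and Bland-Altman 95% limits of agreement.
#'
#' @param reference,measured Paired values.
#' @return A list of class `agreement_report` with `rho_c`, `slope`,
#'   `intercept`, `md`, `loa_low`, `loa_high`, `n`.
#' @export
agreement_report <- function(reference, measured) {
  ok <- is.finite(reference) & is.finite(measured)
  x <- reference[ok]; y <- measured[ok]
  ba <- bland_altman(x, y)
  fit <- lm(y ~ x)
  structure(list(rho_c = ccc(x, y),
                 slope = coef(fit)[[2]], intercept = coef(fit)[[1]],
                 md = ba$md, loa_low = ba$loa_low, loa_high = ba$loa_high,
                 n = length(x)),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement_report> n = %d\n", x$n))
  cat(sprintf("  rho_c = %.4f, fit y = %.3f x + %.3f\n",
              x$rho_c, x$slope, x$intercept))
  cat(sprintf("  MD = %.3f, 95%% LoA [%.3f, %.3f]\n",
              x$md, x$loa_low, x$loa_high))
  invisible(x)
}

#' Group comparison of ROI measurements
#'
#' Convenience wrappers around the standard nonparametric tests used to
#' compare reconstruction methods: Kruskal-Wallis across methods and
#' pairwise Wilcoxon signed-rank tests with Bonferroni correction.
#'
#' @param data A data frame with columns `value`, `method`, and (for the
#'   paired test) a subject/ROI identifier `id`.
#' @return A list with the `kruskal.test` result and a tibble of pairwise
#'   Bonferroni-adjusted Wilcoxon p-values.
#' @export
compare_methods <- function(data) {
  stopifnot(all(c("value", "method") %in% names(data)))
  kw <- stats::kruskal.test(value ~ factor(method), data = data)
  methods <- unique(data$method)
  pairs <- utils::combn(methods, 2, simplify = FALSE)
  wil <- purrr::map_dfr(pairs, function(pr) {
    a <- data$value[data$method == pr[1]]
    b <- data$value[data$method == pr[2]]
    paired <- "id" %in% names(data) && length(a) == length(b)
    p <- stats::wilcox.test(a, b, paired = paired, exact = FALSE)$p.value
    tibble::tibble(method_a = pr[1], method_b = pr[2], p_raw = p)
  })
  wil$p_bonferroni <- pmin(wil$p_raw * nrow(wil), 1)
  list(kruskal = kw, wilcoxon = wil)
}
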
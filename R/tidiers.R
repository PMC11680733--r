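#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy quantitative maps into a per-voxel tibble
#'
#' @param x A `quant_maps` object.
#' @param mask_only Keep only voxels inside the fit mask (default TRUE).
#' @param ... Unused.
#' @return A tibble with voxel coordinates and `pdff`, `r2s`, `fieldmap`,
#'   `residual`, `reliable`.
#' @export
tidy.quant_maps <- function(x, mask_only = TRUE, ...) {
  maps <- x
  d <- dim(maps$pdff)
  coords <- expand.grid(x = seq_len(d[1]), y = seq_len(d[2]),
                        z = seq_len(d[3]))
  out <- tibble::tibble(
    x = coords$x, y = coords$y, z = coords$z,
    pdff = as.vector(maps$pdff), r2s = as.vector(maps$r2s),
    fieldmap = as.vector(maps$fieldmap),
    residual = as.vector(maps$residual),
    reliable = as.vector(maps$reliable))
  if (mask_only) out <- out[as.vector(maps$mask), ]
  out
}

#' @export
#' @rdname tidy.quant_maps
glance.quant_maps <- function(x, ...) {
  m <- x$mask
  tibble::tibble(
    n_voxels = sum(m),
    n_reliable = sum(x$reliable[m]),
    pdff_median = median(x$pdff[m], na.rm = TRUE),
    r2s_median = median(x$r2s[m], na.rm = TRUE),
    fieldmap_median = median(x$fieldmap[m], na.rm = TRUE))
}

#' @export
print.quant_maps <- function(x, ...) {
  d <- dim(x$pdff)
  cat(sprintf("<quant_maps> %s, %d voxels in mask (%d reliable)\n",
              paste(d, collapse = "x"), sum(x$mask),
              sum(x$reliable[x$mask])))
  invisible(x)
}

#' Plot one map of a `quant_maps` object
#'
#' @param object A `quant_maps`.
#' @param map One of `"pdff"`, `"r2s"`, `"fieldmap"`, `"residual"`.
#' @param slice Slice index (default: middle).
#' @param ... Unused.
#' @return A ggplot raster plot.
#' @export
autoplot.quant_maps <- function(object, map = "pdff", slice = NULL, ...) {
  stopifnot(map %in% c("pdff", "r2s", "fieldmap", "residual"))
  d <- dim(object$pdff)
  if (is.null(slice)) slice <- max(1L, round(d[3] / 2))
  df <- tidy.quant_maps(object, mask_only = FALSE)
  df <- dplyr::filter(df, .data$z == slice)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data[[map]])) +
    ggplot2::geom_raster() +
    ggplot2::coord_fixed() +
    ggplot2::scale_fill_viridis_c(na.value = "grey20", name = map) +
    ggplot2::labs(title = sprintf("%s (slice %d)", map, slice)) +
    ggplot2::theme_void()
}

#' @export
#' @rdname tidy.quant_maps
#' @param x An object to tidy.
tidy.agreement_report <- function(x, ...) {
  tibble::tibble(term = c("rho_c", "slope", "intercept", "md",
                          "loa_low", "loa_high"),
                 estimate = c(x$rho_c, x$slope, x$intercept, x$md,
                              x$loa_low, x$loa_high))
}

#' @export
glance.agreement_report <- function(x, ...) {
  tibble::tibble(rho_c = x$rho_c, slope = x$slope, intercept = x$intercept,
                 md = x$md, loa_low = x$loa_low, loa_high = x$loa_high,
                 n = x$n)
}

#' @export
glance.mc_result <- function(x, ...) summarize_mc(x)

#' Tidy a repetition experiment
#'
#' Per-method summary of in-object voxelwise SD of PDFF and R2* across
#' repetitions.
#'
#' @param x A `rep_experiment`.
#' @param ... Unused.
#' @export
tidy.rep_experiment <- function(x, ...) {
  purrr::map_dfr(x$methods, function(m) {
    tibble::tibble(
      method = m,
      mean_pdff_sd = mean(x$sd_maps[[m]]$pdff[x$mask], na.rm = TRUE),
      mean_r2s_sd = mean(x$sd_maps[[m]]$r2s[x$mask], na.rm = TRUE))
  })
}

#' @export
print.rep_experiment <- function(x, ...) {
  cat(sprintf("<rep_experiment> %d repetitions, sigma = %.4g, methods: %s\n",
              x$n_reps, x$sigma, paste(x$methods, collapse = ", ")))
  print(tidy.rep_experiment(x))
  invisible(x)
}

#' Bland-Altman plot of paired measurements
#'
#' @param x,y Paired values (reference first).
#' @param label Axis label for the measured quantity.
#' @return A ggplot object with MD and limits of agreement.
#' @export
plot_bland_altman <- function(x, y, label = "measurement") {
  ba <- bland_altman(x, y)
  df <- tibble::tibble(avg = (x + y) / 2, diff = y - x)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$avg, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = ba$md, linetype = 1) +
    ggplot2::geom_hline(yintercept = c(ba$loa_low, ba$loa_high),
                        linetype = 2) +
    ggplot2::labs(x = paste("mean", label), y = paste("difference in", label),
                  title = sprintf("MD %.3f, LoA [%.3f, %.3f]",
                                  ba$md, ba$loa_low, ba$loa_high)) +
    ggplot2::theme_minimal()
}

#' Write quantitative maps as NIfTI volumes
#'
#' Writes `pdff.nii.gz`, `r2s.nii.gz`, `fieldmap.nii.gz`,
#' `residual.nii.gz` and `reliable.nii.gz` into a directory, plus a JSON
#' provenance sidecar (`maps.json`) when jsonlite is available.
#'
#' @param maps A `quant_maps` object.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_quant_maps <- function(maps, dir) {
  stopifnot(inherits(maps, "quant_maps"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  pr <- attr(maps, "protocol")
  vox <- if (!is.null(pr)) pr$voxel else c(1, 1, 1)
  for (nm in c("pdff", "r2s", "fieldmap", "residual")) {
    RNifti::writeNifti(RNifti::asNifti(maps[[nm]], pixdim = vox),
                       file.path(dir, paste0(nm, ".nii.gz")))
  }
  RNifti::writeNifti(RNifti::asNifti(maps$reliable * 1, pixdim = vox),
                     file.path(dir, "reliable.nii.gz"))
  if (requireNamespace("jsonlite", quietly = TRUE) && !is.null(pr)) {
    jsonlite::write_json(
      list(te_ms = pr$te, tr_ms = pr$tr, fa_deg = pr$fa, b0_t = pr$b0,
           package = "pdffmap",
           version = as.character(utils::packageVersion("pdffmap"))),
      file.path(dir, "maps.json"), auto_unbox = TRUE)
  }
  invisible(dir)
}
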
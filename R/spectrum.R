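#' Multi-peak fat spectrum
#'
#' Constructs a fat resonance spectrum: a small table of spectral peaks with
#' chemical shifts relative to water (ppm) and relative amplitudes. The
#' amplitudes are normalized to sum to one. At a given field strength the
#' peak frequencies in Hz are `shift_ppm * 42.577 * B0`.
#'
#' @param shift_ppm Numeric vector of chemical shifts relative to water, in
#'   ppm. Negative values resonate below water (the dominant methylene
#'   protons sit near -3.4 ppm).
#' @param amplitude Numeric vector of non-negative relative amplitudes, same
#'   length as `shift_ppm`. Normalized internally to sum to 1.
#' @return A tibble of class `fat_spectrum` with columns `shift_ppm` and
#'   `amplitude`.
#' @seealso [default_fat_spectrum()], [fat_frequencies()]
#' @export
#' @examples
#' fat_spectrum(shift_ppm = -3.4, amplitude = 1)   # single-peak model
fat_spectrum <- function(shift_ppm, amplitude) {
  if (length(shift_ppm) != length(amplitude) || length(shift_ppm) < 1) {
    stop_invalid("`shift_ppm` and `amplitude` must be non-empty and of equal length")
  }
  if (any(!is.finite(shift_ppm))) stop_invalid("chemical shifts must be finite")
  if (any(amplitude < 0) || any(!is.finite(amplitude))) {
    stop_invalid("amplitudes must be finite and non-negative")
  }
  s <- sum(amplitude)
  if (s <= 0) stop_invalid("at least one amplitude must be positive")
  out <- tibble::tibble(shift_ppm = as.double(shift_ppm),
                        amplitude = as.double(amplitude) / s)
  class(out) <- c("fat_spectrum", class(out))
  out
}

#' Default seven-peak liver fat spectrum
#'
#' The packaged seven-peak triglyceride model (shifts in ppm relative to
#' water with the main methylene peak at -3.40 ppm). Amplitudes sum to one.
#'
#' @return A `fat_spectrum` tibble with seven rows.
#' @export
default_fat_spectrum <- function() {
  fat_spectrum(
    shift_ppm = c(-3.80, -3.40, -3.10, -2.60, -1.94, -0.39, 0.60),
    amplitude = c(0.087, 0.693, 0.001, 0.128, 0.004, 0.039, 0.048)
  )
}

#' Peak frequencies of a fat spectrum at a given field strength
#'
#' @param spectrum A [fat_spectrum()].
#' @param b0 Main field strength in tesla.
#' @return Numeric vector of peak frequencies in Hz (relative to water).
#' @export
fat_frequencies <- function(spectrum, b0) {
  stopifnot(inherits(spectrum, "fat_spectrum"))
  if (!is.numeric(b0) || b0 <= 0) stop_invalid("`b0` must be a positive field strength in tesla")
  spectrum$shift_ppm * GAMMA_MHZ_T * b0
}

#' Read / write a fat spectrum as plain-text CSV
#'
#' The on-disk format is a two-column CSV with header `shift_ppm,amplitude`.
#'
#' @param path File path.
#' @param spectrum A `fat_spectrum` (for writing).
#' @return `read_spectrum()` returns a `fat_spectrum`;
#'   `write_spectrum()` returns `path` invisibly.
#' @export
read_spectrum <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("shift_ppm", "amplitude") %in% names(d))) {
    stop_invalid("spectrum file must have columns shift_ppm, amplitude")
  }
  fat_spectrum(d$shift_ppm, d$amplitude)
}

#' @rdname read_spectrum
#' @export
write_spectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "fat_spectrum"))
  utils::write.csv(as.data.frame(spectrum), path, row.names = FALSE)
  invisible(path)
}

#' In-phase and opposed-phase echo times
#'
#' Echo times at which the main fat peak is aligned with (in-phase) or
#' opposed to (opposed-phase) the water signal. The fat-water frequency
#' difference is `|shift_ppm| * 42.577 * B0` Hz; the in-phase time is its
#' reciprocal and the opposed-phase time is half of that. At 0.55 T with the
#' 3.30 ppm effective methylene shift these are 12.94 ms and 6.47 ms.
#'
#' @param b0 Field strength in tesla.
#' @param main_shift_ppm Effective chemical shift of the dominant fat peak,
#'   ppm (default 3.30).
#' @return A one-row tibble with columns `te_op_ms` and `te_in_ms`.
#' @export
#' @examples
#' inphase_opposed_te(0.55)
inphase_opposed_te <- function(b0, main_shift_ppm = 3.30) {
  if (!is.numeric(b0) || b0 <= 0) stop_invalid("`b0` must be positive")
  if (!is.numeric(main_shift_ppm) || main_shift_ppm == 0) {
    stop_invalid("`main_shift_ppm` must be non-zero")
  }
  df_hz <- abs(main_shift_ppm) * GAMMA_MHZ_T * b0
  te_in <- 1000 / df_hz
  tibble::tibble(te_op_ms = te_in / 2, te_in_ms = te_in)
}
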
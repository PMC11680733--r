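#' Tissue parameters for the fat-water signal model
#'
#' @param f Proton density fat fraction as a fraction in \[0, 1\].
#' @param r2s Effective transverse relaxation rate R2* in 1/s, >= 0.
#' @param phi Off-resonance (B0 inhomogeneity) frequency in Hz.
#' @param t1_water,t1_fat Longitudinal relaxation times in ms. Defaults are
#'   liver values at 0.55 T (339 ms water, 187 ms fat).
#' @param rho Proton-density scale (arbitrary units, >= 0).
#' @return A list of class `tissue_params`.
#' @export
tissue_params <- function(f, r2s, phi = 0, t1_water = 339, t1_fat = 187,
                          rho = 1) {
  if (any(f < 0 | f > 1)) stop_invalid("`f` must lie in [0, 1]")
  if (any(r2s < 0)) stop_invalid("`r2s` must be non-negative")
  if (any(rho < 0)) stop_invalid("`rho` must be non-negative")
  if (t1_water <= 0 || t1_fat <= 0) stop_invalid("T1 values must be positive")
  structure(list(f = f, r2s = r2s, phi = phi,
                 t1_water = t1_water, t1_fat = t1_fat, rho = rho),
            class = "tissue_params")
}

#' Complex Gaussian noise model
#'
#' Real and imaginary noise components are drawn independently from
#' `N(0, sigma^2)`.
#'
#' @param sigma Per-component standard deviation, >= 0.
#' @param seed Optional integer seed for reproducible realizations.
#' @return A list of class `noise_model`.
#' @export
noise_model <- function(sigma, seed = NULL) {
  if (sigma < 0) stop_invalid("`sigma` must be non-negative")
  structure(list(sigma = sigma, seed = seed), class = "noise_model")
}

#' SPGR steady-state amplitude factor
#'
#' Spoiled gradient-echo steady-state magnetization
#' `sin(a) * (1 - E1) / (1 - E1 * cos(a))` with `E1 = exp(-TR/T1)`.
#' Echo-time dependence of the acquired signal is carried entirely by the
#' explicit `exp(-R2* t)` decay in the signal model, so this factor is
#' TE-independent.
#'
#' @param t1 Longitudinal relaxation time, ms.
#' @param tr Repetition time, ms.
#' @param fa Flip angle, degrees (0 < fa < 180).
#' @return Dimensionless amplitude in (0, 1].
#' @export
#' @examples
#' spgr_factor(t1 = 339, tr = 14.7, fa = 8)
spgr_factor <- function(t1, tr, fa) {
  if (any(t1 <= 0) || any(tr <= 0)) stop_invalid("`t1` and `tr` must be positive")
  if (any(fa <= 0) || any(fa >= 180)) stop_invalid("`fa` must be in (0, 180) degrees")
  a <- fa * pi / 180
  e1 <- exp(-tr / t1)
  sin(a) * (1 - e1) / (1 - e1 * cos(a))
}

## Fat spectral modulation F~(t) = sum_j a_j exp(+i 2 pi f_j t) evaluated at
## the echo times (t in seconds). `phase_sign` flips the convention.
fat_modulation <- function(spectrum, b0, t_s, phase_sign = 1) {
  fj <- fat_frequencies(spectrum, b0)
  ph <- outer(t_s, fj, function(t, f) phase_sign * 2 * pi * f * t)
  as.vector(exp(1i * ph) %*% spectrum$amplitude)
}

#' Simulate a multi-echo Dixon signal
#'
#' Generates the complex signal at the protocol's echo times from the
#' single-R2* fat-water model
#' \deqn{s(t_m) = \rho\,[(1-F)E_w + F E_f \sum_j a_j e^{i2\pi f_j t_m}]
#'   e^{-R_2^* t_m} e^{-i2\pi\varphi t_m} + n_m,}
#' where \eqn{E_w, E_f} are the SPGR steady-state factors for the water and
#' fat T1, \eqn{a_j, f_j} are the fat spectral amplitudes and frequencies at
#' the protocol's field strength, and \eqn{n_m} is complex Gaussian noise
#' with independent `N(0, sigma^2)` real and imaginary parts.
#'
#' @param params A [tissue_params()].
#' @param protocol An [acq_protocol()].
#' @param spectrum A [fat_spectrum()] (default: the seven-peak liver model).
#' @param noise A [noise_model()] or `NULL` for a noiseless signal.
#' @param phase_sign Sign convention: `-1` (default) uses
#'   `exp(-i 2 pi phi t)` for the field term and `exp(+i 2 pi f_j t)` for
#'   the fat peaks; `+1` conjugates both.
#' @return Complex vector of length `length(protocol$te)`.
#' @export
#' @examples
#' s <- dixon_signal(tissue_params(f = 0.2, r2s = 40, phi = 30),
#'                   protocol_0p55t())
#' Mod(s)
dixon_signal <- function(params, protocol, spectrum = default_fat_spectrum(),
                         noise = NULL, phase_sign = -1) {
  stopifnot(inherits(params, "tissue_params"), inherits(protocol, "acq_protocol"))
  if (length(protocol$te) == 0) stop_invalid("protocol has no echoes")
  s <- dixon_signal_matrix(f = params$f, r2s = params$r2s, phi = params$phi,
                           rho = params$rho, protocol = protocol,
                           spectrum = spectrum,
                           t1_water = params$t1_water, t1_fat = params$t1_fat,
                           phase_sign = phase_sign)
  s <- as.vector(s)
  if (!is.null(noise) && noise$sigma > 0) {
    draw <- function() {
      ne <- length(s)
      complex(real = rnorm(ne, 0, noise$sigma),
              imaginary = rnorm(ne, 0, noise$sigma))
    }
    n <- if (!is.null(noise$seed)) with_seed(noise$seed, draw()) else draw()
    s <- s + n
  }
  s
}

## Vectorized noiseless signal synthesis: f, r2s, phi, rho are parallel
## vectors of voxel parameters; returns an Ne x N complex matrix.
dixon_signal_matrix <- function(f, r2s, phi, rho, protocol,
                                spectrum = default_fat_spectrum(),
                                t1_water = 339, t1_fat = 187,
                                phase_sign = -1) {
  t_s <- protocol$te / 1000
  ew <- spgr_factor(t1_water, protocol$tr, protocol$fa)
  ef <- spgr_factor(t1_fat, protocol$tr, protocol$fa)
  fm <- fat_modulation(spectrum, protocol$b0, t_s, phase_sign = -phase_sign)
  n <- max(length(f), length(r2s), length(phi), length(rho))
  f <- rep_len(f, n); r2s <- rep_len(r2s, n)
  phi <- rep_len(phi, n); rho <- rep_len(rho, n)
  ## Ne x N: (water + fat modulation) * decay * field phasor
  amp <- outer(rep(1, length(t_s)), (1 - f) * ew) +
    outer(fm, f * ef)
  decay <- exp(-outer(t_s, r2s)) *
    exp(1i * phase_sign * 2 * pi * outer(t_s, phi))
  amp * decay * outer(rep(1, length(t_s)), rho)
}
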
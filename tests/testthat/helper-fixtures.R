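## Shared fixtures: built in code, small enough to keep every test fast.

liver_protocol <- protocol_0p55t()
ref_protocol12 <- protocol_12echo_ref()
seven_peak <- default_fat_spectrum()

## complex Gaussian matrix with per-component SD `sigma`
rcnorm_mat <- function(p, q, sigma = 1) {
  matrix(complex(real = rnorm(p * q, 0, sigma),
                 imaginary = rnorm(p * q, 0, sigma)), p, q)
}

## tiny multi-echo image: smooth low-rank object + optional noise
tiny_me_image <- function(dims = c(8, 8, 6), protocol = liver_protocol,
                          f = 0.2, r2s = 40, sigma = 0, seed = NULL) {
  nvox <- prod(dims)
  s <- as.vector(dixon_signal(tissue_params(f = f, r2s = r2s, phi = 10),
                              protocol))
  arr <- array(rep(s, each = nvox), c(dims, length(s)))
  if (sigma > 0) {
    draw <- function() array(complex(real = rnorm(length(arr), 0, sigma),
                                     imaginary = rnorm(length(arr), 0, sigma)),
                             dim(arr))
    arr <- arr + if (is.null(seed)) draw() else with_seed_test(seed, draw())
  }
  multi_echo_image(arr, te = protocol$te)
}

with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

## small two-ring phantom that fits a 32x32x6 grid quickly
small_phantom <- function(dims = c(32, 32, 6)) {
  make_phantom(vials = vial_specs_default(dims), dims = dims)
}
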
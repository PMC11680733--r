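# pdffmap

Quantitative liver fat and iron imaging at low field strength works against
physics: at 0.55 T the equilibrium polarization is low, so proton-density
fat fraction (PDFF) and R2\* maps computed from multi-echo Dixon
acquisitions are noisy, and the smaller fat-water frequency difference
stretches the usable echo times. `pdffmap` is an R toolbox for studying and
improving that pipeline entirely in silico: it simulates multi-echo
chemical-shift-encoded signals and digital vial phantoms, designs
acquisition protocols by Monte Carlo simulation, denoises complex image
stacks with two locally low-rank patch methods, fits PDFF/R2\*/field maps
voxelwise, and scores accuracy and precision with the field's standard
agreement metrics. It is aimed at MR physicists and methods researchers who
want a reproducible, scanner-free testbed for low-field fat-water
quantification.

## The model

A spoiled gradient-echo voxel with fat fraction `F` produces at echo time
`t_m`

```
s(t_m) = rho * [ (1-F) E_w + F E_f * sum_j a_j exp(i 2 pi f_j t_m) ]
         * exp(-R2* t_m) * exp(-i 2 pi phi t_m) + n_m
```

with per-species SPGR steady-state factors
`E = sin(a) (1-E1)/(1-E1 cos a)`, `E1 = exp(-TR/T1)`, a seven-peak fat
spectrum `(a_j, f_j)`, a single R2\* decay, field offset `phi`, and complex
Gaussian noise. Fitting inverts this model by variable projection over the
complex water/fat amplitudes with a grid-plus-Levenberg-Marquardt search
over `(phi, R2*)`; image fitting adds a robust polynomial field-map
reference and per-region basin selection that suppresses fat-water swaps.
The two denoisers are RLLR (random-matrix calibration of the smallest
singular value, SURE-optimal singular-value soft thresholding on
coil-combined `[125 x Ne]` patches) and RMT (Marchenko-Pastur noise
estimation and optimal Frobenius shrinkage on multi-coil
`[125 x 2*Ne*Nc]` real patches).

## Worked example

```r
library(pdffmap)

protocol <- protocol_0p55t()       # TE = 2.16 ... 12.96 ms, TR 14.7, FA 8
inphase_opposed_te(0.55)
#> # A tibble: 1 × 2
#>   te_op_ms te_in_ms
#>      <dbl>    <dbl>
#> 1     6.47     12.9

## one noiseless voxel, fitted back
s <- dixon_signal(tissue_params(f = 0.2, r2s = 40, phi = 30), protocol)
fit_voxel(s, protocol)[, c("pdff", "r2s", "phi", "residual")]
#> # A tibble: 1 × 4
#>    pdff   r2s   phi  residual
#>   <dbl> <dbl> <dbl>     <dbl>
#> 1  21.4    40    30   6.94e-18
```

The fitted PDFF of 21.4% against a true fat fraction of 20% is not an
error: the fit recovers `R2*` and `phi` exactly (residual ~1e-18) but
reports the *apparent* fat fraction, which carries the SPGR T1-weighting
bias (+1.4 points here; water and fat T1 differ). That bias is exactly what
the protocol-design study trades against SNR when choosing the flip angle.

```r
## the chosen-protocol Monte Carlo study (500 instances per node, aSNR 10)
sigma <- calibrate_noise_sigma(protocol, target_asnr = 10)
mc <- run_mc_grid(mc_grid(), sigma, seed = 1)
summarize_mc(mc)
#>      fa   te1   dte max_abs_pdff_bias max_pdff_sd max_abs_r2s_bias max_r2s_sd
#> 1     8  2.16  2.16              1.99        6.96             2.07       28.1
```

Maximum PDFF bias just under 2 percentage points (T1-dominated, at
PDFF 40%), maximum PDFF SD about 7 points, R2\* bias within about
2 s^-1. The R2\* SD at high reference R2\* sits at the Cramér-Rao bound of
the six-echo acquisition (about 27 s^-1 at R2\* = 90).

```r
## digital vial phantom, 20 repetitions, with and without denoising
phantom <- make_phantom()          # 64 x 64 x 8, 7 PDFF + 10 R2* vials
rx <- repetition_experiment(phantom, protocol, n_reps = 20, seed = 101)
rx$sd_change[, c("method", "pdff_sd_change_pct", "r2s_sd_change_pct",
                 "frac_pdff_sd_reduced")]
#>   method pdff_sd_change_pct r2s_sd_change_pct frac_pdff_sd_reduced
#> 1   rllr              -82.3             -79.8                    1
#> 2    rmt               -84.5            -90.1                    1
```

Both denoisers cut the voxelwise SD of PDFF and R2\* across repetitions by
roughly 80-90% in every quantifiable object voxel, while vial-mean PDFF and
R2\* agree with ground truth at concordance correlation above 0.998. The
full experiment takes on the order of fifteen minutes on one core.

Plot helpers: `autoplot(mc, metric = "pdff_sd")`, `autoplot(maps)`,
`plot_bland_altman()`; tidiers: `tidy()`/`glance()` on maps, agreement
reports and repetition experiments. Shell front-ends for the two studies
live in `inst/cli/`.

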
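# blochsort

Fast quantitative T1rho and T1rho-dispersion mapping for spin-lock-prepared
**golden-angle radial** MRI, built around three ideas:

1. **High-flip-angle readout trains.** With only a few gradient-echo
   readouts per preparation (short diastolic window) and long recovery
   times (respiratory gating), signal is maximized by large flip angles:
   without relaxation the mean signal of an `NR`-pulse train,
   `sum_k sin(a) cos(a)^(k-1)`, peaks at **43.51°** for `NR = 4`; the full
   Bloch simulation with incomplete recovery moves the optimum to
   **39.35°** for myocardial parameters.
2. **Bloch sorting.** High flip angles make successive readouts decay
   strongly, so golden-angle indices `N` (projection angle
   `N * 360°/(1+sqrt(5))`) are assigned in order of the Bloch-*predicted*
   signal rather than chronologically — azimuthally adjacent spokes then
   carry nearly equal signal and streaking collapses.
3. **KWIC view sharing.** Each T1rho weighting's k-space center is filled
   exclusively by the 13 first readouts after its own preparation (correct
   contrast), while the periphery is shared with golden-index neighbors in
   Fibonacci-count annuli (13, 21, 34, 55, ...) that always satisfy the
   azimuthal Nyquist condition `n_phi > pi * r * f_nyq`.

Pixel-wise mono-exponential fitting `S = S0 exp(-t_SL / T1rho)` and the
linear dispersion model `T1rho(f_SL) = T1rho0 + m1rho * f_SL` (ms, ms/kHz)
turn the reconstructed series into parameter maps. Digital phantoms (a
four-tube BSA relaxometry phantom and a cardiac-like ring) plus a radial
k-space forward simulator make the whole chain testable without scanner
data. Reconstruction uses a Kaiser–Bessel gridding NUFFT with angular-cell
ramp density compensation; a direct nonuniform-DFT path serves as the
numerical oracle.

Intended users: MRI methods researchers who want a desk-scale, fully
reproducible implementation of signal-ordered radial sampling and
view-sharing relaxometry to study sampling/reconstruction trade-offs.

## Worked example

Flip-angle optimization for the myocardial protocol:

```r
library(blochsort)
optimize_flip_report(sequence_params(), tissue_params(T1 = 1400, T1rho0 = 40))
#> Readout flip-angle optimization (NR = 4)
#>   protocol: TR = 5 ms, t_rec = 1500 ms, t_SL = 4, 12, 20, 28, 36, 44, 52, 60 ms
#>   tissue:   T1 = 1400 ms, T1rho(f_SL = 1500 Hz) = 40 ms
#>   relaxation-free optimum: 43.51 deg
#>   Bloch-simulated optimum: 39.35 deg
```

End-to-end phantom experiment — simulate the four-tube BSA phantom on the
published protocol (13 × 8 preparations, 416 spokes, matrix 128),
reconstruct with KWIC, fit T1rho, and score each tube interior against the
matched fully-sampled reference reconstruction:

```r
seqp <- sequence_params(matrix = 128, t_rec = 1000,
                        t_SL_list = seq(4, 102, length.out = 8))
ph  <- make_bsa_phantom(matrix = 128)
pat <- build_pattern(seqp, tissue_params(T1 = 1400, T1rho0 = 60), mode = "bloch")
ks  <- simulate_kspace(ph, pat)
map <- fit_t1rho(reconstruct_series(ks, design_kwic(pat)))
ref <- fit_t1rho(reference_series(ph, pat))
ras <- rasterize_phantom(ph)
for (i in 1:4) {
  roi <- erode_mask(ras$masks[[i]], 2)
  print(delta_q(map, ref, roi, label = ph$shapes[[i]]$label))
}
#> ROI 10%: dQ = -0.20 +- 6.57 % (n = 2097)
#> ROI 15%: dQ = +0.03 +- 6.66 % (n = 2097)
#> ROI 20%: dQ = +0.58 +- 6.80 % (n = 2097)
#> ROI 25%: dQ = +3.20 +- 7.83 % (n = 2097)
```

Each line is the pixel-wise relative T1rho error (mean ± std, percent)
inside one tube, longest T1rho (10% BSA) to shortest (25%): accurate to
within a few percent, with the characteristic slight underestimation of
long and overestimation of short T1rho that view sharing produces. A full
run — including NIfTI maps, schedule tables, k-space bundles, a dispersion
slope/offset map when several spin-lock amplitudes are configured, and a
run manifest — goes through `run_config()` + `run_pipeline()`, or the
command-line wrapper in `inst/cli/blochsort.R`.

The methods vignette (`vignettes/blochsort-methods.Rmd`) documents the
signal model, the filter design rules, all tunable parameters with units
and defaults, and what the phantom validation does and does not show.

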
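# boutonkit

Quantitative analysis of synaptic vesicle (SV) recycling from
pHluorin time-lapse microscopy, and of presynaptic bouton morphology from
fixed-tissue images — for neuroscientists quantifying exo/endocytosis,
recycling-pool size, SV dispersion and reporter enrichment at synapses.

Synaptophysin-pHluorin (sypHy) is quenched inside acidic SVs and fluoresces
upon exocytosis; endocytosis and re-acidification re-quench it, and NH₄Cl
perfusion reveals the total reporter pool (F_max). boutonkit implements:

* **Puncta detection** — iterative threshold descent with area and roundness
  (4πA/P² > 0.7) filtering and blanking of accepted objects, plus 2×2
  center-of-mass peak intensities and control-based session normalization.
* **ΔF/F₀ kinetics** — baseline normalization (F₀ = mean of 6 pre-stimulation
  frames), non-responder exclusion, trace averaging with SEM, peak ΔF/F₀, and
  the endocytosis decay fit *y = y₀ + A·e^(−t/τ)* over 32 frames (160 s)
  starting 5 s after stimulation cessation, discarding fits with τ > 160 s.
* **Recycling-pool fraction** — under bafilomycin, the baseline-subtracted
  saturation plateau (last three pre-NH₄Cl frames) over baseline-subtracted
  F_max.
* **Morphometry** — Gaussian line-profile fits
  *F(x) = F_axon + F_syn·e^(−(x−x_c)²/2w²)*, FWHM = 2√(2 ln 2)·σ ≈ 2.355σ,
  per-experiment FWHM means, and two-channel synaptic enrichment
  *E% = ((F_syn/F_axon)_red / (F_syn/F_axon)_blue − 1)·100*.
* **Gated statistics** — Shapiro-Wilk-gated choice among Student's t,
  Mann-Whitney U, ANOVA+Tukey and Kruskal-Wallis+Dunn, with Grubbs outlier
  screening.
* **A synthetic-data generator** (traces, bouton fields, time-lapse stacks,
  two-channel profiles) with machine-readable ground truth and seeded noise,
  so the whole pipeline is testable without microscope data.

All user-facing functions take data frames first and return tibbles, so
stages chain with the pipe; fitted objects support `tidy()`/`glance()` and
`autoplot()`.

## Worked example

Simulate a 30-ROI sypHy experiment (15 s of 20-Hz stimulation, 50 frames,
per-ROI peak SNR 10), normalize, filter, average and fit the endocytosis
decay:

```r
library(boutonkit)
library(dplyr)

prot   <- protocol_standard()
params <- kinetic_params(tau_endo = 30)      # ground-truth tau = 30 s

mt <- simulate_experiment(params, prot, n_roi = 30, noise_snr = 10, seed = 42) |>
  compute_dff(prot) |>
  exclude_nonresponders(prot) |>
  average_traces()

peak_dff(mt, prot)
#> [1] 1.029334

fit_endocytosis(mt, prot)
#> <decay_fit> y = y0 + A exp(-t/tau)
#>   y0 = 0.009525, A = 1.805, tau = 28.71 s (valid)
#>   residual RMS 0.02 over 32 frames
```

The peak ΔF/F₀ of ~1.03 means fluorescence roughly doubled at the response
maximum; the fitted τ of 28.7 s recovers the generating 30-s endocytosis
time constant, and the fit is kept because τ ≤ 160 s. A bafilomycin
experiment recovers the generating recycling-pool fraction (0.45):

```r
baf <- kinetic_params(k_exo = 0.025, bafilomycin = TRUE)
btr <- simulate_experiment(baf, protocol_bafilomycin(), n_roi = 30,
                           noise_snr = 10, seed = 42) |>
  group_by(frame) |> summarise(time = time[1], raw_f = mean(raw_f))

recycling_pool_fraction(btr, protocol_bafilomycin())
#> <pool_fraction>
#>   recycling pool fraction = 0.450
#>   baseline 45.09, plateau 473.2, F_max 996.1
```

Detection on a synthetic bouton field with known ground truth:

```r
cfg <- random_scene(n_boutons = 15, image_shape = c(256, 256), sigma = 2,
                    amplitude = 150, offset = 20, noise_gaussian_sd = 30,
                    noise_poisson = TRUE, seed = 1)
sc     <- render_scene(cfg)
puncta <- detect_puncta(sc$image)
match_puncta(puncta, sc$truth)[c("precision", "recall")]
#> $precision
#> [1] 1
#> $recall
#> [1] 1
```

`run_pipeline()` chains simulation → detection → ROI extraction → kinetics
end to end with provenance, and `vignettes/bouton-analysis.Rmd` documents the
models, parameter choices and their rationale.

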
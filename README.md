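# t2relax

Multi-compartment transverse-relaxation (T2) analysis of multi-echo
magnitude MRI, built around ex-vivo breast-tumour specimens.

Water in tumour tissue decays at compartment-specific rates: the crowded
intra-cellular pool has a short T2, the extra-cellular pool a long one.
From a multi-echo acquisition (24 echoes, first echo 13 ms, 13 ms spacing
by default) the package estimates, voxel by voxel:

- **T2,MONO** — the overall T2 from the single-compartment fit
  `S(TE) = S0 · exp(−TE/T2)`, by non-linear least squares;
- **T2S, T2L, f** — short (intra-cellular) and long (extra-cellular) T2
  and the intra-cellular signal fraction from the two-compartment model
  `S(TE) = S0 · [f · exp(−TE/T2S) + (1−f) · exp(−TE/T2L)]`, with a
  Bayesian algorithm that couples neighbouring voxels through an intrinsic
  Gaussian Markov random field prior on the transformed parameters
  (Metropolis-within-Gibbs, compiled sampler) — or by independent-voxel
  multistart NLLS as the baseline it is measured against.

Whole-tumour ROI means (necrotic regions and failed fits excluded), the
volume ratio `100 · mean(f)`, and Ki-67 dichotomization (high iff
strictly > 14 %) produce one record per specimen; the statistics stage
runs Shapiro–Wilk-gated t / Mann–Whitney group comparisons and
Pearson/Spearman correlations against tumour diameter and the Nottingham
Prognostic Index, producing a compact report.

Because no specimen scans are distributed, the package ships a seeded
simulator: multi-echo phantoms with known piecewise-constant compartment
structure, Rician noise and an excludable necrotic core, plus a
20-specimen synthetic cohort (11 low / 9 high Ki-67) calibrated to the
emulated study's group statistics.

## Worked example

```r
library(t2relax)

cohort <- make_cohort(seed = 1)   # 11 low / 9 high Ki-67 specimens
report <- build_report(cohort)
report
```

```
Relaxometry report (n = 11 low / 9 high Ki-67, alpha = 0.05)

  T2,MONO (ms) low  76.93 +/- 11.95 | high  82.86 +/-  2.73 | t p = 0.164
  T2S (ms)     low  64.91 +/- 11.90 | high  72.75 +/-  8.48 | t p = 0.115
  T2L (ms)     low 161.22 +/- 18.61 | high 152.79 +/-  6.38 | mann-whitney p = 0.067
  f (%)        low  41.67 +/- 11.92 | high  29.62 +/-  5.96 | t p = 0.013 *
```

Each row is one relaxometry outcome: group mean ± SD per Ki-67 group, the
test the normality gate selected, and its two-sided p-value (`*` flags
p < 0.05). With n = 20 the p-values move considerably between seeds; the
generating group means (73.30/83.55 ms for T2,MONO, 61.30/73.52 for T2S,
156.56/147.38 for T2L, 41.65/33.64 % for f) are recovered within sampling
error.

Image-level pieces compose the same way:

```r
ph  <- make_phantom(shape = c(32, 32, 1), snr = 50, seed = 1)  # noisy specimen
mono <- fit_mono_image(ph$signal, ph$tumour_mask, ph$schedule)
bi   <- fit_bi_bayes_image(ph$signal, ph$tumour_mask, ph$schedule,
                           bi_fit_config(seed = 1))
summarize_specimen(mono, bi, ph$tumour_mask, ph$necrosis_mask)
autoplot(bi)        # f / T2S / T2L maps
tidy(bi)            # one row per voxel
```

`run_pipeline(run_config(...))` chains
simulate → fit-mono → fit-bi → summarize → stats end to end with one
global seed, and `inst/cli/t2relax` exposes the stages as shell
subcommands. The methods vignette
(`vignettes/t2-compartment-modelling.Rmd`) documents the model, the
priors, the calibration of the spatial scale, and the accuracy limits at
low SNR.

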
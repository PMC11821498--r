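---
title: "Multi-compartment T2 relaxometry: models, priors, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-compartment T2 relaxometry: models, priors, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(t2relax)
```

## The problem

Water in tumour tissue relaxes at different rates depending on its
micro-environment: intra-cellular water, crowded by macromolecules, has a
shorter transverse relaxation time (T2) than the freer extra-cellular pool.
A multi-echo acquisition samples the decay curve at a train of echo times;
fitting compartment models to that curve, voxel by voxel, yields maps of
the short (intra-cellular) T2, the long (extra-cellular) T2, and the
intra-cellular signal fraction, alongside the overall T2 of a
single-compartment fit. Whole-tumour means of these maps can then be
compared between groups of specimens — here, tumours dichotomized by the
Ki-67 proliferation index (high if strictly more than 14 % of nuclei stain
positive).

`t2relax` implements the full chain: a seeded simulator of multi-echo
specimen images with known compartment structure, the voxel-wise fitters,
whole-tumour summarization with necrosis exclusion, and the
normality-gated group statistics.

## Signal models

With echo times $TE_k$ (default: 24 echoes, first echo 13 ms, spacing
13 ms, matching the emulated specimen protocol), the single-compartment
model is

$$S(TE) = S_0 \, e^{-TE/T_2},$$

and the two-compartment model, with no water exchange between pools, is

$$S(TE) = S_0\left[ f\, e^{-TE/T_{2S}} + (1-f)\, e^{-TE/T_{2L}} \right],
\qquad 0 \le f \le 1,\; T_{2S} \le T_{2L}.$$

The short component is identified with the intra-cellular pool, so $f$ is
directly the per-voxel intra-cellular volume (signal) fraction; its
whole-tumour mean, times 100, is the "volume ratio" outcome. The decay
equations are the standard mono- and bi-exponential forms; the protocol
this package emulates did not print its equations, so these conventional
forms are assumed and stated here explicitly.

Amplitudes are parameterized as $(S_0, f)$ rather than as two separate
compartment amplitudes because $f$ is itself the reported outcome. All
times are in milliseconds, signals in arbitrary units.

## Voxel-wise fitting

**Single-compartment.** Ordinary least squares on $\log S$ over echoes
above $10^{-3} \cdot \max S$ gives the initializer (the log-model is affine
in TE with slope $-1/T_2$); Levenberg–Marquardt refines it with box bounds
on $T_2$ (default (1, 1000] ms). The refined fit never ends worse than its
initializer. No echo weighting and no noise-floor offset term is applied;
whether the original analysis excluded echoes is unstated, so none are.

**Two-compartment, independent voxels.** Multistart Levenberg–Marquardt on
the unconstrained scale
$\eta = (\log S_0,\ \mathrm{logit} f,\ \log T_{2S},\ \log(T_{2L}-T_{2S}))$,
which enforces every invariant by construction — no rejection steps, no
label switching. The first start derives from the voxel's mono fit
($f = 0.5$, $T_{2S} = 0.7\,T_2$, $T_{2L} = 1.6\,T_2$); the rest are seeded
jitters. Bi-exponential least squares has a flat cost valley wherever the
two compartments barely differ, so near-degenerate solutions ($f$ outside
(0.01, 0.99) or $T_{2L}/T_{2S} < 1.05$) are flagged, not masked.

**Two-compartment, spatially regularized.** The headline fitter couples
neighbouring voxels through probabilistic constraints. The hierarchical
model is

- likelihood: $y_v \sim \mathcal N\big(S(\theta_v),\ \sigma^2 I\big)$ per
  in-mask voxel, with one shared noise variance;
- spatial prior: each transformed channel $\eta_{v,p}$ follows an intrinsic
  first-order Gaussian Markov random field on the mask-interior neighbour
  graph — conditionally,
  $\eta_{v,p} \mid \text{neighbours} \sim
  \mathcal N(\bar\eta_{N(v),p},\ \tau_p^2 / |N(v)|)$;
- anchors: each channel additionally carries a weakly informative Gaussian
  prior, SD $(3, 3, 2, 2)$, centred on robust mono-fit statistics of the
  image ($S_0$ at the mono amplitude, $f$ at $1/2$, $T_{2S}$ at
  $0.7\times$, and the $T_{2L}-T_{2S}$ gap at $0.9\times$ the median
  overall T2);
- hyperprior: Jeffreys on $\sigma^2$, giving a conjugate inverse-gamma
  Gibbs update.

Sampling is Metropolis-within-Gibbs in compiled code: one random-walk
update per voxel and channel per sweep, plus one *global-shift* Metropolis
move per channel (all voxels moved together — the intrinsic GMRF is
invariant under such shifts, so the collective likelihood decides; this
mixes the channel's global level, by far the slowest mode of a single-site
sampler on a coupled field). Proposal scales adapt toward roughly 30 %
acceptance during burn-in only and are frozen afterwards, so the retained
draws satisfy detailed balance. Chains start at the voxel-wise NLLS
estimate, clamped to physical ranges. Defaults: 4000 sweeps, 2000 burn-in;
the point estimate is the posterior mean of $\eta$, back-transformed
(posterior median and best-likelihood-sweep estimators are available);
posterior SD maps, acceptance-rate and split-chain convergence maps are
always returned, and non-identifiable voxels surface as large posterior
spread rather than holes.

### Why the anchors exist

Without them the posterior is improper: as
$\log(T_{2L}-T_{2S}) \to -\infty$ or $\mathrm{logit}\,f \to \pm\infty$ the
two-compartment curve tends to a mono-exponential limit with a positive,
flat likelihood, so a translation-invariant prior puts infinite mass in the
compartment-merging cone and chains drift into it without bound (we
observed exactly this drift before adding the anchors). The anchor widths
are broad — two to three log-units — so identifiable voxels are essentially
unconstrained.

### Why the spatial scale is fixed rather than sampled

The natural fully Bayesian treatment samples $\tau_p^2$ under a
Jeffreys-type hyperprior. In practice that joint chain descends a funnel:
smoothing shrinks the field's neighbour differences, which shrinks the
sampled $\tau_p^2$, which smooths harder, and the chain settles in an
over-smoothed state whose residual sum of squares is roughly twice that of
the ground truth. The default therefore fixes $\tau_p = 0.2$ on the
transformed scale (about 20 % relative variation between neighbours),
calibrated on simulated phantoms as the bias/variance compromise;
`tau = "empirical"` (matched to the initial field's roughness) and
`tau = "gibbs"` (the hierarchical update, with its caveat) remain
available.

### Accuracy limits at low SNR

Two facts, both verifiable with the package, bound what any fitter can do
on this problem. First, the Cramér–Rao bound: at first-echo SNR 50 with the
24-echo protocol, even an oracle that pools a 160-voxel homogeneous region
perfectly has a standard deviation of about 0.05 in $f$ and about 7 % in
$T_{2S}$ when the compartments are separated by the cohort-typical factor
of two; the bound relaxes quickly as the separation grows. Second, the
posterior at SNR 50 carries a curved-ridge marginalization skew of order
$+3$ ms in $T_{2S}$ and $+8$ ms in $T_{2L}$ that is invisible at SNR 150
and above — a property of the model's likelihood geometry, not of the
sampler (posterior mean, median and maximum all carry it). Region-mean
recovery at SNR 50 is therefore accurate to roughly 5–8 % for $T_{2S}$,
2–6 % for $T_{2L}$ and 0.02–0.05 absolute in $f$ for well-separated
compartments, and degrades when $T_{2L}/T_{2S}$ approaches 1. The
noise-robustness gain over independent-voxel NLLS is, by contrast, large
and robust: RMSE ratios of 0.05–0.2 at SNR 25–50.

## The synthetic phantom and cohort

`make_phantom()` builds a spatially coherent digital specimen: a disk
tumour (optionally split into parameter bands, or any list of
non-overlapping disk regions), an optional necrotic core, the noiseless
closed-form signal at every voxel, and magnitude noise. The necrotic core
is simulated as a long-T2, high-amplitude region so that excluding it
measurably changes the ROI means — making the exclusion logic testable.
Defaults: a single 64×64 slice at 2.2 mm nominal spacing (the emulated
in-plane resolution; specimens were imaged slice-wise, so the default
neighbourhood is in-plane 4-neighbour, with a volumetric 6-neighbour
option), band parameters drawn uniformly from $T_{2S} \in [45, 95]$ ms,
$T_{2L} \in [125, 185]$ ms, $f \in [0.20, 0.60]$ — the cohort's span.

Noise is Rician by default (magnitude MRI):
$\tilde S = \sqrt{(S+\varepsilon_1)^2 + \varepsilon_2^2}$ with independent
Gaussian channels; Gaussian noise is available for fitter unit tests where
unbiased residuals are wanted. The emulated protocol reports no noise
level, so SNR is a free simulation parameter, defined on the mean in-tumour
first-echo signal (default 50) — a choice, not a measured fact. The
Gaussian likelihood of the Bayesian fitter mismatches the Rician floor at
very low SNR; at the default SNR the first-echo floor bias is below one
percent, and it is documented as a limitation rather than corrected.

`make_cohort()` draws the 20-specimen cohort: 11 low / 9 high Ki-67, each
outcome Normal per group (truncated to physical ranges, compartment
ordering enforced by redrawing) with the emulated study's group means and
SDs as defaults, Ki-67 uniform within (1, 14] for the low and (15, 60) for
the high group, diameters and NPI from the cohort demography. The
ground-truth overall T2 is drawn directly from its own group statistics
rather than derived from $(f, T_{2S}, T_{2L})$, because the study treats it
as an independent outcome with its own model; consequently, in end-to-end
phantom runs the *fitted* overall T2 is the effective mono-T2 of the
bi-exponential decay (always between $T_{2S}$ and $T_{2L}$), not the drawn
value — the structural test asserts exactly that bracketing.

What the generator does **not** emulate: real anatomy, partial-volume
mixing at boundaries, B1/stimulated-echo effects, coil profiles, any
correlation between relaxometry and the clinical covariates (diameter,
NPI). Passing tests therefore demonstrate the correctness of the
estimation and statistics machinery under the stated noise model — not
that the biological effect sizes would reproduce in new specimens.

## ROI summarization

Whole-tumour values are arithmetic means over tumour-mask voxels with
necrotic voxels and invalid fits excluded; the count of excluded voxels is
recorded per specimen. The volume ratio is the mean of the per-voxel $f$
(times 100): the mean-of-voxel-fractions reading of "intra-cellular volume
over total volume". The alternative — ratio of summed compartment volumes,
i.e. an $S_0$-weighted mean — is a one-line variant but is not the default,
since per-voxel $f$ is already the intra/total fraction and the tumour
$S_0$ is nearly uniform in the emulated data. Ki-67 exactly 14 % classifies
as low (strict "more than 14 %" rule).

## Group statistics

Per outcome (volume ratio, overall, intra- and extra-cellular T2):
Shapiro–Wilk in each Ki-67 group at $\alpha = 0.05$ gates the comparison —
Student's t (pooled variance; Welch by flag) when both groups are
compatible with normality, Mann–Whitney U otherwise (exact p for combined
$n \le 25$, which covers the 20-specimen design; normal approximation with
tie correction beyond). Correlations against tumour diameter are Pearson or
Spearman by the same normality logic on the outcome; correlations against
NPI are always Spearman, NPI being an ordinal-ish composite index. No
multiple-testing correction is applied, each test read at $\alpha = 0.05$ —
a faithful-reproduction choice mirroring the emulated analysis, not a
recommendation. Groups smaller than three (possible in reduced synthetic
runs) skip the gate and take the rank-based route.

```{r report, eval = FALSE}
cohort <- make_cohort(seed = 1)
report <- build_report(cohort)
report
autoplot(report, cohort)
```

## Pipeline and reproducibility

`run_pipeline()` chains simulate → fit-mono → fit-bi → summarize → stats,
writing cohort/records/report CSVs and a JSON manifest (config, seeds,
package version) under one output directory; existing stage outputs are
reused with `resume = TRUE`. One global seed deterministically derives
per-stage, per-specimen seeds, so the full run — including the MCMC — is
bit-reproducible. A thin command-line wrapper with `simulate`, `fit-mono`,
`fit-bi`, `summarize`, `stats` and `run-all` subcommands ships in
`inst/cli/`; images are NIfTI-1, tables CSV, configuration YAML.

Default problem sizes keep the simulation studies small — 24–32 voxel
grids, 2000–4000 sweeps, 20 specimens — chosen so that each benchmark runs
in seconds to a few minutes on one CPU while leaving the Monte-Carlo error
well below the tolerances being checked.

## Known limitations

- Gaussian likelihood on Rician magnitudes: negligible at the default SNR,
  increasingly biased below SNR ~20.
- Two compartments, fixed: no luminal/third pool, no exchange, no
  continuous T2 spectra.
- The spatial prior smooths across region boundaries over a width of one
  to two voxels; very small structures (a few voxels) inherit their
  surroundings.
- Low-SNR marginalization skew as quantified above; report posterior
  spread alongside point maps.
- Masks are inputs: no segmentation is attempted, and histology
  co-registration is out of scope.
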
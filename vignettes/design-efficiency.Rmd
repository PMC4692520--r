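---
title: "Choosing SOA and single-trial GLM under trial-to-trial variability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Choosing SOA and single-trial GLM under trial-to-trial variability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soaopt)
```

## The problem

Rapid event-related fMRI designs overlap the BOLD responses of successive
trials, and the evoked amplitude itself fluctuates from trial to trial —
through attention, arousal, or genuine stimulus differences. Classical
design-efficiency theory ignores that second source of variability and
therefore answers only part of the design question. This package simulates
the full generative process and asks, by Monte Carlo, which stimulus onset
asynchrony (SOA) and which single-trial GLM estimate most precisely the
quantity a study actually cares about:

* the **mean response** of a condition (univariate contrasts),
* the **response of each individual trial** (beta-series connectivity),
* the **pattern of trial responses across voxels** (MVPA).

## Generative model

A session of duration $D$ seconds is sampled every TR. Trial $j$ of type
$k$ occurs at onset $o_j$ (fixed SOA, types randomly intermixed) with true
amplitude

$$\beta_{j} \sim \mathcal{N}(\mu_k,\ \sigma_{\mathrm{trial}}^2),$$

and the voxel timeseries is

$$y(t) = \sum_j \beta_j\, h(t - o_j) + \varepsilon(t), \qquad
  \varepsilon(t) \sim \mathcal{N}(0,\ \sigma_{\mathrm{scan}}^2)\ \text{i.i.d.},$$

where $h$ is the canonical double-gamma HRF scaled to peak height 1, so
amplitudes and scan noise share one unit and the amplitude SNR is simply
$\mu_k / \sigma_{\mathrm{scan}}$. Defaults follow the reference simulation
conditions throughout: TR 1 s, 45-min sessions, SOA grid 2–24 s in 1-s
steps, $\mu_1 = 3$ (and $\mu_2 = 5$ for two-type designs),
$\sigma_{\mathrm{trial}} \in \{0, 0.5, 0.8, 1.6, 3\}$,
$\sigma_{\mathrm{scan}} \in \{0.5, 0.8, 1.6, 3\}$ (SNRs 6, 3.8, 1.9, 1).
Amplitudes are deliberately not clipped: with $\mu = 3$,
$\sigma_{\mathrm{trial}} = 3$ the Gaussian model implies occasional
negative responses.

The HRF is evaluated directly from the closed-form difference of gamma
densities (response delay 6 s, undershoot delay 16 s, unit dispersions,
undershoot ratio 1/6, 32-s support) at multiples of the TR. Because the
formula is closed-form, evaluating at a fine microtime grid and decimating
to the scan grid would give identical samples, so no intermediate grid is
used. The kernel is rescaled so the maximum *sampled* value is exactly 1;
off-grid onsets are supported by sampling the continuous shape at scan
times with the same scale factor.

## The competing estimators

All models share a final constant regressor and, optionally, the nuisance
set described below; they differ only in how trials enter the design:

* **LSU** — one regressor per trial type. Trial variability is relegated
  to the residual; only condition means are estimable.
* **LSA** — one regressor per trial in a single GLM; the coefficient
  sequence is the beta series. Optionally ridge-regularized:
  $\hat\beta = (X^\top X + \lambda D)^{-1} X^\top y$ with $D$ selecting
  the *task* columns only. Penalizing the constant (or the drift
  regressors) would bias every estimate towards an arbitrary signal zero,
  so nuisance columns are exempt; this is a package decision where the
  defining equation's identity matrix was read as acting on the
  parameters of interest.
* **LSS-1 / LSS-N** — one GLM per target trial; non-targets collapse into
  one aggregate regressor (LSS-1) or one per type (LSS-N, i.e. LSS-2 for
  two types). Only the target coefficient of each fit is kept. All
  nuisance columns are included in every per-target GLM.

Ordinary least squares is solved by QR decomposition, never by inverting
the normal equations; a rank-deficient design is reported as an error
naming the collinear columns rather than silently pivoting, because at
SOA 2 s an LSA design has well over a thousand strongly overlapping
columns and silent dropping would corrupt the beta series.

### Nuisance handling

Two optional components mirror common practice:

* **Transient trimming** — the first and last 32 s of data are discarded,
  only trials whose complete HRF fits the retained window are modeled,
  and a *single* covariate of no interest (the summed regressors of all
  boundary-crossing trials) absorbs the partial responses.
* **High-pass filtering** — a DCT basis with all cosine orders up to
  $\lfloor 2\,n\,\mathrm{TR}/128 \rfloor$ (cutoff 128 s) is appended to
  the design.

## Efficiency metrics

With $N$ replicate simulations indexed by $i$, $M$ modeled trials, and
per-trial estimates $\hat\beta_{ij}$:

$$\mathrm{PPM} = \Big[\operatorname{std}_i \tfrac1M \textstyle\sum_j
  \hat\beta_{ij}\Big]^{-1}, \qquad
  \mathrm{PSM} = \Big[\operatorname{std}_i \tfrac1M \textstyle\sum_j
  (\hat\beta_{ij} - \beta_{ij})\Big]^{-1}, \qquad
  \mathrm{PSC} = \tfrac1N \textstyle\sum_i
  \operatorname{cor}_j(\hat\beta_{ij}, \beta_{ij}).$$

PPM scores the estimate of the *population* mean (trials are exchangeable
noise); PSM scores the estimate of the *realized sample* mean (each
trial's identity matters); PSC scores trial-level recovery and is the
quantity relevant to beta-series connectivity. For LSU the "mean
estimate" is the condition coefficient itself; for two-type designs every
metric is applied to the difference contrast (type 1 minus type 2), with
per-type means taken over each type's fully modeled trials. PSC requires
per-trial estimates and positive trial variability, and refuses anything
else explicitly.

Conventions fixed for reproducibility where the definitions are silent:
sample standard deviations use the $N-1$ denominator and correlations the
matching sample convention (immaterial at $N = 10{,}000$, visible in toy
tests); a zero across-replicate standard deviation is reported as the
infinite-precision sentinel `Inf` — never an error, never dropped — and
heatmaps render it at the color-map maximum.

Classification performance (CP) scores pattern recovery: two sessions are
simulated independently with shared amplitude means, single-trial
patterns are estimated per voxel, and a linear soft-margin SVM (cost 1,
no feature scaling — two voxels in common units) is trained on one
session and tested on the other, both ways, accuracies averaged. Trial
variability and scan noise can each be **coherent** (one sample shared by
all voxels) or **incoherent** (independent samples per voxel); the 2×2
factorial spans the extremes between which real spatial correlation
interpolates. LSS-N uses label knowledge for its non-target regressors,
which is unbiased here because folds are separate sessions; LSS-1 is
provided for single-session use.

## Sweeps, seeding and reproducibility

`run_sweep()` iterates `run_cell()` over the model × SOA × trial-SD ×
scan-SD grid. Every replicate derives three sub-seeds (label, amplitude,
noise streams) from the master seed and its cell coordinates through a
base-31 rolling hash reduced modulo $2^{31}-1$, so any cell is
reproducible in isolation, metrics requested together share one
replicate ensemble, and execution order (or parallel scheduling) cannot
change results. Within a cell the design matrix — and its QR or Cholesky
factorization — is computed once whenever it does not depend on the
random label sequence (LSA always; single-type LSU/LSS); that caching is
what makes full 23-SOA sweeps interactive, and a dedicated test pins the
cached paths to the plain per-replicate estimator.

`argmax_soa()` reports the maximizing SOA with ties broken towards the
longer SOA (longer SOAs cost less collinearity for equal efficiency) and
a flatness diagnostic: all SOAs within one Monte-Carlo standard error of
the maximum. The efficiency surfaces are genuinely flat near their
optima — the trial-SD-0 PPM curve varies by under 1% across SOAs 16–19 —
so a single-integer argmax should always be read alongside that set.

## Problem sizes

Two named profiles are shipped. `sweep_profile("reference")` is the full
protocol (45-min sessions, $N = 10{,}000$). `sweep_profile("desk")`
(15-min sessions, $N = 500$) preserves the optima — which are governed by
the ratio of the variabilities and the HRF bandpass, not by session
length — at interactive cost, and is what the test suite and the
acceptance script build on; where a flat plateau must be resolved to 1 s
the replicate count is raised into the thousands instead of lengthening
sessions, which is the cheaper axis for LSU/LSA cells whose designs are
cached.

## What the simulations do and do not emulate

The generator reproduces the structure the efficiency question turns on:
convolutional signal overlap, Gaussian trial-amplitude variability,
Gaussian scan noise, session-edge transients, and voxel-wise coherence of
each variability source. It deliberately omits temporally autocorrelated
(colored) noise, low-frequency drift, physiological noise, hemodynamic
nonlinearity, HRF shape variability and variable-duration (epoch) events.
Consequently, passing tests establish the *relative* efficiency ordering
of designs and estimators under white noise and a known canonical HRF;
absolute precision values in real data, where low-frequency noise
dominates, will differ — the DCT option models the analysis response to
such noise, not the noise itself. Statistical significance of single
fits (T-statistics, effective degrees of freedom) is out of scope by
construction: only the sampling precision of the point estimates across
realizations is measured.

## Worked example

```{r example, eval = FALSE}
hrf <- canonical_hrf(1)
sch <- generate_schedule(soa = 6, session_duration = 900, n_types = 1)
ses <- simulate_session(sch, amplitude_spec(3, trial_sd = 1.6), hrf,
                        scan_sd = 0.8, amp_seed = 1, noise_seed = 2)
fit <- trial_glm(ses$y, sch, model = "lsa")
summary(fit)

cfg <- sweep_profile("desk", soas = 2:24, trial_sds = c(0, 3),
                     scan_sds = 0.8, models = "lsu", metrics = "ppm",
                     trim_transients = TRUE, seed = 1)
grid <- run_sweep(cfg)
argmax_soa(grid, trial_sd = 0, scan_sd = 0.8)
plot(grid)
```

## Known limitations

* The ridge estimator's bias (its shrinkage towards zero) is not scored;
  only precision is. Comparing ridge-LSA to OLS models on PPM/PSM alone
  therefore flatters regularization.
* LSS estimates carry no single-fit residual, so `residuals()` is defined
  only for LSU/LSA fits.
* Efficiency surfaces are computed per voxel; the CP analysis covers
  exactly two voxels, the smallest pattern that distinguishes coherent
  from incoherent variability. Searchlights, RSA and partial coherence
  are out of scope.
* Fixed-SOA schedules only; jitter enters solely through random
  intermixing of types (a type with mean and SD 0 emulates null events).
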
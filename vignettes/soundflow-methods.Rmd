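---
title: "Methods: transfer-entropy analysis of multi-site soundscapes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: transfer-entropy analysis of multi-site soundscapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soundflow)
```

## Overview

`soundflow` turns multi-site eco-acoustic index time series into directed
networks of acoustic information flow. The pipeline has five stages, each a
module of the package:

1. **Index extraction** — eight eco-acoustic indices per 1-minute audio
   window per site (or a synthetic fast path that emits index series
   directly).
2. **Dimension reduction** — PCA over the pooled (site, window)
   observations; two dimensions retained; one representative index per
   dimension.
3. **Transfer entropy** — the representative series are discretized per
   site and the Shannon (STE) and Rényi (RTE) transfer entropies estimated
   for every ordered site pair, optionally per period of the day.
4. **Flow networks** — site pairs oriented by the TE difference, arrows
   thresholded at a percentile of the pooled oriented differences, and
   summarized geometrically (arrow density, normalized distance index).
5. **Reporting** — aural-survey summaries, orchestration, persisted
   artifacts.

This vignette documents the model assumptions, the parameters that matter,
the numerical conventions, and the deliberate design choices in places the
method leaves open.

## The estimand and its estimator

For symbolic series $x_t, y_t$ with alphabets $A_x, A_y$, target Markov
order $n$ and source order $m$, we estimate

$$\mathrm{STE}(X \to Y) = \sum_{y_{t+1}, y_t^n, x_t^m}
  p(y_{t+1}, y_t^n, x_t^m)\,
  \log_2 \frac{p(y_{t+1} \mid y_t^n, x_t^m)}{p(y_{t+1} \mid y_t^n)},$$

the Kullback–Leibler departure of the observed transition distribution from
the Markov condition $p(y_{t+1}\mid y_t^n, x_t^m) = p(y_{t+1}\mid y_t^n)$ —
i.e. how much the source's past improves one-step prediction of the target
beyond the target's own past. We use the plug-in estimator: empirical
transition counts over $(y_{t+1}, y_t^n, x_t^m)$ tuples, zero-count contexts
contributing zero terms. All logarithms are base 2; values are bits.
Defaults are $m = n = 1$.

The Rényi variant weights contexts by the escort distribution
$\phi_q(j) = p^q(j) / \sum_j p^q(j)$:

$$\mathrm{RTE}_q(X \to Y) = \frac{1}{1-q} \log_2
  \frac{\sum_{y_t^n} \phi_q(y_t^n) \sum_{y_{t+1}} p^q(y_{t+1} \mid y_t^n)}
       {\sum_{y_t^n, x_t^m} \phi_q(y_t^n, x_t^m) \sum_{y_{t+1}}
        p^q(y_{t+1} \mid y_t^n, x_t^m)}.$$

For $q < 1$ rare contexts gain weight (tail events — sporadic calls,
occasional passages); for $q \to 1$ RTE converges to STE (verified in the
tests at $q = 0.9, 0.99, 0.999$ with shrinking tolerances). Unlike STE,
plug-in RTE can be negative; the package never clips it. Conventional
choices here are $q = 0.1$ and $q = 0.5$.

Properties the implementation guarantees, each backed by a test:

* $\mathrm{STE}(X \to X) = 0$ exactly (for $m = n$).
* Plug-in STE $\ge 0$ on every input (it is a conditional mutual
  information); negative floating-point dust is clamped at zero.
* Invariance under relabeling of symbol codes and under monotone transforms
  of the raw values (discretization is rank-based).
* Exact agreement (to $10^{-12}$) with a brute-force enumeration of the
  defining sums, coded independently in the test suite.
* On the exact joint distribution of the binary copy process
  ($Y_{t+1} = X_t$, $X$ a fair coin), STE is exactly 1 bit
  (`te_from_joint()` evaluates the functional on a known distribution).

### Discretization

The method itself does not dictate a discretization; this is the largest
open choice in the pipeline. The default is **per-series quantile coding at
the 5th and 95th percentiles**, producing 3 symbols that isolate the two
tails of each series' own distribution. Rationale: TE on index series is
driven by excursions (dawn choruses, noise events) rather than by small
fluctuations around the median, and per-series edges make the coding
invariant to site-specific gain. Quantiles use type-7 linear interpolation
(the R default) everywhere in the package; values falling exactly on an
edge go to the lower bin, which makes the coding a pure function of ranks.
Boundaries and bin counts are configurable and always recorded in outputs.
A series with fewer distinct values than bins is rejected with a message
rather than silently coded.

### Contiguity blocks

Transitions are only formed between windows that are adjacent in the
recording sequence. Duty-cycle pauses (1 min on / 5 min off) are treated as
*adjacent* retained windows — the 3360-element series is one sequence, the
pause being part of the sampling interval — but flagged missing values and
period splits cut blocks: when a series is restricted to dawn windows, the
jump from 08:00 to the next day's 05:00 never forms a transition.
Discretization edges are computed on the full series *before* period
filtering, so symbols are comparable across the periods of one site.

### Finite-sample bias

Plug-in TE is positively biased at finite length; the package reports raw
values (no bias correction by default) and offers `shuffle_null()` —
block-respecting permutations of the source — as opt-in diagnostics. With
the default 3-symbol alphabet and $m = n = 1$ the joint table has 27 cells,
so series of a few hundred windows are comfortably in the regime where the
bias is small relative to real coupling; an estimate from fewer transitions
than joint cells triggers a warning.

## Eco-acoustic indices

The indices follow their standard literature formulas; the parameters are
defaults of this package, chosen to match common reference implementations,
and all are configurable:

| Parameter | Default | Notes |
|---|---|---|
| FFT frame | 512 samples, 0 overlap, no taper | no taper keeps Parseval exact and tests closed-form |
| dB reference | full-scale sine = 0 dBFS | BI and ADI/AEI depend on it |
| BI band | 2000–8000 Hz, half-open `[lo, hi)` | the biophony band |
| NDSI bands | anthrophony 1–2 kHz, biophony 2–8 kHz | power ratio $(B-A)/(B+A)$ |
| ADI/AEI bands | 1 kHz bands, 0–10 kHz, capped at Nyquist | occupancy threshold −50 dBFS |
| ACI clump | 5 s | temporal clumps for the difference sums |

Two conventions deserve explicit statement. **DSC** is implemented as the
temporal mean of the per-frame amplitude-weighted spectral centroid (the
cited uses of a "dynamic spectral centroid" do not pin down one formula;
this one is documented as the package's). **Silence policy**: H and NDSI
are undefined on silent input and return flagged `NA`, never numeric 0; BI
returns 0 by convention (flagged); ADI/AEI return `NA` when no
time-frequency cell clears the occupancy threshold. Missing values
propagate as `NA` and are counted when dropped (before PCA) or used to cut
contiguity blocks (before TE).

## PCA and representative selection

Observations are pooled across sites and windows — one PCA per deployment —
matching the view that the index battery, not the site, is what is being
reduced; a per-site PCA mode is deliberately not offered. Columns are
standardized; the explained-variance fractions $V_i$ sum to 1 (tested to
$10^{-10}$); contributions are squared-loading shares per dimension
($100\,\ell_{ij}^2 / \sum_k \ell_{kj}^2$). PCA signs are arbitrary, so each
loading vector is oriented with its largest-magnitude entry positive —
purely to make outputs deterministic.

Retention defaults to the top two dimensions (a threshold policy on
$V_i > \bar V$ is available). Representative selection defaults to the
highest-contribution index per dimension, ties broken by the canonical
order H, ACI, ADI, AEI, NDSI, BI, DSC, ZCR. Because interpretability can
trump a marginal contribution difference (a bioacoustic index may be
preferred as "the biophony axis" over a slightly higher abstract
contributor), manual overrides are first-class and recorded as
`policy = "manual"` rather than hidden behind a guessed rule.

## Flow networks

For each unordered pair the oriented difference
$\mathrm{DTEM} = \mathrm{TEM}(X \to Y) - \mathrm{TEM}(Y \to X)$ points the
arrow toward the net receiver of information; exact ties produce no arrow
and are logged. Arrows are kept when their DTEM lies **strictly above** the
percentile cutoff (75th or 95th by convention) of the pooled oriented
values.

**Pooling scope.** The pool is one (index, estimator, q) configuration.
When a deployment is split into day periods, the cutoff is computed on the
pool across periods and then applied to each period's network: a dawn
network with more arrows than a night network is then a statement about
dawn, not an artifact of per-period thresholds (which would force equal
arrow counts in every period). `build_network()` accepts an explicit
`cutoff` for exactly this purpose; pooling across *configurations* is never
done, since different estimators and indices live on different scales.

Summaries:

* **Emission/reception** — row and column sums of the TE matrix per site;
  the net is computed from the exactly antisymmetric pairwise difference
  matrix, so the nets sum to zero exactly and the hot/cold classification
  (net emitter / net receiver) is conservative.
* **Arrow density** — arrows per site within a group. Arrows are attributed
  to their **source** site: an arrow is information emitted. Groups are the
  interior/edge partition of the site map, or the day periods (one network
  per period).
* **Normalized distance index** —
  $d_n = \frac{1}{\bar n} \sum_i d_i / d_{max} \in (0, 1]$, the mean arrow
  length relative to $d_{max}$. The package reads $d_{max}$ as the maximum
  length *among the drawn arrows* (so a single-arrow network has
  $d_n = 1$); the alternative reading — the maximum over all site pairs —
  is available as `ndi(network, d_max = "pairs")`. Neither reading is
  asserted as canonical; the choice is recorded in the output. An empty
  network has undefined $d_n$ (flagged `NA`).

## The synthetic soundscape generator

No recordings of this kind are publicly deposited, so validation rests on a
generator whose causal structure is known by construction. It emulates:

* **Deployment timelines** — continuous recording (3.5 h of 1-minute
  windows → 210 windows) and duty-cycle recording (1 min on / 5 min pause
  for 14 days → 3360 windows), with ISO timestamps and half-open period
  intervals dawn [05:00, 08:00), day [08:00, 18:00), night [18:00, 05:00).
* **Dawn-peaking biophony** — a smooth circadian bump (Gaussian in circular
  hour-of-day, default peak 06:30, width 1.25 h) modulating a shared AR(1)
  process (coefficient 0.7) through a logistic squashing.
* **Interior-to-edge coupling** — interior sites carry the shared process
  undelayed; edge sites receive it `inter_site_lag` windows later (default
  1), so information flows interior → edge by construction.
* **Road-noise gradient** — a line-segment road; site attenuation
  $(1 + d/50\,\mathrm{m})^{-\gamma}$ with decay exponent $\gamma = 1$ (a
  geometric-spreading surrogate), modulated by a diel traffic profile
  (quiet at night).
* **Index responses** — the eight indices are monotone noisy maps of the
  biophony driver $b$, the anthrophony driver $a$, the biophony fraction
  $b/(b+a)$ and the mixing measure $4p(1-p)$: BI and ACI track biophony
  (BI also picks up a high-frequency traffic leakage term), NDSI/DSC/ZCR
  track the biophony fraction, H/ADI/AEI track spectral mixing. Every index
  respects its declared range. With `road_noise_amp = 0` the generator is
  symmetric across site groups (tested: no systematic internal/external
  contrast).
* **An audio path** — Poisson-arriving FM chirps confined to 2–8 kHz at a
  rate proportional to $b$ (zero driver, zero chirps), plus low-passed
  red-weighted noise below 2 kHz scaled by $a$, peak-limited to full scale.
  It exists to exercise the index engine end to end, not to be
  species-realistic.
* **Aural-survey labels** — thresholds on the drivers map each (site,
  window) into the closed survey vocabulary (birds singing none/few/many,
  traffic intensity none/low/high, singing-activity quartile bands, ...).

All randomness flows from one integer seed through deterministic child
seeds (`child_seed()`), so modules are reproducible independently and
bit-identical under repetition.

What the generator does **not** emulate: acoustic propagation physics
(diffraction, ground and vegetation effects), species-realistic song,
recorder frequency-response differences, weather. Passing tests therefore
demonstrate that the *pipeline* recovers known structure from data of this
statistical shape — not that any particular field deployment has that
structure. The coupling magnitudes among real sites are unknown; the
generator's defaults (coupling through a shared latent with lag 1, index
noise multiplier 1) are calibration choices of this package.

## Problem sizes and numerical checks

The test suite validates the estimators against independent brute-force
enumeration (100 random 30-symbol pairs, agreement to $10^{-12}$), the
conditional-entropy decomposition of STE (to $10^{-12}$), direction
recovery on 100 seeded coupled simulations (linear VAR, coupling 0.8,
lag 1, $n = 2000$, 3-bin coding; the true direction must win at least 95),
exact conservation of net emission on 1000 random TE matrices, and the
dawn/interior flow structure on 20 seeds of the default 14-day, 8-site
soundscape. These sizes keep the full suite under a minute of estimator
time while leaving each check far from its decision boundary.

Degenerate inputs are handled explicitly rather than numerically: constant
columns are rejected by name before PCA; series too concentrated for the
requested bins are rejected with a suggestion; zero-count contexts
contribute zero terms; escort normalization runs over observed contexts
only; silent audio yields flagged `NA` (or a flagged conventional 0 for
BI), never a silent numeric zero.

## Known limitations

* Bivariate TE only: conditional/multivariate TE, kernel and
  nearest-neighbor continuous estimators, and Granger causality are out of
  scope. Spurious pairwise links that a multivariate analysis would explain
  away are possible.
* No recorder calibration layer: index values from heterogeneous hardware
  are comparable only through the rank-based discretization.
* The plug-in estimator is biased at short lengths; `shuffle_null()` is
  provided for calibration but no automatic correction is applied.
* Maps are abstract coordinate plots; no basemap rendering.
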
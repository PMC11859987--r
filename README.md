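# soundflow

Directed acoustic information flow in multi-site soundscapes.

## The problem

Passive acoustic monitoring networks record the same soundscape from many
points at once. Classical eco-acoustic indices — acoustic entropy (H),
acoustic complexity (ACI), acoustic diversity and evenness (ADI, AEI), the
normalized difference soundscape index (NDSI), the bioacoustic index (BI),
the dynamic spectral centroid (DSC) and the zero crossing rate (ZCR) —
summarize each recording in isolation. They describe *how much* and *what
kind* of sound is present, but not how acoustic activity at one site relates
to activity at another, nor in which direction that relation runs. In parks
where birdsong and road-traffic noise overlap, that directional structure is
exactly what distinguishes a connected biophonic network from a fragmented,
noise-masked one.

`soundflow` implements a transfer-entropy approach to this question. For
index time series x_t (site X) and y_t (site Y), discretized into a small
symbol alphabet, the Shannon transfer entropy

    STE(X → Y) = Σ p(y_{t+1}, y_t, x_t) · log2 [ p(y_{t+1} | y_t, x_t) / p(y_{t+1} | y_t) ]

measures, in bits, how much the past of X improves the prediction of Y
beyond Y's own past — a model-free, asymmetric measure of information flow
(STE(X → X) = 0, and STE(X → Y) ≠ STE(Y → X) in general). The Rényi variant
replaces context probabilities with escort weights
φ_q(j) = p(j)^q / Σ p(j)^q,

    RTE_q(X → Y) = 1/(1−q) · log2 [ Σ φ_q(y_t) Σ p^q(y_{t+1}|y_t) / Σ φ_q(y_t, x_t) Σ p^q(y_{t+1}|y_t, x_t) ]

so q < 1 emphasizes rare (tail) events such as sporadic calls; RTE → STE as
q → 1 and may legitimately be negative.

From the pairwise TE matrix the package derives a directed **flow network**:
each site pair is oriented by the TE difference DTEM = TEM(X→Y) − TEM(Y→X),
arrows above a percentile threshold are drawn between site coordinates, and
the network is summarized by per-site emission/reception totals, arrow
density per site group (interior vs. road-edge sites) or per day period
(dawn/day/night), and the normalized distance index
d_n = (1/n̄) Σ d_i / d_max — the spatial scale of acoustic interconnection.

Because deployments of this kind are rarely public, the package ships a
synthetic soundscape generator with *known* causal structure (dawn-peaking
biophony, lagged interior-to-edge coupling, distance-attenuated road noise)
plus coupled driver/response process pairs, so every claim the analysis
makes can be validated against ground truth.

## Worked example

Simulate a 14-day duty-cycle deployment (1 min on / 5 min pause) over the
8-site river-park layout, pick representative indices by PCA, and compare
dawn and night flow networks:

```r
library(soundflow)

sm   <- river_park_sites()                       # 8 usable of 9 deployed
spec <- soundscape_spec(sm, protocol = "duty_cycle", days = 14, seed = 42)
im   <- gen_index_series(spec)                   # 3360 windows per site

fit <- index_pca(im)
fit
#> <index_pca> 26880 observations, 8 dimensions
#> explained variance [%]: 67.2 23.5 4.9 1.9 1.3 0.9 0.2 0.2

reps <- select_representatives(fit, 2, overrides = list(Dim1 = "H", Dim2 = "BI"))

tem_dawn  <- te_matrix(im, "BI", estimator = "shannon", period = "dawn")
tem_night <- te_matrix(im, "BI", estimator = "shannon", period = "night")

# one cutoff for the whole configuration, pooled across periods
pool <- unlist(lapply(list(tem_dawn, tem_night), function(tb) {
  m <- te_to_matrix(tb); up <- upper.tri(m); abs(m[up] - t(m)[up])
}))
cut75 <- percentile_threshold(pool, 75)

nw <- build_network(tem_dawn, sm, percentile = 75, cutoff = cut75)
nw
#> <flow_network> 14 arrows above 0.3152 bits (75th pct), period dawn
#> d_max = 353.8 m; d_n = 0.72
arrow_density(nw)
#> # A tibble: 2 × 4
#>   group    n_arrows n_sites density
#>   <chr>       <int>   <int>   <dbl>
#> 1 external        0       3     0
#> 2 internal       14       5     2.8

build_network(tem_night, sm, percentile = 75, cutoff = cut75)
#> <flow_network> 0 arrows above 0.3152 bits (75th pct), period night
```

The two dimensions retained by the PCA carry 90.7% of the variance; H and BI
are recorded as their (manually chosen) representatives. At dawn the network
shows 14 arrows, all sourced at interior sites (arrow density 2.8 per
interior site vs. 0 at the road edge) with a normalized distance index of
0.72; at night, with biophony absent, no arrow clears the same cutoff —
the dawn-peaking, interior-led connectivity the generator encodes.
`emission_reception(tem_dawn)` classifies the interior sites as biophonic
"hot" (net emitters). `autoplot(nw)` draws the arrows over the site map;
`run_pipeline(pipeline_config(spec))` runs all stages (indices → PCA → TE →
networks → survey summary) in one call and can persist every artifact.

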
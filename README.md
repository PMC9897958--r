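# nhpimove

Does a dispersing animal choose its path through habitat that resembles
where it grew up?  `nhpimove` is an R package for testing natal habitat
preference induction (NHPI) along *extra-home-range movements* (EHRMs) —
excursions and dispersals — in hourly GPS telemetry of large ungulates.
It is aimed at movement ecologists who have collar data, a land-cover
raster, and linear features (streams, roads), and who want a reproducible
version of the full workflow: fix screening, Brownian bridge home ranges,
EHRM detection and classification, multi-grain landscape metrics, natal
habitat dissimilarity, and tiered step-selection modeling.

## The model

Each observed (used) hourly step is compared with 50 random (available)
steps sharing its start point, drawn from a gamma distribution of step
lengths and a von Mises distribution of turn angles fitted to pooled EHRM
steps.  Relative intensity of use is modeled as

    w(x) = exp(b1 x1 + b2 x2 + ... + bn xn)

estimated by conditional logistic regression, stratified by step, with
step length as a covariate.  Habitat covariates are Euclidean distances to
forest, agriculture, streams and roads, and the squared Mahalanobis
dissimilarity

    D2 = (x - mu)' C^-1 (x - mu)

of each location's seven moving-window landscape metrics (percent forest,
percent developed, percent open, edge density, interspersion–juxtaposition
index, patch richness density, aggregation index; radii 175/250/350/500 m)
from the distribution of the movement's own pre-EHRM home-range locations
(`D_IND`) or all animals' pooled pre-EHRM locations (`D_ALL`).  Model
selection is tiered by AICc: functional forms per covariate, then base
habitat hypotheses (Corridors, Human Footprint, Global), then the grain
and form of `D_ALL` and `D_IND` (with an r > 0.70 correlation guard), with
Akaike weights and model-averaged log relative selection strength,
ln(RSS), for visualization.

A first-class synthetic-data module (`simulate_study()`,
`simulate_track()`, `simulate_ssf_steps()`, `generate_landscape()`)
generates patch-mosaic landscapes and trajectories with planted events and
known selection coefficients, so the whole pipeline is testable against
ground truth.

## Worked example

```r
library(nhpimove)

study <- simulate_study(n_animals = 10, seed = 1)   # landscapes + tracks
res <- run_nhpi_pipeline(study$tracks, study$landscape,
                         study$streams, study$roads, J = 50, seed = 2)

print(res$kernel)
#> movement_kernel: gamma(shape 2.835, scale 106.5 m),
#>                  vonMises(mu -0.082, kappa 0.732), n = 1478

summarize_ehrms(res$events)$stats[, c("type", "n_events", "steps_mean",
                                      "dist_median_m")]
#>        type n_events steps_mean dist_median_m
#>   dispersal        8       66.5          5001
#>   excursion       16       63.9          3522

res$fits$dispersal$tier3$table
#>                         model k    AICc    dAICc        w       LL
#>  Base + D_ALL_175 + D_IND_175 9 3833.88   0.0000 9.96e-01 -1907.75
#>              Base + D_ALL_175 8 3844.82  10.9412 4.19e-03 -1914.26
#>                          Base 7 3962.66 128.7774 1.08e-28 -1974.22
```

The simulation planted avoidance of natal-dissimilar habitat during
dispersal movements only.  The tier-3 table shows the dispersal subset
overwhelmingly favouring the model with the movement-specific
dissimilarity term (Akaike weight 0.996), whose coefficient is negative
(`D_IND_175` estimate -0.015, 95% CI [-0.025, -0.006]): deer-like
trajectories avoiding unfamiliar habitat.  The model-averaged ln(RSS)
curve declines with dissimilarity accordingly:

```r
t3 <- res$fits$dispersal$tier3
rss <- model_average_rss(t3$fits, t3$weights, res$designs$dispersal,
                         focus_var = t3$d_ind$var, seed = 3)
rss[c(1, 51), ]
#>          v  lnRSS  lower  upper
#> 1    0.412  0.262  0.101  0.423
#> 51 175.659 -2.436 -3.928 -0.941
```

Negative ln(RSS) at high `D_IND` means a location that dissimilar is used
several-fold less than an average-dissimilarity location, all else equal.

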
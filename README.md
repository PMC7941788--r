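# firexcess

Spatiotemporal analysis of excess respiratory hospitalizations during
wildfire smoke episodes, for epidemiologists working with daily counts
aggregated to small areas (ZIP codes). The package implements, as tested R
functions plus a scripted analysis workflow:

1. **Within-community matched design** — each spatial unit's exposed-day
   count is contrasted with the median of its four weekday-matched
   bidirectional control days (±1 and ±2 weeks):
   `e_id = Y_id − median{Y_i,d±7, Y_i,d±14}`. Per-day county totals,
   period totals and percent-of-total summaries reproduce the layout of
   the published county tables (bundled in `inst/extdata/`).
2. **Spatial clustering inference** — Global Moran's I and Anselin Local
   Moran's I (LISA quadrants) over per-unit excess, with k-nearest-neighbour
   row-standardized weights and conditional-permutation pseudo p-values,
   plus a falsification workflow contrasting fire and no-fire periods.
3. **Bayesian hierarchical smoothing** — `Y_i = β0 + W_i + ε_i` with
   `W ~ N(0, σ² H(φ))`, `H` spherical and isotropic; semivariogram-derived
   priors; Metropolis-within-Gibbs MCMC (10,000 draws / 7,500 burn-in);
   per-unit posterior means, SDs and signal-to-noise ratios; and a
   multilevel B-spline surface on a 300 × 300 raster (ESRI ASCII export).
4. **Synthetic data with ground truth** — Poisson count panels with
   weekday structure and an anisotropic wind-aligned plume excess, plus
   pure Gaussian-process fields, since real discharge panels are
   confidential.

See `vignettes/wildfire-excess-methods.Rmd` for the models, assumptions,
defaults and limitations.

## Worked example

```r
library(firexcess)

geom <- gen_geometry(108, seed = 1)                    # ZIP-like centroids, km
sim  <- gen_count_panel(geom, scenario_config(seed = 2))
des  <- study_design()                                  # exposed 2007-10-22..26

select_control_days(as.Date("2007-10-22"), window_weeks = 2)
#> [1] "2007-10-08" "2007-10-15" "2007-10-29" "2007-11-05"

ep <- excess_panel(sim$panel, des)
ep
#> Excess panel: 108 units x 5 exposed days
#>   per-day county excess: 35.5, 42.5, 42.5, 58.5, 38.5
#>   total excess 217.5 of 431 admissions (50.5%)

w  <- build_weights(geom, "knn", k = 8)
me <- mean_excess_for_mapping(ep)
global_moran(me, w, n_permutations = 999, seed = 3)
#> Global Moran's I = 0.2433 (E[I] = -0.0093), pseudo p = 0.0010 [two.sided] -> clustered

post <- run_mcmc(me * 5, geom[, c("x_km", "y_km")],
                 bhm_config(seed = 4), ids = geom$unit_id)
surf <- interpolate_surface(post$summary$mean, geom[, c("x_km", "y_km")])
dim(surf$z)
#> [1] 300 300
```

The Moran verdict says the five-day mean excess is spatially clustered
(pseudo p at the permutation floor), as expected when a plume doubles
expected counts over the downwind half of the domain; on an
amplitude-zero panel the same pipeline returns "random". `snr_map(post)`
gives the per-unit precision map, highest downwind of the fire.

The same analysis, stage by stage with printed narration and CSV outputs
under `results/analysis/`, is scripted in `analysis/01_simulate.R` through
`analysis/05_surface.R` (run them in order from the repository root), and
`run_report()` drives the whole pipeline from one `pipeline_config()`.

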
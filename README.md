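# rifasurv

Spatial surveillance analysis of red imported fire ant (*Solenopsis
invicta*, RIFA) occurrence for invasive-species monitoring programmes.

City-scale RIFA control relies on seasonal surveys of georeferenced sites:
at each site the number of active nests on a known area is counted, graded
into an ordinal occurrence level, and the point data are turned into maps
and statistics that tell managers *where* infestations cluster and *which
habitats, in which seasons*, carry the load. `rifasurv` implements that
analysis chain as tested, reusable R functions:

* **Site metrics** — nest density `D = N / S` (nests/ha), occurrence-level
  grading under a configurable threshold scheme, half-ellipsoid mound
  volume `V = (2/3) π a b c`.
* **Surfaces** — inverse distance weighting (`Z(x) = Σ W_i Z(x_i)`,
  `W_i ∝ d_i^{-a}`) and a density-weighted quartic kernel density surface
  `f(x,y) = (1/t²) Σ_{d_i<t} (3/π) ρ_i (1 − (d_i/t)²)²`, both written as
  ESRI ASCII grids.
* **Spatial autocorrelation** — global Moran's I with analytic
  (normality / randomization) and seeded permutation inference; Anselin
  local Moran's I with conditional-permutation p-values and HH / LL /
  HL / LH / NS cluster labels (LISA).
* **Habitat contrasts** — season-wise Kruskal–Wallis tests, Dunn's post
  hoc pairwise z tests, Benjamini–Hochberg FDR adjustment, and compact
  letter displays.
* **Synthetic surveys** — a generator that emulates the statistical
  structure of a 129-site, four-habitat, four-season urban survey
  (habitat-specific seasonal means, overdispersed counts, spatially
  inhibited site placement, a core–periphery clustered field) so the whole
  pipeline is testable without field data.

Everything is glued together by `run_pipeline()`, which emits per-season
density tables, IDW and KDE rasters, global Moran rows, LISA tables,
habitat statistics and a manifest recording every parameter and seed. A
thin command-line wrapper (`inst/cli/rifasurv-cli.R`) exposes the stages
as subcommands (`simulate`, `density`, `idw`, `kde`, `moran`, `lisa`,
`stats`, `report`).

## Worked example

```r
library(rifasurv)

sites <- generate_survey(synthetic_config(seed = 1))
spring <- sites[sites$season == "spring", ]

w <- build_weights(cbind(spring$x, spring$y), ids = spring$site_id)
moran_inference(spring$density, w, n_perm = 999, seed = 1)
#> Global Moran's I: 0.251815 (E[I] = -0.007812, n = 129)
#>   method = permutation (999 permutations); z = 6.5291; p = 0.002
```

The spring density field is strongly positively autocorrelated: the
statistic (0.25) sits far above its null expectation (−1/128), with a
permutation p-value of 0.002 — similar values cluster in space, as planted
by the generator's peripheral high-density field.

```r
lisa <- lisa_classify(spring$density, w, n_perm = 999, seed = 1)
table(lisa$label)
#>  HH  LH  NS
#>  12   5 112
```

Twelve sites are significant high-high cluster cores (hotspots within the
planted peripheral clusters); five are low sites adjacent to hotspots
(LH outliers); the rest show no significant local association.

```r
ht <- habitat_season_tests(sites)
ht$tests
#>   season         H df    p_value   n
#> 1 spring 13.550467  3 0.00358552 129
#> 2 summer  3.529300  3 0.31698182 129
#> 3 autumn 10.391548  3 0.01551493 129
#> 4 winter  8.367004  3 0.03900559 129
ht$letters$spring
#>    farmland    fishpond     orchard urban_green
#>         "a"        "ab"        "ab"         "b"
```

Spring habitats differ (Kruskal–Wallis H = 13.55, df = 3, p = 0.0036);
the compact letters show farmland and urban green space differ after BH
adjustment while fishpond and orchard are intermediate — the classic
"a / ab / ab / b" annotation used on density figures.

```r
run_pipeline(sites, pipeline_config(seed = 1), out_dir = "report")
# writes density_<season>.csv, idw_<season>.asc, kde_<season>.asc,
# lisa_<season>.csv, moran_global.csv, habitat_*.csv, manifest.json
```

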
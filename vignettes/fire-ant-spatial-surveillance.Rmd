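---
title: "Methods: spatial surveillance analysis of fire ant occurrence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial surveillance analysis of fire ant occurrence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rifasurv)
```

## The surveillance problem

Red imported fire ant (*Solenopsis invicta*, RIFA) control programmes in
invaded urban regions monitor georeferenced survey sites across habitat
types and seasons, recording the number of active nests found on a known
surveyed area. Three questions recur: *how much* (site-level nest density
and an ordinal occurrence grade), *where* (continuous surfaces interpolated
from the point survey, and statistically significant local clusters), and
*which habitats, when* (habitat contrasts within each season). `rifasurv`
implements that analysis chain end to end and pairs it with a synthetic
survey generator so that every stage can be exercised and validated without
access to field data.

## Site-level metrics

Nest density is `D = N / S` in nests per hectare, with `N` the active-nest
count and `S` the surveyed area in hectares. Densities are carried in
nests/ha throughout; coordinates are planar metres. Geographic coordinates
are first projected with a spherical Lambert azimuthal equal-area
projection centred on the data centroid (sphere radius 6 371 008.8 m);
great-circle distances are never silently substituted for planar ones.

Occurrence grading maps density to the ordinal levels `none_detected`,
`I`–`IV`. The national grading standard used by field protocols does not
publish its cut-offs in open sources, so the thresholds are **required
configuration**: the shipped `example_occurrence_scheme()` (and
`inst/extdata/occurrence_scheme_example.yaml`) is an explicitly labelled
placeholder. Intervals take a closed lower and open upper bound, the top
level is closed at both ends, and density exactly 0 always maps to
`none_detected`; this makes boundary behaviour deterministic and the
classification monotone in density.

Mound volume treats the mound as a half-ellipsoid over basal semi-axes
`a`, `b` (metres) and height `c`: `V = (2/3) * pi * a * b * c`. The tests
verify this against midpoint quadrature of the half-ellipsoid height field
to 0.1%.

## Interpolated surfaces

**IDW.** The estimate at a target `x` is the convex combination
`Z(x) = sum_i W_i Z(x_i)` with weights
`W_i = d(x, x_i)^(-a) / sum_j d(x, x_j)^(-a)`. The power `a` (default 2,
the conventional choice; surfaced as a parameter) controls how sharply
influence decays. A target coincident with an observation returns the
observed value exactly; with distinct positive distances the weights are
positive and sum to one, so the surface never exceeds the observed
extremes. All observations participate unless a nearest-neighbour cap is
set.

**Weighted KDE.** Hotspot surfaces use a quartic (biweight) kernel with
finite support, weighted by each plot's nest density `rho_i`:

```
f(x, y) = (1 / t^2) * sum_{d_i < t} (3 / pi) * rho_i * (1 - (d_i / t)^2)^2
```

where `t` is the search radius in metres. Each point's kernel integrates
to exactly `rho_i` over its support disk, so the surface mass over any
domain containing all disks equals `sum(rho_i)`; the tests confirm this by
quadrature to 1%. The default bandwidth is twice the mean
nearest-neighbour distance — a deterministic, scale-equivariant rule that
adapts the search radius to the survey's spacing — and is overridable.

Both surfaces are evaluated at cell centres of a regular grid (row 1 is
the northernmost row in serialized output) and written as ESRI ASCII
grids, a plain-text raster format any GIS reads.

## Spatial autocorrelation

**Weights.** The pairwise weight structure `W` defaults to k-nearest
neighbours with `k = 8`, row-standardized, built on planar Euclidean
distances; distance ties are broken by site order so the construction is
deterministic. A symmetric distance-band alternative is provided. kNN
guarantees no isolated sites for scattered survey designs; sites that do
end up isolated (possible under a distance band) are excluded from Moran
computations with a warning, avoiding 0/0 spatial lags. Both the method
and its parameter are surfaced configuration, since surveillance reports
rarely state how `W` was built.

**Global Moran's I.**

```
I = (n / S0) * sum_ij w_ij (x_i - xbar)(x_j - xbar) / sum_i (x_i - xbar)^2
```

with `S0 = sum_ij w_ij` and the diagonal excluded. Under every null,
`E[I] = -1/(n-1)`. Inference is available three ways: closed-form
normality and randomization (Cliff–Ord) moments giving analytic Z-scores,
and a Monte-Carlo permutation test (default, `n_perm = 999`) whose
two-sided p-value is `(1 + #{|I* - E[I]| >= |I - E[I]|}) / (n_perm + 1)`.
Both analytic variants are provided because published reports often quote
analytic-style Z-scores without naming the assumption. The permutation
draw is seeded and bit-reproducible.

**Local Moran's I and LISA.** The Anselin local statistic is

```
I_i = (x_i - xbar) * sum_j w_ij (x_j - xbar) / ((1/n) sum_k (x_k - xbar)^2)
```

with the neighbour sum weighted by `w_ij`; with row-standardized weights
the identity `sum_i I_i = n * I` holds and is tested to 1e-10. (A
widely-circulated transcription of the local statistic omits `w_ij` from
the neighbour sum; that form would make `I_i` identical up to scale for
all sites with the same deviation and breaks the averaging identity, so
the weighted form is implemented.) Significance uses conditional
permutation: site `i`'s value is held fixed and its neighbours' values
are redrawn without replacement from the remaining `n - 1` observations.
Significant sites are labelled by the quadrant of (deviation, spatial
lag): HH and LL clusters, HL and LH outliers; everything else NS. The
default is raw per-site `p <= 0.05` — matching common LISA mapping
practice — with an optional Benjamini–Hochberg adjustment flag for a
stricter map.

**Which variable to map.** Density is the default analysis variable, with
ordinal occurrence codes accepted as an alternative. The distinction
matters for LISA: raw nest densities are strongly right-skewed, and when
most sites share the low background level, a two-sided conditional
permutation test can rarely call a *low* site's neighbourhood
significantly low — random neighbour draws from a mostly-low pool look
just like the observed one. Mapping the bounded ordinal occurrence code
compresses the high tail and recovers both HH cores and the LL core, which
is how the package's own acceptance checks exercise the planted geography.

## Habitat-by-season statistics

Within each season, habitat differences in density (or abundance) are
tested with the tie-corrected Kruskal–Wallis H (chi-square reference,
`df = k - 1`); when every observation is identical the tie correction
degenerates and the test reports `H = 0, p = 1` by convention. Dunn's
post hoc z statistics compare mean mid-ranks per habitat pair with the
pooled tie correction; the six pairwise p-values are Benjamini–Hochberg
adjusted *within the season*, which is the natural family for a
season-wise report. Compact letter displays are computed as the maximal
cliques of the non-significance graph, enumerated deterministically, so
two groups share a letter exactly when their adjusted difference is not
significant and identical inputs always give identical letterings.

## The synthetic survey generator

The generator emulates the statistical structure such a surveillance
campaign produces, at the study's scale:

* **Design**: 129 sites — 28 farmland, 23 fishpond, 15 orchard, 63 urban
  green — each surveyed in all four seasons over 0.12 ha, placed by
  inhibition sampling (uniform proposals rejected until a 2 000 m minimum
  spacing holds, with bounded retries) in a 70 km x 70 km domain, the
  scale of a large invaded municipality.
* **Habitat geography**: habitats are allocated site-by-site with
  probability proportional to a radial placement weight times the
  habitat's remaining quota — farmland and fishpond weights grow towards
  the periphery (`exp(2 r)` on normalized radius), urban green space
  decays (`exp(-2 r)`), orchard is neutral. This mirrors an urban land-use
  gradient and induces the core–periphery contrast.
* **Seasonal means**: expected density at a background site is the
  habitat-by-season mean table (`default_mean_densities()`), anchored to
  published seasonal group means for the four habitats (e.g. spring
  farmland 36.7 nests/ha, winter urban green 8.9 nests/ha).
* **Clustering**: a log-scale spatial field of three peripheral Gaussian
  bumps multiplies the expected count:
  `E[N_i] = S * mu(habitat_i, season) * exp(field_i)`. The field is
  centred on its domain average (each bump integrates to
  `amplitude * 2 pi range^2`), so it redistributes density from core to
  periphery instead of inflating the overall level. Defaults are
  amplitude 3.0 and range 10 km. They were calibrated once, as part of the
  generator's design, so that the planted clustering dominates the
  irreducible count noise: at 0.12 ha and ~25 nests/ha a site yields only
  ~3 nests, whose negative-binomial sampling variation is i.i.d. and
  therefore dilutes Moran's I; a weaker or narrower field produces surveys
  whose clustering is frequently undetectable at n = 129, which would
  misrepresent the strongly autocorrelated pattern the generator is meant
  to emulate. At these defaults a default survey yields seasonal global
  Moran's I around 0.2–0.3, significant in every season.
* **Counts**: negative-binomial with dispersion `theta = 1.5`
  (variance `mu + mu^2/theta`), reflecting the overdispersion implied by
  published SE-to-mean ratios; `dispersion = Inf` gives Poisson counts,
  used by the convergence tests.
* **Determinism**: a fixed seed reproduces the table byte for byte; the
  generator restores the caller's RNG state.

What the generator does **not** emulate: real geography or administrative
districts, within-season revisit dynamics (seasons are independent draws
given the site layout), detection error in the meandering search, habitat
misclassification, or any correlation between habitat and surveyed area.
Passing tests therefore demonstrate that the *methods* recover planted
structure of this kind — not that real surveys satisfy these assumptions.

Two auxiliary fixtures support calibration: `generate_checkerboard()`
(alternating ±1 rook lattice, the exact `I = -1` configuration) and
`generate_null()` (i.i.d. normal values at uniform points, for type-I
error checks).

## Numerical and degenerate-case choices

* kNN distance ties break by site order (stable sort); constructions are
  deterministic.
* IDW at zero distance returns the observed value exactly, avoiding the
  singular weight.
* Row standardization leaves all-zero rows untouched and is idempotent.
* Zero-variance values are a degenerate-input error for Moran statistics;
  all-isolated weights are an invalid-weights error.
* Permutation p-values use the `+1` correction and so lie in (0, 1].
* BH adjustment validates `p` in [0, 1] and clips at 1.
* Raster cells are addressed by origin plus cell size; serialized rows run
  north to south.

## Validation problem sizes

The shipped test-suite checks run at sizes chosen to make the Monte-Carlo
bands tight enough to be meaningful while keeping the whole suite quick:
50 random-instance oracle comparisons (n up to 50) at 1e-10; 500 null
replicates of the permutation Moran test (n = 50 sites, 199 permutations)
and 1 000 Kruskal–Wallis null simulations, each required to reject within
5% ± 2% at the 5% level; and 100 replicate clustered surveys for the
parameter-recovery rate (at least 95% detected). `scripts/acceptance.R`
recomputes the same quantities from scratch against the installed package.

## Known limitations

* IDW and KDE evaluation is exact but naive (O(points x cells)); grids
  finer than ~10^6 cells at n in the hundreds will be slow.
* Conditional-permutation LISA p-values are raw by default; with 129
  sites, about six false-positive labels are expected per map at
  `alpha = 0.05` — use the BH flag for conservative maps.
* The occurrence scheme ships as a placeholder; real grading requires the
  governing standard's thresholds.
* No edge correction is applied to the KDE beyond its finite support, so
  mass near the domain boundary leaks outside the mapped grid rather than
  being reflected.
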
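# Synthetic survey generator: emulates the statistical structure of a
# city-scale four-season fire-ant nest survey — habitat-specific seasonal
# mean densities, overdispersed counts, spatially inhibited site placement,
# and a core-periphery clustered spatial field — so every pipeline stage is
# testable without field data.

#' Default habitat-by-season mean densities
#'
#' Mean nest densities (nests per hectare) per habitat and season used as
#' generator defaults. Rows are habitats, columns seasons.
#'
#' @return A 4 x 4 numeric matrix.
#' @export
default_mean_densities <- function() {
  m <- matrix(
    c(36.7, 26.8, 31.0, 28.0,   # farmland
      27.2, 21.5, 22.6, 21.5,   # fishpond
      30.3, 21.8, 22.8, 17.4,   # orchard
      17.4, 14.0, 15.9, 8.90),  # urban_green
    nrow = 4, byrow = TRUE,
    dimnames = list(habitat_levels(), season_levels())
  )
  m
}

#' Synthetic survey configuration
#'
#' Full parameterization of the survey simulator. Defaults emulate the
#' structure of a 129-site, four-habitat, four-season urban survey:
#' 63 urban green spaces, 15 orchards, 28 farmlands and 23 fishponds placed
#' with a 2000 m minimum spacing in a 70 km square domain; habitat-by-season
#' mean densities from [default_mean_densities()]; 0.12 ha surveyed per
#' site; negative-binomial counts (dispersion theta = 1.5); and a
#' multiplicative log-scale Gaussian-bump spatial field with three
#' peripheral cluster centres that induces core-periphery clustering.
#' Habitat placement is spatially biased (farmland/fishpond towards the
#' periphery, urban green spaces towards the core) to mirror an urban
#' land-use gradient.
#'
#' @param domain Numeric `c(width, height)` of the rectangular study domain
#'   in metres.
#' @param n_sites Named integer vector of site counts per habitat.
#' @param mean_density Habitat x season matrix of mean densities
#'   (nests/ha).
#' @param area_ha Surveyed area per site, hectares.
#' @param dispersion Negative-binomial dispersion theta (variance
#'   mu + mu^2/theta); `Inf` gives Poisson counts.
#' @param cluster_centers Matrix of cluster-centre coordinates (metres), one
#'   row each; `NULL` for no spatial field.
#' @param cluster_amplitude Peak height of each Gaussian bump on the log
#'   scale.
#' @param cluster_range Bump range parameter in metres (field =
#'   sum of amplitude * exp(-d^2 / (2 range^2))).
#' @param min_spacing Minimum inter-site distance in metres.
#' @param habitat_bias Strength of the radial habitat-placement bias
#'   (0 = none).
#' @param seed Integer random seed.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(domain = c(70000, 70000),
                             n_sites = c(farmland = 28, fishpond = 23,
                                         orchard = 15, urban_green = 63),
                             mean_density = default_mean_densities(),
                             area_ha = 0.12,
                             dispersion = 1.5,
                             cluster_centers = NULL,
                             cluster_amplitude = 3.0,
                             cluster_range = 10000,
                             min_spacing = 2000,
                             habitat_bias = 2.0,
                             seed = 1L) {
  if (is.null(cluster_centers)) {
    cluster_centers <- rbind(
      c(0.15, 0.80), c(0.85, 0.75), c(0.75, 0.15)
    ) %*% diag(domain)
  }
  stopifnot(all(n_sites > 0), all(mean_density >= 0), min_spacing >= 0,
            cluster_amplitude >= 0, cluster_range > 0, area_ha > 0,
            all(domain > 0))
  if (!all(habitat_levels() %in% names(n_sites))) {
    stop("n_sites must name every habitat")
  }
  if (!all(habitat_levels() %in% rownames(mean_density)) ||
      !all(season_levels() %in% colnames(mean_density))) {
    stop("mean_density must have habitat rows and season columns")
  }
  structure(
    list(domain = domain, n_sites = n_sites, mean_density = mean_density,
         area_ha = area_ha, dispersion = dispersion,
         cluster_centers = cluster_centers,
         cluster_amplitude = cluster_amplitude,
         cluster_range = cluster_range, min_spacing = min_spacing,
         habitat_bias = habitat_bias, seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat(sprintf("Synthetic survey config: %d sites in %g x %g km domain\n",
              sum(x$n_sites), x$domain[1] / 1000, x$domain[2] / 1000))
  cat("  sites per habitat:",
      paste(names(x$n_sites), x$n_sites, sep = "=", collapse = ", "), "\n")
  cat(sprintf("  spacing >= %g m; NB dispersion %g; %d cluster centre(s), amplitude %g, range %g m; seed %d\n",
              x$min_spacing, x$dispersion, nrow(x$cluster_centers),
              x$cluster_amplitude, x$cluster_range, x$seed))
  invisible(x)
}

cluster_field <- function(coords, config) {
  f <- numeric(nrow(coords))
  if (config$cluster_amplitude == 0 || is.null(config$cluster_centers)) {
    return(f)
  }
  for (ci in seq_len(nrow(config$cluster_centers))) {
    dx <- coords[, 1] - config$cluster_centers[ci, 1]
    dy <- coords[, 2] - config$cluster_centers[ci, 2]
    f <- f + config$cluster_amplitude *
      exp(-(dx * dx + dy * dy) / (2 * config$cluster_range^2))
  }
  # centre the log-scale field on its domain average (each bump integrates
  # to amplitude * 2 pi range^2) so the field redistributes density between
  # core and periphery instead of inflating the overall level
  avg <- nrow(config$cluster_centers) * config$cluster_amplitude *
    2 * pi * config$cluster_range^2 / prod(config$domain)
  f - avg
}

sample_inhibited_points <- function(n, domain, min_spacing,
                                    max_tries = 200L) {
  pts <- matrix(NA_real_, n, 2)
  placed <- 0L
  tries <- 0L
  while (placed < n) {
    cand <- c(stats::runif(1, 0, domain[1]), stats::runif(1, 0, domain[2]))
    ok <- placed == 0L ||
      min((pts[seq_len(placed), 1] - cand[1])^2 +
            (pts[seq_len(placed), 2] - cand[2])^2) >= min_spacing^2
    if (ok) {
      placed <- placed + 1L
      pts[placed, ] <- cand
      tries <- 0L
    } else {
      tries <- tries + 1L
      if (tries > max_tries * n) {
        stop("could not satisfy the minimum spacing within the domain")
      }
    }
  }
  pts
}

#' Generate a synthetic four-season survey
#'
#' Draws site locations by inhibition sampling (uniform proposals rejected
#' until the minimum spacing holds, with bounded retries), assigns habitats
#' with a radial bias (farmland and fishpond towards the domain periphery,
#' urban green spaces towards the core, orchards unbiased), and for every
#' season draws nest counts: expected count at site i is
#' `area_ha * mu(habitat, season) * exp(field_i)` where `field_i` is the
#' Gaussian-bump cluster field, and counts are negative-binomial with the
#' configured dispersion (Poisson when `dispersion = Inf`). The same seed
#' always reproduces the same table.
#'
#' @param config A [synthetic_config()].
#' @return A site table (data frame) with one row per site per season and a
#'   `density` column.
#' @export
generate_survey <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)
  n <- sum(config$n_sites)
  pts <- sample_inhibited_points(n, config$domain, config$min_spacing)
  # radial habitat bias: periphery weight grows with distance from centre
  ctr <- config$domain / 2
  r <- sqrt((pts[, 1] - ctr[1])^2 + (pts[, 2] - ctr[2])^2)
  r_norm <- r / max(max(r), 1e-12)
  bias <- config$habitat_bias
  habitat <- character(n)
  # site-wise quota allocation: habitat drawn with probability proportional
  # to its radial placement weight times its remaining quota, so every
  # habitat's bias acts (periphery for farmland/fishpond, core for urban
  # green, neutral for orchard)
  spec <- cbind(
    farmland = exp(bias * r_norm), fishpond = exp(bias * r_norm),
    orchard = rep(1, n), urban_green = exp(-bias * r_norm)
  )
  quota <- config$n_sites[colnames(spec)]
  for (i in sample.int(n)) {
    p <- spec[i, ] * quota
    h <- colnames(spec)[sample.int(4L, 1L, prob = p / sum(p))]
    habitat[i] <- h
    quota[h] <- quota[h] - 1L
  }
  field <- cluster_field(pts, config)
  rows <- list()
  for (s in season_levels()) {
    mu <- config$area_ha * config$mean_density[habitat, s] * exp(field)
    counts <- if (is.infinite(config$dispersion)) {
      stats::rpois(n, mu)
    } else {
      stats::rnbinom(n, size = config$dispersion, mu = mu)
    }
    rows[[s]] <- data.frame(
      site_id = sprintf("S%03d", seq_len(n)),
      x = pts[, 1], y = pts[, 2],
      habitat = habitat, season = s,
      area_ha = config$area_ha, nest_count = as.integer(counts),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  add_density(out)
}

#' Checkerboard lattice fixture
#'
#' An even `side x side` unit lattice of alternating +1/-1 values with
#' rook-adjacency, row-standardized weights: the canonical perfectly
#' negatively autocorrelated configuration (global Moran's I = -1).
#'
#' @param side Even integer >= 2.
#' @return List with `values`, `coords`, and `weights` (a
#'   `spatial_weights`).
#' @export
generate_checkerboard <- function(side) {
  if (side < 2 || side %% 2 != 0) stop("side must be an even integer >= 2")
  ij <- expand.grid(row = seq_len(side), col = seq_len(side))
  values <- ifelse((ij$row + ij$col) %% 2 == 0, 1, -1)
  n <- side * side
  idx <- function(r, c) (r - 1L) * side + c
  ii <- integer(0); jj <- integer(0)
  for (r in seq_len(side)) for (c in seq_len(side)) {
    i <- idx(r, c)
    if (r > 1) { ii <- c(ii, i); jj <- c(jj, idx(r - 1L, c)) }
    if (r < side) { ii <- c(ii, i); jj <- c(jj, idx(r + 1L, c)) }
    if (c > 1) { ii <- c(ii, i); jj <- c(jj, idx(r, c - 1L)) }
    if (c < side) { ii <- c(ii, i); jj <- c(jj, idx(r, c + 1L)) }
  }
  W <- Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(n, n))
  w <- new_spatial_weights(W, seq_len(n), method = "rook", parameter = side)
  w <- row_standardize(w)
  ord <- idx(ij$row, ij$col)
  coords <- cbind(x = ij$col, y = ij$row)[order(ord), ]
  values <- values[order(ord)]
  list(values = values, coords = coords, weights = w)
}

#' Null spatial fixture
#'
#' `n` i.i.d. standard-normal values at uniform random points in a 10 km
#' square, with default kNN weights: a spatially random configuration used
#' to calibrate Moran inference (type-I error).
#'
#' @param n Number of sites, >= 10.
#' @param seed Integer seed.
#' @param k Neighbours for the kNN weights (default 8).
#' @return List with `values`, `coords`, `weights`.
#' @export
generate_null <- function(n, seed = 1L, k = 8) {
  if (n < 10) stop("n must be at least 10")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  coords <- cbind(x = stats::runif(n, 0, 10000), y = stats::runif(n, 0, 10000))
  values <- stats::rnorm(n)
  w <- build_weights(coords, method = "knn", parameter = k)
  list(values = values, coords = coords, weights = w)
}
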
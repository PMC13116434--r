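# Independent brute-force oracles used to cross-check the vectorised
# implementations. These deliberately follow the defining formulas with
# explicit loops and know nothing about the package internals.

oracle_global_moran <- function(values, W) {
  W <- as.matrix(W)
  n <- length(values)
  xb <- mean(values)
  num <- 0; S0 <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j) {
    num <- num + W[i, j] * (values[i] - xb) * (values[j] - xb)
    S0 <- S0 + W[i, j]
  }
  (n / S0) * num / sum((values - xb)^2)
}

oracle_local_moran <- function(values, W) {
  W <- as.matrix(W)
  n <- length(values)
  xb <- mean(values)
  m2 <- sum((values - xb)^2) / n
  out <- numeric(n)
  for (i in seq_len(n)) {
    lag <- 0
    for (j in seq_len(n)) if (j != i) lag <- lag + W[i, j] * (values[j] - xb)
    out[i] <- (values[i] - xb) * lag / m2
  }
  out
}

oracle_idw <- function(obs, vals, target, power) {
  d <- sqrt((obs[, 1] - target[1])^2 + (obs[, 2] - target[2])^2)
  if (any(d == 0)) return(vals[which(d == 0)[1]])
  w <- d^(-power)
  sum(w * vals) / sum(w)
}

oracle_kde_point <- function(pts, wts, at, t) {
  total <- 0
  for (i in seq_len(nrow(pts))) {
    d <- sqrt((pts[i, 1] - at[1])^2 + (pts[i, 2] - at[2])^2)
    if (d < t) total <- total + (3 / pi) * wts[i] * (1 - (d / t)^2)^2 / t^2
  }
  total
}

# random raw spatial weights over random points (kNN-style sparsity)
random_weights_instance <- function(n, seed) {
  set.seed(seed)
  coords <- cbind(runif(n, 0, 100), runif(n, 0, 100))
  k <- sample(2:min(6, n - 1), 1)
  w <- build_knn_weights(coords, k = k)
  if (runif(1) < 0.5) w <- row_standardize(w)
  list(coords = coords, w = w, values = rnorm(n))
}

make_sites <- function(n = 8, seed = 1) {
  set.seed(seed)
  data.frame(
    site_id = sprintf("S%02d", seq_len(n)),
    x = runif(n, 0, 1000), y = runif(n, 0, 1000),
    habitat = sample(habitat_levels(), n, replace = TRUE),
    season = "spring",
    area_ha = 0.12,
    nest_count = rpois(n, 4),
    stringsAsFactors = FALSE
  )
}
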
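# Global and local Moran's I with analytic and permutation inference, and
# LISA cluster classification. Conventions follow Cliff & Ord (global
# moments) and Anselin (local statistic and conditional permutation).

check_moran_inputs <- function(values, w) {
  stopifnot(inherits(w, "spatial_weights"))
  n <- length(w$ids)
  if (length(values) != n) stop("one value per site required")
  if (any(!is.finite(values))) stop("values must be finite")
  iso <- which(Matrix::rowSums(w$W) == 0 & Matrix::colSums(w$W) == 0)
  if (length(iso) == n) stop("all sites are isolated: invalid weights")
  if (length(iso) > 0) {
    warning("excluding ", length(iso),
            " isolated site(s) from Moran computation: ",
            paste(utils::head(w$ids[iso], 5), collapse = ", "),
            if (length(iso) > 5) ", ..." else "")
    keep <- setdiff(seq_len(n), iso)
    w <- new_spatial_weights(w$W[keep, keep, drop = FALSE], w$ids[keep],
                             w$method, w$parameter, w$standardized)
    values <- values[keep]
    n <- length(keep)
  }
  if (n < 3) stop("at least 3 non-isolated sites required")
  if (stats::var(values) == 0) stop("values have zero variance: Moran's I undefined")
  list(values = values, w = w)
}

moran_stat <- function(z, W, S0, m2n) {
  # z centred values; m2n = sum(z^2); I = (n/S0) * z'Wz / sum(z^2)
  (length(z) / S0) * sum(z * as.numeric(W %*% z)) / m2n
}

#' Global Moran's I
#'
#' I = (n / S0) * sum_ij w_ij (x_i - xbar)(x_j - xbar) / sum_i (x_i - xbar)^2
#' with S0 = sum_ij w_ij and the diagonal excluded. Positive I indicates that
#' similar values cluster in space, negative I that dissimilar values are
#' neighbours. Isolated sites are dropped with a warning.
#'
#' @param values Numeric site attribute (e.g. nest density), one per site.
#' @param w A `spatial_weights` object over the same sites.
#' @return The Moran's I statistic (numeric scalar).
#' @export
global_moran <- function(values, w) {
  inp <- check_moran_inputs(values, w)
  z <- inp$values - mean(inp$values)
  S0 <- sum(inp$w$W)
  moran_stat(z, inp$w$W, S0, sum(z * z))
}

moran_moments <- function(W, n, assumption = c("randomization", "normality"),
                          z = NULL) {
  assumption <- match.arg(assumption)
  S0 <- sum(W)
  Wd <- W + Matrix::t(W)
  S1 <- 0.5 * sum(Wd@x^2)
  rs <- Matrix::rowSums(W); cs <- Matrix::colSums(W)
  S2 <- sum((rs + cs)^2)
  EI <- -1 / (n - 1)
  if (assumption == "normality") {
    VarI <- (n^2 * S1 - n * S2 + 3 * S0^2) / (S0^2 * (n^2 - 1)) - EI^2
  } else {
    b2 <- (sum(z^4) / n) / (sum(z^2) / n)^2
    VarI <- (n * ((n^2 - 3 * n + 3) * S1 - n * S2 + 3 * S0^2) -
               b2 * ((n^2 - n) * S1 - 2 * n * S2 + 6 * S0^2)) /
      ((n - 1) * (n - 2) * (n - 3) * S0^2) - EI^2
  }
  list(EI = EI, VarI = VarI)
}

#' Inference on global Moran's I
#'
#' Computes Moran's I with a null reference distribution: closed-form
#' moments under the `normality` or `randomization` assumption (Cliff–Ord),
#' or a Monte-Carlo `permutation` null obtained by recomputing I over random
#' relabelings of the values. The expected value under every null is
#' E\[I\] = -1/(n-1). Z-scores are (I - E\[I\]) / sd; p-values are two-sided
#' (for permutation: fraction of permuted |I - E\[I\]| at least as extreme,
#' with the +1 correction).
#'
#' @param values Numeric site attribute.
#' @param w A `spatial_weights` object.
#' @param method `"permutation"` (default), `"randomization"`, or
#'   `"normality"`.
#' @param n_perm Number of permutations (>= 99) for the permutation method.
#' @param seed Integer seed for the permutation draw; required for
#'   reproducible permutation inference.
#' @return An object of class `moran_result`: list with `I`, `expected`,
#'   `variance`, `sd`, `z_score`, `p_value`, `method`, `n`, and for
#'   permutation inference `n_perm`, `seed` and the vector `perm_I`.
#' @export
moran_inference <- function(values, w,
                            method = c("permutation", "randomization",
                                       "normality"),
                            n_perm = 999, seed = NULL) {
  method <- match.arg(method)
  inp <- check_moran_inputs(values, w)
  x <- inp$values; W <- inp$w$W
  n <- length(x)
  z <- x - mean(x)
  S0 <- sum(W)
  m2n <- sum(z * z)
  I_obs <- moran_stat(z, W, S0, m2n)
  EI <- -1 / (n - 1)
  res <- list(I = I_obs, expected = EI, method = method, n = n)
  if (method == "permutation") {
    if (n_perm < 99) stop("n_perm must be at least 99")
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
      set.seed(seed)
    }
    perm_I <- vapply(seq_len(n_perm), function(b) {
      zp <- z[sample.int(n)]
      moran_stat(zp, W, S0, m2n)
    }, numeric(1))
    p <- (1 + sum(abs(perm_I - EI) >= abs(I_obs - EI))) / (n_perm + 1)
    sdI <- stats::sd(perm_I)
    res$variance <- sdI^2
    res$sd <- sdI
    res$z_score <- (I_obs - EI) / sdI
    res$p_value <- p
    res$n_perm <- n_perm
    res$seed <- seed
    res$perm_I <- perm_I
  } else {
    mom <- moran_moments(W, n, assumption = method, z = z)
    sdI <- sqrt(mom$VarI)
    zsc <- (I_obs - EI) / sdI
    res$variance <- mom$VarI
    res$sd <- sdI
    res$z_score <- zsc
    res$p_value <- 2 * stats::pnorm(-abs(zsc))
  }
  class(res) <- "moran_result"
  res
}

#' @export
print.moran_result <- function(x, ...) {
  cat(sprintf("Global Moran's I: %.6f (E[I] = %.6f, n = %d)\n", x$I,
              x$expected, x$n))
  cat(sprintf("  method = %s%s; z = %.4f; p = %.4g\n", x$method,
              if (!is.null(x$n_perm)) sprintf(" (%d permutations)", x$n_perm)
              else "", x$z_score, x$p_value))
  invisible(x)
}

#' Local Moran's I
#'
#' The Anselin local statistic
#' I_i = (x_i - xbar) * sum_j w_ij (x_j - xbar) / m2, with
#' m2 = (1/n) sum_k (x_k - xbar)^2. With row-standardized weights the local
#' statistics average to the global statistic: sum_i I_i = n * I.
#'
#' @param values Numeric site attribute.
#' @param w A `spatial_weights` object, normally row-standardized.
#' @return Numeric vector of local statistics, one per (non-isolated) site,
#'   named by site id.
#' @export
local_moran <- function(values, w) {
  inp <- check_moran_inputs(values, w)
  z <- inp$values - mean(inp$values)
  m2 <- sum(z * z) / length(z)
  lag <- as.numeric(inp$w$W %*% z)
  out <- z * lag / m2
  names(out) <- inp$w$ids
  out
}

#' LISA cluster classification
#'
#' Per-site local Moran's I with conditional-permutation p-values and
#' cluster labels. For site i the permutation null holds x_i fixed and
#' redraws its neighbours' values from the remaining n-1 observations; the
#' two-sided p-value uses the +1 correction. Sites significant at `alpha`
#' are labelled by the quadrant of (deviation from the mean, spatial lag of
#' the deviation): HH (high surrounded by high), LL, HL, LH; all others NS.
#'
#' @param values Numeric site attribute.
#' @param w A `spatial_weights` object, normally row-standardized.
#' @param alpha Per-site significance level (default 0.05).
#' @param n_perm Conditional permutations per site (default 999).
#' @param seed Integer seed.
#' @param adjust `"none"` (default, matching a raw per-site threshold) or
#'   `"BH"` for false-discovery-rate adjustment across sites.
#' @return A data frame of class `lisa_result`: `site_id`, `I_i`,
#'   `deviation`, `lag`, `p_value`, `label`; attributes record `alpha`,
#'   `n_perm`, `seed`, `adjust`.
#' @export
lisa_classify <- function(values, w, alpha = 0.05, n_perm = 999, seed = NULL,
                          adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  inp <- check_moran_inputs(values, w)
  x <- inp$values; W <- inp$w$W
  n <- length(x)
  z <- x - mean(x)
  m2 <- sum(z * z) / n
  lag <- as.numeric(W %*% z)
  Ii <- z * lag / m2
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  p <- numeric(n)
  for (i in seq_len(n)) {
    wi <- W[i, ]
    nb <- which(wi != 0)
    if (length(nb) == 0L) { p[i] <- NA_real_; next }
    wnb <- as.numeric(wi[nb])
    pool <- z[-i]
    k <- length(nb)
    # permuted lags: draw k neighbour values without replacement per sweep
    perm_lag <- vapply(seq_len(n_perm), function(b)
      sum(wnb * pool[sample.int(n - 1, k)]), numeric(1))
    perm_Ii <- z[i] * perm_lag / m2
    p[i] <- (1 + sum(abs(perm_Ii) >= abs(Ii[i]))) / (n_perm + 1)
  }
  p_use <- if (adjust == "BH") bh_adjust(p) else p
  label <- rep("NS", n)
  sig <- !is.na(p_use) & p_use <= alpha
  label[sig & z > 0 & lag > 0] <- "HH"
  label[sig & z < 0 & lag < 0] <- "LL"
  label[sig & z > 0 & lag < 0] <- "HL"
  label[sig & z < 0 & lag > 0] <- "LH"
  out <- data.frame(site_id = inp$w$ids, I_i = Ii, deviation = z, lag = lag,
                    p_value = p_use, label = label, stringsAsFactors = FALSE)
  attr(out, "alpha") <- alpha
  attr(out, "n_perm") <- n_perm
  attr(out, "seed") <- seed
  attr(out, "adjust") <- adjust
  class(out) <- c("lisa_result", "data.frame")
  out
}
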
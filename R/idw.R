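# Inverse distance weighting: deterministic interpolation in which the
# influence of an observation decays as distance to the power -a.

#' Inverse-distance-weighted prediction
#'
#' Estimates the value at each target point as the convex combination
#' Z(x) = sum_i W_i Z(x_i) with W_i = d(x, x_i)^(-a) / sum_j d(x, x_j)^(-a),
#' where `a` is the power (distance index). A target coincident with an
#' observation returns that observation's value exactly. With
#' `max_neighbours` set, only the nearest that many observations enter the
#' sum; by default every observation participates.
#'
#' @param obs_coords Two-column matrix of observation coordinates (metres).
#' @param obs_values Numeric observation values, one per row of `obs_coords`.
#' @param targets Two-column matrix of prediction locations.
#' @param power Positive power `a` (default 2, the conventional choice).
#' @param max_neighbours Optional cap on the number of nearest observations
#'   used per target; `NULL` (default) uses all.
#' @return Numeric vector of predictions, one per target.
#' @export
idw_predict <- function(obs_coords, obs_values, targets, power = 2,
                        max_neighbours = NULL) {
  obs_coords <- as.matrix(obs_coords)
  targets <- as.matrix(targets)
  if (nrow(obs_coords) == 0L) stop("empty observation set")
  if (length(obs_values) != nrow(obs_coords)) {
    stop("one value per observation required")
  }
  if (anyDuplicated(obs_coords)) stop("observation coordinates must be distinct")
  if (!is.finite(power) || power <= 0) stop("power must be > 0")
  n <- nrow(obs_coords)
  m <- nrow(targets)
  out <- numeric(m)
  for (t in seq_len(m)) {
    dx <- obs_coords[, 1] - targets[t, 1]
    dy <- obs_coords[, 2] - targets[t, 2]
    d <- sqrt(dx * dx + dy * dy)
    hit <- which(d == 0)
    if (length(hit)) { out[t] <- obs_values[hit[1]]; next }
    use <- seq_len(n)
    if (!is.null(max_neighbours) && max_neighbours < n) {
      use <- order(d)[seq_len(max_neighbours)]
    }
    wgt <- d[use]^(-power)
    out[t] <- sum(wgt * obs_values[use]) / sum(wgt)
  }
  out
}

#' IDW interpolation onto a raster grid
#'
#' Evaluates [idw_predict()] at every cell centre of the supplied grid
#' geometry. Because IDW is a convex combination, the surface extremes never
#' exceed the observed extremes.
#'
#' @param obs_coords,obs_values,power,max_neighbours As in [idw_predict()].
#' @param grid A `raster_surface` supplying the grid geometry (values are
#'   ignored).
#' @return A `raster_surface` filled with predictions.
#' @export
idw_grid <- function(obs_coords, obs_values, grid, power = 2,
                     max_neighbours = NULL) {
  stopifnot(inherits(grid, "raster_surface"))
  centers <- cell_centers(grid)
  pred <- idw_predict(obs_coords, obs_values, centers, power = power,
                      max_neighbours = max_neighbours)
  raster_surface(grid$xmin, grid$ymin, grid$cellsize, grid$nrow, grid$ncol,
                 values = matrix(pred, grid$nrow, grid$ncol, byrow = TRUE),
                 nodata = grid$nodata)
}
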
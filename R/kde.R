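# Density-weighted quartic (biweight) kernel density surface with finite
# support, used for hotspot mapping of infested plots.

#' Density-weighted quartic kernel density surface
#'
#' Evaluates, at every cell centre of the grid,
#' f(x, y) = (1 / t^2) * sum_i (3 / pi) * rho_i * (1 - (d_i / t)^2)^2
#' over points with d_i < t, where d_i is the distance from (x, y) to
#' weighted point i, rho_i its weight (here the plot's nest density), and t
#' the bandwidth (search radius) in metres. The quartic kernel has finite
#' support: points at distance >= t contribute nothing, and the surface
#' integrates to sum(rho_i) over any domain containing all support disks.
#'
#' @param coords Two-column matrix of point coordinates (metres).
#' @param weights Non-negative point weights rho_i (nest densities).
#' @param grid A `raster_surface` supplying the grid geometry.
#' @param bandwidth Search radius t in metres, > 0; defaults to
#'   [default_bandwidth()] of the points.
#' @return A `raster_surface` of kernel density values (weight per m^2).
#' @export
weighted_kde <- function(coords, weights, grid, bandwidth = NULL) {
  coords <- as.matrix(coords)
  stopifnot(inherits(grid, "raster_surface"))
  if (nrow(coords) == 0L) stop("at least one point required")
  if (length(weights) != nrow(coords)) stop("one weight per point required")
  if (any(!is.finite(weights)) || any(weights < 0)) {
    stop("weights must be finite and non-negative")
  }
  if (is.null(bandwidth)) bandwidth <- default_bandwidth(coords)
  if (!is.finite(bandwidth) || bandwidth <= 0) {
    stop("bandwidth must be > 0")
  }
  centers <- cell_centers(grid)
  t2 <- bandwidth^2
  f <- numeric(nrow(centers))
  # accumulate per data point: each touches only cells inside its support disk
  for (i in seq_len(nrow(coords))) {
    if (weights[i] == 0) next
    dx <- centers[, 1] - coords[i, 1]
    dy <- centers[, 2] - coords[i, 2]
    d2 <- dx * dx + dy * dy
    inside <- d2 < t2
    if (any(inside)) {
      u <- 1 - d2[inside] / t2
      f[inside] <- f[inside] + (3 / pi) * weights[i] * u * u / t2
    }
  }
  raster_surface(grid$xmin, grid$ymin, grid$cellsize, grid$nrow, grid$ncol,
                 values = matrix(f, grid$nrow, grid$ncol, byrow = TRUE),
                 nodata = grid$nodata)
}

#' Rule-of-thumb KDE bandwidth
#'
#' Twice the mean nearest-neighbour distance among the points: a
#' deterministic, scale-aware search radius that adapts to survey density.
#' Scaling all coordinates by k scales the bandwidth by k.
#'
#' @param coords Two-column matrix of point coordinates (metres), >= 2 rows.
#' @return Bandwidth in metres (> 0).
#' @export
default_bandwidth <- function(coords) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 2L) stop("at least two points required")
  D <- as.matrix(stats::dist(coords))
  diag(D) <- Inf
  nn <- apply(D, 1L, min)
  t <- 2 * mean(nn)
  if (t <= 0) stop("degenerate configuration: all points coincide")
  t
}
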
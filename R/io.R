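# Readers/writers for the standard site table (CSV and GeoJSON points),
# occurrence-scheme config, lon/lat projection, and serialization helpers.

#' Project longitude/latitude to planar metres
#'
#' Spherical Lambert azimuthal equal-area projection centred on
#' `center` (defaults to the data centroid), sphere radius 6371008.8 m.
#' All package distance computations require planar metres; geographic
#' inputs must pass through this projection first — great-circle distance is
#' never silently substituted.
#'
#' @param lon,lat Numeric degrees.
#' @param center Optional `c(lon0, lat0)` projection centre in degrees.
#' @return Two-column matrix of (x, y) in metres; the centre used is
#'   attached as attribute `center`.
#' @export
project_lonlat <- function(lon, lat, center = NULL) {
  if (any(!is.finite(lon)) || any(!is.finite(lat)) ||
      any(abs(lat) > 90) || any(abs(lon) > 360)) {
    stop("lon/lat out of range")
  }
  if (is.null(center)) center <- c(mean(lon), mean(lat))
  R <- 6371008.8
  d2r <- pi / 180
  lam <- lon * d2r; phi <- lat * d2r
  lam0 <- center[1] * d2r; phi0 <- center[2] * d2r
  kden <- 1 + sin(phi0) * sin(phi) + cos(phi0) * cos(phi) * cos(lam - lam0)
  kp <- sqrt(2 / kden)
  x <- R * kp * cos(phi) * sin(lam - lam0)
  y <- R * kp * (cos(phi0) * sin(phi) - sin(phi0) * cos(phi) * cos(lam - lam0))
  out <- cbind(x = x, y = y)
  attr(out, "center") <- center
  out
}

#' Read and write site tables
#'
#' Site tables are comma-delimited text with header columns `site_id`, `x`,
#' `y`, `habitat`, `season`, `area_ha`, `nest_count`. In `lonlat_deg` mode
#' the `x`/`y` columns are longitude/latitude degrees and are projected to
#' planar metres ([project_lonlat()]) on read. Malformed rows are rejected
#' with their line numbers.
#'
#' @param path File path.
#' @param coordinate_mode `"projected_m"` (default) or `"lonlat_deg"`.
#' @return A validated site table with a `density` column.
#' @export
read_sites <- function(path, coordinate_mode = c("projected_m",
                                                 "lonlat_deg")) {
  coordinate_mode <- match.arg(coordinate_mode)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  required <- c("site_id", "x", "y", "habitat", "season", "area_ha",
                "nest_count")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    stop("header is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  line_no <- seq_len(nrow(raw)) + 1L  # header is line 1
  num <- function(col) suppressWarnings(as.numeric(raw[[col]]))
  x <- num("x"); y <- num("y"); area <- num("area_ha"); cnt <- num("nest_count")
  bad <- which(is.na(x) | is.na(y) | is.na(area) | is.na(cnt))
  if (length(bad)) {
    stop("non-numeric fields at line(s): ", paste(line_no[bad], collapse = ", "))
  }
  probe <- data.frame(site_id = raw$site_id, x = x, y = y,
                      habitat = raw$habitat, season = raw$season,
                      area_ha = area, nest_count = cnt,
                      stringsAsFactors = FALSE)
  bad <- which(probe$area_ha <= 0)
  if (length(bad)) {
    stop("non-positive area_ha at line(s): ", paste(line_no[bad], collapse = ", "))
  }
  bad <- which(!(probe$habitat %in% habitat_levels()) |
                 !(probe$season %in% season_levels()))
  if (length(bad)) {
    stop("unknown habitat/season token at line(s): ",
         paste(line_no[bad], collapse = ", "))
  }
  bad <- which(probe$nest_count < 0 | probe$nest_count != round(probe$nest_count))
  if (length(bad)) {
    stop("invalid nest_count at line(s): ", paste(line_no[bad], collapse = ", "))
  }
  probe$nest_count <- as.integer(round(probe$nest_count))
  if (coordinate_mode == "lonlat_deg") {
    xy <- project_lonlat(probe$x, probe$y)
    probe$x <- xy[, 1]; probe$y <- xy[, 2]
  }
  add_density(validate_sites(probe))
}

#' @param sites A site table.
#' @rdname read_sites
#' @export
write_sites <- function(sites, path) {
  sites <- validate_sites(sites)
  cols <- c("site_id", "x", "y", "habitat", "season", "area_ha", "nest_count")
  utils::write.csv(sites[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write GeoJSON point site tables
#'
#' GeoJSON FeatureCollection of Point geometries whose properties carry
#' `site_id`, `habitat`, `season`, `area_ha`, `nest_count`; coordinates are
#' the point geometry. Coordinate mode is handled as in [read_sites()].
#'
#' @param path File path.
#' @param coordinate_mode `"projected_m"` or `"lonlat_deg"`.
#' @return A validated site table.
#' @export
read_sites_geojson <- function(path, coordinate_mode = c("projected_m",
                                                         "lonlat_deg")) {
  coordinate_mode <- match.arg(coordinate_mode)
  gj <- jsonlite::read_json(path)
  if (is.null(gj$features)) stop("not a GeoJSON FeatureCollection")
  rows <- lapply(gj$features, function(f) {
    cc <- unlist(f$geometry$coordinates)
    p <- f$properties
    data.frame(site_id = as.character(p$site_id), x = cc[1], y = cc[2],
               habitat = as.character(p$habitat),
               season = as.character(p$season),
               area_ha = as.numeric(p$area_ha),
               nest_count = as.numeric(p$nest_count),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (coordinate_mode == "lonlat_deg") {
    xy <- project_lonlat(out$x, out$y)
    out$x <- xy[, 1]; out$y <- xy[, 2]
  }
  add_density(validate_sites(out))
}

#' @param sites A site table.
#' @rdname read_sites_geojson
#' @export
write_sites_geojson <- function(sites, path) {
  sites <- validate_sites(sites)
  features <- lapply(seq_len(nrow(sites)), function(i) {
    list(
      type = "Feature",
      geometry = list(type = "Point",
                      coordinates = c(sites$x[i], sites$y[i])),
      properties = list(site_id = sites$site_id[i],
                        habitat = sites$habitat[i],
                        season = sites$season[i],
                        area_ha = sites$area_ha[i],
                        nest_count = sites$nest_count[i])
    )
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an occurrence scheme from a YAML config
#'
#' The config maps level labels to `[lower, upper]` density bounds in
#' nests/ha, e.g. `II: [10, 50]`; `.inf` denotes an unbounded top level.
#'
#' @param path YAML file path.
#' @return An [occurrence_scheme()].
#' @export
read_occurrence_scheme <- function(path) {
  y <- yaml::read_yaml(path)
  levels <- names(y)
  lower <- vapply(y, function(b) as.numeric(b[[1]]), numeric(1))
  upper <- vapply(y, function(b) as.numeric(b[[2]]), numeric(1))
  occurrence_scheme(levels, lower, upper)
}
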
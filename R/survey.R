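# Site-level metrics: nest density, occurrence-level classification,
# mound volume, and habitat/season summary tables.

HABITATS <- c("farmland", "fishpond", "orchard", "urban_green")
SEASONS <- c("spring", "summer", "autumn", "winter")

#' Habitat and season level sets
#'
#' The closed enumerations used throughout the package: four habitat
#' categories (farmland, fishpond, orchard, urban green space) and the four
#' survey seasons.
#'
#' @return A character vector of levels.
#' @export
habitat_levels <- function() HABITATS

#' @rdname habitat_levels
#' @export
season_levels <- function() SEASONS

#' Validate a survey-site table
#'
#' Checks a data frame of georeferenced survey observations against the
#' site-table contract: columns `site_id`, `x`, `y`, `habitat`, `season`,
#' `area_ha`, `nest_count`; positive areas; non-negative integer nest counts;
#' habitat and season drawn from the closed enumerations; `site_id` unique
#' within each season. Coordinates are planar metres.
#'
#' @param sites A data frame with the columns above.
#' @return The validated data frame (invisibly unchanged), with habitat and
#'   season coerced to character.
#' @export
validate_sites <- function(sites) {
  required <- c("site_id", "x", "y", "habitat", "season", "area_ha",
                "nest_count")
  if (!is.data.frame(sites)) stop("'sites' must be a data frame")
  missing_cols <- setdiff(required, names(sites))
  if (length(missing_cols) > 0L) {
    stop("site table is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  sites$habitat <- as.character(sites$habitat)
  sites$season <- as.character(sites$season)
  problems <- character(0)
  bad <- which(!is.finite(sites$x) | !is.finite(sites$y))
  if (length(bad)) problems <- c(problems,
    paste0("non-finite coordinates in rows: ", paste(bad, collapse = ", ")))
  bad <- which(!is.finite(sites$area_ha) | sites$area_ha <= 0)
  if (length(bad)) problems <- c(problems,
    paste0("non-positive area_ha in rows: ", paste(bad, collapse = ", ")))
  bad <- which(!is.finite(sites$nest_count) | sites$nest_count < 0 |
                 sites$nest_count != round(sites$nest_count))
  if (length(bad)) problems <- c(problems,
    paste0("nest_count not a non-negative integer in rows: ",
           paste(bad, collapse = ", ")))
  bad <- which(!(sites$habitat %in% HABITATS))
  if (length(bad)) problems <- c(problems,
    paste0("unknown habitat token in rows: ", paste(bad, collapse = ", ")))
  bad <- which(!(sites$season %in% SEASONS))
  if (length(bad)) problems <- c(problems,
    paste0("unknown season token in rows: ", paste(bad, collapse = ", ")))
  for (s in unique(sites$season)) {
    ids <- sites$site_id[sites$season == s]
    if (anyDuplicated(ids)) {
      dup <- unique(ids[duplicated(ids)])
      problems <- c(problems,
        paste0("duplicate site_id within season '", s, "': ",
               paste(dup, collapse = ", ")))
    }
  }
  if (length(problems)) {
    stop("invalid site table:\n  ", paste(problems, collapse = "\n  "))
  }
  invisible(sites)
}

#' Nest density of a surveyed site
#'
#' Density D = N / S in nests per hectare, where N is the count of active
#' nests and S the surveyed area in hectares.
#'
#' @param nest_count Non-negative integer count(s) of active nests.
#' @param area_ha Surveyed area(s) in hectares; must be strictly positive.
#' @return Numeric vector of densities in nests per hectare.
#' @examples
#' compute_density(10, 0.5)  # 20 nests/ha
#' @export
compute_density <- function(nest_count, area_ha) {
  if (any(!is.finite(area_ha)) || any(area_ha <= 0)) {
    stop("area_ha must be strictly positive")
  }
  if (any(!is.finite(nest_count)) || any(nest_count < 0)) {
    stop("nest_count must be non-negative")
  }
  nest_count / area_ha
}

#' Add a density column to a site table
#'
#' @param sites A validated site table.
#' @return The table with a `density` column (nests per hectare).
#' @export
add_density <- function(sites) {
  sites <- validate_sites(sites)
  sites$density <- compute_density(sites$nest_count, sites$area_ha)
  sites
}

#' Occurrence-level classification schemes
#'
#' An occurrence scheme is an ordered set of density intervals, one per
#' infestation level, in nests per hectare. Levels are drawn from
#' `none_detected`, `I`, `II`, `III`, `IV`. Intervals use a closed lower and
#' open upper bound, except the highest level which is closed on both ends;
#' density 0 always maps to `none_detected`. The national standard the field
#' protocol cites does not publish its cut-offs openly, so the thresholds are
#' required configuration: `example_occurrence_scheme()` returns a clearly
#' labelled placeholder for testing and demonstration, not the standard's
#' values.
#'
#' @param levels Character vector of level labels, ordered from lowest.
#' @param lower,upper Numeric bounds per level (nests per hectare).
#' @return An object of class `occurrence_scheme`.
#' @export
occurrence_scheme <- function(levels, lower, upper) {
  if (length(levels) != length(lower) || length(levels) != length(upper)) {
    stop("levels, lower and upper must have equal length")
  }
  allowed <- c("none_detected", "I", "II", "III", "IV")
  if (!all(levels %in% allowed)) {
    stop("level labels must be drawn from: ", paste(allowed, collapse = ", "))
  }
  if (any(upper < lower)) stop("upper bounds must be >= lower bounds")
  o <- order(lower)
  levels <- levels[o]; lower <- lower[o]; upper <- upper[o]
  n <- length(levels)
  if (n > 1L) {
    if (any(lower[-1] != upper[-n])) {
      stop("intervals must be contiguous and non-overlapping")
    }
    if (any(diff(lower) <= 0)) stop("bounds must be strictly increasing")
  }
  if (lower[1] != 0) stop("the scheme must start at density 0")
  if (levels[1] != "none_detected") {
    stop("the lowest interval must be 'none_detected' so density 0 maps to it")
  }
  structure(list(levels = levels, lower = lower, upper = upper),
            class = "occurrence_scheme")
}

#' @export
print.occurrence_scheme <- function(x, ...) {
  cat("Occurrence-level scheme (nests/ha):\n")
  for (i in seq_along(x$levels)) {
    hi <- if (is.finite(x$upper[i])) format(x$upper[i]) else "Inf"
    close_hi <- if (i == length(x$levels)) "]" else ")"
    cat(sprintf("  %-13s [%s, %s%s\n", x$levels[i], format(x$lower[i]), hi,
                close_hi))
  }
  invisible(x)
}

#' Placeholder occurrence scheme
#'
#' @return An `occurrence_scheme` with illustrative (placeholder) cut-offs.
#'   These are NOT the national standard's thresholds, which are not printed
#'   in open sources; supply your own scheme for real surveys.
#' @rdname occurrence_scheme
#' @export
example_occurrence_scheme <- function() {
  occurrence_scheme(
    levels = c("none_detected", "I", "II", "III", "IV"),
    lower = c(0, 1e-9, 10, 50, 100),
    upper = c(1e-9, 10, 50, 100, Inf)
  )
}

#' Classify nest density into an occurrence level
#'
#' Maps densities to ordinal infestation levels under a configured scheme.
#' Intervals are closed below and open above (the top level is closed at both
#' ends); density exactly 0 is always `none_detected`. Classification is
#' monotone non-decreasing in density.
#'
#' @param density Numeric vector of nest densities (nests per hectare), >= 0.
#' @param scheme An [occurrence_scheme()].
#' @return Character vector of level labels.
#' @export
classify_occurrence <- function(density, scheme) {
  if (!inherits(scheme, "occurrence_scheme")) {
    stop("'scheme' must be an occurrence_scheme")
  }
  if (any(!is.finite(density)) || any(density < 0)) {
    stop("density must be finite and non-negative")
  }
  n <- length(scheme$levels)
  top <- scheme$upper[n]
  if (is.finite(top) && any(density > top)) {
    stop("density outside the range covered by the scheme (max bound ",
         top, ")")
  }
  out <- character(length(density))
  for (i in seq_along(density)) {
    d <- density[i]
    if (d == 0) { out[i] <- "none_detected"; next }
    hit <- which(d >= scheme$lower & (d < scheme$upper |
                   (seq_len(n) == n & d <= scheme$upper)))
    out[i] <- scheme$levels[hit[1]]
  }
  out
}

#' Mound volume from field dimensions
#'
#' Treats the mound as a half-ellipsoid with basal semi-axes `a` (half
#' length) and `b` (half width) and height `c`, all in metres:
#' V = (2/3) * pi * a * b * c. The basal area is S = pi * a * b.
#'
#' @param a,b Half-length and half-width of the mound base, metres.
#' @param c Mound height, metres.
#' @return Volume in cubic metres.
#' @examples
#' mound_volume(0.3, 0.2, 0.1)
#' @export
mound_volume <- function(a, b, c) {
  if (any(!is.finite(a)) || any(!is.finite(b)) || any(!is.finite(c)) ||
      any(a < 0) || any(b < 0) || any(c < 0)) {
    stop("mound dimensions must be finite and non-negative")
  }
  (2 / 3) * pi * a * b * c
}

#' Summarise density and abundance by habitat and season
#'
#' One row per observed (habitat, season) combination with the number of
#' sites, mean nest density, its standard error (sample SD / sqrt(n); `NA`
#' for n = 1), and mean nest count per site.
#'
#' @param sites A site table; a `density` column is added if absent.
#' @return A data frame sorted by season then habitat.
#' @export
summarize_by_habitat_season <- function(sites) {
  sites <- validate_sites(sites)
  if (nrow(sites) == 0L) stop("site table is empty")
  if (is.null(sites$density)) sites <- add_density(sites)
  key <- interaction(sites$habitat, sites$season, drop = TRUE)
  rows <- lapply(levels(key), function(k) {
    idx <- key == k
    d <- sites$density[idx]
    n <- sum(idx)
    data.frame(
      habitat = sites$habitat[idx][1],
      season = sites$season[idx][1],
      n = n,
      mean_density = mean(d),
      se_density = if (n > 1L) stats::sd(d) / sqrt(n) else NA_real_,
      mean_nest_count = mean(sites$nest_count[idx]),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(match(out$season, SEASONS), match(out$habitat, HABITATS)), ]
  rownames(out) <- NULL
  out
}
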
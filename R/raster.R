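# A minimal regular-grid raster container with an ESRI ASCII grid
# reader/writer. Values are stored as a matrix whose first row is the
# NORTHERNMOST row; cells are addressed by origin + cell size, never by
# 1-based row/col arithmetic in user code.

#' Regular raster surface
#'
#' A regular grid of values with georeferencing metadata: lower-left corner
#' `(xmin, ymin)`, square cell size in metres, and an `nrow x ncol` value
#' matrix whose first row is the northernmost. Cell values are registered at
#' cell centres.
#'
#' @param xmin,ymin Coordinates of the lower-left corner of the grid extent
#'   (metres).
#' @param cellsize Cell edge length in metres, > 0.
#' @param nrow,ncol Grid dimensions.
#' @param values Optional value matrix (`nrow x ncol`, row 1 = north);
#'   defaults to all `NA`.
#' @param nodata No-data sentinel used on serialization.
#' @return An object of class `raster_surface`.
#' @export
raster_surface <- function(xmin, ymin, cellsize, nrow, ncol, values = NULL,
                           nodata = -9999) {
  if (!is.finite(cellsize) || cellsize <= 0) stop("cellsize must be > 0")
  if (nrow < 1 || ncol < 1) stop("grid must cover at least one cell")
  if (is.null(values)) values <- matrix(NA_real_, nrow, ncol)
  values <- as.matrix(values)
  if (!identical(dim(values), c(as.integer(nrow), as.integer(ncol)))) {
    stop("values must be an nrow x ncol matrix")
  }
  if (any(is.infinite(values), na.rm = TRUE)) {
    stop("raster values must be finite or NA")
  }
  structure(
    list(xmin = xmin, ymin = ymin, cellsize = cellsize,
         nrow = as.integer(nrow), ncol = as.integer(ncol),
         values = values, nodata = nodata),
    class = "raster_surface"
  )
}

#' @export
print.raster_surface <- function(x, ...) {
  cat(sprintf("Raster surface: %d x %d cells of %g m\n", x$nrow, x$ncol,
              x$cellsize))
  cat(sprintf("  extent: x [%g, %g], y [%g, %g]\n", x$xmin,
              x$xmin + x$ncol * x$cellsize, x$ymin,
              x$ymin + x$nrow * x$cellsize))
  v <- x$values[is.finite(x$values)]
  if (length(v)) cat(sprintf("  values: min %g, max %g\n", min(v), max(v)))
  invisible(x)
}

#' Cell-centre coordinates of a raster
#'
#' @param r A `raster_surface`.
#' @return A two-column matrix of (x, y) cell centres in the raster's
#'   row-major order (north row first).
#' @export
cell_centers <- function(r) {
  stopifnot(inherits(r, "raster_surface"))
  xs <- r$xmin + (seq_len(r$ncol) - 0.5) * r$cellsize
  ys <- r$ymin + (r$nrow - seq_len(r$nrow) + 0.5) * r$cellsize  # row 1 north
  cbind(x = rep(xs, times = r$nrow), y = rep(ys, each = r$ncol))
}

#' Grid geometry covering a set of points
#'
#' Convenience constructor: a raster whose extent covers the points plus a
#' margin, at the requested cell size.
#'
#' @param coords Two-column matrix of planar coordinates (metres).
#' @param cellsize Cell edge length in metres.
#' @param margin Extra extent added on every side, metres (default one cell).
#' @return An empty `raster_surface`.
#' @export
grid_over_points <- function(coords, cellsize, margin = cellsize) {
  coords <- as.matrix(coords)
  xmin <- min(coords[, 1]) - margin
  ymin <- min(coords[, 2]) - margin
  ncol <- max(1L, ceiling((max(coords[, 1]) + margin - xmin) / cellsize))
  nrow <- max(1L, ceiling((max(coords[, 2]) + margin - ymin) / cellsize))
  raster_surface(xmin, ymin, cellsize, nrow, ncol)
}

#' Read and write ESRI ASCII grids
#'
#' The standard plain-text raster interchange format: a six-line header
#' (ncols, nrows, xllcorner, yllcorner, cellsize, NODATA_value) followed by
#' rows of values, northernmost row first.
#'
#' @param r A `raster_surface`.
#' @param path File path.
#' @return `write_esri_ascii` returns `path` invisibly; `read_esri_ascii`
#'   returns a `raster_surface`.
#' @export
write_esri_ascii <- function(r, path) {
  stopifnot(inherits(r, "raster_surface"))
  vals <- r$values
  vals[!is.finite(vals)] <- r$nodata
  header <- c(
    paste("ncols", r$ncol),
    paste("nrows", r$nrow),
    paste("xllcorner", format(r$xmin, digits = 17)),
    paste("yllcorner", format(r$ymin, digits = 17)),
    paste("cellsize", format(r$cellsize, digits = 17)),
    paste("NODATA_value", format(r$nodata, digits = 17))
  )
  rows <- apply(vals, 1L, function(row)
    paste(sprintf("%.10g", row), collapse = " "))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' @rdname write_esri_ascii
#' @export
read_esri_ascii <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1:6]
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  get <- function(key) as.numeric(kv[match(tolower(key), tolower(kv[, 1])), 2])
  ncol <- as.integer(get("ncols")); nrow <- as.integer(get("nrows"))
  nodata <- get("NODATA_value")
  vals <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  m <- matrix(vals, nrow = nrow, ncol = ncol, byrow = TRUE)
  m[m == nodata] <- NA_real_
  raster_surface(get("xllcorner"), get("yllcorner"), get("cellsize"),
                 nrow, ncol, values = m, nodata = nodata)
}
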
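# Pairwise spatial weight structures for global and local Moran's I.
# Internally a sparse dgCMatrix with a zero diagonal; rows index sites in
# the order of `ids`.

new_spatial_weights <- function(W, ids, method, parameter,
                                standardized = FALSE) {
  W <- methods::as(methods::as(W, "generalMatrix"), "CsparseMatrix")
  stopifnot(nrow(W) == ncol(W), nrow(W) == length(ids))
  if (any(Matrix::diag(W) != 0)) stop("weight matrix must have a zero diagonal")
  if (any(W@x < 0)) stop("weights must be non-negative")
  structure(
    list(W = W, ids = as.character(ids), method = method,
         parameter = parameter, standardized = standardized),
    class = "spatial_weights"
  )
}

#' @export
print.spatial_weights <- function(x, ...) {
  n <- length(x$ids)
  iso <- isolated_sites(x)
  cat(sprintf("Spatial weights: %d sites, method = %s(%s), %s\n", n,
              x$method, format(x$parameter),
              if (x$standardized) "row-standardized" else "raw"))
  cat(sprintf("  nonzero links: %d; isolated sites: %d\n",
              length(x$W@x), length(iso)))
  invisible(x)
}

#' Sites with no neighbours
#'
#' @param w A `spatial_weights` object.
#' @return Character vector of site ids whose weight row is all zero.
#' @export
isolated_sites <- function(w) {
  stopifnot(inherits(w, "spatial_weights"))
  w$ids[Matrix::rowSums(w$W) == 0 & Matrix::colSums(w$W) == 0]
}

#' k-nearest-neighbour spatial weights
#'
#' Binary weights in which w_ij = 1 exactly when j is among the k nearest
#' neighbours of i (Euclidean distance on planar coordinates). Distance ties
#' are broken by site order, so the construction is deterministic. kNN
#' weights are not necessarily symmetric.
#'
#' @param coords Two-column matrix (or data frame) of planar coordinates in
#'   metres, one row per site.
#' @param k Number of neighbours; must satisfy 1 <= k < nrow(coords).
#' @param ids Optional site identifiers (defaults to row numbers).
#' @return A `spatial_weights` object (raw, binary).
#' @export
build_knn_weights <- function(coords, k = 8, ids = NULL) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (is.null(ids)) ids <- seq_len(n)
  if (anyDuplicated(coords)) stop("points must be distinct for kNN weights")
  if (k < 1 || k >= n) stop("k must satisfy 1 <= k < number of points")
  D <- as.matrix(stats::dist(coords))
  ii <- integer(0); jj <- integer(0)
  for (i in seq_len(n)) {
    d <- D[i, ]
    d[i] <- Inf
    # order() is a stable sort: equidistant candidates resolve by site order
    nb <- order(d)[seq_len(k)]
    ii <- c(ii, rep.int(i, k)); jj <- c(jj, nb)
  }
  W <- Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(n, n))
  new_spatial_weights(W, ids, method = "knn", parameter = k)
}

#' Distance-band spatial weights
#'
#' Binary symmetric weights with w_ij = 1 exactly when
#' 0 < d(i, j) <= threshold. Sites without any neighbour inside the band are
#' left isolated (all-zero row) and reported by [isolated_sites()].
#'
#' @param coords Two-column matrix of planar coordinates in metres.
#' @param threshold Band radius in metres, > 0.
#' @param ids Optional site identifiers.
#' @return A `spatial_weights` object (raw, binary, symmetric).
#' @export
build_distance_band <- function(coords, threshold, ids = NULL) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (is.null(ids)) ids <- seq_len(n)
  if (!is.finite(threshold) || threshold <= 0) stop("threshold must be > 0")
  D <- as.matrix(stats::dist(coords))
  A <- (D > 0 & D <= threshold) * 1
  diag(A) <- 0
  w <- new_spatial_weights(Matrix::Matrix(A, sparse = TRUE), ids,
                           method = "distance_band", parameter = threshold)
  iso <- isolated_sites(w)
  if (length(iso)) {
    warning(length(iso), " site(s) have no neighbour within ", threshold,
            " m: ", paste(utils::head(iso, 5), collapse = ", "),
            if (length(iso) > 5) ", ..." else "")
  }
  w
}

#' Row-standardize a weight matrix
#'
#' Divides every nonzero row by its sum so that spatial lags become
#' neighbour averages. Isolated (all-zero) rows are left as zero. The
#' operation is idempotent.
#'
#' @param w A `spatial_weights` object.
#' @return A row-standardized `spatial_weights` object.
#' @export
row_standardize <- function(w) {
  stopifnot(inherits(w, "spatial_weights"))
  rs <- Matrix::rowSums(w$W)
  scale <- ifelse(rs > 0, 1 / rs, 0)
  W <- Matrix::Diagonal(x = scale) %*% w$W
  out <- new_spatial_weights(W, w$ids, method = w$method,
                             parameter = w$parameter, standardized = TRUE)
  out
}

#' Build the pipeline's default weights
#'
#' k-nearest-neighbour (k = 8) binary weights followed by row
#' standardization — the package default for Moran analyses; both the
#' method and the parameter are surfaced in the pipeline configuration.
#'
#' @param coords Planar coordinates in metres.
#' @param method `"knn"` or `"distance_band"`.
#' @param parameter k for kNN, the band radius in metres otherwise.
#' @param ids Optional site identifiers.
#' @param standardize Row-standardize the result (default TRUE).
#' @return A `spatial_weights` object.
#' @export
build_weights <- function(coords, method = c("knn", "distance_band"),
                          parameter = 8, ids = NULL, standardize = TRUE) {
  method <- match.arg(method)
  w <- switch(method,
    knn = build_knn_weights(coords, k = parameter, ids = ids),
    distance_band = build_distance_band(coords, threshold = parameter,
                                        ids = ids)
  )
  if (standardize) w <- row_standardize(w)
  w
}

#' Serialize weights as sparse triplets
#'
#' Writes a plain-text sparse triplet file: comment header lines (`#`)
#' recording the construction method, parameter and standardization, then a
#' `i j w` table keyed by site id. [read_weights()] restores the object.
#'
#' @param w A `spatial_weights` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_weights <- function(w, path) {
  stopifnot(inherits(w, "spatial_weights"))
  T <- methods::as(w$W, "TsparseMatrix")
  ord <- order(T@i, T@j)
  header <- c(
    paste0("# method: ", w$method),
    paste0("# parameter: ", format(w$parameter, digits = 17)),
    paste0("# standardized: ", if (w$standardized) "row" else "raw"),
    paste0("# n: ", length(w$ids)),
    paste0("# ids: ", paste(w$ids, collapse = ","))
  )
  lines <- c(header, "i\tj\tw",
             sprintf("%s\t%s\t%.17g", w$ids[T@i[ord] + 1L],
                     w$ids[T@j[ord] + 1L], T@x[ord]))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_weights
#' @export
read_weights <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  get <- function(key) {
    ln <- hdr[startsWith(hdr, paste0("# ", key, ":"))]
    sub(paste0("^# ", key, ":\\s*"), "", ln[1])
  }
  ids <- strsplit(get("ids"), ",")[[1]]
  body <- lines[!startsWith(lines, "#")]
  tab <- utils::read.table(text = body, header = TRUE, sep = "\t",
                           colClasses = c("character", "character", "numeric"))
  i <- match(tab$i, ids); j <- match(tab$j, ids)
  W <- Matrix::sparseMatrix(i = i, j = j, x = tab$w,
                            dims = c(length(ids), length(ids)))
  param <- as.numeric(get("parameter"))
  new_spatial_weights(W, ids, method = get("method"), parameter = param,
                      standardized = identical(get("standardized"), "row"))
}
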
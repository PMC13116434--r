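test_that("kNN weights: tie-break by site order and brute-force agreement", {
  # three collinear equally spaced points, k = 1: endpoints pick the middle;
  # the middle point ties and picks the lower-indexed endpoint
  coords <- cbind(c(0, 1, 2), 0)
  w <- build_knn_weights(coords, k = 1)
  A <- as.matrix(w$W)
  expect_equal(A[1, ], c(0, 1, 0))
  expect_equal(A[3, ], c(0, 1, 0))
  expect_equal(A[2, ], c(1, 0, 0))
  # k = n - 1 gives the complete graph
  set.seed(21)
  pts <- cbind(runif(6), runif(6))
  wc <- build_knn_weights(pts, k = 5)
  expect_true(all(as.matrix(wc$W) + diag(6) == 1))
  # neighbour sets equal an all-pairs distance sort on random points
  set.seed(22)
  pts <- cbind(runif(20, 0, 50), runif(20, 0, 50))
  k <- 4
  wk <- build_knn_weights(pts, k = k)
  D <- as.matrix(dist(pts))
  for (i in 1:20) {
    d <- D[i, ]; d[i] <- Inf
    expect_setequal(which(as.matrix(wk$W)[i, ] == 1), order(d)[1:k])
  }
  expect_error(build_knn_weights(pts, k = 20), "k must")
})

test_that("distance-band weights match brute-force adjacency and warn on isolates", {
  set.seed(23)
  pts <- cbind(runif(15, 0, 100), runif(15, 0, 100))
  D <- as.matrix(dist(pts))
  thr <- median(D)
  w <- suppressWarnings(build_distance_band(pts, thr))
  expect_equal(as.matrix(w$W), (D > 0 & D <= thr) * 1, ignore_attr = TRUE)
  expect_true(isSymmetric(as.matrix(w$W)))
  # threshold below the minimum distance isolates everything
  expect_warning(w0 <- build_distance_band(pts, min(D[D > 0]) * 0.5),
                 "no neighbour")
  expect_identical(length(isolated_sites(w0)), 15L)
  # threshold at the maximum distance gives the complete graph
  wall <- build_distance_band(pts, max(D))
  expect_true(all(as.matrix(wall$W) + diag(15) == 1))
})

test_that("distance-band adjacency is invariant under rigid motions", {
  set.seed(24)
  pts <- cbind(runif(12, 0, 10), runif(12, 0, 10))
  w0 <- suppressWarnings(build_distance_band(pts, 4))
  for (rep in 1:5) {
    th <- runif(1, 0, 2 * pi)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    moved <- pts %*% R + matrix(runif(2, -50, 50), 12, 2, byrow = TRUE)
    wm <- suppressWarnings(build_distance_band(moved, 4))
    expect_equal(as.matrix(wm$W), as.matrix(w0$W), tolerance = 1e-12)
  }
})

test_that("row standardization: rows sum to 1, idempotent, zero diagonal", {
  set.seed(25)
  pts <- cbind(runif(10), runif(10))
  w <- build_knn_weights(pts, k = 4)
  ws <- row_standardize(w)
  expect_equal(unname(Matrix::rowSums(ws$W)), rep(1, 10), tolerance = 1e-9)
  expect_equal(as.matrix(ws$W)[1, ][as.matrix(ws$W)[1, ] > 0],
               rep(0.25, 4), ignore_attr = TRUE)
  ws2 <- row_standardize(ws)
  expect_equal(as.matrix(ws2$W), as.matrix(ws$W), tolerance = 1e-12)
  expect_true(all(Matrix::diag(ws$W) == 0))
  # isolated rows stay all-zero
  wb <- suppressWarnings(build_distance_band(cbind(c(0, 1, 50), 0), 2))
  wbs <- row_standardize(wb)
  expect_equal(unname(Matrix::rowSums(wbs$W)), c(1, 1, 0))
})

test_that("weights survive the sparse-triplet round trip", {
  set.seed(26)
  pts <- cbind(runif(9, 0, 30), runif(9, 0, 30))
  w <- row_standardize(build_knn_weights(pts, k = 3, ids = letters[1:9]))
  f <- tempfile(fileext = ".tsv")
  write_weights(w, f)
  w2 <- read_weights(f)
  expect_identical(w2$ids, w$ids)
  expect_identical(w2$method, "knn")
  expect_identical(w2$standardized, TRUE)
  expect_equal(as.matrix(w2$W), as.matrix(w$W), tolerance = 1e-15)
})
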
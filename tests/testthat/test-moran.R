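test_that("global Moran matches hand values on canonical configurations", {
  # mutually adjacent +1/-1 pairs: the 2x2 checkerboard gives I = -1
  cb2 <- generate_checkerboard(2)
  expect_equal(global_moran(cb2$values, cb2$weights), -1, tolerance = 1e-12)
  cb4 <- generate_checkerboard(4)
  expect_equal(global_moran(cb4$values, cb4$weights), -1, tolerance = 1e-12)
  expect_equal(global_moran(cb4$values, cb4$weights),
               oracle_global_moran(cb4$values, cb4$weights$W),
               tolerance = 1e-12)
  # constant values are degenerate
  expect_error(global_moran(rep(2, 16), cb4$weights), "variance")
})

test_that("global and local Moran agree with the O(n^2) oracle", {
  for (seed in 1:15) {
    inst <- random_weights_instance(sample(5:50, 1), seed)
    expect_equal(global_moran(inst$values, inst$w),
                 oracle_global_moran(inst$values, inst$w$W),
                 tolerance = 1e-10)
    expect_equal(unname(local_moran(inst$values, inst$w)),
                 oracle_local_moran(inst$values, inst$w$W),
                 tolerance = 1e-10)
  }
})

test_that("local statistics average to the global statistic (row-standardized)", {
  for (seed in 16:25) {
    set.seed(seed)
    n <- sample(8:40, 1)
    coords <- cbind(runif(n), runif(n))
    w <- row_standardize(build_knn_weights(coords, k = min(5, n - 1)))
    v <- rnorm(n)
    expect_equal(mean(local_moran(v, w)), global_moran(v, w),
                 tolerance = 1e-10)
  }
})

test_that("Moran's I is invariant under affine transforms of the values", {
  inst <- random_weights_instance(30, 99)
  I0 <- global_moran(inst$values, inst$w)
  for (a in c(3, -2, 0.01)) {
    expect_equal(global_moran(a * inst$values + 7, inst$w), I0,
                 tolerance = 1e-10)
  }
})

test_that("sign semantics of the local statistic", {
  # a high site surrounded by high neighbours scores positive
  coords <- rbind(c(0, 0), c(1, 0), c(0, 1), c(100, 100), c(101, 100),
                  c(100, 101))
  v <- c(10, 11, 12, 1, 1.5, 0.5)
  w <- row_standardize(build_knn_weights(coords, k = 2))
  li <- local_moran(v, w)
  expect_true(li[1] > 0)
  # a site exactly at the mean has a zero local statistic:
  # x = mean(c(x, rest)) solves to x = sum(rest) / (n - 1)
  x_star <- sum(v[-1]) / (length(v) - 1)
  li2 <- local_moran(c(x_star, v[-1]), w)
  expect_equal(unname(li2[1]), 0, tolerance = 1e-10)
})

test_that("inference: E[I], reproducibility, and closed-form vs permutation sd", {
  for (n in c(5, 12, 30)) {
    inst <- random_weights_instance(n, 100 + n)
    mi <- moran_inference(inst$values, inst$w, method = "randomization")
    expect_equal(mi$expected, -1 / (n - 1))
  }
  inst <- random_weights_instance(40, 7)
  p1 <- moran_inference(inst$values, inst$w, n_perm = 199, seed = 5)
  p2 <- moran_inference(inst$values, inst$w, n_perm = 199, seed = 5)
  expect_identical(p1$perm_I, p2$perm_I)
  expect_identical(p1$p_value, p2$p_value)
  p3 <- moran_inference(inst$values, inst$w, n_perm = 199, seed = 6)
  expect_false(identical(p1$perm_I, p3$perm_I))
  # permutation spread approaches the randomization closed form
  big <- moran_inference(inst$values, inst$w, n_perm = 9999, seed = 1)
  anal <- moran_inference(inst$values, inst$w, method = "randomization")
  expect_equal(big$sd, anal$sd, tolerance = 0.1)
  # permutation p is in (0, 1]
  expect_true(p1$p_value > 0 && p1$p_value <= 1)
})

test_that("LISA classification: quadrants, sign symmetry, and planted clusters", {
  set.seed(55)
  # a tight high cluster and a tight low cluster, far apart, over a
  # mid-valued scattered background: cores label HH and LL
  high <- cbind(rnorm(10, 0, 3), rnorm(10, 0, 3))
  low <- cbind(rnorm(10, 500, 3), rnorm(10, 500, 3))
  background <- cbind(runif(20, 100, 400), runif(20, 100, 400))
  coords <- rbind(high, low, background)
  v <- c(rnorm(10, 100, 2), rnorm(10, 1, 2), rnorm(20, 50, 5))
  w <- build_weights(coords, parameter = 4)
  res <- lisa_classify(v, w, alpha = 0.05, n_perm = 499, seed = 9)
  expect_true(all(res$label[1:10] %in% c("HH", "NS")))
  expect_true(all(res$label[11:20] %in% c("LL", "NS")))
  expect_true(sum(res$label[1:10] == "HH") >= 5)
  expect_true(sum(res$label[11:20] == "LL") >= 5)
  # labels other than NS only where p <= alpha
  expect_true(all(res$p_value[res$label != "NS"] <= 0.05))
  # quadrant consistency
  sig <- res$label != "NS"
  expect_true(all(res$deviation[res$label == "HH"] > 0 &
                    res$lag[res$label == "HH"] > 0))
  expect_true(all(res$deviation[res$label == "LL"] < 0 &
                    res$lag[res$label == "LL"] < 0))
  # negating the values swaps HH<->LL and HL<->LH exactly
  neg <- lisa_classify(-v, w, alpha = 0.05, n_perm = 499, seed = 9)
  swap <- c(HH = "LL", LL = "HH", HL = "LH", LH = "HL", NS = "NS")
  expect_identical(unname(swap[res$label]), neg$label)
})

test_that("everything non-significant yields all NS", {
  set.seed(56)
  inst <- random_weights_instance(25, 77)
  res <- lisa_classify(inst$values, inst$w, alpha = 1e-6, n_perm = 199,
                       seed = 3)
  expect_true(all(res$label == "NS"))
})
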
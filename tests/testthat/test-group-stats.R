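test_that("Kruskal-Wallis: hand value, two-group identity, degenerate ties", {
  # {1,2,3} vs {4,5,6} vs {7,8,9}: ranks are the values themselves,
  # H = 12/(N(N+1)) * sum n_g (Rbar_g - (N+1)/2)^2 = 7.2
  kw <- kruskal_wallis(1:9, rep(c("a", "b", "c"), each = 3))
  expect_equal(kw$H, 7.2)
  expect_identical(kw$df, 2L)
  expect_equal(kw$p_value, pchisq(7.2, 2, lower.tail = FALSE))
  # all observations identical: H = 0, p = 1 by convention
  kw0 <- kruskal_wallis(rep(4.2, 9), rep(c("a", "b", "c"), each = 3))
  expect_identical(kw0$H, 0)
  expect_identical(kw0$p_value, 1)
  # two untied groups: H equals the squared standardized rank-sum statistic
  set.seed(61)
  x <- sample(seq(1, 40, by = 1))  # distinct values, no ties
  g <- rep(c("a", "b"), c(17, 23))
  kw2 <- kruskal_wallis(x, g)
  N <- 40; n1 <- 17
  R1 <- sum(rank(x)[g == "a"])
  z <- (R1 - n1 * (N + 1) / 2) / sqrt(n1 * 23 * (N + 1) / 12)
  expect_equal(kw2$H, z^2, tolerance = 1e-10)
  expect_error(kruskal_wallis(1:3, c("a", "a", "a")), "two groups")
})

test_that("Dunn's z matches a brute-force mean-rank computation with ties", {
  vals <- c(3, 5, 5, 8, 1, 5, 9, 9, 2, 7, 4, 6)
  grp <- rep(c("a", "b", "c"), each = 4)
  dn <- dunn_posthoc(vals, grp)
  N <- length(vals)
  r <- rank(vals)
  ties <- table(vals)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  for (row in seq_len(nrow(dn))) {
    g1 <- dn$group1[row]; g2 <- dn$group2[row]
    se <- sqrt((N * (N + 1) / 12 - tie_term) *
                 (1 / sum(grp == g1) + 1 / sum(grp == g2)))
    z <- (mean(r[grp == g1]) - mean(r[grp == g2])) / se
    expect_equal(dn$z[row], z, tolerance = 1e-12)
    expect_equal(dn$p_value[row], 2 * pnorm(-abs(z)), tolerance = 1e-12)
  }
  # identical groups: z = 0, p = 1
  dn0 <- dunn_posthoc(rep(c(1, 2, 3), 2), rep(c("a", "b"), each = 3))
  expect_equal(dn0$z, 0)
  expect_equal(dn0$p_value, 1)
})

test_that("BH adjustment: worked example, monotonicity, bounds", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_identical(bh_adjust(0.37), 0.37)
  expect_error(bh_adjust(c(0.2, 1.3)), "\\[0, 1\\]")
  set.seed(62)
  for (rep in 1:20) {
    p <- runif(sample(2:10, 1))
    q <- bh_adjust(p)
    expect_true(all(q >= p - 1e-15))
    expect_true(all(q <= 1))
    # raising one raw p never lowers any adjusted p
    i <- sample(length(p), 1)
    p2 <- p; p2[i] <- min(1, p2[i] + runif(1, 0, 1 - p2[i]))
    expect_true(all(bh_adjust(p2) >= q - 1e-12))
  }
})

test_that("compact letters encode exactly the non-significant pairs", {
  habs <- c("farmland", "fishpond", "orchard", "urban_green")
  none <- matrix(FALSE, 4, 4, dimnames = list(habs, habs))
  expect_identical(unname(compact_letters(none)), rep("a", 4))
  all_sig <- matrix(TRUE, 4, 4, dimnames = list(habs, habs))
  lets <- compact_letters(all_sig)
  expect_identical(length(unique(lets)), 4L)
  expect_true(all(nchar(lets) == 1))
  # only farmland vs urban_green differs
  one <- none
  one["farmland", "urban_green"] <- one["urban_green", "farmland"] <- TRUE
  l1 <- compact_letters(one)
  shared <- function(a, b)
    length(intersect(strsplit(l1[[a]], "")[[1]],
                     strsplit(l1[[b]], "")[[1]])) > 0
  expect_false(shared("farmland", "urban_green"))
  expect_true(shared("farmland", "fishpond"))
  expect_true(shared("farmland", "orchard"))
  expect_true(shared("urban_green", "fishpond"))
  expect_true(shared("urban_green", "orchard"))
  # the iff property on random significance patterns
  set.seed(63)
  for (rep in 1:15) {
    k <- sample(3:6, 1)
    m <- matrix(FALSE, k, k)
    up <- upper.tri(m)
    m[up] <- runif(sum(up)) < 0.4
    m <- m | t(m)
    dimnames(m) <- list(paste0("g", 1:k), paste0("g", 1:k))
    ll <- compact_letters(m)
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      sh <- length(intersect(strsplit(ll[i], "")[[1]],
                             strsplit(ll[j], "")[[1]])) > 0
      expect_identical(sh, !m[i, j])
    }
  }
})

test_that("season-wise habitat pipeline is deterministic and coherent", {
  s <- generate_survey(synthetic_config(seed = 12))
  r1 <- habitat_season_tests(s)
  r2 <- habitat_season_tests(s)
  expect_identical(r1, r2)
  expect_identical(nrow(r1$tests), 4L)
  expect_identical(nrow(r1$pairwise), 4L * 6L)
  expect_true(all(r1$pairwise$p_adj >= r1$pairwise$p_value - 1e-15))
  # letters reflect the adjusted significance pattern within each season
  for (season in names(r1$letters)) {
    pw <- r1$pairwise[r1$pairwise$season == season, ]
    lt <- r1$letters[[season]]
    for (row in seq_len(nrow(pw))) {
      sh <- length(intersect(strsplit(lt[[pw$group1[row]]], "")[[1]],
                             strsplit(lt[[pw$group2[row]]], "")[[1]])) > 0
      expect_identical(sh, pw$p_adj[row] > 0.05)
    }
  }
})
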
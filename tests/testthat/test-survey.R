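test_that("nest density is N/S and homogeneous in the count", {
  expect_identical(compute_density(10, 0.5), 20)
  expect_identical(compute_density(0, 3.7), 0)
  # division of the survey-wide totals: 2825 nests over 69.22 ha
  expect_equal(compute_density(2825, 69.22), 2825 / 69.22)
  expect_equal(compute_density(2825, 69.22), 40.8119, tolerance = 1e-4)
  # homogeneity: scaling N by k scales density by k exactly
  for (k in c(2, 5, 10)) {
    expect_identical(compute_density(k * 7, 1.4), k * compute_density(7, 1.4))
  }
  expect_error(compute_density(3, 0), "area")
  expect_error(compute_density(-1, 1), "nest_count")
})

test_that("occurrence classification respects bounds and is monotone", {
  sch <- example_occurrence_scheme()
  expect_identical(classify_occurrence(0, sch), "none_detected")
  # closed lower bound: a density at an interval's lower bound gets that level
  expect_identical(classify_occurrence(10, sch), "II")
  expect_identical(classify_occurrence(50, sch), "III")
  expect_identical(classify_occurrence(c(5, 49.999, 100, 2500), sch),
                   c("I", "II", "IV", "IV"))
  # monotone non-decreasing over a dense grid
  grid <- seq(0, 200, by = 0.25)
  codes <- match(classify_occurrence(grid, sch), sch$levels)
  expect_true(all(diff(codes) >= 0))
  expect_error(classify_occurrence(-1, sch), "non-negative")
  # a bounded scheme rejects out-of-range densities
  bounded <- occurrence_scheme(c("none_detected", "I"), c(0, 1e-9),
                               c(1e-9, 10))
  expect_error(classify_occurrence(11, bounded), "outside")
})

test_that("classification after density computation is monotone in count", {
  sch <- example_occurrence_scheme()
  counts <- 0:40
  lv <- classify_occurrence(compute_density(counts, 0.12), sch)
  expect_true(all(diff(match(lv, sch$levels)) >= 0))
})

test_that("mound volume is the half-ellipsoid formula", {
  expect_equal(mound_volume(0.3, 0.2, 0.1), (2 / 3) * pi * 0.006)
  expect_equal(mound_volume(0.3, 0.2, 0.1), 0.012566, tolerance = 1e-4)
  # symmetric case: half-ball of radius r
  r <- 0.37
  expect_equal(mound_volume(r, r, r), (2 / 3) * pi * r^3)
  expect_identical(mound_volume(0, 1, 1), 0)
  expect_error(mound_volume(-0.1, 1, 1), "non-negative")
})

test_that("mound volume matches numeric integration of the half-ellipsoid", {
  set.seed(11)
  for (rep in 1:10) {
    abc <- runif(3, 0.05, 0.8)
    a <- abc[1]; b <- abc[2]; cc <- abc[3]
    # midpoint quadrature of the height field c*sqrt(1 - x^2/a^2 - y^2/b^2)
    m <- 1200
    xs <- seq(-a, a, length.out = m + 1); xs <- (xs[-1] + xs[-(m + 1)]) / 2
    ys <- seq(-b, b, length.out = m + 1); ys <- (ys[-1] + ys[-(m + 1)]) / 2
    g <- outer(xs^2 / a^2, ys^2 / b^2, "+")
    h <- cc * sqrt(pmax(0, 1 - g))
    vol <- sum(h) * (2 * a / m) * (2 * b / m)
    expect_equal(mound_volume(a, b, cc), vol, tolerance = 1e-3)
  }
})

test_that("habitat/season summary reports n, mean, SE and handles n = 1", {
  one <- make_sites(1, seed = 2)
  s1 <- summarize_by_habitat_season(one)
  expect_identical(nrow(s1), 1L)
  expect_equal(s1$mean_density, one$nest_count / one$area_ha)
  expect_true(is.na(s1$se_density))
  # two identical sites: SE exactly zero
  two <- make_sites(2, seed = 3)
  two$habitat <- "farmland"; two$nest_count <- 5; two$site_id <- c("a", "b")
  s2 <- summarize_by_habitat_season(two)
  expect_identical(s2$se_density, 0)
  expect_identical(s2$n, 2L)
  # grouped means/SEs agree with direct computation on a mixed table
  tab <- make_sites(40, seed = 4)
  sm <- summarize_by_habitat_season(tab)
  tab$density <- tab$nest_count / tab$area_ha
  for (i in seq_len(nrow(sm))) {
    d <- tab$density[tab$habitat == sm$habitat[i] & tab$season == sm$season[i]]
    expect_equal(sm$mean_density[i], mean(d))
    if (length(d) > 1) expect_equal(sm$se_density[i], sd(d) / sqrt(length(d)))
  }
})

test_that("site-table validation pinpoints offending rows", {
  bad <- make_sites(5, seed = 5)
  bad$area_ha[3] <- 0
  expect_error(validate_sites(bad), "area_ha.*3")
  bad2 <- make_sites(5, seed = 6)
  bad2$habitat[2] <- "swamp"
  expect_error(validate_sites(bad2), "habitat.*2")
  bad3 <- make_sites(5, seed = 7)
  bad3$site_id[2] <- bad3$site_id[1]
  expect_error(validate_sites(bad3), "duplicate")
})
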
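test_that("Fisher's ratio handles unit, degenerate and published cases", {
  expect_equal(fishersRatio(3, 1, 3, 1), 0)
  expect_equal(fishersRatio(1, 0.5, 0, 0.5), 1)
  expect_equal(fishersRatio(0, 0, 0, 0), 0)
  expect_identical(fishersRatio(1, 0, 0, 0), Inf)
  # FaP1D7 group statistics: (248.23 - 578.61)^2 / (84.05^2 + 291.75^2)
  hand <- (248.23 - 578.61)^2 / (84.05^2 + 291.75^2)
  expect_equal(fishersRatio(248.23, 84.05^2, 578.61, 291.75^2), hand)
  expect_equal(hand, 1.184, tolerance = 1e-3)
})

test_that("Fisher's ratio is affine-invariant and symmetric in group order", {
  set.seed(13)
  for (i in 1:20) {
    m1 <- rnorm(1, 100, 30); m2 <- rnorm(1, 150, 30)
    v1 <- rgamma(1, 2, 0.01); v2 <- rgamma(1, 2, 0.01)
    r <- fishersRatio(m1, v1, m2, v2)
    a <- runif(1, 0.1, 10); b <- runif(1, -50, 50)
    expect_equal(fishersRatio(a * m1 + b, a^2 * v1, a * m2 + b, a^2 * v2), r,
                 tolerance = 1e-10)
    expect_equal(fishersRatio(m2, v2, m1, v1), r)
  }
})

test_that("summary-statistic t-tests reproduce the published bulk contrasts", {
  w <- twoSampleT(248.23, 84.05, 12, 578.61, 291.75, 12, "welch")
  expect_equal(round(w$t, 2), -3.77)
  expect_equal(round(w$df, 1), 12.8)
  expect_true(w$p < 0.01)

  p <- twoSampleT(282.66, 119.63, 12, 106.71, 57.26, 12, "pooled")
  expect_equal(round(p$t, 2), 4.60)
  expect_equal(p$df, 22)

  same <- twoSampleT(5, 1, 10, 5, 1, 10, "pooled")
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_error(twoSampleT(5, 0, 10, 5, 0, 10), "undefined")
})

test_that("pooled and Welch t coincide for equal group sizes; dfs differ", {
  set.seed(17)
  for (i in 1:20) {
    m1 <- rnorm(1); m2 <- rnorm(1)
    s1 <- rgamma(1, 2); s2 <- rgamma(1, 2)
    p <- twoSampleT(m1, s1, 12, m2, s2, 12, "pooled")
    w <- twoSampleT(m1, s1, 12, m2, s2, 12, "welch")
    expect_equal(p$t, w$t, tolerance = 1e-12)
    expect_lte(w$df, p$df + 1e-12)
  }
})

test_that("Welch significance at p < 0.01 implies a positive Fisher's ratio", {
  set.seed(19)
  for (i in 1:30) {
    m1 <- rnorm(1, 100, 50); m2 <- rnorm(1, 100, 50)
    s1 <- rgamma(1, 2, 0.05) + 1; s2 <- rgamma(1, 2, 0.05) + 1
    tt <- twoSampleT(m1, s1, 12, m2, s2, 12, "welch")
    if (tt$p < 0.01)
      expect_gt(fishersRatio(m1, s1^2, m2, s2^2), 0)
  }
})

test_that("the published 20-row group-statistics table yields exactly 11 significant markers", {
  st <- fdpGroupStats()
  tt <- twoSampleT(st$mean_H, st$sd_H, st$n_H, st$mean_L, st$sd_L, st$n_L,
                   "welch", st$feature)
  expect_equal(sum(tt$p < 0.01), 11)
  expect_setequal(tt$feature[tt$p < 0.01],
                  c("FaP1D7", "FaP1D11", "FaP3A2", "FaP3B9", "FaP1E7MH",
                    "FaP1B3", "FaP1G2", "FaP2E6", "FaP3E12", "FaP2D11",
                    "FaP1A7"))
})

test_that("Levene-based variant selection distinguishes equal and unequal variances", {
  set.seed(29)
  pooledPicks <- 0
  for (i in 1:20) {
    v <- c(rnorm(12, 10, 2), rnorm(12, 10, 2))
    g <- rep(c("H", "L"), each = 12)
    if (leveneVarianceTest(v, g)$variant == "pooled") pooledPicks <- pooledPicks + 1
  }
  expect_gte(pooledPicks, 15)

  welchPicks <- 0
  for (i in 1:10) {
    v <- c(rnorm(12, 10, 1), rnorm(12, 10, 10))
    g <- rep(c("H", "L"), each = 12)
    if (leveneVarianceTest(v, g)$variant == "welch") welchPicks <- welchPicks + 1
  }
  expect_equal(welchPicks, 10)

  const <- leveneVarianceTest(rep(c(1, 2), each = 4), rep(c("H", "L"), each = 4))
  expect_true(const$fallback)
  expect_equal(const$variant, "welch")
})

test_that("top-K Fisher ranking matches a brute-force sort and breaks ties lexicographically", {
  st <- data.frame(feature = c("b", "a"), mean_H = c(2, 2), var_H = c(1, 1),
                   mean_L = c(0, 0), var_L = c(1, 1))
  rk <- rankTopK(st, 10)
  expect_equal(rk$feature, c("a", "b")) # equal ratios: lexicographic
  expect_equal(nrow(rk), 2) # K larger than the list keeps everything

  set.seed(37)
  stats <- data.frame(feature = sprintf("F%03d", 1:287),
                      mean_H = rnorm(287, 100, 40), var_H = rgamma(287, 2, 0.001),
                      mean_L = rnorm(287, 100, 40), var_L = rgamma(287, 2, 0.001))
  rk10 <- rankTopK(stats, 10)
  ratios <- (stats$mean_H - stats$mean_L)^2 / (stats$var_H + stats$var_L)
  oracle <- stats$feature[order(-ratios, stats$feature)][1:10]
  expect_equal(rk10$feature, oracle)
  expect_true(all(diff(rk10$fisher_ratio) <= 0))
})

test_that("three-way intersection computes all 7 Venn regions consistently", {
  dis <- threeWayIntersection(c("a"), c("b"), c("c"))
  expect_length(markerIntersection(dis), 0)
  expect_equal(sum(vennRegions(dis)), 3)

  same <- threeWayIntersection(c("a", "b"), c("a", "b"), c("a", "b"))
  expect_equal(markerIntersection(same), c("a", "b"))
  expect_equal(unname(vennRegions(same)["all_three"]), 2)
  expect_equal(sum(vennRegions(same)), 2)

  set.seed(41)
  for (i in 1:15) {
    u <- sprintf("F%02d", 1:30)
    A <- sample(u, sample(0:20, 1)); B <- sample(u, sample(0:20, 1))
    C <- sample(u, sample(0:20, 1))
    ms <- threeWayIntersection(A, B, C)
    expect_equal(sum(vennRegions(ms)), length(union(union(A, B), C)))
    expect_true(all(markerIntersection(ms) %in% A))
    expect_true(all(markerIntersection(ms) %in% B))
    expect_true(all(markerIntersection(ms) %in% C))
    # dropping a criterion never shrinks the selection
    expect_true(all(markerIntersection(ms) %in% intersect(A, B)))
  }
})

test_that("filterMarkers recovers a single strong planted marker as a singleton intersection", {
  cfg <- simConfig(seed = 4)
  arr <- simulateArray(cfg, "linalool") # one planted marker
  scr <- screenCompound(arr$signal)
  ms <- filterMarkers(groupStatistics(arr$signal), scr$model,
                      compound = "linalool")
  expect_true(all(markerIntersection(ms) %in% selectedFeatures(scr$model)))
  # no significant t-tests => empty intersection regardless of the DFA set
  stNull <- data.frame(feature = c("F1", "F2"), mean_H = c(10, 11),
                       sd_H = c(10, 10), mean_L = c(10.5, 10.2),
                       sd_L = c(10, 10), n_H = 12, n_L = 12)
  msNull <- filterMarkers(stNull, c("F1", "F2"))
  expect_length(markerIntersection(msNull), 0)
})
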
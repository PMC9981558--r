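test_that("regionIndex follows the ceiling with left-continuous boundaries", {
  expect_identical(regionIndex(0.2, d = 1, k = 2), 1L)
  expect_identical(regionIndex(0.5, d = 1, k = 2), 1L)  # boundary belongs below
  expect_identical(regionIndex(0.50001, d = 1, k = 2), 2L)
  expect_identical(regionIndex(0, d = 1, k = 3), 1L)
  expect_identical(regionIndex(1, d = 1, k = 3), 3L)
  # position analytically on a boundary but not representable exactly
  expect_identical(regionIndex(0.1 + 0.2, d = 0.9, k = 3), 1L)
  expect_error(regionIndex(1.2, d = 1, k = 2), "outside")
  expect_error(regionIndex(0.5, d = 1, k = 0), "k must be")
})

test_that("p0GivenK evaluates all four branches", {
  expect_equal(p0GivenK(0.3, 0.9, d = 1, k = 0), 1)
  expect_equal(p0GivenK(0.1, 0.2, d = 1, k = 2), 0.8, tolerance = 1e-12)
  expect_equal(p0GivenK(0.4, 0.6, d = 1, k = 2), 0.64, tolerance = 1e-12)
  expect_equal(p0GivenK(0.1, 0.9, d = 1, k = 3), 0)
  # argument order is normalised
  expect_equal(p0GivenK(0.6, 0.4, d = 1, k = 2), 0.64, tolerance = 1e-12)
  expect_error(p0GivenK(0.1, 0.2, d = 1, k = -1), "non-negative")
})

test_that("p0GivenK matches the brute-force placement oracle", {
  set.seed(101)
  for (rep in 1:12) {
    d <- stats::runif(1, 0.3, 3)
    k <- sample(0:5, 1)
    m <- sort(stats::runif(2, 0, d))
    ana <- p0GivenK(m[1], m[2], d, k)
    mc <- mcP0Placement(m[1], m[2], d, k, nDraws = 2e4)
    expect_lt(abs(ana - mc$p), 4 * mc$se + 1e-12)
  }
})

test_that("p0Marginal mixes the conditional over the bivalent distribution", {
  dist <- BivalentDistribution(c(`1` = 0.5, `2` = 0.5))
  expect_equal(p0Marginal(0.4, 0.6, d = 1, dist = dist), 0.72,
               tolerance = 1e-12)
  expect_equal(p0Marginal(0.4, 0.4, d = 1, dist = dist), 1)
  none <- BivalentDistribution(c(`0` = 1))
  expect_equal(p0Marginal(0.1, 0.9, d = 1, dist = none), 1)
  bad <- BivalentDistribution(c(`1` = 1))
  bad@probs <- c(0.5, 0.4)  # bypasses the constructor's validity check
  expect_error(p0Marginal(0.1, 0.2, 1, bad), "sum to 1")
})

test_that("recombinationFromP0 maps [0,1] onto [0,0.5]", {
  expect_equal(recombinationFromP0(c(1, 0.72, 0)), c(0, 0.14, 0.5))
  expect_error(recombinationFromP0(1.5), "0, 1")
  expect_error(recombinationFromP0(-0.1), "0, 1")
})

test_that("whole-chromosome pair has r = 0.5 under any obligate distribution", {
  for (k in 1:5) {
    dist <- BivalentDistribution(stats::setNames(1, k))
    expect_equal(p0Marginal(0, 1, d = 1, dist = dist), 0)
    expect_equal(predictPairR(0, 1, 1, dist), 0.5)
  }
})

test_that("predicted r is monotone in the second marker position", {
  set.seed(7)
  for (rep in 1:5) {
    dist <- randomDist(4)
    d <- stats::runif(1, 0.5, 2)
    m_i <- stats::runif(1, 0, d / 2)
    mj <- seq(m_i, d, length.out = 60)
    r <- vapply(mj, function(m) predictPairR(m_i, m, d, dist), numeric(1))
    expect_true(all(diff(r) >= -1e-12))
    expect_true(all(r >= 0 & r <= 0.5))
  }
})

test_that("triangle inequality holds for ordered marker triples", {
  set.seed(11)
  for (rep in 1:50) {
    dist <- randomDist(sample(1:5, 1))
    d <- stats::runif(1, 0.3, 3)
    m <- sort(stats::runif(3, 0, d))
    rij <- predictPairR(m[1], m[2], d, dist)
    rjk <- predictPairR(m[2], m[3], d, dist)
    rik <- predictPairR(m[1], m[3], d, dist)
    expect_gte(rij + rjk, rik - 1e-12)
  }
})

test_that("predictPairs tabulates distances and all four predictors", {
  map <- makeMap(list(chr1 = c(0, 40, 60, 100)))
  dist <- BivalentDistribution(c(`2` = 1), "chr1", "maternal")
  pred <- predictPairs(map, dist, pairs = "all")
  expect_equal(nrow(pred), 6L)  # 4 markers -> C(4,2)
  row <- pred[pred$marker_i == "chr1_m02" & pred$marker_j == "chr1_m03", ]
  expect_equal(row$distance_cM, 20)
  expect_equal(row$r_p0k, 0.18, tolerance = 1e-12)
  expect_equal(row$r_haldane, inverseHaldane(0.2))
  expect_equal(row$r_kosambi, inverseKosambi(0.2))
  expect_equal(row$r_linear, 0.2)
})

test_that("predictPairs handles identical markers and rejects cross-chromosome pairs", {
  map <- makeMap(list(chr1 = c(0, 0, 50), chr2 = c(0, 30)))
  dists <- list(BivalentDistribution(c(`1` = 1), "chr1", "maternal"),
                BivalentDistribution(c(`1` = 1), "chr2", "maternal"))
  pred <- predictPairs(map, dists,
                       pairs = cbind("chr1_m01", "chr1_m02"))
  expect_equal(pred$r_p0k, 0)
  expect_equal(pred$r_haldane, 0)
  expect_equal(pred$r_linear, 0)
  expect_error(predictPairs(map, dists, pairs = cbind("chr1_m01", "chr2_m01")),
               "same chromosome")
  expect_error(predictPairs(map, dists, pairs = cbind("chr1_m01", "nope")),
               "not on the map")
})

test_that("subsampled maps keep the full-map d for region widths", {
  map <- makeMap(list(chr1 = seq(0, 100, by = 1)))
  sub <- subsampleMarkers(map, fraction = 0.1, seed = 3)
  expect_equal(mapLength(sub, "chr1"), 1)  # full-map d, not marker span
  dist <- BivalentDistribution(c(`2` = 1), "chr1", "maternal")
  pred <- predictPairs(sub, dist, pairs = "all")
  expect_true(all(pred$r_p0k >= 0 & pred$r_p0k <= 0.5))
})
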
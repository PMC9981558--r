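test_that("gameteSamplingProb is the Binomial(n, 1/2) mass", {
  expect_equal(gameteSamplingProb(0, 0), 1)
  expect_equal(gameteSamplingProb(0:2, 2), c(0.25, 0.5, 0.25))
  expect_equal(sum(gameteSamplingProb(0:5, 5)), 1)
  expect_error(gameteSamplingProb(3, 2), "k <= n")
})

test_that("emFit concentrates on the only explaining count", {
  # all-zero gametes: only n = 0 has P(k=0 | n) = 1
  fit0 <- emFit(c(`0` = 10))
  expect_gte(bivalentProbs(fit0$dist)[["0"]], 1 - 1e-6)
  # a clean binomial(2, 1/2) histogram is best explained by n = 2
  fit2 <- emFit(c(`0` = 25, `1` = 50, `2` = 25))
  expect_gte(bivalentProbs(fit2$dist)[["2"]], 0.99)
  expect_equal(length(fit2$dist@probs), 4L)  # support 0..2N-1 = 0..3
})

test_that("EM log-likelihood never decreases across iterations", {
  set.seed(5)
  for (rep in 1:5) {
    probs <- randomDist(3)@probs
    n <- sample.int(4, 500, replace = TRUE, prob = probs) - 1L
    k <- stats::rbinom(500, n, 0.5)
    h <- stats::setNames(tabulate(k + 1L, nbins = max(k) + 1L), 0:max(k))
    fit <- emFit(h)
    expect_true(all(diff(fit$logliks) >= -1e-9))
  }
})

test_that("EM matches a simplex grid search on a small support", {
  h <- c(`0` = 30, `1` = 50, `2` = 20)
  fit <- emFit(h, supportMax = 3)
  # grid over (p0, p1, p2, p3) with step 0.02
  step <- 0.02
  grid <- expand.grid(p0 = seq(0, 1, step), p1 = seq(0, 1, step),
                      p2 = seq(0, 1, step))
  grid <- grid[grid$p0 + grid$p1 + grid$p2 <= 1 + 1e-12, ]
  P <- cbind(grid$p0, grid$p1, grid$p2, 1 - grid$p0 - grid$p1 - grid$p2)
  B <- outer(0:2, 0:3, function(k, n) ifelse(k <= n, dbinom(k, n, 0.5), 0))
  mix <- P %*% t(B)
  ll <- as.vector((log(pmax(mix, 1e-300)) %*% h))
  expect_gte(fit$loglik, max(ll) - 1e-6)
})

test_that("EM recovers a known distribution from simulated gametes", {
  dist <- BivalentDistribution(c(`1` = 0.6, `2` = 0.4), "chr1", "maternal")
  g <- simulateGameteSet(1, dist, 20000, seed = 99)
  h <- countsPerRecord(g, "chr1", "maternal")
  fit <- emFit(h)
  truth <- numeric(length(fit$dist@probs))
  truth[2:3] <- c(0.6, 0.4)
  tv <- 0.5 * sum(abs(fit$dist@probs - truth))
  expect_lt(tv, 0.05)
})

test_that("restricted EM fixes p0 at zero and still normalises", {
  h <- c(`0` = 40, `1` = 40, `2` = 20)
  fit <- emFit(h, minSupport = 1L)
  expect_identical(fit$dist@probs[1L], 0)
  expect_equal(sum(fit$dist@probs), 1, tolerance = 1e-9)
})

test_that("obligate test short-circuits when p0_hat is numerically zero", {
  h <- c(`0` = 0, `1` = 10)  # prop(k=0) = 0 forces p0_hat to the boundary
  res <- obligateCrossoverTest(h, nBootstrap = 10, seed = 1)
  expect_equal(res$p_zero_hat, 0)
  expect_equal(res$p_value, 1)
  expect_equal(res$n_bootstrap, 0L)
})

test_that("obligate test detects a genuinely positive p0", {
  dist <- BivalentDistribution(c(`0` = 0.3, `1` = 0.7), "chr1", "maternal")
  h <- countsPerRecord(simulateGameteSet(1, dist, 5000, seed = 21),
                       "chr1", "maternal")
  res <- obligateCrossoverTest(h, nBootstrap = 200, seed = 2)
  expect_gt(res$p_zero_hat, 0.2)
  expect_lt(res$p_value, 0.05)
  expect_identical(res$restricted@probs[1L], 0)
})

test_that("obligate test is deterministic given the seed", {
  dist <- BivalentDistribution(c(`0` = 0.1, `1` = 0.9), "chr1", "maternal")
  h <- countsPerRecord(simulateGameteSet(1, dist, 800, seed = 31),
                       "chr1", "maternal")
  r1 <- obligateCrossoverTest(h, nBootstrap = 100, seed = 7)
  r2 <- obligateCrossoverTest(h, nBootstrap = 100, seed = 7)
  expect_identical(r1$p_value, r2$p_value)
})

test_that("selectDistribution treats the obligate crossover as the null", {
  dist <- BivalentDistribution(c(`0` = 0.3, `1` = 0.7), "chr1", "maternal")
  h <- countsPerRecord(simulateGameteSet(1, dist, 3000, seed = 41),
                       "chr1", "maternal")
  test <- obligateCrossoverTest(h, nBootstrap = 100, seed = 3)
  test$p_value <- 0.01
  expect_identical(selectDistribution(test), test$unrestricted)
  test$p_value <- 0.64
  expect_identical(selectDistribution(test), test$restricted)
  test$p_value <- 0.05  # boundary: strict inequality keeps the null
  expect_identical(selectDistribution(test), test$restricted)
})

test_that("probAllCrossoversVisible applies Bayes under binomial sampling", {
  expect_equal(probAllCrossoversVisible(
    BivalentDistribution(c(`2` = 1)), 2), 1)
  expect_equal(probAllCrossoversVisible(
    BivalentDistribution(c(`1` = 0.5, `2` = 0.5)), 1), 0.5)
  expect_error(probAllCrossoversVisible(
    BivalentDistribution(c(`0` = 1)), 1), "impossible|zero probability")
})

test_that("fitted mixture reproduces empirical histogram proportions", {
  dist <- BivalentDistribution(c(`1` = 0.5, `2` = 0.3, `3` = 0.2),
                               "chr1", "maternal")
  g <- simulateGameteSet(1, dist, 20000, seed = 55)
  h <- countsPerRecord(g, "chr1", "maternal")
  fit <- emFit(h)
  p <- fit$dist@probs
  ns <- seq_along(p) - 1L
  pred <- vapply(as.integer(names(h)), function(k)
    sum(p[ns >= k] * dbinom(k, ns[ns >= k], 0.5)), numeric(1))
  expect_equal(pred, unname(h) / sum(h), tolerance = 0.02)
})
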
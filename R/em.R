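#' Probability of observing k crossovers in a random meiotic product
#'
#' Without chromatid interference each bivalent crossover involves two of the
#' four chromatids, so a single meiotic product carries each crossover with
#' probability 1/2 independently: given n bivalent crossovers the gametic
#' count is Binomial(n, 1/2), \eqn{P(k \mid n) = \binom{n}{k} (1/2)^n}.
#'
#' @param k observed gametic crossover count, 0 <= k <= n; vectorised.
#' @param n bivalent crossover count.
#' @return binomial probability mass.
#' @examples
#' gameteSamplingProb(0:2, 2)  # 0.25 0.50 0.25
#' @export
gameteSamplingProb <- function(k, n) {
  if (any(k < 0) || any(k > n) || any(k != floor(k)) || n != floor(n))
    stop("require integer 0 <= k <= n")
  stats::dbinom(k, size = n, prob = 0.5)
}

## log-likelihood of a gametic count histogram under bivalent probs p
## (support minSupport..minSupport+length(p)-1)
.mixLoglik <- function(counts, p, minSupport = 0L) {
  ks <- as.integer(names(counts))
  ns <- minSupport + seq_along(p) - 1L
  ## B[k+1, j] = P(k | n_j)
  B <- outer(ks, ns, function(k, n) ifelse(k <= n, stats::dbinom(k, n, 0.5), 0))
  mix <- as.vector(B %*% p)
  if (any(mix <= 0 & counts > 0)) return(-Inf)
  sum(counts[counts > 0] * log(mix[counts > 0]))
}

#' EM inference of the bivalent crossover-count distribution
#'
#' Estimates the multinomial distribution of bivalent crossover counts that
#' maximises the likelihood of an observed gametic count histogram under the
#' Binomial(n, 1/2) sampling model (\code{\link{gameteSamplingProb}}). With
#' maximum observed gametic count N, a support of 0..2N-1 suffices and is
#' the default. The E-step computes the posterior over n for each observed
#' k; the M-step sets each \eqn{p_n} to its posterior-weighted frequency.
#' Initialisation is uniform over the support; iteration stops when the
#' log-likelihood improves by less than \code{tol}.
#'
#' @param counts integer histogram \code{c_0..c_N} of gametic crossover
#'   counts, named by count (as from \code{\link{countsPerRecord}}); unnamed
#'   vectors are taken to start at count 0.
#' @param supportMax largest bivalent count in the support; default 2N-1
#'   (at least 1).
#' @param minSupport smallest bivalent count in the support; 1 fits the
#'   restricted (obligate-crossover, \eqn{p_0 = 0}) model.
#' @param tol convergence tolerance on the log-likelihood increment.
#' @param maxIter iteration cap; hitting it flags \code{converged = FALSE}
#'   rather than erroring.
#' @param chromosome,sex labels for the returned distribution.
#' @return list with elements \code{dist}
#'   (\linkS4class{BivalentDistribution}, support 0..supportMax with zeros
#'   below \code{minSupport}), \code{loglik}, \code{iterations},
#'   \code{converged}, \code{logliks} (per-iteration trace).
#' @examples
#' emFit(c(`0` = 25, `1` = 50, `2` = 25))
#' @export
emFit <- function(counts, supportMax = NULL, minSupport = 0L,
                  tol = 1e-10, maxIter = 10000L,
                  chromosome = "chr", sex = "maternal") {
  if (is.null(names(counts))) names(counts) <- seq_along(counts) - 1L
  counts <- stats::setNames(as.numeric(counts), names(counts))
  if (sum(counts) < 1) stop("histogram must contain at least one record")
  ks <- as.integer(names(counts))
  N <- max(ks[counts > 0])
  if (is.null(supportMax)) supportMax <- max(2L * N - 1L, 1L)
  if (supportMax < max(N, minSupport))
    stop("supportMax must be >= max observed count and >= minSupport")
  ns <- minSupport:supportMax
  B <- outer(ks, ns, function(k, n) ifelse(k <= n, stats::dbinom(k, n, 0.5), 0))
  obs <- counts > 0
  if (any(rowSums(B[obs, , drop = FALSE]) == 0))
    stop("observed count outside the model support")
  p <- rep(1 / length(ns), length(ns))
  total <- sum(counts)
  logliks <- numeric(0)
  ll <- -Inf
  converged <- FALSE
  iter <- 0L
  while (iter < maxIter) {
    iter <- iter + 1L
    mix <- as.vector(B %*% p)                       # P(k) per observed bin
    llNew <- sum(counts[obs] * log(mix[obs]))
    logliks <- c(logliks, llNew)
    ## E-step responsibilities W[k+1, j] = P(n_j | k); M-step weighted freq
    W <- B * rep(p, each = length(ks)) / mix
    p <- as.vector(counts %*% W) / total
    p <- pmax(p, 0)
    p <- p / sum(p)
    if (is.finite(ll) && llNew - ll < tol) { converged <- TRUE; ll <- llNew; break }
    ll <- llNew
  }
  full <- numeric(supportMax + 1L)
  full[ns + 1L] <- p
  list(dist = BivalentDistribution(full, chromosome = chromosome, sex = sex),
       loglik = ll, iterations = iter, converged = converged,
       logliks = logliks)
}

## draw a gametic count histogram of given size from bivalent probs
.simulateHistogram <- function(probs, size) {
  n <- sample.int(length(probs), size, replace = TRUE, prob = probs) - 1L
  k <- stats::rbinom(size, n, 0.5)
  stats::setNames(tabulate(k + 1L, nbins = max(k) + 1L), 0:max(k))
}

## EM on many histograms at once (rows of C over counts 0..K). Each row r has
## its own support 0..(2*N_r - 1): entries above it start at 0 and stay 0
## under EM multiplicative updates, so one shared matrix serves all rows.
## Returns the fitted probability matrix (rows normalised).
.emFitBatch <- function(C, tol = 1e-10, maxIter = 10000L) {
  R <- nrow(C); K <- ncol(C) - 1L
  Nr <- apply(C, 1L, function(cc) max(which(cc > 0)) - 1L)
  suppMax <- pmax(2L * Nr - 1L, 1L)
  S <- max(suppMax)
  B <- outer(0:K, 0:S, function(k, n)
    ifelse(k <= n, stats::dbinom(k, n, 0.5), 0))
  P <- matrix(0, R, S + 1L)
  for (r in seq_len(R)) P[r, 1:(suppMax[r] + 1L)] <- 1 / (suppMax[r] + 1L)
  total <- rowSums(C)
  ll <- rep(-Inf, R)
  active <- rep(TRUE, R)
  for (iter in seq_len(maxIter)) {
    mix <- P %*% t(B)                              # R x (K+1)
    mix[mix <= 0] <- .Machine$double.xmin
    llNew <- rowSums(C * log(mix))
    ratio <- C / mix
    P <- P * (ratio %*% B) / total
    P <- P / rowSums(P)
    done <- is.finite(ll) & (llNew - ll < tol)
    active <- active & !done
    ll <- llNew
    if (!any(active)) break
  }
  P
}

#' Parametric bootstrap test of the obligate-crossover hypothesis
#'
#' Tests whether the EM point estimate \eqn{\hat p_0} (probability of a
#' bivalent with no crossover) deviates significantly from zero, taking the
#' obligate crossover as the null hypothesis. The restricted model
#' (\eqn{p_0 = 0}) is fitted by running EM over support 1..2N-1 (the
#' constrained MLE is not a renormalisation of the unrestricted fit).
#' \code{nBootstrap} gametic histograms of the observed size are then
#' simulated from the restricted fit through the Binomial(n, 1/2) sampling
#' model, the unrestricted EM is refitted on each, and the p-value is the
#' proportion of bootstrap \eqn{\hat p_0^*} at least as large as the
#' observed \eqn{\hat p_0}. If \eqn{\hat p_0 = 0} (numerically, below 1e-8:
#' EM only approaches the boundary geometrically) there is nothing to test
#' and the p-value is 1 without resampling.
#'
#' @inheritParams emFit
#' @param nBootstrap number of bootstrap replicates.
#' @param seed integer seed making the resampling reproducible.
#' @return list with \code{p_zero_hat}, \code{p_value}, \code{n_bootstrap},
#'   \code{unrestricted} and \code{restricted}
#'   (\linkS4class{BivalentDistribution}s).
#' @export
obligateCrossoverTest <- function(counts, nBootstrap = 1000L, seed = 1L,
                                  chromosome = "chr", sex = "maternal") {
  if (nBootstrap < 1) stop("nBootstrap must be >= 1")
  fitU <- emFit(counts, chromosome = chromosome, sex = sex)
  supportMax <- length(fitU$dist@probs) - 1L
  fitR <- emFit(counts, supportMax = supportMax, minSupport = 1L,
                chromosome = chromosome, sex = sex)
  p0hat <- fitU$dist@probs[1L]
  ## EM reaches the p0 = 0 boundary only in the limit; estimates below
  ## 1e-8 are numerically zero and there is nothing to test
  if (p0hat <= 1e-8) {
    return(list(p_zero_hat = 0, p_value = 1, n_bootstrap = 0L,
                unrestricted = fitU$dist, restricted = fitR$dist))
  }
  size <- sum(counts)
  set.seed(seed)
  probsR <- fitR$dist@probs
  hists <- lapply(seq_len(nBootstrap), function(b)
    .simulateHistogram(probsR, size))
  K <- max(vapply(hists, length, integer(1))) - 1L
  C <- t(vapply(hists, function(h) {
    out <- numeric(K + 1L); out[seq_along(h)] <- h; out
  }, numeric(K + 1L)))
  p0star <- .emFitBatch(C)[, 1L]
  list(p_zero_hat = unname(p0hat),
       p_value = mean(p0star >= p0hat),
       n_bootstrap = as.integer(nBootstrap),
       unrestricted = fitU$dist, restricted = fitR$dist)
}

#' Choose between the unrestricted and restricted bivalent distribution
#'
#' The obligate crossover is the null hypothesis: only when the bootstrap
#' rejects it (p-value strictly below \code{alpha}) is the unrestricted
#' distribution, with its non-zero \eqn{p_0}, retained; otherwise the
#' restricted (\eqn{p_0 = 0}) distribution is used.
#'
#' @param test result of \code{\link{obligateCrossoverTest}}.
#' @param alpha significance level, default 0.05.
#' @return a \linkS4class{BivalentDistribution}.
#' @export
selectDistribution <- function(test, alpha = 0.05) {
  if (test$p_value < alpha) test$unrestricted else test$restricted
}

#' Probability that a gamete with k crossovers shows all bivalent crossovers
#'
#' By Bayes' rule under the Binomial(n, 1/2) sampling model,
#' \eqn{P(n = k \mid \mathrm{gamete\ shows\ } k) =
#' p_k (1/2)^k / \sum_{n \ge k} p_n \binom{n}{k} (1/2)^n}: the chance that a
#' gamete observed with k crossovers comes from a bivalent that had exactly
#' those k, i.e. that no crossover went unseen.
#'
#' @param dist a \linkS4class{BivalentDistribution}.
#' @param k observed gametic crossover count.
#' @return probability in [0, 1].
#' @examples
#' probAllCrossoversVisible(BivalentDistribution(c(`1` = 0.5, `2` = 0.5)), 1)
#' @export
probAllCrossoversVisible <- function(dist, k) {
  stopifnot(is(dist, "BivalentDistribution"))
  if (k < 0 || k != floor(k)) stop("k must be a non-negative integer")
  p <- dist@probs
  nmax <- length(p) - 1L
  if (k > nmax) stop("k = ", k, " is impossible under this distribution")
  ns <- k:nmax
  denom <- sum(p[ns + 1L] * stats::dbinom(k, ns, 0.5))
  if (denom <= 0)
    stop("k = ", k, " has zero probability under this distribution")
  p[k + 1L] * 0.5^k / denom
}
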
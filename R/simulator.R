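#' Simulate bivalent crossover positions under the equal-regions model
#'
#' Draws meioses from the structural interference model: for each meiosis a
#' bivalent crossover count k is drawn from \code{dist}; for k > 0 the map
#' [0, d] is split into k equal regions of width d/k and one crossover is
#' placed uniformly and independently in each region. The simulator is the
#' package's brute-force oracle for the analytic no-crossover probability.
#'
#' @param d chromosome map length in Morgans.
#' @param dist a \linkS4class{BivalentDistribution}.
#' @param nMeioses number of meioses to draw.
#' @param seed optional integer seed.
#' @return list of numeric vectors, one per meiosis: sorted bivalent
#'   crossover positions in Morgans.
#' @export
simulateBivalent <- function(d, dist, nMeioses, seed = NULL) {
  stopifnot(is(dist, "BivalentDistribution"))
  if (!is.numeric(d) || d <= 0) stop("d must be a positive map length")
  if (nMeioses < 1) stop("nMeioses must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  probs <- dist@probs
  ks <- sample.int(length(probs), nMeioses, replace = TRUE, prob = probs) - 1L
  total <- sum(ks)
  ## flatten: region index j in 1..k per crossover, uniform within region
  kRep <- rep.int(ks, ks)
  j <- sequence(ks)
  pos <- (j - 1 + stats::runif(total)) * (d / kRep)
  split(pos, factor(rep.int(seq_len(nMeioses), ks), levels = seq_len(nMeioses)))
}

#' Sample a gamete from bivalent crossovers
#'
#' Without chromatid interference each bivalent crossover involves the
#' sampled chromatid with probability 1/2, independently; the gametic count
#' is then the Binomial(n, 1/2) thinning of the bivalent count.
#'
#' @param positions sorted bivalent crossover positions (Morgans).
#' @return the subset of positions carried by one meiotic product.
#' @export
sampleGamete <- function(positions) {
  if (!length(positions)) return(numeric(0))
  positions[stats::runif(length(positions)) < 0.5]
}

#' Simulate a set of gametes
#'
#' Composes \code{\link{simulateBivalent}} and \code{\link{sampleGamete}}
#' into one meiotic product per meiosis, in the standard gamete container.
#'
#' @inheritParams simulateBivalent
#' @param chromosome,sex labels for the records (default: those of
#'   \code{dist}).
#' @return a \linkS4class{GameteCrossoverSet} with \code{nMeioses} records.
#' @export
simulateGameteSet <- function(d, dist, nMeioses, seed = NULL,
                              chromosome = dist@chromosome, sex = dist@sex) {
  if (nMeioses < 1) stop("nMeioses must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  biv <- simulateBivalent(d, dist, nMeioses)
  gam <- lapply(biv, sampleGamete)
  rec <- data.frame(meiosis_id = sprintf("m%06d", seq_len(nMeioses)),
                    sex = sex, chromosome = chromosome,
                    stringsAsFactors = FALSE)
  rec$positions <- unname(gam)
  new("GameteCrossoverSet", records = rec)
}

#' Monte-Carlo recombination frequency for a marker pair
#'
#' Simulates gametes under the structural model and estimates the
#' recombination frequency of the pair as the fraction of gametes with an
#' odd number of crossovers in the half-open interval (m_i, m_j], with its
#' binomial standard error. Serves as the independent oracle for
#' \code{\link{predictPairR}}.
#'
#' @inheritParams simulateBivalent
#' @param m_i,m_j marker map positions in Morgans, 0 <= m_i <= m_j <= d.
#' @param nDraws number of simulated gametes.
#' @return list with \code{r} (estimate), \code{se} (standard error) and
#'   \code{n} (draws).
#' @export
mcPairR <- function(d, dist, m_i, m_j, nDraws, seed = NULL) {
  if (m_i > m_j) stop("require m_i <= m_j")
  if (m_i < 0 || m_j > d * (1 + 1e-12)) stop("pair outside [0, d]")
  if (!is.null(seed)) set.seed(seed)
  biv <- simulateBivalent(d, dist, nDraws)
  ## vectorised thinning + interval parity
  lens <- lengths(biv)
  pos <- unlist(biv, use.names = FALSE)
  keep <- stats::runif(length(pos)) < 0.5
  inside <- keep & pos > m_i & pos <= m_j
  id <- rep.int(seq_len(nDraws), lens)
  cnt <- tabulate(id[inside], nbins = nDraws)
  r <- mean(cnt %% 2 == 1)
  list(r = r, se = sqrt(r * (1 - r) / nDraws), n = nDraws)
}
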
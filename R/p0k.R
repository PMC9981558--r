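#' Crossover region index under the equal-regions model
#'
#' With k crossovers in the bivalent, the chromosome of map length d is
#' partitioned into k non-overlapping regions of equal width d/k and each
#' crossover falls in its own region. A position m belongs to region
#' \eqn{\lceil m k / d \rceil}; a position exactly on a boundary belongs to
#' the lower-index region (left-continuity of the ceiling), and m = 0 is
#' assigned region 1 so the index is total on [0, d]. A relative tolerance of
#' 1e-9 is applied to m*k/d before the ceiling so that positions analytically
#' on a boundary do not jump regions through floating-point rounding.
#'
#' @param m map position in Morgans, in [0, d]; vectorised.
#' @param d chromosome map length in Morgans, > 0.
#' @param k number of crossovers in the bivalent, integer >= 1.
#' @return integer region index in 1..k.
#' @examples
#' regionIndex(0.2, d = 1, k = 2)  # 1
#' regionIndex(0.5, d = 1, k = 2)  # 1 (boundary belongs below)
#' regionIndex(0,   d = 1, k = 3)  # 1
#' @export
regionIndex <- function(m, d, k) {
  if (!is.numeric(d) || length(d) != 1L || d <= 0)
    stop("d must be a positive map length in Morgans")
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k != floor(k))
    stop("k must be an integer >= 1")
  if (any(m < 0) || any(m > d * (1 + 1e-12)))
    stop("position m outside [0, d]")
  t <- m * k / d
  snap <- abs(t - round(t)) <= 1e-9 * pmax(1, abs(t))
  t[snap] <- round(t[snap])
  idx <- ceiling(t)
  idx[idx < 1] <- 1L
  as.integer(idx)
}

#' Probability of no crossover between two markers given k bivalent crossovers
#'
#' The piecewise no-crossover probability under the structural interference
#' model: k crossovers occur in k equal-width regions of the map, one per
#' region, uniformly and independently within regions. For marker positions
#' \eqn{m_i \le m_j} with region indices computed by \code{\link{regionIndex}}
#' and region upper boundaries \eqn{b = \mathrm{index} \cdot d/k}:
#' \itemize{
#'   \item k = 0: probability 1;
#'   \item same region: \eqn{1 - (m_j - m_i)/(d/k)};
#'   \item adjacent regions: \eqn{(1 - (b_i - m_i)/(d/k)) \cdot (b_j - m_j)/(d/k)};
#'   \item regions further apart: 0 (the intervening region's crossover is
#'     certain to fall between the markers).
#' }
#'
#' @param m_i,m_j marker map positions in Morgans; order is normalised
#'   internally so \code{m_j >= m_i}.
#' @param d chromosome map length in Morgans (of the full map, not a
#'   subsampled marker set).
#' @param k bivalent crossover count, integer >= 0.
#' @return probability in [0, 1].
#' @examples
#' p0GivenK(0.1, 0.2, d = 1, k = 2)  # same region: 0.8
#' p0GivenK(0.4, 0.6, d = 1, k = 2)  # adjacent regions: 0.64
#' p0GivenK(0.1, 0.9, d = 1, k = 3)  # gap of 2 regions: 0
#' @export
p0GivenK <- function(m_i, m_j, d, k) {
  if (!is.numeric(k) || length(k) != 1L || k < 0 || k != floor(k))
    stop("k must be a non-negative integer")
  if (k == 0) return(1)
  if (m_j < m_i) { tmp <- m_i; m_i <- m_j; m_j <- tmp }
  w <- d / k
  ri <- regionIndex(m_i, d, k)
  rj <- regionIndex(m_j, d, k)
  gap <- rj - ri
  if (gap == 0L) {
    p <- 1 - (m_j - m_i) / w
  } else if (gap == 1L) {
    b_i <- ri * w
    b_j <- rj * w
    p <- (1 - (b_i - m_i) / w) * ((b_j - m_j) / w)
  } else {
    p <- 0
  }
  min(max(p, 0), 1)
}

#' Marginal no-crossover probability over a bivalent distribution
#'
#' \eqn{p_0 = \sum_k p_k \, p_0(k)}: the probability of no bivalent crossover
#' between the two markers, averaging the conditional \code{\link{p0GivenK}}
#' over the multinomial distribution of bivalent crossover counts.
#'
#' @inheritParams p0GivenK
#' @param dist a \linkS4class{BivalentDistribution}.
#' @return probability in [0, 1]; equals 1 when \code{m_i == m_j}.
#' @examples
#' dist <- BivalentDistribution(c(`1` = 0.5, `2` = 0.5))
#' p0Marginal(0.4, 0.6, d = 1, dist = dist)  # 0.72
#' @export
p0Marginal <- function(m_i, m_j, d, dist) {
  stopifnot(is(dist, "BivalentDistribution"))
  validObject(dist)
  p <- dist@probs
  ks <- seq_along(p) - 1L
  sum(p * vapply(ks, function(k) p0GivenK(m_i, m_j, d, k), numeric(1)))
}

#' Recombination frequency from the no-crossover probability
#'
#' Absent chromatid interference, any positive number of bivalent crossovers
#' between two loci yields recombinant and non-recombinant gametes in equal
#' proportion, so \eqn{r = \frac{1}{2}(1 - p_0)}.
#'
#' @param p0 probability of no bivalent crossover between the loci, in [0, 1].
#' @return recombination frequency in [0, 0.5]; vectorised.
#' @examples
#' recombinationFromP0(c(1, 0.72, 0))  # 0 0.14 0.5
#' @export
recombinationFromP0 <- function(p0) {
  if (!is.numeric(p0) || anyNA(p0) || any(p0 < -1e-12) || any(p0 > 1 + 1e-12))
    stop("p0 must lie in [0, 1]")
  (1 - pmin(pmax(p0, 0), 1)) / 2
}

#' Predicted recombination frequency between two positions
#'
#' Convenience composition of \code{\link{p0Marginal}} and
#' \code{\link{recombinationFromP0}}.
#'
#' @inheritParams p0Marginal
#' @return recombination frequency in [0, 0.5].
#' @export
predictPairR <- function(m_i, m_j, d, dist)
  recombinationFromP0(p0Marginal(m_i, m_j, d, dist))

#' Predict recombination frequencies for marker pairs on a linkage map
#'
#' For each requested marker pair, computes the additive map distance and the
#' recombination frequency predicted by the structural no-crossover model
#' (column \code{r_p0k}) and by the inverse Haldane, Kosambi and capped
#' linear mapping functions. Pairs must lie on the same chromosome:
#' inter-chromosomal pairs have r = 0.5 by independent assortment and are
#' outside the model.
#'
#' @param map a \linkS4class{LinkageMap}.
#' @param dists a single \linkS4class{BivalentDistribution} (one-chromosome
#'   map) or a list of them covering every chromosome of \code{pairs};
#'   matched to chromosomes by their \code{chromosome} slot.
#' @param pairs two-column character matrix or data.frame of marker ids, or
#'   \code{"all"} for all within-chromosome pairs.
#' @param d optional named numeric overriding the chromosome map length(s),
#'   e.g. the full-map lengths when \code{map} is subsampled (the map's own
#'   \code{d} slot already retains them when produced by
#'   \code{\link{subsampleMarkers}}).
#' @return data.frame with columns \code{chromosome}, \code{marker_i},
#'   \code{marker_j}, \code{distance_cM}, \code{r_p0k}, \code{r_haldane},
#'   \code{r_kosambi}, \code{r_linear}.
#' @export
predictPairs <- function(map, dists, pairs = "all", d = NULL) {
  stopifnot(is(map, "LinkageMap"))
  if (is(dists, "BivalentDistribution")) dists <- list(dists)
  distFor <- function(chrom) {
    for (dd in dists) if (dd@chromosome == chrom) return(dd)
    if (length(dists) == 1L) return(dists[[1L]])
    stop("no bivalent distribution supplied for chromosome ", chrom)
  }
  m <- map@markers
  if (identical(pairs, "all")) {
    pairs <- do.call(rbind, lapply(split(m$marker, m$chromosome), function(ids) {
      if (length(ids) < 2L) return(NULL)
      idx <- utils::combn(length(ids), 2L)
      cbind(ids[idx[1L, ]], ids[idx[2L, ]])
    }))
    if (is.null(pairs)) stop("map has no chromosome with >= 2 markers")
  }
  pairs <- as.matrix(pairs)
  pos <- stats::setNames(m$map_pos, m$marker)
  chr <- stats::setNames(m$chromosome, m$marker)
  miss <- setdiff(c(pairs), m$marker)
  if (length(miss))
    stop("markers not on the map: ", paste(utils::head(miss, 5), collapse = ", "))
  ci <- chr[pairs[, 1L]]
  cj <- chr[pairs[, 2L]]
  if (any(ci != cj))
    stop("marker pairs must lie on the same chromosome")
  dchr <- if (is.null(d)) map@d else d
  out <- data.frame(chromosome = unname(ci),
                    marker_i = pairs[, 1L], marker_j = pairs[, 2L],
                    stringsAsFactors = FALSE)
  mi <- pmin(pos[pairs[, 1L]], pos[pairs[, 2L]])
  mj <- pmax(pos[pairs[, 1L]], pos[pairs[, 2L]])
  dv <- dchr[out$chromosome]
  if (anyNA(dv)) stop("missing map length d for some chromosome")
  out$distance_cM <- unname(100 * (mj - mi))
  out$r_p0k <- vapply(seq_len(nrow(out)), function(i)
    predictPairR(mi[i], mj[i], dv[i], distFor(out$chromosome[i])), numeric(1))
  dd <- mj - mi
  out$r_haldane <- unname(inverseHaldane(dd))
  out$r_kosambi <- unname(inverseKosambi(dd))
  out$r_linear <- unname(inverseLinear(dd))
  rownames(out) <- NULL
  out
}
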
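#' Intra-chromosomal component of genetic shuffling
#'
#' The mean pairwise recombination frequency over all \eqn{\binom{\Lambda}{2}}
#' locus pairs of a chromosome, \eqn{\bar r = \sum_{i<j} r_{ij} /
#' \binom{\Lambda}{2}}: the chromosome's contribution to genome-wide genetic
#' shuffling due to crossover rate and localisation.
#'
#' @param r either an upper-triangular/full square matrix of pairwise rates
#'   (only i < j entries are used) or a plain vector of the
#'   \eqn{\Lambda(\Lambda-1)/2} pairwise rates.
#' @param nLoci number of loci \eqn{\Lambda}; required (and checked) when
#'   \code{r} is a vector.
#' @return mean pairwise rate, in [0, 0.5] when all rates are.
#' @examples
#' rbarIntra(c(0.1, 0.1, 0.2), nLoci = 3)  # 0.1333
#' @export
rbarIntra <- function(r, nLoci = NULL) {
  if (is.matrix(r)) {
    if (nrow(r) != ncol(r)) stop("rate matrix must be square")
    nLoci <- nrow(r)
    if (nLoci < 2) stop("need at least 2 loci")
    vals <- r[upper.tri(r)]
  } else {
    if (is.null(nLoci)) stop("nLoci required when r is a vector")
    if (nLoci < 2) stop("need at least 2 loci")
    if (length(r) != nLoci * (nLoci - 1) / 2)
      stop("expected choose(nLoci, 2) pairwise rates")
    vals <- r
  }
  mean(vals)
}

#' Genetic shuffling predicted from a linkage map
#'
#' Builds all marker-pair recombination frequencies on each chromosome with
#' the chosen predictor and averages them into the intra-chromosomal
#' \eqn{\bar r}. A genome-level aggregate across chromosomes is also
#' returned, weighted by pair count by default (each marker pair counts
#' once) or as a plain chromosome mean.
#'
#' @param map a \linkS4class{LinkageMap}.
#' @param predictor \code{"p0k"}, \code{"haldane"}, \code{"kosambi"} or
#'   \code{"linear"}.
#' @param dists bivalent distribution(s), required for \code{"p0k"}.
#' @param aggregate \code{"pairs"} (pair-count-weighted) or
#'   \code{"chromosomes"} (unweighted mean of per-chromosome values).
#' @return list with \code{per_chromosome} (data.frame \code{chromosome},
#'   \code{n_loci}, \code{rbar}) and \code{overall}.
#' @export
rbarFromPredictions <- function(map,
                                predictor = c("p0k", "haldane", "kosambi",
                                              "linear"),
                                dists = NULL,
                                aggregate = c("pairs", "chromosomes")) {
  stopifnot(is(map, "LinkageMap"))
  predictor <- match.arg(predictor)
  aggregate <- match.arg(aggregate)
  if (predictor == "p0k" && is.null(dists))
    stop("the p0k predictor requires bivalent distribution(s)")
  m <- map@markers
  perChrom <- lapply(chromosomes(map), function(ch) {
    sub <- m[m$chromosome == ch, , drop = FALSE]
    nl <- nrow(sub)
    if (nl < 2) return(NULL)
    idx <- utils::combn(nl, 2L)
    dd <- abs(sub$map_pos[idx[2L, ]] - sub$map_pos[idx[1L, ]])
    r <- if (predictor == "p0k") {
      dv <- mapLength(map, ch)
      dist <- if (is(dists, "BivalentDistribution")) dists else {
        hit <- Filter(function(x) x@chromosome == ch, dists)
        if (!length(hit)) {
          if (length(dists) == 1L) dists[[1L]]
          else stop("no bivalent distribution for chromosome ", ch)
        } else hit[[1L]]
      }
      vapply(seq_along(dd), function(p)
        predictPairR(sub$map_pos[idx[1L, p]], sub$map_pos[idx[2L, p]],
                     dv, dist), numeric(1))
    } else inverseMappingFunction(predictor)(dd)
    data.frame(chromosome = ch, n_loci = nl,
               rbar = rbarIntra(r, nLoci = nl),
               n_pairs = length(r), stringsAsFactors = FALSE)
  })
  perChrom <- do.call(rbind, perChrom)
  if (is.null(perChrom)) stop("no chromosome with >= 2 markers")
  overall <- if (aggregate == "pairs")
    sum(perChrom$rbar * perChrom$n_pairs) / sum(perChrom$n_pairs)
  else mean(perChrom$rbar)
  list(per_chromosome = perChrom[, c("chromosome", "n_loci", "rbar")],
       overall = overall)
}
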
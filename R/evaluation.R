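#' Empirical recombination frequency of a marker pair from gamete data
#'
#' The proportion of meiotic products with an odd number of crossovers in
#' the half-open interval (m_i, m_j]. Crossovers exactly at a marker's map
#' position separate loci above it, matching the left-continuous region
#' convention of the structural model. The value is not clipped at 0.5:
#' sampling noise can push it above and the evaluation reports what the
#' data show.
#'
#' @param g a \linkS4class{GameteCrossoverSet}.
#' @param chromosome,sex restrict to these records.
#' @param m_i,m_j interval endpoints in Morgans, m_i <= m_j.
#' @return proportion in [0, 1].
#' @export
empiricalPairR <- function(g, chromosome, sex, m_i, m_j) {
  stopifnot(is(g, "GameteCrossoverSet"))
  if (m_i > m_j) stop("require m_i <= m_j")
  rec <- g@records
  sel <- rec$chromosome == chromosome & rec$sex == sex
  if (!any(sel))
    stop("no gamete records for chromosome ", chromosome, ", sex ", sex)
  odd <- vapply(rec$positions[sel], function(p)
    sum(p > m_i & p <= m_j) %% 2 == 1, logical(1))
  mean(odd)
}

## parity counts for many pairs at once; rec already filtered
.empiricalPairRMany <- function(positions, mi, mj) {
  n <- length(positions)
  lens <- lengths(positions)
  pos <- unlist(positions, use.names = FALSE)
  id <- rep.int(seq_len(n), lens)
  vapply(seq_along(mi), function(p) {
    inside <- pos > mi[p] & pos <= mj[p]
    mean(tabulate(id[inside], nbins = n) %% 2 == 1)
  }, numeric(1))
}

#' Subsample markers of a linkage map
#'
#' Draws \code{ceiling(fraction * n)} markers per chromosome without
#' replacement (so small chromosomes keep at least one), preserving map
#' order. The full-map chromosome lengths d are retained on the result:
#' region widths d/k of the structural model must not shrink because the
#' marker set was thinned.
#'
#' @param map a \linkS4class{LinkageMap}.
#' @param fraction fraction of markers to keep, in (0, 1].
#' @param seed integer seed making the draw reproducible.
#' @return a \linkS4class{LinkageMap} on the subsampled markers.
#' @export
subsampleMarkers <- function(map, fraction = 0.015, seed = 2021L) {
  stopifnot(is(map, "LinkageMap"))
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1)
    stop("fraction must lie in (0, 1]")
  if (fraction == 1) return(map)
  set.seed(seed)
  m <- map@markers
  keep <- unlist(lapply(split(seq_len(nrow(m)), m$chromosome), function(idx) {
    sort(sample(idx, ceiling(fraction * length(idx))))
  }), use.names = FALSE)
  out <- m[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  new("LinkageMap", markers = out, sex = map@sex, d = map@d)
}

#' Mean absolute error between empirical and predicted rates
#'
#' \eqn{\frac{1}{n} \sum |r_e - r_p|} over marker pairs.
#'
#' @param empirical,predicted numeric vectors of equal length >= 1.
#' @return non-negative scalar.
#' @export
meanAbsoluteError <- function(empirical, predicted) {
  if (length(empirical) != length(predicted))
    stop("empirical and predicted must have equal length")
  if (!length(empirical)) stop("need at least one pair")
  mean(abs(empirical - predicted))
}

#' Compare recombination-frequency predictors against gamete data
#'
#' The evaluation workflow: subsample the map's markers, form all
#' within-chromosome marker pairs, compute the empirical recombination
#' frequency of each pair from the gamete records (odd-crossover-count
#' proportion) and the predictions of the structural model and the three
#' inverse mapping functions, and report the mean absolute error of each
#' predictor per chromosome and sex.
#'
#' @param map a \linkS4class{LinkageMap} (full map; subsampling is done
#'   here so the full-map d is retained).
#' @param g a \linkS4class{GameteCrossoverSet} for the same sex.
#' @param dists a \linkS4class{BivalentDistribution} or list of them
#'   covering the map's chromosomes.
#' @param fraction,seed marker subsampling parameters (see
#'   \code{\link{subsampleMarkers}}).
#' @return list with \code{summary} (data.frame \code{chromosome},
#'   \code{sex}, \code{fun}, \code{n_pairs}, \code{mae}) and \code{pairs}
#'   (per-pair table with empirical and predicted rates).
#' @export
compareFunctions <- function(map, g, dists, fraction = 0.015, seed = 2021L) {
  stopifnot(is(map, "LinkageMap"), is(g, "GameteCrossoverSet"))
  sub <- subsampleMarkers(map, fraction, seed)
  sex <- sub@sex
  pred <- predictPairs(sub, dists, pairs = "all")
  pos <- stats::setNames(sub@markers$map_pos, sub@markers$marker)
  rec <- g@records
  pred$r_empirical <- NA_real_
  for (ch in unique(pred$chromosome)) {
    sel <- rec$chromosome == ch & rec$sex == sex
    if (!any(sel))
      stop("no gamete records for chromosome ", ch, ", sex ", sex)
    rows <- which(pred$chromosome == ch)
    mi <- pmin(pos[pred$marker_i[rows]], pos[pred$marker_j[rows]])
    mj <- pmax(pos[pred$marker_i[rows]], pos[pred$marker_j[rows]])
    pred$r_empirical[rows] <-
      .empiricalPairRMany(rec$positions[sel], mi, mj)
  }
  funs <- c(p0k = "r_p0k", haldane = "r_haldane",
            kosambi = "r_kosambi", linear = "r_linear")
  summ <- do.call(rbind, lapply(unique(pred$chromosome), function(ch) {
    rows <- pred$chromosome == ch
    data.frame(chromosome = ch, sex = sex, fun = names(funs),
               n_pairs = sum(rows),
               mae = vapply(funs, function(col)
                 meanAbsoluteError(pred$r_empirical[rows], pred[[col]][rows]),
                 numeric(1)),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  list(summary = summ, pairs = pred)
}
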
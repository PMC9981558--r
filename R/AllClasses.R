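#' @import methods
NULL

.SEXES <- c("maternal", "paternal")

#' LinkageMap: ordered markers with sex-specific genetic positions
#'
#' Container for one sex-specific linkage map. Markers are stored per
#' chromosome with their physical coordinate (bp, metadata only) and genetic
#' map position in Morgans. The chromosome map length \code{d} is the length
#' of the whole chromosome, which after subsampling can exceed the span of
#' the retained markers; it is the \code{d} that enters all region-width
#' computations.
#'
#' @slot markers data.frame with columns \code{marker}, \code{chromosome},
#'   \code{position_bp}, \code{map_pos} (Morgans), sorted by map position
#'   within chromosome.
#' @slot sex either \code{"maternal"} or \code{"paternal"}.
#' @slot d named numeric, map length in Morgans per chromosome.
#' @exportClass LinkageMap
setClass("LinkageMap",
  representation(markers = "data.frame", sex = "character", d = "numeric"))

setValidity("LinkageMap", function(object) {
  msgs <- character()
  need <- c("marker", "chromosome", "position_bp", "map_pos")
  if (!all(need %in% names(object@markers)))
    msgs <- c(msgs, paste("markers must have columns",
                          paste(need, collapse = ", ")))
  if (length(object@sex) != 1L || !object@sex %in% .SEXES)
    msgs <- c(msgs, "sex must be 'maternal' or 'paternal'")
  if (length(msgs) == 0L) {
    m <- object@markers
    chroms <- unique(m$chromosome)
    if (!all(chroms %in% names(object@d)))
      msgs <- c(msgs, "every chromosome needs an entry in d")
    else {
      if (any(object@d[chroms] <= 0))
        msgs <- c(msgs, "chromosome has zero map length")
      if (any(m$map_pos < 0))
        msgs <- c(msgs, "negative map positions")
      over <- m$map_pos > object@d[m$chromosome] + 1e-12
      if (any(over))
        msgs <- c(msgs, "marker map position exceeds chromosome map length")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' GameteCrossoverSet: per-meiotic-product crossover positions
#'
#' One record per (meiosis, chromosome): the map positions (Morgans, sorted
#' ascending) of the crossovers observed in that meiotic product, plus the
#' parent sex.
#'
#' @slot records data.frame with columns \code{meiosis_id}, \code{sex},
#'   \code{chromosome} and a list-column \code{positions} of numeric vectors
#'   (Morgans, sorted).
#' @exportClass GameteCrossoverSet
setClass("GameteCrossoverSet", representation(records = "data.frame"))

setValidity("GameteCrossoverSet", function(object) {
  msgs <- character()
  need <- c("meiosis_id", "sex", "chromosome", "positions")
  if (!all(need %in% names(object@records)))
    msgs <- c(msgs, paste("records must have columns",
                          paste(need, collapse = ", ")))
  else {
    if (!is.list(object@records$positions))
      msgs <- c(msgs, "positions must be a list-column")
    if (!all(object@records$sex %in% .SEXES))
      msgs <- c(msgs, "sex must be 'maternal' or 'paternal'")
    bad <- vapply(object@records$positions, function(p)
      length(p) > 0 && (is.unsorted(p) || any(p < 0)), logical(1))
    if (any(bad))
      msgs <- c(msgs, "crossover positions must be sorted and non-negative")
  }
  if (length(msgs)) msgs else TRUE
})

#' BivalentDistribution: multinomial bivalent crossover-count probabilities
#'
#' Probabilities \eqn{p_0 \ldots p_{nmax}} that a bivalent of one chromosome
#' in one sex carries 0..nmax crossovers. When EM-derived from gametic counts
#' with maximum observed count N, the support runs to 2N-1.
#'
#' @slot chromosome chromosome label.
#' @slot sex \code{"maternal"} or \code{"paternal"}.
#' @slot probs numeric vector of probabilities for counts \code{0:(length-1)};
#'   non-negative, summing to 1 within 1e-9.
#' @exportClass BivalentDistribution
setClass("BivalentDistribution",
  representation(chromosome = "character", sex = "character",
                 probs = "numeric"))

setValidity("BivalentDistribution", function(object) {
  msgs <- character()
  p <- object@probs
  if (length(p) < 1L) msgs <- c(msgs, "probs must be non-empty")
  if (any(p < -1e-12)) msgs <- c(msgs, "probs must be non-negative")
  if (length(p) >= 1L && abs(sum(p) - 1) > 1e-9)
    msgs <- c(msgs, "probs must sum to 1 (within 1e-9)")
  if (length(object@sex) != 1L || !object@sex %in% .SEXES)
    msgs <- c(msgs, "sex must be 'maternal' or 'paternal'")
  if (length(msgs)) msgs else TRUE
})

#' Construct a BivalentDistribution
#'
#' @param probs numeric vector of probabilities for bivalent crossover counts
#'   \code{0:(length(probs)-1)}; must sum to 1. Alternatively a named vector
#'   (names are counts, gaps filled with 0), e.g. \code{c(`1` = 0.6, `2` = 0.4)}.
#' @param chromosome,sex labels attached to the distribution.
#' @return a \linkS4class{BivalentDistribution}.
#' @examples
#' BivalentDistribution(c(`1` = 0.6, `2` = 0.4))
#' @export
BivalentDistribution <- function(probs, chromosome = "chr", sex = "maternal") {
  if (!is.null(names(probs)) && !all(names(probs) == "")) {
    counts <- suppressWarnings(as.integer(names(probs)))
    if (anyNA(counts) || any(counts < 0))
      stop("names of probs must be non-negative integer counts")
    full <- numeric(max(counts) + 1L)
    full[counts + 1L] <- probs
    probs <- full
  }
  new("BivalentDistribution", chromosome = chromosome, sex = sex,
      probs = as.numeric(probs))
}

#' @describeIn BivalentDistribution probabilities, named by crossover count.
#' @param x a \code{BivalentDistribution}.
#' @export
bivalentProbs <- function(x) {
  stopifnot(is(x, "BivalentDistribution"))
  stats::setNames(x@probs, seq_along(x@probs) - 1L)
}

#' Accessors for map and gamete containers
#'
#' \code{chromosomes} lists chromosome labels; \code{mapLength} returns the
#' chromosome map length(s) d in Morgans; \code{markerTable} and
#' \code{gameteRecords} return the underlying data.frames; \code{mapSex} the
#' sex of a map; \code{nMarkers} the marker count per chromosome.
#'
#' @param x a \linkS4class{LinkageMap} or \linkS4class{GameteCrossoverSet}.
#' @param chromosome optional chromosome label to restrict to.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("chromosomes", function(x) standardGeneric("chromosomes"))

#' @rdname accessors
#' @export
setMethod("chromosomes", "LinkageMap", function(x)
  unique(x@markers$chromosome))

#' @rdname accessors
#' @export
setMethod("chromosomes", "GameteCrossoverSet", function(x)
  unique(x@records$chromosome))

#' @rdname accessors
#' @export
setGeneric("mapLength", function(x, chromosome = NULL)
  standardGeneric("mapLength"))

#' @rdname accessors
#' @export
setMethod("mapLength", "LinkageMap", function(x, chromosome = NULL) {
  if (is.null(chromosome)) x@d else {
    if (!chromosome %in% names(x@d))
      stop("unknown chromosome: ", chromosome)
    unname(x@d[chromosome])
  }
})

#' @rdname accessors
#' @export
markerTable <- function(x, chromosome = NULL) {
  stopifnot(is(x, "LinkageMap"))
  m <- x@markers
  if (!is.null(chromosome)) m <- m[m$chromosome == chromosome, , drop = FALSE]
  m
}

#' @rdname accessors
#' @export
gameteRecords <- function(x) {
  stopifnot(is(x, "GameteCrossoverSet"))
  x@records
}

#' @rdname accessors
#' @export
mapSex <- function(x) {
  stopifnot(is(x, "LinkageMap"))
  x@sex
}

#' @rdname accessors
#' @export
nMarkers <- function(x, chromosome = NULL)
  nrow(markerTable(x, chromosome))

setMethod("show", "LinkageMap", function(object) {
  cat(sprintf("LinkageMap (%s): %d markers on %d chromosome(s)\n",
              object@sex, nrow(object@markers),
              length(unique(object@markers$chromosome))))
  d <- object@d
  cat(sprintf("  map length: %s cM\n",
              paste(sprintf("%s=%.4g", names(d), 100 * d), collapse = ", ")))
})

setMethod("show", "GameteCrossoverSet", function(object) {
  n <- nrow(object@records)
  k <- vapply(object@records$positions, length, integer(1))
  cat(sprintf(
    "GameteCrossoverSet: %d records, %d chromosome(s), mean %.3f crossovers\n",
    n, length(unique(object@records$chromosome)),
    if (n) mean(k) else NA_real_))
})

setMethod("show", "BivalentDistribution", function(object) {
  cat(sprintf("BivalentDistribution (%s, %s): counts 0..%d\n",
              object@chromosome, object@sex, length(object@probs) - 1L))
  print(round(bivalentProbs(object), 4))
})
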
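#' Inverse and forward mapping functions
#'
#' The classical translations between map distance d (Morgans) and
#' recombination frequency r. The inverse functions predict r from d:
#' Haldane \eqn{r = \frac{1}{2}(1 - e^{-2d})} (no interference), Kosambi
#' \eqn{r = \frac{1}{2}\tanh(2d)} (partial interference), and the linear
#' function \eqn{r = \min(d, 1/2)} (capped at 0.5). The forward functions
#' invert them: Haldane \eqn{d = -\frac{1}{2}\log(1 - 2r)}, Kosambi
#' \eqn{d = \frac{1}{4}\log\frac{1+2r}{1-2r}}.
#'
#' Negative distances and r >= 0.5 raise errors rather than being clipped,
#' so unit mistakes (cM passed where Morgans are expected) surface early.
#'
#' @param d map distance in Morgans, non-negative; vectorised.
#' @param r recombination frequency in [0, 0.5); vectorised.
#' @return numeric vector of the same length as the input.
#' @examples
#' inverseHaldane(0.5)        # 0.3160603
#' inverseKosambi(0.5)        # 0.3807971
#' inverseLinear(c(0.3, 0.7)) # 0.3 0.5
#' forwardHaldane(0.25)       # 0.3465736
#' @name mappingFunctions
NULL

.checkD <- function(d) {
  if (!is.numeric(d) || anyNA(d) || any(d < 0))
    stop("map distance d must be non-negative (Morgans)")
}

.checkR <- function(r) {
  if (!is.numeric(r) || anyNA(r) || any(r < 0) || any(r >= 0.5))
    stop("recombination frequency r must lie in [0, 0.5)")
}

#' @rdname mappingFunctions
#' @export
inverseHaldane <- function(d) {
  .checkD(d)
  0.5 * (1 - exp(-2 * d))
}

#' @rdname mappingFunctions
#' @export
inverseKosambi <- function(d) {
  .checkD(d)
  0.5 * tanh(2 * d)
}

#' @rdname mappingFunctions
#' @export
inverseLinear <- function(d) {
  .checkD(d)
  pmin(d, 0.5)
}

#' @rdname mappingFunctions
#' @export
forwardHaldane <- function(r) {
  .checkR(r)
  -0.5 * log(1 - 2 * r)
}

#' @rdname mappingFunctions
#' @export
forwardKosambi <- function(r) {
  .checkR(r)
  0.25 * log((1 + 2 * r) / (1 - 2 * r))
}

#' Look up an inverse mapping function by name
#'
#' @param kind one of \code{"haldane"}, \code{"kosambi"}, \code{"linear"}.
#' @return the corresponding inverse function of map distance.
#' @export
inverseMappingFunction <- function(kind = c("haldane", "kosambi", "linear")) {
  switch(match.arg(kind),
         haldane = inverseHaldane,
         kosambi = inverseKosambi,
         linear = inverseLinear)
}
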
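#' Haldane mapping function
#'
#' Converts a map distance in centiMorgan into a recombination fraction under
#' the Haldane model (independent crossovers, no interference):
#' \eqn{r = (1 - e^{-2d/100})/2}.
#'
#' @param d_cm Numeric vector of map distances in centiMorgan (>= 0).
#' @return Recombination fractions in [0, 0.5).
#' @seealso [haldane_inv()]
#' @export
#' @examples
#' haldane(0)    # 0
#' haldane(50)   # (1 - exp(-1)) / 2
haldane <- function(d_cm) {
  stopifnot(is.numeric(d_cm))
  if (any(d_cm < 0, na.rm = TRUE)) stop("map distances must be non-negative")
  (1 - exp(-2 * d_cm / 100)) / 2
}

#' Inverse Haldane mapping function
#'
#' Converts a recombination fraction back into a Haldane map distance in
#' centiMorgan: \eqn{d = -50 \log(1 - 2r)}.
#'
#' @param r Numeric vector of recombination fractions in [0, 0.5).
#' @return Map distances in centiMorgan.
#' @export
haldane_inv <- function(r) {
  stopifnot(is.numeric(r))
  if (any(r < 0 | r >= 0.5, na.rm = TRUE)) {
    stop("recombination fraction must lie in [0, 0.5) for the inverse Haldane map")
  }
  -50 * log(1 - 2 * r)
}
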
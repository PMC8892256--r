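#' Local maxima with topographic prominence
#'
#' Finds local maxima of a series and their prominence: the drop from the
#' peak to the highest of the two "key saddles", the minima separating it
#' from higher terrain on each side (series edges count as terrain ends).
#' Used for velocity-peak counting and force-peak detection, where a
#' prominence floor separates genuine sub-movements or presses from noise
#' ripple.
#'
#' @param x Numeric series.
#' @param min_prominence Keep only peaks at least this prominent.
#' @return A data.frame with columns `index`, `value`, `prominence`
#'   (zero rows if none qualify).
#' @examples
#' find_peaks(c(0, 2, 1, 3, 0), min_prominence = 0.5)
#' @export
find_peaks <- function(x, min_prominence = 0) {
  n <- length(x)
  empty <- data.frame(index = integer(0), value = numeric(0),
                      prominence = numeric(0))
  if (n < 3) return(empty)
  d <- diff(x)
  # strict rise into the peak, non-rise out; plateaus credit their first point
  cand <- which(d[-(n - 1)] > 0 & d[-1] <= 0) + 1L
  cand <- cand[vapply(cand, function(i) {
    j <- i
    while (j < n && x[j + 1] == x[i]) j <- j + 1L
    j == n || x[j + 1] < x[i]
  }, logical(1))]
  if (!length(cand)) return(empty)
  prom <- vapply(cand, function(i) {
    lmin <- x[i]; j <- i
    while (j > 1 && x[j - 1] <= x[i]) { j <- j - 1L; lmin <- min(lmin, x[j]) }
    rmin <- x[i]; j <- i
    while (j < n && x[j + 1] <= x[i]) { j <- j + 1L; rmin <- min(rmin, x[j]) }
    x[i] - max(lmin, rmin)
  }, numeric(1))
  keep <- prom >= min_prominence
  data.frame(index = cand[keep], value = x[cand[keep]], prominence = prom[keep])
}
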
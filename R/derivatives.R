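#' Smoothed kinematic derivatives
#'
#' Angular velocity, acceleration and jerk of a uniformly sampled angle
#' series by Savitzky-Golay polynomial-smoothing differentiation
#' ([signal::sgolayfilt()]): a polynomial of order `polyorder` is fit over a
#' sliding window and differentiated analytically, which suppresses the
#' amplification of encoder quantization noise that plain finite differences
#' would suffer at the third derivative.
#'
#' @param theta Angle series (rad), uniformly sampled.
#' @param fs Sampling rate (Hz).
#' @param window Smoothing window length (s); converted to an odd sample
#'   count.
#' @param polyorder Fitted polynomial order (>= 3 so jerk is defined).
#' @return A data.frame with columns `omega` (rad/s), `alpha` (rad/s^2),
#'   `jerk` (rad/s^3), same length as `theta`.
#' @examples
#' d <- kinematic_derivatives(sin(seq(0, 2, by = 1/80)), fs = 80)
#' max(abs(d$omega))
#' @export
kinematic_derivatives <- function(theta, fs, window = 0.35, polyorder = 3) {
  if (polyorder < 3) stop("`polyorder` must be >= 3 (jerk needs a cubic)")
  n <- round(window * fs)
  if (n %% 2 == 0) n <- n + 1
  if (n < polyorder + 2) n <- polyorder + 2 + (polyorder %% 2)
  if (length(theta) < n)
    stop("insufficient data: series shorter than the smoothing window (",
         n, " samples)")
  data.frame(
    omega = signal::sgolayfilt(theta, p = polyorder, n = n, m = 1, ts = 1 / fs),
    alpha = signal::sgolayfilt(theta, p = polyorder, n = n, m = 2, ts = 1 / fs),
    jerk = signal::sgolayfilt(theta, p = polyorder, n = n, m = 3, ts = 1 / fs)
  )
}
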
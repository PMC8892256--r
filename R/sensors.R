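#' Sensor model
#'
#' Acquisition model of the device: load cells sampled at a fixed rate with a
#' fixed force quantum and saturation, and an incremental encoder whose
#' angular resolution under quadrature decoding is `2*pi / (4 * ppr)`.
#'
#' @param force_rate Sampling rate (Hz, default 80).
#' @param force_resolution Force quantization step (kgf, default 0.025).
#' @param force_capacity Load-cell saturation (kgf, default 20).
#' @param encoder_ppr Encoder pulses per revolution (default 500).
#' @param quadrature Quadrature decoding factor (default 4).
#' @return An object of class `sensor_model`.
#' @examples
#' sensor_model()$theta_resolution
#' @export
sensor_model <- function(force_rate = 80, force_resolution = 0.025,
                         force_capacity = 20, encoder_ppr = 500,
                         quadrature = 4) {
  if (!(force_resolution > 0)) stop("`force_resolution` must be > 0")
  if (!(force_rate > 0)) stop("`force_rate` must be > 0")
  if (!(force_capacity > 0)) stop("`force_capacity` must be > 0")
  structure(list(
    force_rate = force_rate, force_resolution = force_resolution,
    force_capacity = force_capacity, encoder_ppr = encoder_ppr,
    quadrature = quadrature,
    theta_resolution = 2 * pi / (quadrature * encoder_ppr)
  ), class = "sensor_model")
}

#' Pass true signals through the sensor model
#'
#' Forces are clipped to `[0, capacity]` and rounded to the nearest multiple
#' of the force resolution; the angle is rounded to the nearest encoder step.
#'
#' @param F_left,F_right True per-side forces (kgf). Vectorized.
#' @param theta True bar angle (rad). Vectorized.
#' @param sensors A [sensor_model()].
#' @return A list with quantized `F_left`, `F_right`, `theta`.
#' @examples
#' acquire(1.2371, 0, 0)$F_left  # 1.225
#' @export
acquire <- function(F_left, F_right, theta, sensors = sensor_model()) {
  stopifnot(inherits(sensors, "sensor_model"))
  q <- function(f) {
    f <- pmin(pmax(f, 0), sensors$force_capacity)
    round(f / sensors$force_resolution) * sensors$force_resolution
  }
  list(F_left = q(F_left), F_right = q(F_right),
       theta = round(theta / sensors$theta_resolution) * sensors$theta_resolution)
}
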
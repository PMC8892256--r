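#' Robot geometry
#'
#' Describes the fixed frame and handlebar of the two-cable device. The
#' coordinate convention used throughout the package is a right-handed frame
#' with its origin at the midpoint of the two anchor points, `x` positive to
#' the user's right and `y` measured *downward* from the anchor line (so any
#' commanded position below the anchors has `y > 0`). The two cables leave the
#' anchors `A = (-Wb/2, 0)` and `B = (+Wb/2, 0)`.
#'
#' @param frame_width Distance `Wb` (m) between the fixed anchor points A and B.
#' @param handlebar_width Width `Wg` (m) of the handlebar (distance between the
#'   two cable attachment points on the bar). Must be smaller than
#'   `frame_width` so the cables splay outward.
#'
#' @return An object of class `robot_geometry` with fields `Wb`, `Wg`,
#'   `anchor_A` and `anchor_B`.
#' @examples
#' geom <- robot_geometry(frame_width = 1, handlebar_width = 0.6)
#' geom$anchor_A
#' @export
robot_geometry <- function(frame_width = 1.0, handlebar_width = 0.6) {
  stopifnot(is.numeric(frame_width), length(frame_width) == 1L,
            is.numeric(handlebar_width), length(handlebar_width) == 1L)
  if (!is.finite(frame_width) || frame_width <= 0)
    stop("`frame_width` (Wb) must be a positive length in meters")
  if (!is.finite(handlebar_width) || handlebar_width <= 0)
    stop("`handlebar_width` (Wg) must be a positive length in meters")
  if (handlebar_width >= frame_width)
    stop("`handlebar_width` (Wg) must be smaller than `frame_width` (Wb): ",
         "the cables must splay outward")
  structure(
    list(Wb = frame_width, Wg = handlebar_width,
         anchor_A = c(x = -frame_width / 2, y = 0),
         anchor_B = c(x = +frame_width / 2, y = 0)),
    class = "robot_geometry"
  )
}

#' @export
print.robot_geometry <- function(x, ...) {
  cat("Two-cable robot geometry\n")
  cat(sprintf("  frame width     Wb = %.3f m  (anchors at x = %+.3f, %+.3f)\n",
              x$Wb, x$anchor_A[["x"]], x$anchor_B[["x"]]))
  cat(sprintf("  handlebar width Wg = %.3f m\n", x$Wg))
  invisible(x)
}

#' Maximum admissible handlebar rotation
#'
#' Two geometric limits cap the bar rotation at a given drop `h`: (i) a cable
#' attachment point reaching the anchor line (`y` no longer positive, cable
#' slack), at `asin(2h/Wg)`; and (ii) an attachment point crossing the line
#' from the bar center to its anchor (`pi/2 - atan((Wb/2)/h)`), beyond which
#' the length-to-angle inversion folds onto a second branch and the arccos
#' argument leaves its single-valued domain. The admissible range is the
#' smaller of the two.
#'
#' @param h Handlebar center drop below the anchor line (m, positive).
#' @param geom A [robot_geometry()].
#' @return Largest admissible `|theta|` in radians.
#' @export
theta_max <- function(h, geom = robot_geometry()) {
  stopifnot(inherits(geom, "robot_geometry"))
  if (any(!is.finite(h)) || any(h <= 0)) stop("`h` must be positive")
  pmin(asin(pmin(1, 2 * h / geom$Wg)),
       pi / 2 - atan((geom$Wb / 2) / h))
}

deg2rad <- function(deg) deg * pi / 180
rad2deg <- function(rad) rad * 180 / pi
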
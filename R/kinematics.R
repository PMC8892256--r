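#' Cable length for the single-degree-of-freedom setup
#'
#' In the 1-DOF setup the end-effector only translates vertically, so with
#' `x` and `z` fixed the cable length equals the vertical drop of the platform:
#' `L = yp`.
#'
#' @param yp Vertical position of the platform (m, positive below the anchor
#'   line). Vectorized.
#' @return Cable length(s) in meters.
#' @examples
#' cable_length_1dof(0.5)
#' @export
cable_length_1dof <- function(yp) {
  if (any(!is.finite(yp))) stop("`yp` must be finite")
  if (any(yp <= 0))
    stop("invalid position: `yp` must be positive (taut cable below anchors)")
  yp
}

#' Cable lengths for a planar position
#'
#' For the planar (2-DOF) setup the two cables and the anchor line form a
#' triangle. The closed form expresses each length through the angle the cable
#' makes with the anchor line, `L = yp / sin(atan2(yp, xp - xa))` with `xa` the
#' anchor abscissa; it agrees with the Euclidean distance from the anchor to
#' the point. The Euclidean form is available as an independent check.
#'
#' @param xp,yp Coordinates of the desired platform position (m); `yp > 0`.
#'   Vectorized over positions.
#' @param geom A [robot_geometry()].
#' @param formula `"closed_form"` (default) or `"euclidean"`.
#' @return A data.frame with columns `L1` and `L2` (m), one row per position.
#' @examples
#' planar_cable_lengths(0, 0.5)
#' @export
planar_cable_lengths <- function(xp, yp, geom = robot_geometry(),
                                 formula = c("closed_form", "euclidean")) {
  stopifnot(inherits(geom, "robot_geometry"))
  formula <- match.arg(formula)
  if (length(xp) != length(yp)) stop("`xp` and `yp` must have equal length")
  if (any(!is.finite(xp)) || any(!is.finite(yp))) stop("coordinates must be finite")
  if (any(yp <= 0))
    stop("invalid position: `yp` must be positive (cables must stay taut)")
  dxA <- xp - geom$anchor_A[["x"]]
  dxB <- xp - geom$anchor_B[["x"]]
  if (any(yp == 0 & (dxA == 0 | dxB == 0)))
    stop("invalid position: degenerate point on an anchor")
  if (formula == "closed_form") {
    L1 <- yp / sin(atan2(yp, dxA))
    L2 <- yp / sin(atan2(yp, dxB))
  } else {
    L1 <- sqrt(dxA^2 + yp^2)
    L2 <- sqrt(dxB^2 + yp^2)
  }
  data.frame(L1 = L1, L2 = L2)
}

#' Discretized circular / polygonal trajectory
#'
#' Generates the `N` points of a circle of diameter `a` centered at
#' `(xc, yc)`, at angles `theta_i = i * 2*pi/N + alpha` for `i = 1..N`.
#' With `N = 3, 4, 5` the same construction yields triangle, quadrilateral and
#' pentagon vertices. With `interpolate = TRUE` a periodic cubic spline is
#' threaded through the closed polygon and densified.
#'
#' @param center_x,center_y Trajectory center `C` (m); `center_y > 0`.
#' @param diameter Movement amplitude `a` (m, > 0).
#' @param n_points Number of discretization points `N` (>= 3, or >= 1 when
#'   `interpolate = FALSE` for degenerate diagnostics).
#' @param rotation Rotation angle `alpha` (rad) added to every vertex angle.
#' @param interpolate Logical; densify with a periodic cubic spline.
#' @param points_per_segment Densification factor for the spline (points per
#'   polygon edge, default 20).
#' @param geom A [robot_geometry()] used for workspace validation.
#' @return A data.frame with columns `index`, `theta`, `x`, `y`. When
#'   `interpolate = TRUE` the vertex rows are followed by the densified path
#'   and a logical column `vertex` distinguishes them.
#' @examples
#' trajectory_points(0, 0.6, diameter = 0.2, n_points = 4)
#' @export
trajectory_points <- function(center_x, center_y, diameter, n_points,
                              rotation = 0, interpolate = FALSE,
                              points_per_segment = 20,
                              geom = robot_geometry()) {
  stopifnot(inherits(geom, "robot_geometry"))
  if (!is.finite(diameter) || diameter < 0) stop("`diameter` must be >= 0")
  if (!is.finite(n_points) || n_points < 1 || n_points != round(n_points))
    stop("`n_points` must be a positive integer")
  i <- seq_len(n_points)
  theta <- i * 2 * pi / n_points + rotation
  x <- center_x + diameter / 2 * cos(theta)
  y <- center_y + diameter / 2 * sin(theta)
  bad <- which(y <= 0)
  if (length(bad))
    stop("workspace error: trajectory point(s) ", paste(bad, collapse = ", "),
         " have non-positive y (cables would go slack)")
  out <- data.frame(index = i, theta = theta, x = x, y = y)
  if (!interpolate) return(out)
  if (n_points < 3) stop("spline interpolation needs `n_points` >= 3")
  # closed path: repeat the first vertex, interpolate x(i) and y(i) with a
  # periodic cubic spline, then drop the duplicated endpoint
  si <- c(0, i)
  sx <- c(x[n_points], x)
  sy <- c(y[n_points], y)
  n_out <- n_points * points_per_segment + 1
  px <- stats::spline(si, sx, n = n_out, method = "periodic")
  py <- stats::spline(si, sy, n = n_out, method = "periodic")
  dense <- data.frame(index = px$x, theta = px$x * 2 * pi / n_points + rotation,
                      x = px$y, y = py$y)
  dense <- dense[-1, ]
  bad <- which(dense$y <= 0)
  if (length(bad))
    stop("workspace error: interpolated point(s) leave the workspace near index ",
         paste(round(dense$index[bad[1]], 2)))
  out$vertex <- TRUE
  dense$vertex <- FALSE
  rbind(out, dense)
}

#' Cable lengths along a trajectory
#'
#' Element-wise composition of [trajectory_points()] and
#' [planar_cable_lengths()].
#'
#' @inheritParams trajectory_points
#' @param ... Passed on to [trajectory_points()].
#' @return A data.frame with columns `index`, `x`, `y`, `L1`, `L2`.
#' @export
trajectory_cable_lengths <- function(center_x, center_y, diameter, n_points,
                                     rotation = 0, geom = robot_geometry(),
                                     ...) {
  pts <- trajectory_points(center_x, center_y, diameter, n_points,
                           rotation = rotation, geom = geom, ...)
  len <- planar_cable_lengths(pts$x, pts$y, geom = geom)
  cbind(pts[c("index", "x", "y")], len)
}

# Handlebar cable attachment points for drop h and rotation theta.
# theta > 0 is counterclockwise as seen by the user: left end down
# (larger y), right end up. Returns list(e1 = left, e2 = right).
handlebar_endpoints <- function(h, theta, geom) {
  r <- geom$Wg / 2
  list(e1 = cbind(x = -r * cos(theta), y = h + r * sin(theta)),
       e2 = cbind(x = +r * cos(theta), y = h - r * sin(theta)))
}

#' Cable lengths for the bimanual handlebar setup
#'
#' Forward kinematics of the bimanual setup: the handlebar center hangs `h`
#' meters below the anchor line and the bar is rotated by `theta` (radians,
#' positive counterclockwise as seen by the user, i.e. right end up). The
#' default `"geometric"` formula computes the distances from each anchor to
#' the corresponding bar attachment point. `"printed"` evaluates the
#' law-of-cosines closed form
#' `L^2 = (Wb/2)^2 + h^2 + Wg*(Wg/2 - d*cos(pi/2 +/- theta - atan((Wb/2)/h)))`
#' with `d = sqrt((Wb/2)^2 + h^2)`, whose `Wg^2/2` expansion differs slightly
#' from the attachment-point geometry (which carries `Wg^2/4`); see
#' [closed_form_discrepancy()].
#'
#' @param h Handlebar center drop (m, > 0). Vectorized with `theta`.
#' @param theta Bar rotation (rad), `|theta|` below [theta_max()].
#' @param geom A [robot_geometry()].
#' @param formula `"geometric"` (default) or `"printed"`.
#' @return A data.frame with columns `L1` (left cable) and `L2` (right cable),
#'   in meters. At `theta = 0` the two are equal; rotating clockwise
#'   (`theta < 0`) shortens `L1` and lengthens `L2`.
#' @examples
#' bimanual_cable_lengths(0.7, 0)
#' @export
bimanual_cable_lengths <- function(h, theta, geom = robot_geometry(),
                                   formula = c("geometric", "printed")) {
  stopifnot(inherits(geom, "robot_geometry"))
  formula <- match.arg(formula)
  n <- max(length(h), length(theta))
  h <- rep_len(h, n); theta <- rep_len(theta, n)
  if (any(!is.finite(h)) || any(h <= 0)) stop("`h` must be positive and finite")
  lim <- theta_max(h, geom)
  if (any(!is.finite(theta)) || any(abs(theta) >= lim))
    stop("invalid orientation: |theta| must be below theta_max(h) = ",
         signif(min(lim), 4), " rad")
  if (formula == "geometric") {
    ep <- handlebar_endpoints(h, theta, geom)
    L1 <- sqrt((ep$e1[, "x"] - geom$anchor_A[["x"]])^2 + ep$e1[, "y"]^2)
    L2 <- sqrt((ep$e2[, "x"] - geom$anchor_B[["x"]])^2 + ep$e2[, "y"]^2)
  } else {
    d2 <- (geom$Wb / 2)^2 + h^2
    d <- sqrt(d2)
    beta <- atan((geom$Wb / 2) / h)
    L1 <- sqrt(d2 + geom$Wg * (geom$Wg / 2 - d * cos(pi / 2 + theta - beta)))
    L2 <- sqrt(d2 + geom$Wg * (geom$Wg / 2 - d * cos(pi / 2 - theta - beta)))
  }
  if (any(!is.finite(L1)) || any(!is.finite(L2)) || any(L1 <= 0) || any(L2 <= 0))
    stop("invalid orientation: cable length would not be a positive real")
  data.frame(L1 = L1, L2 = L2)
}

#' Handlebar orientation from cable lengths
#'
#' Inverse kinematics of the bimanual setup. Each cable length fixes, through
#' the cosine law in the triangle anchor / bar center / attachment point, the
#' angle between the bar and the line from the bar center to its anchor; the
#' difference of the two arccos terms equals **twice** the bar rotation, so
#' the returned angle is half that difference. `formula = "printed"` uses the
#' arccos arguments `(-4L^2 + Wb^2 + 2*Wg^2 + 4h^2) / (4*Wg*sqrt(Wb^2/4 + h^2))`
#' (matching the `"printed"` forward model); the default `"geometric"`
#' arguments carry `Wg^2` in place of `2*Wg^2`, matching the attachment-point
#' geometry. Either pair round-trips with its own forward model.
#'
#' @param L1,L2 Left and right cable lengths (m). Vectorized.
#' @param h Handlebar center drop (m, > 0).
#' @param geom A [robot_geometry()].
#' @param formula `"geometric"` (default) or `"printed"`.
#' @return Bar rotation `theta` in radians (positive counterclockwise;
#'   `L1 = L2` gives 0; swapping `L1` and `L2` flips the sign).
#' @examples
#' L <- bimanual_cable_lengths(0.7, 0.2)
#' handlebar_orientation(L$L1, L$L2, 0.7)
#' @export
handlebar_orientation <- function(L1, L2, h, geom = robot_geometry(),
                                  formula = c("geometric", "printed")) {
  stopifnot(inherits(geom, "robot_geometry"))
  formula <- match.arg(formula)
  n <- max(length(L1), length(L2), length(h))
  L1 <- rep_len(L1, n); L2 <- rep_len(L2, n); h <- rep_len(h, n)
  if (any(!is.finite(h)) || any(h <= 0)) stop("`h` must be positive")
  if (any(L1 <= 0) || any(L2 <= 0)) stop("cable lengths must be positive")
  wg2 <- if (formula == "printed") 2 * geom$Wg^2 else geom$Wg^2
  den <- 4 * geom$Wg * sqrt(geom$Wb^2 / 4 + h^2)
  a1 <- (-4 * L1^2 + geom$Wb^2 + wg2 + 4 * h^2) / den
  a2 <- (-4 * L2^2 + geom$Wb^2 + wg2 + 4 * h^2) / den
  tol <- 1e-12
  if (any(abs(a1) > 1 + tol) || any(abs(a2) > 1 + tol))
    stop("inconsistent lengths: arccos argument outside [-1, 1]")
  a1 <- pmin(1, pmax(-1, a1)); a2 <- pmin(1, pmax(-1, a2))
  (acos(a1) - acos(a2)) / 2
}

#' Numeric discrepancy between the printed and geometric closed forms
#'
#' Evaluates both forward models over a grid of `(h, theta)` and reports the
#' largest absolute cable-length difference. The printed closed form carries a
#' `Wg^2/2` term where the attachment-point geometry (lever arm `Wg/2`) gives
#' `Wg^2/4`, so the two differ by a small, geometry-dependent amount.
#'
#' @param geom A [robot_geometry()].
#' @param h Vector of handlebar drops to scan (m).
#' @param n_theta Number of rotation angles per drop.
#' @return A list with `max_abs_diff_m` and the grid maxima per `h`.
#' @export
closed_form_discrepancy <- function(geom = robot_geometry(),
                                    h = c(0.5, 0.7, 0.9), n_theta = 41) {
  per_h <- vapply(h, function(hh) {
    th <- seq(-0.9, 0.9, length.out = n_theta) * theta_max(hh, geom)
    g <- bimanual_cable_lengths(hh, th, geom, formula = "geometric")
    p <- bimanual_cable_lengths(hh, th, geom, formula = "printed")
    max(abs(as.matrix(g) - as.matrix(p)))
  }, numeric(1))
  list(max_abs_diff_m = max(per_h), per_h = data.frame(h = h, max_abs_diff_m = per_h))
}

#' Export a trajectory with cable lengths as CSV
#'
#' Writes columns `index`, `x_m`, `y_m`, `L1_m`, `L2_m`.
#'
#' @param trajectory A data.frame as returned by [trajectory_cable_lengths()].
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_trajectory_csv <- function(trajectory, file) {
  stopifnot(all(c("index", "x", "y", "L1", "L2") %in% names(trajectory)))
  out <- data.frame(index = trajectory$index,
                    x_m = trajectory$x, y_m = trajectory$y,
                    L1_m = trajectory$L1, L2_m = trajectory$L2)
  utils::write.csv(format(out, digits = 17, trim = TRUE), file,
                   row.names = FALSE, quote = FALSE)
  invisible(file)
}
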
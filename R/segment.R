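#' Segmentation configuration
#'
#' Parameters of the movement segmentation. Each change of the desired angle
#' opens a repetition; within it four landmarks are located: `T_0` (target
#' issued), `T_i` (movement onset: productive torque direction, smoothed
#' angular speed above the onset threshold, and the recorded position at
#' least one encoder step away from its pre-movement value), `T_d` (desired
#' position first inside the position tolerance) and `T_f` (first instant
#' after `T_d` with angular speed below the end threshold).
#'
#' @param onset_velocity_threshold Angular speed (rad/s) for onset; `NULL`
#'   (default) resolves to 5\% of the session's median per-repetition peak
#'   speed, floored at `velocity_floor`.
#' @param end_velocity_threshold Angular speed (rad/s) for settling; `NULL`
#'   resolves like the onset threshold.
#' @param smoothing_window,smoothing_order Savitzky-Golay settings passed to
#'   [kinematic_derivatives()] (s / polynomial order).
#' @param peak_prominence Velocity-peak prominence for `N_p`, as a fraction
#'   of the segment's peak speed.
#' @param force_peak_prominence Force-peak prominence (kgf) for the peak-force
#'   parameters.
#' @param position_tolerance Angular tolerance (rad) for `T_d`; `NULL` takes
#'   the game capture tolerance from the log (the evaluator then uses the
#'   same success criterion as the game).
#' @param velocity_floor Lower bound (rad/s) for auto-resolved thresholds.
#' @param signed_jerk Use the signed jerk integral in the normalized-jerk
#'   parameter instead of its absolute value (the signed integral largely
#'   cancels over a movement that starts and ends at rest; kept as a variant).
#' @return An object of class `segmentation_config`.
#' @export
segmentation_config <- function(onset_velocity_threshold = NULL,
                                end_velocity_threshold = NULL,
                                smoothing_window = 0.35, smoothing_order = 3,
                                peak_prominence = 0.15,
                                force_peak_prominence = 0.5,
                                position_tolerance = NULL,
                                velocity_floor = 0.01,
                                signed_jerk = FALSE) {
  chk <- function(v, nm) if (!is.null(v) && !(v > 0)) stop("`", nm, "` must be > 0")
  chk(onset_velocity_threshold, "onset_velocity_threshold")
  chk(end_velocity_threshold, "end_velocity_threshold")
  chk(position_tolerance, "position_tolerance")
  stopifnot(smoothing_window > 0, peak_prominence > 0, force_peak_prominence > 0)
  structure(list(
    onset_velocity_threshold = onset_velocity_threshold,
    end_velocity_threshold = end_velocity_threshold,
    smoothing_window = smoothing_window, smoothing_order = smoothing_order,
    peak_prominence = peak_prominence,
    force_peak_prominence = force_peak_prominence,
    position_tolerance = position_tolerance,
    velocity_floor = velocity_floor, signed_jerk = isTRUE(signed_jerk)
  ), class = "segmentation_config")
}

# Sampling rate and sensor/controller snapshots for a log, with fallbacks
# for logs lacking metadata.
log_fs <- function(log) {
  if (!is.null(log$metadata$fs)) return(log$metadata$fs)
  1 / stats::median(diff(log$samples$t_s))
}

log_theta_res <- function(log) {
  s <- log$metadata$sensors
  if (!is.null(s$encoder_ppr)) 2 * pi / ((s$quadrature %||% 4) * s$encoder_ppr)
  else 2 * pi / 2000
}

log_pos_tol <- function(log) {
  cfg <- log$metadata$cfg
  if (!is.null(cfg$tolerance) && !is.null(cfg$theta_span))
    cfg$tolerance * cfg$theta_span
  else 0.08
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Segment a session into movement repetitions
#'
#' One segment per desired-position change. Segments where the onset criteria
#' are never met are marked `has_onset = FALSE`; segments that never reach the
#' desired position carry a no-completion mark (`completed = FALSE`) and are
#' excluded from movement-time and speed statistics downstream. Degenerate
#' segments are marked, never raised.
#'
#' @param log A `session_log` (from [simulate_session()] or
#'   [read_session_log()]).
#' @param cfg A [segmentation_config()].
#' @return An object of class `movement_segments`: a data.frame `segments`
#'   with the landmark times and index ranges, the derivative series, and the
#'   resolved thresholds.
#' @export
segment_movements <- function(log, cfg = segmentation_config()) {
  stopifnot(inherits(log, "session_log"), inherits(cfg, "segmentation_config"))
  s <- log$samples
  fs <- log_fs(log)
  dt <- 1 / fs
  der <- kinematic_derivatives(s$theta_rad, fs, cfg$smoothing_window,
                               cfg$smoothing_order)
  runs <- rle(s$theta_d_rad)
  ends <- cumsum(runs$lengths)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  pos_tol <- cfg$position_tolerance %||% log_pos_tol(log)
  theta_res <- log_theta_res(log)

  peak_per_reach <- mapply(function(i0, i1) max(abs(der$omega[i0:i1])),
                           starts, ends)
  auto_thr <- max(cfg$velocity_floor, 0.05 * stats::median(peak_per_reach))
  onset_thr <- cfg$onset_velocity_threshold %||% auto_thr
  end_thr <- cfg$end_velocity_threshold %||% auto_thr

  seg <- lapply(seq_along(starts), function(k) {
    i0 <- starts[k]; i1 <- ends[k]
    idx <- i0:i1
    theta_d <- s$theta_d_rad[i0]
    theta_start <- s$theta_rad[i0]
    dir <- sign(theta_d - theta_start)
    T_0 <- s$t_s[i0] - dt   # target issued one tick before the first sample
    prod <- if (dir >= 0) s$F_left_kgf[idx] - s$F_right_kgf[idx] > 0
            else s$F_right_kgf[idx] - s$F_left_kgf[idx] > 0
    moved <- abs(s$theta_rad[idx] - theta_start) > theta_res
    fast <- abs(der$omega[idx]) > onset_thr
    oi <- which(prod & moved & fast)
    has_onset <- length(oi) > 0
    T_i <- if (has_onset) s$t_s[idx[oi[1]]] else NA_real_
    di <- which(abs(s$theta_rad[idx] - theta_d) <= pos_tol)
    if (has_onset) di <- di[di >= oi[1]]
    completed <- length(di) > 0
    T_d <- if (completed) s$t_s[idx[di[1]]] else NA_real_
    T_f <- NA_real_
    if (completed) {
      fi <- which(abs(der$omega[idx]) < end_thr)
      fi <- fi[fi >= di[1]]
      T_f <- if (length(fi)) s$t_s[idx[fi[1]]] else s$t_s[i1]
    }
    data.frame(reach = k, i0 = i0, i1 = i1, T_0 = T_0, T_i = T_i, T_d = T_d,
               T_f = T_f, direction = if (dir >= 0) "CCW" else "CW",
               has_onset = has_onset, completed = has_onset && completed)
  })
  structure(list(segments = do.call(rbind, seg), derivatives = der,
                 onset_threshold = onset_thr, end_threshold = end_thr,
                 position_tolerance = pos_tol, fs = fs, cfg = cfg),
            class = "movement_segments")
}

#' @export
print.movement_segments <- function(x, ...) {
  sg <- x$segments
  cat(sprintf("Movement segmentation: %d repetitions (%d with onset, %d completed)\n",
              nrow(sg), sum(sg$has_onset), sum(sg$completed)))
  cat(sprintf("  velocity thresholds: onset %.3f, end %.3f rad/s; position tolerance %.3f rad\n",
              x$onset_threshold, x$end_threshold, x$position_tolerance))
  invisible(x)
}
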
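#' Interquartile-fence outlier validation
#'
#' Values outside `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]` are discarded before
#' averaging any per-repetition parameter, so single inconsistent repetitions
#' (much higher or smaller, e.g. a distracted trial) do not distort session
#' means, while the wide natural range of human movement is kept. With fewer
#' than four finite values no decision is meaningful and everything is kept.
#'
#' @param values Numeric vector (NAs are dropped).
#' @return A list with `kept`, `discarded`, and the logical `keep` mask over
#'   the finite values' positions in `values`.
#' @examples
#' validate_outliers(c(2.4, 2.5, 2.6, 2.5, 25))$discarded
#' @export
validate_outliers <- function(values) {
  ok <- is.finite(values)
  v <- values[ok]
  if (length(v) < 4)
    return(list(kept = v, discarded = numeric(0),
                keep = stats::setNames(ok, NULL)))
  q <- stats::quantile(v, c(0.25, 0.75), names = FALSE)
  fence <- c(q[1] - 1.5 * (q[2] - q[1]), q[2] + 1.5 * (q[2] - q[1]))
  inside <- v >= fence[1] & v <= fence[2]
  keep <- ok
  keep[ok] <- inside
  list(kept = v[inside], discarded = v[!inside], keep = keep)
}

vmean <- function(values) {
  k <- validate_outliers(values)$kept
  if (length(k)) mean(k) else NA_real_
}

seg_slice <- function(sg_row, log, from = "T_i", to = "T_f") {
  idx <- sg_row$i0:sg_row$i1
  t <- log$samples$t_s[idx]
  idx[t >= sg_row[[from]] - 1e-9 & t <= sg_row[[to]] + 1e-9]
}

#' Time parameters
#'
#' Reaction time `T_r = T_i - T_0` over repetitions with a detected onset and
#' movement time `T_m = T_f - T_i` over completed repetitions, each averaged
#' after [validate_outliers()].
#'
#' @param segments A [segment_movements()] result (or its `segments` frame).
#' @return A list with `T_r` (s), `T_m` (s), the per-segment values, and the
#'   used/discarded counts. `T_r`/`T_m` are `NA` when no repetition
#'   qualifies (empty-report marker).
#' @export
time_parameters <- function(segments) {
  sg <- if (inherits(segments, "movement_segments")) segments$segments else segments
  tr <- (sg$T_i - sg$T_0)[sg$has_onset]
  tm <- (sg$T_f - sg$T_i)[sg$completed]
  vr <- validate_outliers(tr); vm <- validate_outliers(tm)
  list(T_r = if (length(vr$kept)) mean(vr$kept) else NA_real_,
       T_m = if (length(vm$kept)) mean(vm$kept) else NA_real_,
       T_r_values = tr, T_m_values = tm,
       n_used = length(vm$kept),
       n_discarded = nrow(sg) - length(vm$kept))
}

#' Speed parameters of one repetition
#'
#' Mean and peak absolute angular velocity over `[T_i, T_f]`.
#'
#' @param sg_row One row of a segmentation frame (completed segment).
#' @param log The `session_log`.
#' @param omega The smoothed angular-velocity series of the whole log.
#' @return `c(omega_m, omega_p)` in rad/s.
#' @export
speed_parameters <- function(sg_row, log, omega) {
  i <- seg_slice(sg_row, log)
  w <- abs(omega[i])
  c(omega_m = mean(w), omega_p = max(w))
}

#' Smoothness parameters of one repetition
#'
#' Normalized jerk `J_n = (1/omega_p) * mean(|jerk|)` over `[T_i, T_f]`
#' (time-normalized jerk integral divided by the peak speed; the signed
#' variant is available via the segmentation config) and the velocity-peak
#' count `N_p`: local maxima of the speed profile with prominence at least
#' `peak_prominence * omega_p`, floored at 1 for any segment with motion.
#'
#' @inheritParams speed_parameters
#' @param cfg The [segmentation_config()] in force.
#' @return `c(J_n, N_p)`; both `NA` when the segment has no motion
#'   (`omega_p = 0`).
#' @export
smoothness_parameters <- function(sg_row, log, derivatives,
                                  cfg = segmentation_config()) {
  i <- seg_slice(sg_row, log)
  w <- abs(derivatives$omega[i])
  wp <- max(w)
  if (wp <= 0) return(c(J_n = NA_real_, N_p = NA_real_))
  jint <- if (cfg$signed_jerk) abs(mean(derivatives$jerk[i]))
          else mean(abs(derivatives$jerk[i]))
  np <- nrow(find_peaks(w, min_prominence = cfg$peak_prominence * wp))
  c(J_n = jint / wp, N_p = max(1, np))
}

#' RMS position error of one repetition
#'
#' Root mean square of `theta - theta_d` over `[T_i, T_f]`, in radians.
#'
#' @inheritParams speed_parameters
#' @return RMS error (rad).
#' @export
error_parameter <- function(sg_row, log) {
  i <- seg_slice(sg_row, log)
  sqrt(mean((log$samples$theta_rad[i] - log$samples$theta_d_rad[i])^2))
}

#' Peak-force parameters of a session
#'
#' Per side, local force maxima with at least `force_peak_prominence` kgf of
#' prominence are detected over the whole session and averaged after outlier
#' validation; the symmetry parameter is `delta_F = F_p_left - F_p_right`
#' (positive when the left peaks are higher, zero when equal).
#'
#' Each force series is low-passed with a short (5-sample) moving average
#' before peak detection, so single-sample sensor ripple does not register
#' as a press.
#'
#' @param log A `session_log`.
#' @param cfg A [segmentation_config()].
#' @return A list with `F_p_left`, `F_p_right`, `delta_F` (kgf; `NA` when a
#'   side has no detectable peaks) and the raw peak tables.
#' @export
force_parameters <- function(log, cfg = segmentation_config()) {
  pk_l <- find_peaks(ctrl_filter(log$samples$F_left_kgf), cfg$force_peak_prominence)
  pk_r <- find_peaks(ctrl_filter(log$samples$F_right_kgf), cfg$force_peak_prominence)
  fpl <- if (nrow(pk_l)) vmean(pk_l$value) else NA_real_
  fpr <- if (nrow(pk_r)) vmean(pk_r$value) else NA_real_
  list(F_p_left = fpl, F_p_right = fpr, delta_F = fpl - fpr,
       peaks_left = pk_l, peaks_right = pk_r)
}

#' Torque parameters of a session
#'
#' Each side's torque contribution is its force deviation from that side's
#' baseline hold level (the per-side median force outside detected movement
#' windows) times the half handlebar width, signed by the rotation it induces
#' (a left press drives counterclockwise, a right press clockwise) and
#' classified against the repetition's desired direction: productive when it
#' drives toward the target, counterproductive otherwise. Total torque is
#' positive (productive) only when both sides are net productive; the
#' symmetry `delta_tau` is left minus right productive torque. Units kgf cm.
#'
#' @param log A `session_log`.
#' @param segments A [segment_movements()] result.
#' @param geom A [robot_geometry()]; defaults to the geometry in the log.
#' @return A list with `tau_p_left`, `tau_p_right`, `tau_cp_left`,
#'   `tau_cp_right`, `tau_total`, `delta_tau` (kgf cm) and the baselines.
#' @export
torque_parameters <- function(log, segments, geom = NULL) {
  sg <- segments$segments
  if (is.null(geom)) {
    Wg <- log$metadata$geom$Wg %||% 0.6
  } else Wg <- geom$Wg
  lever_cm <- Wg / 2 * 100
  s <- log$samples
  move <- rep(FALSE, nrow(s))
  for (k in which(sg$completed))
    move[seg_slice(sg[k, ], log, "T_i", "T_f")] <- TRUE
  base_l <- stats::median(s$F_left_kgf[!move])
  base_r <- stats::median(s$F_right_kgf[!move])

  per_seg <- lapply(which(sg$has_onset & sg$completed), function(k) {
    row <- sg[k, ]
    i <- seg_slice(row, log)
    d <- if (row$direction == "CCW") +1 else -1
    c_l <- (s$F_left_kgf[i] - base_l) * lever_cm * (+1) * d
    c_r <- (s$F_right_kgf[i] - base_r) * lever_cm * (-1) * d
    c(tp_l = mean(pmax(c_l, 0)), tcp_l = mean(pmax(-c_l, 0)),
      tp_r = mean(pmax(c_r, 0)), tcp_r = mean(pmax(-c_r, 0)))
  })
  if (!length(per_seg)) {
    na <- NA_real_
    return(list(tau_p_left = na, tau_p_right = na, tau_cp_left = na,
                tau_cp_right = na, tau_total = na, delta_tau = na,
                baseline_left = base_l, baseline_right = base_r))
  }
  m <- do.call(rbind, per_seg)
  tp_l <- vmean(m[, "tp_l"]); tcp_l <- vmean(m[, "tcp_l"])
  tp_r <- vmean(m[, "tp_r"]); tcp_r <- vmean(m[, "tcp_r"])
  net_l <- tp_l - tcp_l
  net_r <- tp_r - tcp_r
  tau_total <- if (net_l > 0 && net_r > 0) net_l + net_r else -abs(net_l + net_r)
  list(tau_p_left = tp_l, tau_p_right = tp_r,
       tau_cp_left = tcp_l, tau_cp_right = tcp_r,
       tau_total = tau_total, delta_tau = tp_l - tp_r,
       baseline_left = base_l, baseline_right = base_r)
}

#' Session performance report
#'
#' Segments a session and assembles the performance parameters: reaction and
#' movement time, mean and peak angular speed, velocity-peak count,
#' normalized jerk, RMS position error, per-side peak forces and force
#' symmetry, per-side productive/counterproductive torque with total torque
#' and torque symmetry, plus the game score and losses from the event stream.
#' Every per-repetition parameter is averaged after [validate_outliers()].
#'
#' @param log A `session_log`.
#' @param cfg A [segmentation_config()].
#' @param geom Optional [robot_geometry()] override for the torque lever arm.
#' @return An object of class `performance_report`. Reaction time is reported
#'   in ms, movement time in s, speeds in rad/s, the RMS error in degrees,
#'   forces in kgf and torques in kgf cm. Parameters that no repetition
#'   supports are `NA`.
#' @examples
#' log <- simulate_session(healthy_profile(), n_reaches = 5, seed = 2)
#' session_report(log)
#' @export
session_report <- function(log, cfg = segmentation_config(), geom = NULL) {
  stopifnot(inherits(log, "session_log"))
  segments <- segment_movements(log, cfg)
  sg <- segments$segments
  tp <- time_parameters(segments)

  comp <- which(sg$completed)
  if (length(comp)) {
    sp <- t(vapply(comp, function(k)
      speed_parameters(sg[k, ], log, segments$derivatives$omega),
      numeric(2)))
    sm <- t(vapply(comp, function(k)
      smoothness_parameters(sg[k, ], log, segments$derivatives, cfg),
      numeric(2)))
    er <- vapply(comp, function(k) error_parameter(sg[k, ], log), numeric(1))
    omega_m <- vmean(sp[, 1]); omega_p <- vmean(sp[, 2])
    J_n <- vmean(sm[, 1]); N_p <- vmean(sm[, 2])
    err_deg <- vmean(er) * 180 / pi
  } else {
    omega_m <- omega_p <- J_n <- N_p <- err_deg <- NA_real_
    sp <- sm <- NULL; er <- numeric(0)
  }
  fp <- force_parameters(log, cfg)
  tq <- torque_parameters(log, segments, geom)
  ev <- log$events
  score <- sum(ev$kind == "caught")
  losses <- sum(ev$kind == "lost")

  structure(list(
    subject_id = log$metadata$subject_id %||% NA_character_,
    date = log$metadata$date %||% NA_character_,
    game = log$metadata$game %||% NA_character_,
    mode = log$metadata$mode %||% NA_character_,
    T_r_ms = tp$T_r * 1000, T_m_s = tp$T_m,
    omega_m = omega_m, omega_p = omega_p,
    N_p = N_p, J_n = J_n, theta_err_rms_deg = err_deg,
    F_p_left = fp$F_p_left, F_p_right = fp$F_p_right, delta_F = fp$delta_F,
    tau_p_left = tq$tau_p_left, tau_p_right = tq$tau_p_right,
    tau_cp_left = tq$tau_cp_left, tau_cp_right = tq$tau_cp_right,
    tau_total = tq$tau_total, delta_tau = tq$delta_tau,
    score = score, losses = losses,
    n_segments = nrow(sg), n_segments_used = tp$n_used,
    n_segments_discarded = tp$n_discarded,
    per_segment = list(segments = sg, speed = sp, smoothness = sm, error = er)
  ), class = "performance_report")
}

#' @export
print.performance_report <- function(x, ...) {
  cat(sprintf("Performance report: %s, %s (%s mode), %s\n",
              x$subject_id, x$game, x$mode, x$date))
  cat(sprintf("  repetitions: %d (%d used, %d discarded/invalid)\n",
              x$n_segments, x$n_segments_used, x$n_segments_discarded))
  f <- function(v, d = 2) ifelse(is.na(v), "  NA", formatC(v, digits = d, format = "f"))
  cat(sprintf("  T_r  %s ms    T_m  %s s\n", f(x$T_r_ms, 0), f(x$T_m_s)))
  cat(sprintf("  w_m  %s rad/s w_p  %s rad/s  N_p %s  J_n %s 1/s^2\n",
              f(x$omega_m), f(x$omega_p), f(x$N_p, 1), f(x$J_n, 1)))
  cat(sprintf("  RMS error %s deg\n", f(x$theta_err_rms_deg)))
  cat(sprintf("  F_p left %s right %s  dF %s kgf\n",
              f(x$F_p_left), f(x$F_p_right), f(x$delta_F)))
  cat(sprintf("  tau_p L/R %s/%s  tau_cp L/R %s/%s  total %s  dtau %s kgf.cm\n",
              f(x$tau_p_left, 1), f(x$tau_p_right, 1), f(x$tau_cp_left, 1),
              f(x$tau_cp_right, 1), f(x$tau_total, 1), f(x$delta_tau, 1)))
  cat(sprintf("  score %d  losses %d\n", x$score, x$losses))
  invisible(x)
}

#' One-row data frame of a performance report
#'
#' @param x A `performance_report`.
#' @param row.names,optional,... Ignored (S3 signature).
#' @return A one-row data.frame suitable for longitudinal stacking.
#' @export
as.data.frame.performance_report <- function(x, row.names = NULL,
                                             optional = FALSE, ...) {
  flat <- x[setdiff(names(x), "per_segment")]
  as.data.frame(flat, stringsAsFactors = FALSE)
}

#' Write a performance report
#'
#' JSON (full report) plus a flat one-row CSV for longitudinal tooling.
#'
#' @param report A `performance_report`.
#' @param path Output path without extension.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "performance_report"))
  flat <- as.data.frame(report)
  jsonlite::write_json(flat, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, na = "null")
  utils::write.csv(flat, paste0(path, ".csv"), row.names = FALSE)
  invisible(path)
}

#' Read a performance report written by [write_report()]
#'
#' @param path Path without extension (reads `<path>.json`).
#' @return A `performance_report`.
#' @export
read_report <- function(path) {
  x <- as.list(jsonlite::fromJSON(paste0(path, ".json")))
  num <- setdiff(names(x), c("subject_id", "date", "game", "mode"))
  x[num] <- lapply(x[num], function(v) if (is.null(v)) NA_real_ else as.numeric(v))
  structure(x, class = "performance_report")
}
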
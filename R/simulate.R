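#' Simulate a closed-loop game session
#'
#' Runs the full loop hardware-free: the subject model reacts to each falling
#' object with a planned force pattern, the force map classifies the intent,
#' an admittance plant rotates the bar (`theta_dot = -admittance * (F_right -
#' F_left)` while the rotation gate is open), the sensor model quantizes what
#' is recorded, and the game resolves each object against the capture
#' tolerance, adapting assistance from the last-five outcome balance.
#' Deterministic given `seed`.
#'
#' @param profile A [subject_profile()].
#' @param cfg A [controller_config()].
#' @param sensors A [sensor_model()].
#' @param duration Session length (s); the session holds as many complete
#'   reaches as fit. Alternatively give `n_reaches`.
#' @param n_reaches Number of objects to resolve (overrides `duration`).
#' @param seed RNG seed (mandatory; the log embeds it).
#' @param subject_id,date Metadata carried into the log.
#' @param h Handlebar drop (m) used for torque lever-arm bookkeeping.
#' @param geom A [robot_geometry()].
#' @return A `session_log`: `metadata` (config snapshots, seed, per-reach
#'   ground truth), `samples` (uniform-rate `t_s`, `theta_rad`, `theta_d_rad`,
#'   `F_left_kgf`, `F_right_kgf`, `assist_level`) and `events` (spawn, caught,
#'   lost, assist_change, overforce_warning).
#' @examples
#' log <- simulate_session(healthy_profile(), n_reaches = 3, seed = 1)
#' log$metadata$truth$caught
#' @export
simulate_session <- function(profile, cfg = controller_config(),
                             sensors = sensor_model(), duration = NULL,
                             n_reaches = NULL, seed, subject_id = "S1",
                             date = "2024-01-01", h = 0.7,
                             geom = robot_geometry()) {
  stopifnot(inherits(profile, "subject_profile"),
            inherits(cfg, "controller_config"),
            inherits(sensors, "sensor_model"))
  if (missing(seed)) stop("`seed` is required for a reproducible session")
  if (is.null(duration) && is.null(n_reaches))
    stop("give `duration` or `n_reaches`")
  check_feasible(profile, cfg)
  set.seed(seed)
  fs <- sensors$force_rate
  dt <- 1 / fs
  sep <- max(0.25, 1.5 * cfg$tolerance)

  draw_crystal <- function(wagon_x) {
    for (i in 1:50) {
      x <- stats::runif(1, -0.85, 0.85)
      if (abs(x - wagon_x) >= sep) return(x)
    }
    x
  }

  state <- game_state(cfg, crystal_x = draw_crystal(0))
  theta <- 0
  t0 <- 0
  reach <- 0L
  samples <- list(); events <- list(); truth <- list()
  ev <- function(t, kind, payload = "") {
    events[[length(events) + 1L]] <<- data.frame(
      t_s = t, kind = kind, payload = as.character(payload))
  }

  repeat {
    fall_time <- 1 / state$fall_speed
    n <- round(fall_time * fs)
    if (!is.null(duration) && t0 + n * dt > duration + 1e-9) break
    if (!is.null(n_reaches) && reach >= n_reaches) break
    reach <- reach + 1L
    lvl <- state$assist_level
    theta_d <- -state$crystal_x * cfg$theta_span
    ev(t0, "spawn", sprintf("crystal_x=%.6f;theta_d=%.6f", state$crystal_x, theta_d))

    plan <- reach_plan(profile, theta_d - theta, cfg, fall_time, fs, lvl)
    f <- noiseless_forces(plan, plan$amplitude, profile)
    nf <- length(f$t)
    F_drive <- pmax(0, f$F_drive + stats::rnorm(nf, 0, profile$tremor_sd))
    F_lift <- pmax(0, f$F_lift + stats::rnorm(nf, 0, profile$tremor_sd))
    if (plan$drive == "left") { Fl <- F_drive; Fr <- F_lift } else { Fl <- F_lift; Fr <- F_drive }
    rec <- acquire(Fl, Fr, 0, sensors)

    res <- plant_response(rec$F_left, rec$F_right, theta, theta_d, lvl, cfg, fs,
                          pos_tol = cfg$tolerance * cfg$theta_span)
    th_true <- res$theta
    rec_theta <- acquire(0, 0, th_true, sensors)$theta

    over <- which(rec$F_left > cfg$F_max | rec$F_right > cfg$F_max)
    if (length(over)) ev(t0 + over[1] * dt, "overforce_warning",
                         if (rec$F_left[over[1]] > cfg$F_max) "left" else "right")

    samples[[reach]] <- data.frame(
      t_s = t0 + seq_len(n) * dt, theta_rad = rec_theta,
      theta_d_rad = rep(theta_d, n), F_left_kgf = rec$F_left,
      F_right_kgf = rec$F_right, assist_level = rep(lvl, n))

    theta <- th_true[n]
    caught <- abs(theta - theta_d) <= cfg$tolerance * cfg$theta_span
    t_end <- t0 + n * dt
    ev(t_end, if (caught) "caught" else "lost", reach)
    truth[[reach]] <- data.frame(
      reach = reach, t_spawn = t0, crystal_x = state$crystal_x,
      theta_d = theta_d, delay = plan$delay,
      onset = if (is.na(res$onset)) NA_real_ else t0 + res$onset,
      move_end = if (is.na(res$offset)) NA_real_ else t0 + res$offset,
      K = plan$K, T_move = plan$T_move, amplitude = plan$amplitude,
      direction = if (plan$dir > 0) "CCW" else "CW", drive = plan$drive,
      shortfall = plan$shortfall, assist_level = lvl, caught = caught)

    state$wagon_x <- -theta / cfg$theta_span
    state <- resolve_object(state, caught, cfg,
                            crystal_x = draw_crystal(state$wagon_x))
    if (state$assist_level != lvl)
      ev(t_end, "assist_change", state$assist_level)
    t0 <- t_end
  }

  structure(list(
    metadata = list(
      subject_id = subject_id, date = as.character(date), game = cfg$game,
      mode = cfg$mode, seed = seed, fs = fs, h = h,
      profile = unclass(profile), cfg = unclass(cfg),
      sensors = unclass(sensors),
      geom = list(Wb = geom$Wb, Wg = geom$Wg),
      truth = do.call(rbind, truth)
    ),
    samples = do.call(rbind, samples),
    events = do.call(rbind, events)
  ), class = "session_log")
}

# Admittance plant over one reach. Returns the true theta path and the
# ground-truth movement landmarks (s since reach start; NA if the gate never
# opens): onset = start of the first sustained (>= 4 samples) open-gate run,
# offset = the gate closure following the first entry into the position
# tolerance band (or the end of the last open run if the band is never
# reached) — the generative counterparts of the evaluator's T_i and T_f.
plant_response <- function(F_left, F_right, theta0, theta_d, lvl, cfg, fs,
                           pos_tol = cfg$tolerance * cfg$theta_span) {
  dt <- 1 / fs
  n <- length(F_left)
  tt <- seq_len(n) * dt
  if (lvl >= cfg$a_max && cfg$a_max > 0L) {
    # full takeover: the controller performs the movement by itself
    v <- cfg$takeover_speed * cfg$theta_span
    t_start <- 0.3
    prog <- pmin(pmax(tt - t_start, 0) * v, abs(theta_d - theta0))
    theta <- theta0 + sign(theta_d - theta0) * prog
    moving <- prog > 0 & prog < abs(theta_d - theta0)
    onset <- if (any(moving)) tt[which(moving)[1]] else NA_real_
    offset <- if (any(moving)) tt[max(which(moving))] else NA_real_
    return(list(theta = theta, onset = onset, offset = offset))
  }
  open <- rotation_gate(F_left, F_right, cfg, lvl)
  omega <- -cfg$admittance * (ctrl_filter(F_right) - ctrl_filter(F_left)) * open
  if (lvl >= 2L) {
    # assist drift toward the target needs the running angle
    theta <- numeric(n)
    th <- theta0
    drift <- cfg$drift_speed * cfg$theta_span
    for (i in seq_len(n)) {
      delta <- theta_d - th
      th <- th + omega[i] * dt + sign(delta) * min(drift * dt, abs(delta))
      theta[i] <- th
    }
  } else {
    theta <- theta0 + cumsum(omega) * dt
  }
  if (!any(open)) return(list(theta = theta, onset = NA_real_, offset = NA_real_))
  onset_i <- which(open)[1]
  entry <- which(abs(theta - theta_d) <= pos_tol & seq_len(n) >= onset_i)[1]
  offset_i <- max(which(open))
  if (!is.na(entry)) {
    # first sustained (>= 4 samples) gate closure after tolerance entry;
    # shorter closures are tremor dips inside an ongoing movement
    r <- rle(open)
    run_end <- cumsum(r$lengths)
    run_start <- run_end - r$lengths + 1L
    stop_run <- which(!r$values & r$lengths >= 4L & run_start > entry)
    if (length(stop_run)) {
      before <- which(open[seq_len(run_start[stop_run[1]] - 1L)])
      if (length(before)) offset_i <- max(before)
    }
  }
  list(theta = theta, onset = tt[onset_i], offset = tt[offset_i])
}

within_cfg_level <- function(cfg, lvl) {
  cfg$assist_level <- as.integer(lvl)
  cfg
}

# Diagnostic feasibility check: at least one rotation direction must be
# achievable under the configured threshold with this subject's strength.
check_feasible <- function(profile, cfg) {
  thr <- effective_threshold(cfg)
  base <- profile$baseline_force
  sev <- profile$paresis_severity
  feas <- function(drive) {
    lift <- if (drive == "left") "right" else "left"
    q <- if (profile$hemiparesis_side == lift) 1 - sev else 1
    cap <- profile$drive_cap * profile$arm_strength[[drive]] *
      (if (profile$hemiparesis_side == drive) 1 - sev else 1)
    lift_min <- base * profile$arm_strength[[lift]] * (1 - profile$lift_depth * q)
    max_diff <- cap + base * profile$arm_strength[[drive]] - lift_min
    lift_min < cfg$F_rot && max_diff > thr
  }
  if (!feas("left") && !feas("right"))
    stop("infeasible config: the rotation threshold (effective delta_F = ",
         signif(thr, 3), " kgf) exceeds what this subject can produce in ",
         "either direction, or the lift threshold F_rot cannot be met")
  invisible(TRUE)
}

#' @export
print.session_log <- function(x, ...) {
  tr <- x$metadata$truth
  cat(sprintf("Session log: %s, %s (%s mode), seed %d\n", x$metadata$subject_id,
              x$metadata$game, x$metadata$mode, x$metadata$seed))
  cat(sprintf("  %d samples at %g Hz, %d reaches (%d caught, %d lost)\n",
              nrow(x$samples), x$metadata$fs, nrow(tr), sum(tr$caught),
              sum(!tr$caught)))
  invisible(x)
}

#' Write / read a session log
#'
#' The sample series goes to `<path>.csv` (columns `t_s`, `theta_rad`,
#' `theta_d_rad`, `F_left_kgf`, `F_right_kgf`, `assist_level`) and metadata
#' plus events to `<path>.json`. The round trip is lossless.
#'
#' @param log A `session_log`.
#' @param path Output path without extension.
#' @return `path` invisibly (writer); a `session_log` (reader).
#' @export
write_session_log <- function(log, path) {
  stopifnot(inherits(log, "session_log"))
  utils::write.csv(format(log$samples, digits = 17, trim = TRUE),
                   paste0(path, ".csv"), row.names = FALSE, quote = FALSE)
  side <- list(metadata = log$metadata, events = log$events)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(path)
}

#' @rdname write_session_log
#' @export
read_session_log <- function(path) {
  samples <- utils::read.csv(paste0(path, ".csv"))
  side <- jsonlite::fromJSON(paste0(path, ".json"))
  md <- side$metadata
  md$truth <- as.data.frame(md$truth)
  md$profile$arm_strength <- unlist(md$profile$arm_strength)
  structure(list(metadata = md, samples = samples,
                 events = as.data.frame(side$events)),
            class = "session_log")
}
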
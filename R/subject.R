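#' Synthetic subject profile
#'
#' Generative parameters of a simulated participant. Each falling object
#' triggers one "reach": after a sampled reaction delay the subject presses
#' the driving side down with a train of minimum-jerk force pulses (one per
#' sub-movement) while lifting the opposite side; hemiparesis scales the
#' affected arm's active force down, slows its drives and adds reaction delay,
#' and the non-paretic arm additionally produces involuntary pressure bursts
#' during idle phases (compensation), so the force-peak asymmetry carries the
#' side of the impairment.
#'
#' @param reaction_delay_mean,reaction_delay_sd Force-onset delay distribution
#'   (s): lag between a new target and the start of productive force
#'   development. The realized movement onset (the gate opening, recorded in
#'   the session truth table) follows roughly 0.2 s later, once the force
#'   differential crosses the rotation threshold.
#' @param movement_time_mean,movement_time_sd Planned movement duration (s)
#'   from force onset to the end of the pulse train.
#' @param arm_strength Named per-side force scale, `c(left = 1, right = 1)`.
#' @param hemiparesis_side `"none"`, `"left"` or `"right"`.
#' @param paresis_severity Severity in `[0, 1)`; reduces exactly the affected
#'   arm's active force (cap `* (1 - severity)`), slows its drives
#'   (duration `* (1 + severity)`), degrades its lift and adds
#'   `0.25 * severity` s of reaction delay.
#' @param submovements_mean Mean sub-movement count per reach (>= 1).
#' @param submovements_dispersion 0 for a deterministic `round(mean)` count;
#'   1 for `1 + Poisson(mean - 1)`.
#' @param tremor_sd Additive force noise per sample and side (kgf).
#' @param baseline_force Static per-side hold force (kgf) from supporting the
#'   weighted handlebar at rest.
#' @param lift_depth Fraction of the baseline removed by a full lift.
#' @param drive_cap Maximum voluntary added force (kgf) for a unit-strength,
#'   unimpaired arm.
#' @param pause_fraction Fraction of the movement duration spent hesitating
#'   between sub-movements (no force drive, bar at rest); fragmented movers
#'   pause more. Ignored for single-pulse reaches.
#' @param compensation_rate Idle-phase pressure bursts on the non-paretic side,
#'   per second per unit severity.
#' @return An object of class `subject_profile`.
#' @seealso [healthy_profile()], [post_stroke_profile()]
#' @export
subject_profile <- function(reaction_delay_mean = 0.53, reaction_delay_sd = 0.18,
                            movement_time_mean = 3.5, movement_time_sd = 0.5,
                            arm_strength = c(left = 1, right = 1),
                            hemiparesis_side = c("none", "left", "right"),
                            paresis_severity = 0,
                            submovements_mean = 1.3, submovements_dispersion = 1,
                            tremor_sd = 0.05, baseline_force = 1.5,
                            lift_depth = 0.6, drive_cap = 6,
                            pause_fraction = 0.12, compensation_rate = 1.2) {
  hemiparesis_side <- match.arg(hemiparesis_side)
  if (!(reaction_delay_mean > 0)) stop("`reaction_delay_mean` must be > 0")
  if (!(movement_time_mean > 0)) stop("`movement_time_mean` must be > 0")
  if (!all(arm_strength > 0) || !all(c("left", "right") %in% names(arm_strength)))
    stop("`arm_strength` must be a named positive vector with `left` and `right`")
  if (paresis_severity < 0 || paresis_severity >= 1)
    stop("`paresis_severity` must lie in [0, 1)")
  if (paresis_severity > 0 && hemiparesis_side == "none")
    stop("`paresis_severity` > 0 requires a `hemiparesis_side`")
  if (submovements_mean < 1) stop("`submovements_mean` must be >= 1")
  if (tremor_sd < 0) stop("`tremor_sd` must be >= 0")
  structure(list(
    reaction_delay_mean = reaction_delay_mean, reaction_delay_sd = reaction_delay_sd,
    movement_time_mean = movement_time_mean, movement_time_sd = movement_time_sd,
    arm_strength = arm_strength[c("left", "right")],
    hemiparesis_side = hemiparesis_side, paresis_severity = paresis_severity,
    submovements_mean = submovements_mean,
    submovements_dispersion = submovements_dispersion,
    tremor_sd = tremor_sd, baseline_force = baseline_force,
    lift_depth = lift_depth, drive_cap = drive_cap,
    pause_fraction = pause_fraction, compensation_rate = compensation_rate
  ), class = "subject_profile")
}

#' Default profiles
#'
#' Starting-point profiles calibrated so that group-level reaction times land
#' near 0.73 s (healthy) and 1.03 s (post-stroke) and movement times near
#' 2.5 s and 4.6 s; sub-movement counts near 1 and 4. These are calibration
#' targets for the generator, not measurements.
#'
#' @param severity Paresis severity for the post-stroke profile.
#' @param side Hemiparesis side for the post-stroke profile.
#' @return A [subject_profile()].
#' @export
healthy_profile <- function() subject_profile()

#' @rdname healthy_profile
#' @export
post_stroke_profile <- function(severity = 0.4, side = "left") {
  subject_profile(
    reaction_delay_mean = 0.70, reaction_delay_sd = 0.5,
    movement_time_mean = 6.0, movement_time_sd = 1.2,
    hemiparesis_side = side, paresis_severity = severity,
    submovements_mean = 4, submovements_dispersion = 1,
    tremor_sd = 0.12, pause_fraction = 0.45
  )
}

#' @export
print.subject_profile <- function(x, ...) {
  cat(sprintf("Subject profile: reaction %.2f±%.2f s, movement %.1f±%.1f s, submovements ~%.1f\n",
              x$reaction_delay_mean, x$reaction_delay_sd,
              x$movement_time_mean, x$movement_time_sd, x$submovements_mean))
  if (x$hemiparesis_side != "none")
    cat(sprintf("  hemiparesis: %s side, severity %.2f\n",
                x$hemiparesis_side, x$paresis_severity))
  invisible(x)
}

# Minimum-jerk speed-profile bell, normalized to peak 1 on tau in [0, 1].
mj_bell <- function(tau) {
  s <- ifelse(tau > 0 & tau < 1, (30 * tau^2 - 60 * tau^3 + 30 * tau^4) / 1.875, 0)
  pmax(s, 0)
}

# Minimum-jerk position S-curve, 0 -> 1 over x in [0, 1].
mj_step <- function(x) {
  x <- pmin(pmax(x, 0), 1)
  10 * x^3 - 15 * x^4 + 6 * x^5
}

# One sub-movement force pulse: minimum-jerk attack to a plateau and
# minimum-jerk release, total duration T_p. Voluntary force develops much
# faster (~0.3 s) than the sub-movement lasts.
force_pulse <- function(t, start, T_p, attack = NULL) {
  if (is.null(attack)) attack <- min(0.3, 0.35 * T_p)
  pmin(mj_step((t - start) / attack), mj_step((start + T_p - t) / attack))
}

# Trapezoidal 0..1 envelope: ramps up over `ramp` s at `on`, holds, ramps
# down after `off`.
trapezoid <- function(t, on, off, ramp = 0.15) {
  pmin(1, pmax(0, (t - on) / ramp), pmax(0, (off + ramp - t) / ramp))
}

#' Plan one reach
#'
#' Draws the stochastic elements of a reach (reaction delay, sub-movement
#' count, movement duration, compensation bursts) from the current RNG stream
#' and sizes the drive pulse amplitude so that the gated plant rotation covers
#' the required angle. The driving side presses, the opposite side lifts;
#' hemiparesis modifies whichever arm is affected.
#'
#' @param profile A [subject_profile()].
#' @param delta_theta Required bar rotation (rad, signed; positive =
#'   counterclockwise = left side drives).
#' @param cfg A [controller_config()].
#' @param fall_time Time available until the object resolves (s).
#' @param fs Sampling rate (Hz).
#' @param assist_level Assist level in force during this reach.
#' @return A `reach_plan` list (delay, pulse schedule, amplitude, sides,
#'   burst schedule, lift quality, diagnostic fields).
#' @export
reach_plan <- function(profile, delta_theta, cfg, fall_time, fs = 80,
                       assist_level = cfg$assist_level) {
  p <- profile
  sev <- p$paresis_severity
  delay <- max(0.15, stats::rnorm(1, p$reaction_delay_mean, p$reaction_delay_sd)) +
    0.25 * sev
  K <- if (p$submovements_dispersion == 0) max(1L, as.integer(round(p$submovements_mean)))
       else 1L + stats::rpois(1, max(0, p$submovements_mean - 1))
  # each sub-movement advances the bar by at least its correction
  # granularity (~0.075 rad), so small corrections use few sub-movements
  K <- max(1L, min(K, as.integer(floor(0.9 * abs(delta_theta) / 0.075))))
  T_move <- max(0.8, stats::rnorm(1, p$movement_time_mean, p$movement_time_sd))
  # movement duration scales with target amplitude: small corrections are
  # brief, full-range rotations take the profile's nominal duration
  T_move <- T_move * min(1, max(0.35, abs(delta_theta) / 0.45))

  dir <- if (delta_theta >= 0) +1 else -1          # +1 CCW, -1 CW
  drive <- if (dir > 0) "left" else "right"
  lift <- if (dir > 0) "right" else "left"
  paretic_drive <- p$hemiparesis_side == drive
  paretic_lift <- p$hemiparesis_side == lift
  if (paretic_drive) T_move <- T_move * (1 + 0.5 * sev)
  q_lift <- if (paretic_lift) 1 - sev else 1
  cap <- p$drive_cap * p$arm_strength[[drive]] * (if (paretic_drive) 1 - sev else 1)

  skip <- FALSE
  available <- fall_time - delay - 0.35
  if (available < 0.5 || abs(delta_theta) < 1e-6) skip <- TRUE
  # leave an idle tail: the bar must settle before the object resolves
  T_move <- min(T_move, max(0.75 * available, 0.5))
  gap_total <- if (K > 1) p$pause_fraction * T_move else 0
  T_p <- (T_move - gap_total) / K
  schedule <- function(T_p) delay + (seq_len(K) - 1) *
    (if (K > 1) (T_move - T_p) / (K - 1) else 0)
  starts <- schedule(T_p)
  move_end <- delay + T_move

  # compensation bursts on the non-paretic side during the idle tail
  bursts <- NULL
  if (sev > 0) {
    idle0 <- move_end + 0.4
    idle1 <- fall_time - 0.2
    n_b <- if (idle1 > idle0)
      stats::rpois(1, p$compensation_rate * sev * (idle1 - idle0)) else 0L
    if (n_b > 0) {
      bursts <- list(
        t = sort(stats::runif(n_b, idle0, idle1)),
        amp = stats::runif(n_b, 1.5, 3.0) * (0.5 + sev),
        width = 0.4,
        side = if (p$hemiparesis_side == "left") "right" else "left"
      )
    }
  }

  plan <- list(
    delay = delay, K = K, T_move = T_move, T_p = T_p, starts = starts,
    move_end = move_end, dir = dir, drive = drive, lift = lift,
    q_lift = q_lift, cap = cap, amplitude = 0, skip = skip,
    shortfall = 0, bursts = bursts, delta_theta = delta_theta,
    assist_level = assist_level, fall_time = fall_time, fs = fs
  )
  if (skip) return(structure(plan, class = "reach_plan"))

  # size the amplitude (and, for small targets, shorten the pulses) so the
  # gated rotation covers |delta_theta|
  thr <- effective_threshold(cfg, assist_level)
  dt <- 1 / fs
  rot <- function(pl, A) {
    f <- noiseless_forces(pl, A, profile)
    if (pl$drive == "left") { Fl <- f$F_drive; Fr <- f$F_lift }
    else { Fl <- f$F_lift; Fr <- f$F_drive }
    open <- rotation_gate(Fl, Fr, cfg, assist_level)
    cfg$admittance * sum(abs(ctrl_filter(Fr) - ctrl_filter(Fl))[open]) * dt
  }
  target <- abs(delta_theta)
  base_lift <- p$baseline_force * p$arm_strength[[lift]]
  A_min <- max(0.2, thr - p$lift_depth * q_lift * base_lift + 0.15)
  if (A_min >= cap) {
    plan$amplitude <- cap
    plan$shortfall <- max(0, target - rot(plan, cap))
    return(structure(plan, class = "reach_plan"))
  }
  r_min <- rot(plan, A_min)
  if (r_min >= target) {
    # even the weakest workable press overshoots: shorten the pulses (the
    # pauses absorb the spare duration), then re-solve the amplitude on the
    # shortened schedule — rotation shrinks faster than pulse time because
    # the attack/release edges do not scale
    fac <- max(0.25 / T_p, 0.95 * target / r_min)
    plan$T_p <- T_p * fac
    plan$starts <- schedule(plan$T_p)
    r2 <- rot(plan, A_min)
    if (r2 >= target) {
      plan$amplitude <- A_min   # overshoot bounded by the duration floor
    } else if (rot(plan, cap) < target) {
      plan$amplitude <- cap
      plan$shortfall <- target - rot(plan, cap)
    } else {
      plan$amplitude <- stats::uniroot(function(A) rot(plan, A) - target,
                                       c(A_min, cap), tol = 1e-6)$root
    }
  } else if (rot(plan, cap) < target) {
    plan$amplitude <- cap
    plan$shortfall <- target - rot(plan, cap)
  } else {
    plan$amplitude <- stats::uniroot(function(A) rot(plan, A) - target,
                                     c(A_min, cap), tol = 1e-6)$root
  }
  structure(plan, class = "reach_plan")
}

# Noiseless drive/lift force traces on the plan's tick grid.
noiseless_forces <- function(plan, A, profile) {
  dt <- 1 / plan$fs
  tt <- seq_len(round(plan$fall_time * plan$fs)) * dt
  base <- profile$baseline_force
  pulses <- numeric(length(tt))
  if (!plan$skip) {
    for (a in plan$starts)
      pulses <- pulses + force_pulse(tt, a, plan$T_p)
    env <- trapezoid(tt, plan$delay, plan$move_end)
  } else env <- numeric(length(tt))
  F_drive <- base * profile$arm_strength[[plan$drive]] + A * pulses
  F_lift <- base * profile$arm_strength[[plan$lift]] *
    (1 - profile$lift_depth * plan$q_lift * env)
  if (!is.null(plan$bursts)) {
    b <- plan$bursts
    burst_sig <- numeric(length(tt))
    for (i in seq_along(b$t))
      burst_sig <- burst_sig + b$amp[i] * mj_bell((tt - b$t[i]) / b$width)
    if (b$side == plan$drive) F_drive <- F_drive + burst_sig
    else F_lift <- F_lift + burst_sig
  }
  list(t = tt, F_drive = F_drive, F_lift = F_lift)
}

#' Generate the per-arm force traces of one reach
#'
#' True (pre-sensor) left/right forces of a reach at the requested times.
#' Before the sampled reaction delay both sides sit at their baseline hold
#' values; afterwards the driving side carries the sub-movement pulse train
#' and the other side lifts; tremor noise is added throughout (drawn from the
#' current RNG stream).
#'
#' @param profile A [subject_profile()].
#' @param direction `"CW"` or `"CCW"`.
#' @param t_since_spawn Sample times (s since the target appeared).
#' @param plan Optional [reach_plan()]; drawn if omitted (consumes RNG).
#' @param cfg A [controller_config()] (used when drawing a plan).
#' @param delta_theta Required rotation when drawing a plan (rad, magnitude).
#' @return A data.frame with columns `t`, `F_left`, `F_right` (kgf, >= 0).
#' @export
generate_reach_forces <- function(profile, direction = c("CW", "CCW"),
                                  t_since_spawn, plan = NULL,
                                  cfg = controller_config(),
                                  delta_theta = 0.35) {
  direction <- match.arg(direction)
  if (is.null(plan)) {
    d <- if (direction == "CCW") abs(delta_theta) else -abs(delta_theta)
    fall_time <- max(t_since_spawn) + 1 / 80
    plan <- reach_plan(profile, d, cfg, fall_time = fall_time)
  }
  f <- noiseless_forces(plan, plan$amplitude, profile)
  idx <- pmin(pmax(round(t_since_spawn * plan$fs), 1), length(f$t))
  F_drive <- f$F_drive[idx]
  F_lift <- f$F_lift[idx]
  n <- length(idx)
  F_drive <- pmax(0, F_drive + stats::rnorm(n, 0, profile$tremor_sd))
  F_lift <- pmax(0, F_lift + stats::rnorm(n, 0, profile$tremor_sd))
  if (plan$drive == "left")
    data.frame(t = t_since_spawn, F_left = F_drive, F_right = F_lift)
  else
    data.frame(t = t_since_spawn, F_left = F_lift, F_right = F_drive)
}
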
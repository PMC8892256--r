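#' Force-map controller and game configuration
#'
#' Configuration of the bimanual force-map controller and of the
#' crystal-catching serious game built on it. The patient rotates the bar by
#' pressing one side down while lifting the other: a rotation intent fires
#' when the pressed side exceeds the lifted side by the (assist-adjusted)
#' threshold `delta_F` *and* the lifted side has dropped below `F_rot`.
#' Forces above `F_max` on either side trigger an over-force warning instead
#' of a movement, discouraging one-sided effort.
#'
#' @param delta_F Rotation-intent force differential threshold (kgf, > 0).
#' @param F_rot Opposite-arm lift threshold (kgf): rotation requires the
#'   non-pressing side to be lifted below this value.
#' @param F_max Per-side warning cap (kgf, > `F_rot`).
#' @param tolerance Capture half-window in game units (playfield spans
#'   `[-1, 1]`); an object is collected when the wagon center is within
#'   `tolerance` of it. The flower-catching variant (`game = "sakura"`) is the
#'   same game with a considerably smaller default tolerance.
#' @param assist_level Integer in `[-a_max, a_max]`. Positive levels assist
#'   (1: halve the rotation threshold, 2: also drift toward the target,
#'   3: full takeover); negative levels are resistive (threshold raised).
#' @param a_max Maximum assistance magnitude (default 3).
#' @param mode Game mode: `"constant"` (fixed fall speed), `"accelerated"`
#'   (fall speed +10\% at every 10th point) or `"dynamic"` (resistive
#'   assistance scheduled from the score).
#' @param game `"minecart"` or `"sakura"`; only the default `tolerance`
#'   differs (0.15 vs 0.05 game units).
#' @param assist_enabled Enable assist-as-needed adaptation from the last-five
#'   outcome balance (ignored in `"dynamic"` mode, which schedules the level
#'   from the score instead).
#' @param assist_trigger Last-five balance (caught - lost) at or below which
#'   the assist level is raised one step (default -1).
#' @param assist_release Balance at or above which a positive assist level is
#'   lowered one step (default +3).
#' @param fall_speed Object fall speed (playfield heights per second; the
#'   field is 1 high, so `1/fall_speed` is the fall time).
#' @param raise_threshold Both forces below this: upward translation intent
#'   (bar raise). Defaults to `F_rot`.
#' @param lower_threshold Both forces above this: downward translation intent.
#'   Defaults to `2 * F_rot`.
#' @param theta_span Bar rotation (rad) mapped to one playfield half-width;
#'   the wagon position is `-theta / theta_span` (clockwise rotation moves the
#'   wagon right). Default 30 degrees.
#' @param admittance Plant gain (rad/s per kgf of force differential) used by
#'   the headless simulation.
#' @param wagon_speed Wagon speed (game units/s) used when the game is stepped
#'   from discrete intents rather than from the bar angle.
#' @param drift_speed Assist drift toward the target at level >= 2 (game
#'   units/s).
#' @param takeover_speed Controller-driven wagon speed at full takeover (game
#'   units/s).
#'
#' @return An object of class `controller_config`.
#' @examples
#' cfg <- controller_config()
#' effective_threshold(cfg)
#' @export
controller_config <- function(delta_F = 1.2, F_rot = 1.0, F_max = 10,
                              tolerance = NULL, assist_level = 0L, a_max = 3L,
                              mode = c("constant", "accelerated", "dynamic"),
                              game = c("minecart", "sakura"),
                              assist_enabled = TRUE,
                              assist_trigger = -1L, assist_release = 3L,
                              fall_speed = 0.11,
                              raise_threshold = F_rot,
                              lower_threshold = 2 * F_rot,
                              theta_span = pi / 6, admittance = 0.12,
                              wagon_speed = 0.5, drift_speed = 0.4,
                              takeover_speed = 2) {
  mode <- match.arg(mode)
  game <- match.arg(game)
  if (is.null(tolerance)) tolerance <- if (game == "sakura") 0.05 else 0.15
  if (!(delta_F > 0)) stop("`delta_F` must be > 0")
  if (!(F_rot > 0 && F_rot < F_max)) stop("need 0 < F_rot < F_max")
  if (!(tolerance > 0)) stop("`tolerance` must be > 0")
  if (abs(assist_level) > a_max) stop("`assist_level` must lie in [-a_max, a_max]")
  if (!(fall_speed > 0)) stop("`fall_speed` must be > 0")
  structure(list(
    delta_F = delta_F, F_rot = F_rot, F_max = F_max, tolerance = tolerance,
    assist_level = as.integer(assist_level), a_max = as.integer(a_max),
    mode = mode, game = game, assist_enabled = isTRUE(assist_enabled),
    assist_trigger = as.integer(assist_trigger),
    assist_release = as.integer(assist_release),
    fall_speed = fall_speed, raise_threshold = raise_threshold,
    lower_threshold = lower_threshold, theta_span = theta_span,
    admittance = admittance, wagon_speed = wagon_speed,
    drift_speed = drift_speed, takeover_speed = takeover_speed
  ), class = "controller_config")
}

#' @export
print.controller_config <- function(x, ...) {
  cat(sprintf("Force-map controller: dF=%.2f kgf (effective %.2f at assist %d), F_rot=%.2f, F_max=%.2f kgf\n",
              x$delta_F, effective_threshold(x), x$assist_level, x$F_rot, x$F_max))
  cat(sprintf("  game=%s mode=%s tolerance=%.3f units, fall_speed=%.3f /s\n",
              x$game, x$mode, x$tolerance, x$fall_speed))
  invisible(x)
}

#' Assist-adjusted rotation threshold
#'
#' The rotation differential threshold after applying the current assistance
#' level: assistive levels halve it per step (`delta_F * 2^-level`), resistive
#' (negative) levels raise it symmetrically. Level 0 returns `delta_F`
#' unchanged.
#'
#' @param cfg A [controller_config()].
#' @param assist_level Optional override of `cfg$assist_level`.
#' @return Effective threshold in kgf.
#' @export
effective_threshold <- function(cfg, assist_level = cfg$assist_level) {
  cfg$delta_F * 2^(-assist_level)
}

#' Classify movement intent from a bimanual force sample
#'
#' Applies the force map: over-force warning first, then rotation (force
#' differential above the assist-adjusted threshold with the opposite arm
#' lifted below `F_rot`), then the translation regions (both forces low:
#' raise; both high: lower), otherwise hold. Clockwise means the right side
#' is pressed; the classification is antisymmetric under a left/right swap.
#'
#' @param F_left,F_right Per-side forces (kgf, >= 0). Vectorized.
#' @param cfg A [controller_config()].
#' @return Character vector with values in
#'   `c("CW", "CCW", "RAISE", "LOWER", "HOLD", "OVERFORCE")`.
#' @examples
#' classify_intent(0.4, 3, controller_config())
#' @export
classify_intent <- function(F_left, F_right, cfg) {
  stopifnot(inherits(cfg, "controller_config"))
  n <- max(length(F_left), length(F_right))
  F_left <- rep_len(F_left, n); F_right <- rep_len(F_right, n)
  if (any(!is.finite(F_left)) || any(!is.finite(F_right)) ||
      any(F_left < 0) || any(F_right < 0))
    stop("invalid sample: forces must be finite and non-negative")
  thr <- effective_threshold(cfg)
  out <- rep("HOLD", n)
  out[F_left < cfg$raise_threshold & F_right < cfg$raise_threshold] <- "RAISE"
  out[F_left > cfg$lower_threshold & F_right > cfg$lower_threshold] <- "LOWER"
  out[F_right - F_left > thr & F_left < cfg$F_rot] <- "CW"
  out[F_left - F_right > thr & F_right < cfg$F_rot] <- "CCW"
  out[F_left > cfg$F_max | F_right > cfg$F_max] <- "OVERFORCE"
  out
}

#' Rotation-gate engagement mask
#'
#' The motors engage a rotation when the force differential exceeds the
#' (assist-adjusted) threshold with the opposite arm lifted below `F_rot`,
#' and stay engaged until the differential falls below 85\% of the threshold
#' (hysteresis). The controller low-passes the load-cell stream with a causal
#' 5-sample moving average before gating, so tremor at the threshold does not
#' chatter the drive. Over-force on either side disengages. Used by the headless plant and by
#' the reach planner, which must size forces against the same gate.
#'
#' @param F_left,F_right Per-side force series (kgf).
#' @param cfg A [controller_config()].
#' @param assist_level Assist level in force (sets the effective threshold).
#' @return Logical vector: gate open at each sample.
#' @export
rotation_gate <- function(F_left, F_right, cfg,
                          assist_level = cfg$assist_level) {
  thr <- effective_threshold(cfg, assist_level)
  F_left <- ctrl_filter(F_left)
  F_right <- ctrl_filter(F_right)
  d <- F_right - F_left
  open_now <- (d > thr & F_left < cfg$F_rot) |
    (-d > thr & F_right < cfg$F_rot)
  close_now <- abs(d) < 0.85 * thr | F_left > cfg$F_max | F_right > cfg$F_max
  sig <- ifelse(open_now & !close_now, 1L, ifelse(close_now, 0L, NA_integer_))
  # carry the last decided state forward over the hysteresis band
  if (is.na(sig[1])) sig[1] <- 0L
  idx <- cummax(seq_along(sig) * !is.na(sig))
  sig[idx] == 1L
}

# Controller-side anti-tremor smoothing: causal 5-sample moving average of
# the 80 Hz load-cell stream, applied before gating and motor commands.
ctrl_filter <- function(x) {
  n <- length(x)
  if (n < 5) return(x)
  cs <- cumsum(x)
  c(cs[1:4] / (1:4), (cs[5:n] - c(0, cs[seq_len(n - 5)])) / 5)
}

#' Initial game state
#'
#' @param cfg A [controller_config()].
#' @param crystal_x Optional first object abscissa (game units in `[-1, 1]`);
#'   drawn uniformly when omitted (uses the current RNG stream).
#' @return An object of class `game_state`: wagon and object positions, fall
#'   speed, score, losses, the last-five outcome window and the assist level.
#' @export
game_state <- function(cfg, crystal_x = NULL) {
  stopifnot(inherits(cfg, "controller_config"))
  if (is.null(crystal_x)) crystal_x <- stats::runif(1, -0.9, 0.9)
  structure(list(
    wagon_x = 0, crystal_x = crystal_x, crystal_y = 1,
    fall_speed = cfg$fall_speed, score = 0L, losses = 0L,
    outcome_window = logical(0), assist_level = cfg$assist_level,
    n_resolved = 0L
  ), class = "game_state")
}

#' Assist-as-needed level update
#'
#' Called after each object resolves. The balance of the last five outcomes
#' (caught minus lost) raises the assistance one step when it falls to the
#' trigger value or below, and lowers a positive level one step when it
#' reaches the release value or above; the result is clamped to
#' `[-a_max, a_max]`. Negative (resistive) levels are a prescription — the
#' adaptation never lowers the level below 0 on good performance, but it can
#' raise a resistive level toward assistance if the player keeps losing.
#'
#' @param state A [game_state()].
#' @param cfg A [controller_config()].
#' @return The new assist level (integer).
#' @export
update_assistance <- function(state, cfg) {
  w <- state$outcome_window
  balance <- sum(w) - sum(!w)
  lvl <- state$assist_level
  if (balance <= cfg$assist_trigger) lvl <- lvl + 1L
  else if (balance >= cfg$assist_release && lvl > 0L) lvl <- lvl - 1L
  max(-cfg$a_max, min(cfg$a_max, lvl))
}

# Shared outcome bookkeeping: score/losses, outcome window, assist
# adaptation, accelerated-mode speed law, dynamic-mode schedule, respawn.
resolve_object <- function(state, caught, cfg, crystal_x = NULL) {
  state$n_resolved <- state$n_resolved + 1L
  if (caught) state$score <- state$score + 1L else state$losses <- state$losses + 1L
  state$outcome_window <- utils::tail(c(state$outcome_window, caught), 5L)
  if (cfg$mode == "accelerated" && caught && state$score %% 10L == 0L)
    state$fall_speed <- state$fall_speed * 1.10
  if (cfg$mode == "dynamic") {
    state$assist_level <- max(-cfg$a_max, -(state$score %/% 20L))
  } else if (cfg$assist_enabled) {
    state$assist_level <- update_assistance(state, cfg)
  }
  if (is.null(crystal_x)) crystal_x <- stats::runif(1, -0.9, 0.9)
  state$crystal_x <- crystal_x
  state$crystal_y <- 1
  state
}

#' Advance the game by one tick
#'
#' Moves the wagon according to the classified intent (clockwise rotation
#' moves it right), applies assist drift or takeover, lets the active object
#' fall, and resolves it when it reaches wagon height: it is collected when
#' the wagon is within the capture tolerance (boundary inclusive), otherwise
#' counted as lost; a new object then spawns at a uniformly drawn abscissa
#' (seed the RNG for reproducibility).
#'
#' @param state A [game_state()].
#' @param intent Intent string from [classify_intent()].
#' @param dt Time step (s, > 0).
#' @param cfg A [controller_config()].
#' @return The updated `game_state`.
#' @export
step_game <- function(state, intent, dt, cfg) {
  stopifnot(inherits(state, "game_state"), dt > 0)
  lvl <- state$assist_level
  if (lvl >= cfg$a_max && cfg$a_max > 0L) {
    # full takeover: the controller drives toward the target by itself
    step <- cfg$takeover_speed * dt
    delta <- state$crystal_x - state$wagon_x
    state$wagon_x <- state$wagon_x + sign(delta) * min(step, abs(delta))
  } else {
    if (intent == "CW") state$wagon_x <- state$wagon_x + cfg$wagon_speed * dt
    if (intent == "CCW") state$wagon_x <- state$wagon_x - cfg$wagon_speed * dt
    if (lvl >= 2L) {
      step <- cfg$drift_speed * dt
      delta <- state$crystal_x - state$wagon_x
      state$wagon_x <- state$wagon_x + sign(delta) * min(step, abs(delta))
    }
  }
  state$wagon_x <- max(-1, min(1, state$wagon_x))
  state$crystal_y <- state$crystal_y - state$fall_speed * dt
  if (state$crystal_y <= 0) {
    caught <- abs(state$wagon_x - state$crystal_x) <= cfg$tolerance
    state <- resolve_object(state, caught, cfg)
  }
  state
}

#' Run the game from a simple intent policy
#'
#' Convenience loop over [step_game()] for tests and demonstrations of the
#' game mechanics alone (no subject model, no sensors). The `"perfect"`
#' policy always pushes toward the falling object; `"idle"` never moves.
#'
#' @param n_objects Number of objects to resolve.
#' @param cfg A [controller_config()].
#' @param policy `"perfect"`, `"idle"`, or a function `(state) -> intent`.
#' @param seed RNG seed for the spawn stream.
#' @param dt Tick length (s).
#' @return A list with the final `state` and a data.frame `outcomes` holding,
#'   per resolved object, the score, losses and the fall speed in force after
#'   resolution.
#' @export
run_game <- function(n_objects, cfg = controller_config(),
                     policy = c("perfect", "idle"), seed = 1, dt = 1 / 80) {
  if (is.character(policy)) {
    policy <- switch(match.arg(policy),
      perfect = function(state) {
        d <- state$crystal_x - state$wagon_x
        if (abs(d) <= 0.2 * cfg$tolerance) "HOLD" else if (d > 0) "CW" else "CCW"
      },
      idle = function(state) "HOLD")
  }
  set.seed(seed)
  state <- game_state(cfg)
  rows <- vector("list", n_objects)
  k <- 0L
  while (state$n_resolved < n_objects) {
    before <- state$n_resolved
    state <- step_game(state, policy(state), dt, cfg)
    if (state$n_resolved > before) {
      k <- k + 1L
      rows[[k]] <- data.frame(resolved = state$n_resolved, score = state$score,
                              losses = state$losses, fall_speed = state$fall_speed,
                              assist_level = state$assist_level)
    }
  }
  list(state = state, outcomes = do.call(rbind, rows))
}
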
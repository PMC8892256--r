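# Shared fixtures. Simulated sessions are cached across test files so the
# suite pays for each study condition once.

.session_cache <- new.env(parent = emptyenv())

cached_session <- function(key, fun) {
  if (is.null(.session_cache[[key]])) .session_cache[[key]] <- fun()
  .session_cache[[key]]
}

cfg_noassist <- function(...) controller_config(assist_enabled = FALSE, ...)

healthy_session <- function(n = 100, seed = 11) {
  cached_session(sprintf("healthy_%d_%d", n, seed), function()
    simulate_session(healthy_profile(), cfg_noassist(), n_reaches = n, seed = seed))
}

stroke_session <- function(n = 100, seed = 11) {
  cached_session(sprintf("stroke_%d_%d", n, seed), function()
    simulate_session(post_stroke_profile(), cfg_noassist(), n_reaches = n, seed = seed))
}

# Hand-built session log: a single repetition with prescribed angle/force
# series, for exercising the evaluator on known signals.
synthetic_log <- function(theta, theta_d, F_left, F_right, fs = 80) {
  n <- length(theta)
  structure(list(
    metadata = list(subject_id = "SYN", date = "2024-01-01", game = "minecart",
                    mode = "constant", seed = 0L, fs = fs, h = 0.7,
                    cfg = unclass(controller_config()),
                    sensors = unclass(sensor_model()),
                    geom = list(Wb = 1, Wg = 0.6), truth = NULL),
    samples = data.frame(
      t_s = seq_len(n) / fs, theta_rad = theta,
      theta_d_rad = rep_len(theta_d, n), F_left_kgf = rep_len(F_left, n),
      F_right_kgf = rep_len(F_right, n), assist_level = 0L),
    events = data.frame(t_s = numeric(0), kind = character(0),
                        payload = character(0))
  ), class = "session_log")
}
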
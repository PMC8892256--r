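test_that("peak finder reports local maxima with hand-computed prominences", {
  pk <- find_peaks(c(0, 2, 1, 3, 0))
  expect_equal(pk$index, c(2L, 4L))
  expect_equal(pk$prominence, c(1, 3))  # saddle at 1 guards the lower peak
  expect_equal(nrow(find_peaks(c(0, 2, 1, 3, 0), min_prominence = 2)), 1L)
  # plateaus count once, monotone series not at all
  expect_equal(find_peaks(c(0, 1, 1, 1, 0))$index, 2L)
  expect_equal(nrow(find_peaks(1:10)), 0L)
  expect_equal(nrow(find_peaks(c(1, 1, 1))), 0L)
})

test_that("smoothed derivatives are exact on polynomials and tight on sinusoids", {
  fs <- 80
  t <- seq(0, 3, by = 1 / fs)
  d0 <- kinematic_derivatives(rep(0.3, length(t)), fs)
  expect_lt(max(abs(as.matrix(d0))), 1e-10)
  dl <- kinematic_derivatives(0.25 * t, fs)
  expect_lt(max(abs(dl$omega - 0.25)), 1e-8)
  expect_lt(max(abs(dl$alpha)), 1e-6)
  ds <- kinematic_derivatives(sin(t), fs)
  interior <- 30:(length(t) - 30)
  expect_lt(max(abs(ds$omega[interior] - cos(t[interior]))), 1e-4)
  expect_lt(abs(max(abs(ds$omega)) - 1), 2e-3)
  expect_error(kinematic_derivatives(1:5, fs), "insufficient data")
})

test_that("interquartile validation discards gross outliers and guards tiny samples", {
  v <- validate_outliers(c(2.4, 2.5, 2.6, 2.5, 25.0))
  expect_equal(v$discarded, 25.0)
  expect_equal(sort(v$kept), c(2.4, 2.5, 2.5, 2.6))
  expect_length(validate_outliers(rep(3.3, 6))$discarded, 0)
  expect_length(validate_outliers(c(1, 100))$discarded, 0)   # n < 4: keep all
  expect_length(validate_outliers(c(1, 2, 100))$discarded, 0)
})

test_that("segmentation finds the four landmarks on a constructed repetition", {
  fs <- 80
  n <- 8 * fs
  t <- seq_len(n) / fs
  v <- 0.2
  theta <- pmin(pmax(t - 2, 0) * v, 0.4)          # rest, ramp at 0.2 rad/s, hold
  Fl <- ifelse(t > 1.9 & t < 4.1, 2.8, 1.5)       # productive CCW press
  Fr <- ifelse(t > 1.9 & t < 4.1, 0.6, 1.5)
  log <- synthetic_log(theta, 0.4, Fl, Fr)
  seg <- segment_movements(log)
  sg <- seg$segments
  expect_equal(nrow(sg), 1L)
  expect_true(sg$has_onset && sg$completed)
  expect_true(sg$T_0 <= sg$T_i && sg$T_i <= sg$T_d && sg$T_d <= sg$T_f)
  expect_equal(sg$T_i, 2.0, tolerance = 0.12)     # onset within the smoothing window
  expect_equal(sg$T_d, 2 + (0.4 - seg$position_tolerance) / v, tolerance = 0.1)
  expect_equal(sg$T_f, 4.0, tolerance = 0.25)
  tp <- time_parameters(seg)
  expect_equal(tp$T_r, sg$T_i - sg$T_0)
  expect_equal(tp$T_m, sg$T_f - sg$T_i)
  # constant-rate rotation: mean and peak speed both equal the rate
  sp <- speed_parameters(sg[1, ], log, seg$derivatives$omega)
  expect_equal(unname(sp["omega_p"]), v, tolerance = 0.1)
  expect_gte(sp["omega_p"], sp["omega_m"])
  expect_equal(unname(sp["omega_m"]), v, tolerance = 0.1)
})

test_that("a repetition that never reaches the target is marked, not raised", {
  fs <- 80
  n <- 6 * fs
  t <- seq_len(n) / fs
  theta <- pmin(pmax(t - 1, 0) * 0.1, 0.15)       # stalls far from 0.5
  Fl <- ifelse(t > 0.9 & t < 3, 2.8, 1.5)
  log <- synthetic_log(theta, 0.5, Fl, 0.8)
  sg <- segment_movements(log)$segments
  expect_true(sg$has_onset)
  expect_false(sg$completed)
  expect_true(is.na(sg$T_d))
  tp <- time_parameters(segment_movements(log))
  expect_false(is.na(tp$T_r))
  expect_true(is.na(tp$T_m))                      # empty-marker, no error
})

test_that("mean speed of a triangular profile is half its peak", {
  fs <- 80
  up <- seq(0, 0.4, length.out = 2 * fs)
  v <- c(up, rev(up))                             # triangular speed 0 -> 0.4 -> 0
  theta <- cumsum(v) / fs
  d <- kinematic_derivatives(theta, fs)
  expect_equal(mean(abs(d$omega)), 0.2, tolerance = 0.01)
})

test_that("RMS error reproduces closed forms", {
  fs <- 80
  n <- 4 * fs
  sg_row <- data.frame(i0 = 1L, i1 = n, T_i = 1 / fs, T_f = n / fs)
  # exact tracking
  log0 <- synthetic_log(rep(0.3, n), 0.3, 1.5, 1.5)
  expect_equal(error_parameter(sg_row, log0), 0)
  # constant offset e -> |e|
  loge <- synthetic_log(rep(0.3 + 0.07, n), 0.3, 1.5, 1.5)
  expect_equal(error_parameter(sg_row, loge), 0.07)
  # sinusoidal error of amplitude e over whole periods -> e / sqrt(2)
  t <- seq_len(n) / fs
  logs <- synthetic_log(0.3 + 0.05 * sin(2 * pi * t), 0.3, 1.5, 1.5)
  expect_equal(error_parameter(sg_row, logs), 0.05 / sqrt(2), tolerance = 1e-3)
})

test_that("velocity-peak count matches constructed sub-movements and is scale-free", {
  fs <- 80
  t <- seq_len(10 * fs) / fs
  # three well-separated speed bells
  v <- 0.3 * (exp(-((t - 2) / 0.3)^2) + exp(-((t - 4.5) / 0.3)^2) +
                exp(-((t - 7) / 0.3)^2))
  theta <- cumsum(v) / fs
  mk <- function(th) {
    log <- synthetic_log(th, max(th), 2.8, 0.6)
    sg <- data.frame(i0 = 1L, i1 = length(th), T_i = 1, T_f = 9)
    smoothness_parameters(sg, log, kinematic_derivatives(th, fs))
  }
  a <- mk(theta)
  expect_equal(unname(a["N_p"]), 3)
  b <- mk(5 * theta)   # amplitude scaling leaves the count unchanged
  expect_equal(unname(b["N_p"]), 3)
  expect_gt(a["J_n"], 0)
})

test_that("torque parameters follow the productive/counterproductive conventions", {
  fs <- 80
  n <- 8 * fs
  t <- seq_len(n) / fs
  # symmetric constant hold forces: zero deviation, all torque parameters zero
  hold_log <- synthetic_log(rep(0, n), 0, 1.5, 1.5)
  hold_sg <- structure(list(segments = data.frame(
    reach = 1L, i0 = 1L, i1 = n, T_0 = 0, T_i = 1, T_d = 3, T_f = 5,
    direction = "CW", has_onset = TRUE, completed = TRUE)),
    class = "movement_segments")
  tq0 <- torque_parameters(hold_log, hold_sg)
  expect_equal(tq0$tau_p_left + tq0$tau_p_right + tq0$tau_cp_left +
                 tq0$tau_cp_right, 0)
  expect_equal(tq0$tau_total, 0)
  expect_equal(tq0$delta_tau, 0)
  # a CW repetition: right press, left lift; both deviations drive clockwise
  theta_cw <- -pmin(pmax(t - 2, 0) * 0.2, 0.4)
  Fl <- ifelse(t > 1.9 & t < 4.1, 0.6, 1.5)       # lift
  Fr <- ifelse(t > 1.9 & t < 4.1, 2.8, 1.5)       # press
  log_cw <- synthetic_log(theta_cw, -0.4, Fl, Fr)
  seg_cw <- segment_movements(log_cw)
  tq <- torque_parameters(log_cw, seg_cw)
  expect_gt(tq$tau_p_right, 0)                    # press drives clockwise
  expect_gt(tq$tau_p_left, 0)                     # lifting also drives clockwise
  expect_gt(tq$tau_total, 0)
  expect_equal(tq$tau_cp_left + tq$tau_cp_right, 0, tolerance = 1e-9)
  # an extra left press during a CW movement is counterproductive
  Fl2 <- ifelse(t > 1.9 & t < 4.1, 2.4, 1.5)
  log_bad <- synthetic_log(theta_cw, -0.4, Fl2, Fr)
  tq2 <- torque_parameters(log_bad, segment_movements(log_bad))
  expect_gt(tq2$tau_cp_left, 0)
})

test_that("session reports are deterministic and carry score bookkeeping", {
  log <- healthy_session(30, seed = 11)
  r1 <- session_report(log)
  r2 <- session_report(log)
  expect_equal(as.data.frame(r1), as.data.frame(r2))
  ev <- log$events
  expect_equal(r1$score, sum(ev$kind == "caught"))
  expect_equal(r1$losses, sum(ev$kind == "lost"))
  expect_equal(r1$n_segments, 30)
  expect_gte(r1$omega_p, r1$omega_m)
  expect_gte(r1$N_p, 1)
  expect_gte(r1$J_n, 0)
})

test_that("landmark ordering holds on every completed repetition of a session", {
  for (log in list(healthy_session(30, seed = 11), stroke_session(100, seed = 11))) {
    sg <- segment_movements(log)$segments
    cc <- sg[sg$completed, ]
    expect_true(all(cc$T_0 <= cc$T_i & cc$T_i <= cc$T_d & cc$T_d <= cc$T_f))
    expect_true(all(cc$T_i - cc$T_0 >= 0))
  }
})

test_that("recovered onsets track the simulator's injected ground truth", {
  log <- stroke_session(100, seed = 11)
  sg <- segment_movements(log)$segments
  tr <- log$metadata$truth
  ok <- sg$has_onset & !is.na(tr$onset)
  err <- sg$T_i[ok] - tr$onset[ok]
  expect_lt(stats::median(abs(err)), 0.35)        # within one smoothing window
})

test_that("outlier validation keeps at least 75% of clean repetitions", {
  r <- session_report(healthy_session(100, seed = 11))
  expect_gte(r$n_segments_used / r$n_segments, 0.75)
})

test_that("reports survive a JSON round trip", {
  r <- session_report(healthy_session(30, seed = 11))
  path <- file.path(tempdir(), "rep_rt")
  write_report(r, path)
  back <- read_report(path)
  expect_equal(back$T_r_ms, r$T_r_ms)
  expect_equal(back$delta_F, r$delta_F)
  expect_equal(back$score, r$score)
})
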
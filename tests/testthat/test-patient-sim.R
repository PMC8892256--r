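test_that("sessions are deterministic given the seed", {
  a <- simulate_session(healthy_profile(), cfg_noassist(), n_reaches = 12, seed = 42)
  b <- simulate_session(healthy_profile(), cfg_noassist(), n_reaches = 12, seed = 42)
  expect_identical(a$samples, b$samples)
  expect_identical(a$events, b$events)
  expect_identical(a$metadata$truth, b$metadata$truth)
  c <- simulate_session(healthy_profile(), cfg_noassist(), n_reaches = 12, seed = 43)
  expect_false(identical(a$samples$F_left_kgf, c$samples$F_left_kgf))
})

test_that("acquisition quantizes, saturates and clips", {
  expect_equal(acquire(1.2371, 0, 0)$F_left, 1.225)
  expect_equal(acquire(25, 0, 0)$F_left, 20)        # load-cell capacity
  expect_equal(acquire(-0.4, 0, 0)$F_left, 0)
  s <- sensor_model()
  expect_equal(s$theta_resolution, 2 * pi / 2000)   # 500 ppr, quadrature
  th <- acquire(0, 0, 0.01234)$theta
  expect_equal(th %% s$theta_resolution, 0, tolerance = 1e-12)
})

test_that("recorded forces are exact multiples of the resolution within capacity", {
  log <- healthy_session(30, seed = 11)
  f <- c(log$samples$F_left_kgf, log$samples$F_right_kgf)
  expect_true(all(abs(f / 0.025 - round(f / 0.025)) < 1e-9))
  expect_true(all(f >= 0 & f <= 20))
  # the measuring grid is visible in the data: smallest gap between distinct
  # recorded values equals one quantum
  expect_equal(min(diff(sort(unique(f)))), 0.025, tolerance = 1e-12)
})

test_that("forces sit at baseline before the sampled reaction delay", {
  p <- subject_profile(tremor_sd = 0)
  set.seed(9)
  tt <- seq(1 / 80, 8, by = 1 / 80)
  f <- generate_reach_forces(p, "CW", tt, delta_theta = 0.4)
  pre <- f$t < 0.15  # delays are floored at 0.15 s
  expect_true(all(abs(f$F_left[pre] - p$baseline_force) < 1e-9))
  expect_true(all(abs(f$F_right[pre] - p$baseline_force) < 1e-9))
})

test_that("healthy long-run per-arm force means are symmetric", {
  p <- healthy_profile()
  set.seed(31)
  tt <- seq(1 / 80, 8, by = 1 / 80)
  means <- replicate(120, {
    dir <- sample(c("CW", "CCW"), 1)
    f <- generate_reach_forces(p, dir, tt, delta_theta = stats::runif(1, 0.15, 0.6))
    c(mean(f$F_left), mean(f$F_right))
  })
  d <- means[1, ] - means[2, ]
  expect_lt(abs(mean(d)), 3 * stats::sd(d) / sqrt(length(d)))
})

test_that("hemiparesis shows up as contralateral force peaks and lower paretic mean", {
  log <- cached_session("stroke_sev05", function()
    simulate_session(post_stroke_profile(severity = 0.5), cfg_noassist(),
                     n_reaches = 50, seed = 17))
  fp <- force_parameters(log)
  # left hemiparesis: more, larger peaks on the (non-paretic) right
  expect_gt(nrow(fp$peaks_right), nrow(fp$peaks_left))
  expect_lt(fp$delta_F, 0)
  expect_lt(mean(log$samples$F_left_kgf), mean(log$samples$F_right_kgf))
})

test_that("a clean single-sub-movement reach yields one velocity peak", {
  p <- subject_profile(submovements_mean = 1, submovements_dispersion = 0,
                       tremor_sd = 0)
  log <- simulate_session(p, cfg_noassist(), n_reaches = 12, seed = 4)
  rep <- session_report(log)
  expect_equal(rep$N_p, 1)
  sm <- rep$per_segment$smoothness
  expect_true(all(sm[, "N_p"] == 1))
})

test_that("severe paresis scores lower and loses more than health, same seed", {
  h <- cached_session("h_vs_p_h", function()
    simulate_session(healthy_profile(), cfg_noassist(), n_reaches = 50, seed = 23))
  p <- cached_session("h_vs_p_p", function()
    simulate_session(post_stroke_profile(severity = 0.55), cfg_noassist(),
                     n_reaches = 50, seed = 23))
  sh <- sum(h$metadata$truth$caught); sp <- sum(p$metadata$truth$caught)
  expect_gt(sh, sp)
  expect_lt(50 - sh, 50 - sp)
})

test_that("an unachievable rotation threshold is rejected or never fires", {
  # both directions impossible: diagnostic error
  expect_error(
    simulate_session(healthy_profile(), cfg_noassist(delta_F = 50),
                     n_reaches = 2, seed = 1),
    "infeasible")
  # threshold above the paretic arm's achievable differential only: that
  # direction never produces a rotation intent
  prof <- post_stroke_profile(severity = 0.4)
  cfg <- cfg_noassist(delta_F = 5.5)
  log <- simulate_session(prof, cfg, n_reaches = 30, seed = 2)
  intents <- classify_intent(log$samples$F_left_kgf, log$samples$F_right_kgf, cfg)
  expect_false("CCW" %in% intents)  # CCW would need the weak left arm to drive
})

test_that("session logs round-trip losslessly through CSV + JSON", {
  log <- simulate_session(post_stroke_profile(), cfg_noassist(),
                          n_reaches = 6, seed = 13)
  path <- file.path(tempdir(), "sess_rt")
  write_session_log(log, path)
  back <- read_session_log(path)
  expect_equal(back$samples, log$samples)
  expect_equal(back$events$kind, log$events$kind)
  expect_equal(back$events$t_s, log$events$t_s)
  expect_equal(back$metadata$seed, log$metadata$seed)
  expect_equal(as.data.frame(back$metadata$truth), log$metadata$truth)
  expect_equal(back$metadata$profile$paresis_severity,
               log$metadata$profile$paresis_severity)
  # the reader restores a log the evaluator accepts
  expect_s3_class(segment_movements(back), "movement_segments")
})

test_that("session log invariants hold: timestamps, spawn alignment, resolution", {
  log <- healthy_session(30, seed = 11)
  expect_true(all(diff(log$samples$t_s) > 0))
  sp <- log$events[log$events$kind == "spawn", ]
  res <- log$events[log$events$kind %in% c("caught", "lost"), ]
  expect_equal(nrow(sp), nrow(res))       # every spawn resolves
  # theta_d changes exactly at spawn events
  chg <- which(diff(log$samples$theta_d_rad) != 0)
  expect_true(all(log$samples$t_s[chg] %in% sp$t_s))
})
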
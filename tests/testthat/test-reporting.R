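mk_report <- function(id, date, ...) report_from_values(id, date, ...)

test_that("percent excess reproduces the integer-percent presentation", {
  expect_equal(percent_excess(728, 1029), 41)
  expect_equal(percent_excess(2.5, 4.6), 84)
  expect_equal(percent_excess(5, 5), 0)
  # invariant to a common unit change
  expect_equal(percent_excess(0.728, 1.029), percent_excess(728, 1029))
})

test_that("group comparison computes baselines, excesses and paired tests", {
  healthy <- lapply(1:6, function(i)
    mk_report(paste0("H", i), "2024-01-08", T_r_ms = 728 + (i - 3.5) * 20,
              T_m_s = 2.5 + (i - 3.5) * 0.1))
  patients <- unlist(lapply(1:8, function(i) list(
    mk_report(paste0("P", i), "2024-02-01",
              T_r_ms = 1029 + (i - 4.5) * 30, T_m_s = 4.6 + (i - 4.5) * 0.2),
    mk_report(paste0("P", i), "2024-03-08",
              T_r_ms = 1247 + (i - 4.5) * 30, T_m_s = 4.1 + (i - 4.5) * 0.2))),
    recursive = FALSE)
  cmp <- group_compare(healthy, patients, parameters = c("T_r_ms", "T_m_s"))
  t <- cmp$table
  expect_equal(t$pct_excess[t$parameter == "T_r_ms"], 41)
  expect_equal(t$pct_excess[t$parameter == "T_m_s"], 84)
  # a uniform admission-to-discharge shift is detected at the 0.05 level
  expect_true(all(t$p_value < 0.05))
  expect_true(all(t$significant))
  # identical groups show zero excess on every parameter
  same <- group_compare(healthy, healthy, parameters = c("T_r_ms", "T_m_s"))
  expect_true(all(same$table$pct_excess == 0))
})

test_that("single-subject comparisons are emitted without p-values", {
  a <- mk_report("A", "2024-01-01", T_r_ms = 728)
  b <- mk_report("B", "2024-01-01", T_r_ms = 1029)
  cmp <- group_compare(list(a), list(b), parameters = "T_r_ms")
  expect_equal(cmp$table$pct_excess, 41)
  expect_true(is.na(cmp$table$p_value))
  expect_false(cmp$table$significant)
  expect_error(group_compare(list(), list(b)), "non-empty")
})

test_that("weekly aggregation partitions sessions into ISO weeks", {
  reports <- list(
    mk_report("S", "2024-01-01", score = 10),  # ISO week 2024-W01
    mk_report("S", "2024-01-03", score = 20),
    mk_report("S", "2024-01-05", score = 30),
    mk_report("S", "2024-01-10", score = 40))  # 2024-W02
  ph <- progress_history(reports, parameters = "score")
  wk <- ph$weekly
  expect_equal(nrow(wk), 2L)
  expect_equal(wk$mean[wk$week == "2024-W01"], 20)
  expect_equal(wk$n_sessions, c(3L, 1L))
  expect_equal(sum(wk$n_sessions), length(reports))  # partition, nothing lost
  # a constant parameter gives a flat series
  flat <- progress_history(lapply(1:3, function(i)
    mk_report("S", sprintf("2024-02-0%d", i), N_p = 4)), parameters = "N_p")
  expect_equal(unique(flat$sessions$value), 4)
  expect_error(progress_history(rev(reports)), "sorted")
})

test_that("a simulated improving subject shows an improving weekly series", {
  sev <- c(0.7, 0.5, 0.3, 0.1)
  dates <- c("2024-03-04", "2024-03-11", "2024-03-18", "2024-03-25")
  reports <- lapply(seq_along(sev), function(i) {
    log <- simulate_session(post_stroke_profile(severity = sev[i]),
                            cfg_noassist(), n_reaches = 40, seed = 90 + i,
                            subject_id = "P1", date = dates[i])
    session_report(log)
  })
  ph <- progress_history(reports, parameters = c("T_m_s", "score"))
  tm <- ph$weekly[ph$weekly$parameter == "T_m_s", ]
  sc <- ph$weekly[ph$weekly$parameter == "score", ]
  # recovery trend: faster movements and better scores week by week
  expect_lt(tm$mean[4], tm$mean[1])
  expect_gt(sc$mean[4], sc$mean[1])
  expect_gt(stats::cor(seq_len(4), sc$mean, method = "spearman"), 0)
})

test_that("command-line verbs tie simulation, evaluation and reporting together", {
  wd <- tempfile("cli")
  dir.create(wd)
  sess <- file.path(wd, "sess1")
  expect_equal(bicar_main(c("simulate", "--profile", "post-stroke",
                            "--severity", "0.4", "--seed", "7",
                            "--n-reaches", "8", "--out", sess)), 0L)
  expect_true(file.exists(paste0(sess, ".csv")))
  expect_true(file.exists(paste0(sess, ".json")))
  rep1 <- file.path(wd, "rep1")
  expect_equal(bicar_main(c("eval", "--session", sess, "--out", rep1)), 0L)
  expect_true(file.exists(paste0(rep1, ".json")))

  # a second session for the progress report
  sess2 <- file.path(wd, "sess2")
  rep2 <- file.path(wd, "rep2")
  bicar_main(c("simulate", "--profile", "healthy", "--seed", "8",
               "--n-reaches", "8", "--out", sess2, "--date", "2024-02-01"))
  bicar_main(c("eval", "--session", sess2, "--out", rep2))
  out <- file.path(wd, "prog")
  expect_equal(bicar_main(c("report", "--reports",
                            paste(paste0(rep1, ".json"), paste0(rep2, ".json"),
                                  sep = ","),
                            "--group-a", paste0(rep2, ".json"),
                            "--group-b", paste0(rep1, ".json"),
                            "--out", out)), 0L)
  expect_true(file.exists(paste0(out, "_progress.json")))
  expect_true(file.exists(paste0(out, "_groups.json")))

  traj <- file.path(wd, "traj.csv")
  expect_equal(bicar_main(c("kinematics", "--diameter-cm", "20",
                            "--n-points", "5", "--out", traj)), 0L)
  expect_named(utils::read.csv(traj), c("index", "x_m", "y_m", "L1_m", "L2_m"))

  # exit codes: invalid input 2, infeasible configuration 3
  expect_equal(suppressMessages(bicar_main(c("nonsense"))), 2L)
  cfgf <- file.path(wd, "bad.cfg")
  writeLines("delta_F = 50", cfgf)
  expect_equal(suppressMessages(
    bicar_main(c("simulate", "--seed", "1", "--config", cfgf,
                 "--out", file.path(wd, "x")))), 3L)
})
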
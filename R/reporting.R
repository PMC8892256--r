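report_parameters <- c(
  "T_r_ms", "T_m_s", "omega_m", "omega_p", "N_p", "J_n", "theta_err_rms_deg",
  "F_p_left", "F_p_right", "delta_F", "tau_p_left", "tau_p_right",
  "tau_cp_left", "tau_cp_right", "tau_total", "delta_tau", "score", "losses")

#' Stack session reports into a table
#'
#' @param reports A list of `performance_report` objects.
#' @return A data.frame, one row per session.
#' @export
sessions_table <- function(reports) {
  if (inherits(reports, "performance_report")) reports <- list(reports)
  do.call(rbind, lapply(reports, as.data.frame))
}

#' Longitudinal progress series
#'
#' Per-parameter time series over a subject's sessions plus weekly aggregates
#' (mean per ISO calendar week), the shape used for week-by-week follow-up
#' plots of score, losses, times, forces, speeds and smoothness.
#'
#' @param reports List of `performance_report`s sorted by date (error if not).
#' @param parameters Which parameters to include.
#' @return An object of class `progress_series`: `sessions` (long data.frame
#'   `parameter`, `date`, `value`), `weekly` (`parameter`, `week`, `mean`,
#'   `n_sessions`) and `n_missing` (undefined parameter values skipped).
#' @export
progress_history <- function(reports, parameters = report_parameters) {
  tab <- sessions_table(reports)
  dates <- as.Date(tab$date)
  if (anyNA(dates)) stop("invalid input: session dates must parse as dates")
  if (is.unsorted(dates)) stop("reports must be sorted by date (caller must sort)")
  parameters <- intersect(parameters, names(tab))
  long <- do.call(rbind, lapply(parameters, function(p)
    data.frame(parameter = p, date = dates, value = as.numeric(tab[[p]]))))
  n_missing <- sum(is.na(long$value))
  ok <- long[!is.na(long$value), ]
  ok$week <- format(ok$date, "%G-W%V")
  weekly <- stats::aggregate(value ~ parameter + week, data = ok, FUN = mean)
  counts <- stats::aggregate(value ~ parameter + week, data = ok, FUN = length)
  names(weekly)[3] <- "mean"
  weekly$n_sessions <- counts$value
  structure(list(sessions = long, weekly = weekly[order(weekly$parameter, weekly$week), ],
                 n_missing = n_missing),
            class = "progress_series")
}

#' @export
print.progress_series <- function(x, ...) {
  cat(sprintf("Progress series: %d parameters over %d sessions, %d weeks (%d missing values)\n",
              length(unique(x$sessions$parameter)),
              length(unique(x$sessions$date)),
              length(unique(x$weekly$week)), x$n_missing))
  invisible(x)
}

#' Percent excess of one mean over another
#'
#' `round(100 * (b - a) / a)`, the integer-percent presentation used for
#' between-group comparisons (e.g. how much longer one group's reaction time
#' is relative to a reference group's).
#'
#' @param a Reference mean.
#' @param b Comparison mean.
#' @return Integer percent.
#' @examples
#' percent_excess(728, 1029)  # 41
#' percent_excess(2.5, 4.6)   # 84
#' @export
percent_excess <- function(a, b) round(100 * (b - a) / a)

#' Compare two groups of subjects
#'
#' For every parameter: group A's first-session mean (the reference group's
#' baseline), group B's admission (first session per subject) and discharge
#' (last session per subject) means with dispersions, the integer percent
#' excess of B's admission mean over A's baseline, and a paired two-sided
#' Wilcoxon signed-rank test of B's admission vs discharge values at the 0.05
#' level. With a single subject in B (or a single session per subject) the
#' comparison is emitted without p-values.
#'
#' @param group_a,group_b Lists of `performance_report`s (several sessions per
#'   subject allowed; subjects identified by `subject_id`), or data.frames
#'   from [sessions_table()].
#' @param parameters Which parameters to compare.
#' @param alpha Significance level (default 0.05).
#' @return An object of class `group_comparison` wrapping a data.frame with
#'   one row per parameter.
#' @export
group_compare <- function(group_a, group_b, parameters = report_parameters,
                          alpha = 0.05) {
  ta <- if (is.data.frame(group_a)) group_a else sessions_table(group_a)
  tb <- if (is.data.frame(group_b)) group_b else sessions_table(group_b)
  if (is.null(ta) || is.null(tb) || !nrow(ta) || !nrow(tb))
    stop("both groups must be non-empty")
  parameters <- intersect(parameters, intersect(names(ta), names(tb)))

  pick <- function(tab, which = c("first", "last")) {
    which <- match.arg(which)
    tab <- tab[order(tab$subject_id, as.Date(tab$date)), ]
    idx <- !duplicated(tab$subject_id, fromLast = (which == "last"))
    tab[idx, ]
  }
  a_first <- pick(ta, "first")
  b_adm <- pick(tb, "first")
  b_dis <- pick(tb, "last")
  paired_possible <- nrow(b_adm) >= 2 && !identical(b_adm$date, b_dis$date)

  rows <- lapply(parameters, function(p) {
    am <- mean(a_first[[p]], na.rm = TRUE)
    bm <- mean(b_adm[[p]], na.rm = TRUE)
    dm <- mean(b_dis[[p]], na.rm = TRUE)
    pv <- NA_real_
    if (paired_possible) {
      x <- b_adm[[p]]; y <- b_dis[[p]]
      ok <- is.finite(x) & is.finite(y)
      if (sum(ok) >= 2 && any(x[ok] != y[ok]))
        pv <- suppressWarnings(
          stats::wilcox.test(x[ok], y[ok], paired = TRUE)$p.value)
    }
    data.frame(parameter = p,
               mean_A = am, sd_A = stats::sd(a_first[[p]], na.rm = TRUE),
               mean_B_admission = bm,
               sd_B_admission = stats::sd(b_adm[[p]], na.rm = TRUE),
               mean_B_discharge = dm,
               sd_B_discharge = stats::sd(b_dis[[p]], na.rm = TRUE),
               pct_excess = percent_excess(am, bm),
               p_value = pv,
               significant = !is.na(pv) && pv < alpha)
  })
  structure(list(table = do.call(rbind, rows), alpha = alpha,
                 n_A = nrow(a_first), n_B = nrow(b_adm)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Group comparison: %d reference vs %d subjects (alpha = %g)\n",
              x$n_A, x$n_B, x$alpha))
  t <- x$table
  for (i in seq_len(nrow(t)))
    cat(sprintf("  %-18s A %8.2f | B adm %8.2f (%+d%%) dis %8.2f | p %s%s\n",
                t$parameter[i], t$mean_A[i], t$mean_B_admission[i],
                t$pct_excess[i], t$mean_B_discharge[i],
                ifelse(is.na(t$p_value[i]), "   --", sprintf("%.3f", t$p_value[i])),
                ifelse(isTRUE(t$significant[i]), " *", "")))
  invisible(x)
}

#' Minimal report objects from summary values
#'
#' Builds skeleton `performance_report`s carrying given parameter values —
#' convenient for feeding published group summaries through
#' [group_compare()].
#'
#' @param subject_id,date Metadata.
#' @param ... Named parameter values (e.g. `T_r_ms = 728`).
#' @return A `performance_report` with unspecified parameters `NA`.
#' @export
report_from_values <- function(subject_id, date, ...) {
  vals <- list(...)
  base <- stats::setNames(as.list(rep(NA_real_, length(report_parameters))),
                          report_parameters)
  base[names(vals)] <- vals
  structure(c(list(subject_id = subject_id, date = as.character(date),
                   game = NA_character_, mode = NA_character_),
              base,
              list(n_segments = NA_real_, n_segments_used = NA_real_,
                   n_segments_discarded = NA_real_,
                   per_segment = NULL)),
            class = "performance_report")
}
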
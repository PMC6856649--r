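# Work and EMG-comparison analyses: muscle power and positive work,
# external work from potential energy, thoracoscapular/glenohumeral work
# grouping, and mean-absolute-error comparison of simulated activations to
# EMG envelopes.

#' Muscle power from force and lengthening velocity
#'
#' `P(t) = F_mtu(t) * (-v_mtu(t))` with `v_mtu` positive when lengthening,
#' so concentric (shortening) contractions yield positive power.
#'
#' @param F_mtu musculotendon force series (N).
#' @param v_mtu lengthening-velocity series (m/s), same length.
#' @return power series (W).
#' @export
muscle_power <- function(F_mtu, v_mtu) {
  if (length(F_mtu) != length(v_mtu))
    stop("F_mtu and v_mtu must have the same length")
  F_mtu * (-v_mtu)
}

#' Positive mechanical work over an interval
#'
#' Trapezoidal integral of `max(P, 0)` over `interval`.
#'
#' @param time time grid (s).
#' @param P power series (W).
#' @param interval `c(t0, t1)` within the series (defaults to the full
#'   series).
#' @return positive work (J).
#' @export
positive_work <- function(time, P, interval = range(time)) {
  sel <- time >= interval[1] & time <= interval[2]
  if (sum(sel) < 2) {
    warning("empty or degenerate interval; returning 0 J")
    return(0)
  }
  trapz_int(time[sel], pmax(P[sel], 0))
}

#' External work as the change in potential energy
#'
#' `dPE` between the interval endpoints: the work done against gravity to
#' elevate the arm segments (and any hand-held mass). Depends only on the
#' endpoint poses.
#'
#' @param model a [shoulder_model()] (including its `hand_mass`).
#' @param result a `simulation_result` (or list with `time` and matrix `q`).
#' @param interval `c(t0, t1)`.
#' @return external work (J).
#' @export
external_work <- function(model, result, interval = range(result$time)) {
  qa <- .q_at_time(result, interval[1])
  qb <- .q_at_time(result, interval[2])
  potential_energy(model, qb) - potential_energy(model, qa)
}

#' @keywords internal
.q_at_time <- function(result, t) {
  i <- which.min(abs(result$time - t))
  result$q[i, ]
}

#' Detect the elevation phase of a task
#'
#' Motion onset to peak of the primary coordinate: from the sample where
#' the coordinate first exceeds 5% of its excursion to the sample of peak
#' excursion. Primary coordinate: scapular elevation for shrug, humeral
#' elevation otherwise.
#'
#' @param result a `simulation_result` (or list with `time`, `q`).
#' @param task task label, `"shrug"`, `"flexion"` or `"abduction"`.
#' @return `c(t_onset, t_peak)` (s).
#' @export
elevation_phase <- function(result, task = "flexion") {
  coord <- if (task == "shrug") "scap_elevation" else "gh_elev"
  x <- result$q[, coord]
  x0 <- x[1]
  excursion <- x - x0
  pk <- which.max(abs(excursion))
  thr <- 0.05 * abs(excursion[pk])
  onset <- which(abs(excursion) >= thr)[1]
  if (is.na(onset)) onset <- 1
  c(result$time[onset], result$time[pk])
}

#' Per-muscle positive work summary for a task
#'
#' Positive work per muscle over the elevation phase, group sums for the
#' thoracoscapular and glenohumeral muscle groups, external work, and the
#' <3% exclusion flag used when ranking top contributors.
#'
#' @param model the model used for the simulation.
#' @param result a `simulation_result`.
#' @param task task label (phase detection).
#' @param phase optional explicit `c(t0, t1)` phase overriding detection.
#' @return object of class `work_summary`: list with `per_muscle`
#'   (data.frame: muscle, group, positive_work_J, percent_of_total,
#'   excluded), `total` (J), `external` (J), `group_totals`, `phase`.
#' @export
work_summary <- function(model, result, task = "flexion", phase = NULL) {
  if (is.null(phase)) phase <- elevation_phase(result, task)
  sel <- result$time >= phase[1] & result$time <= phase[2]
  mn <- colnames(result$F_mtu)
  w <- vapply(seq_along(mn), function(i) {
    P <- muscle_power(result$F_mtu[sel, i], result$v_mtu[sel, i])
    positive_work(result$time[sel], P, range(result$time[sel]))
  }, numeric(1))
  total <- sum(w)
  groups <- muscle_groups(model)
  df <- data.frame(muscle = mn,
                   group = groups$group[match(mn, groups$muscle)],
                   positive_work_J = w,
                   percent_of_total = if (total > 0) 100 * w / total else 0,
                   stringsAsFactors = FALSE)
  df$excluded <- df$percent_of_total < 3
  df <- df[order(-df$positive_work_J), ]
  gt <- tapply(df$positive_work_J, df$group, sum)
  structure(list(per_muscle = df, total = total,
                 external = external_work(model, result, phase),
                 group_totals = gt, phase = phase),
            class = "work_summary")
}

#' @export
print.work_summary <- function(x, ...) {
  cat(sprintf("<work_summary: phase %.2f-%.2f s>\n", x$phase[1], x$phase[2]))
  cat(sprintf("  total positive muscle work: %.2f J; external work: %.2f J\n",
              x$total, x$external))
  for (g in names(x$group_totals))
    cat(sprintf("  %s: %.2f J\n", g, x$group_totals[[g]]))
  top <- utils::head(x$per_muscle[!x$per_muscle$excluded, ], 7)
  cat("  top contributors:\n")
  for (i in seq_len(nrow(top)))
    cat(sprintf("    %-32s %6.2f J (%4.1f%%)\n", top$muscle[i],
                top$positive_work_J[i], top$percent_of_total[i]))
  invisible(x)
}

#' Mean absolute error between simulated activation and an EMG envelope
#'
#' Both series are linearly resampled to a common grid over the comparison
#' interval. For serratus anterior the model's three bundle activations are
#' averaged before comparison (pass a matrix/data.frame with the three
#' bundles as `a_model`).
#'
#' @param t_model,a_model model activation series; `a_model` may be a
#'   vector, or a matrix/data.frame of bundle activations to average.
#' @param t_emg,emg_env normalized EMG envelope series.
#' @param interval comparison interval `c(t0, t1)`; must overlap both
#'   series.
#' @param n resampling grid size.
#' @return scalar MAE (unitless).
#' @export
activation_mae <- function(t_model, a_model, t_emg, emg_env,
                           interval = NULL, n = 200) {
  if (is.data.frame(a_model) || is.matrix(a_model))
    a_model <- rowMeans(as.matrix(a_model))
  lo <- max(min(t_model), min(t_emg))
  hi <- min(max(t_model), max(t_emg))
  if (!is.null(interval)) { lo <- max(lo, interval[1]); hi <- min(hi, interval[2]) }
  if (hi <= lo) stop("non-overlapping comparison intervals")
  grid <- seq(lo, hi, length.out = n)
  am <- stats::approx(t_model, a_model, grid)$y
  ae <- stats::approx(t_emg, emg_env, grid)$y
  mean(abs(am - ae))
}
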
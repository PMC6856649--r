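# Synthetic study fixtures: the six shoulder tasks (shrug, forward flexion,
# abduction, each with and without a 2 kg hand-held mass) as minimum-jerk
# joint-angle trajectories, 120 Hz marker trajectories with Gaussian noise,
# and amplitude-modulated EMG-like signals, all deterministically seeded.

#' Specify a synthetic shoulder task
#'
#' @param task `"shrug"`, `"flexion"` or `"abduction"`.
#' @param hand_mass hand-held mass in kg (0 or 2 in the study battery).
#' @param duration total task duration (s): elevation-and-return.
#' @param peak peak amplitude (rad) of the primary coordinate: scapular
#'   elevation for shrug (default 12 deg, about a 4 cm scapular rise on the
#'   thoracic ellipsoid -- see the package vignette), humeral elevation for
#'   the arm tasks (default 110 deg).
#' @param trial integer trial index (1-3 in the study battery); only used
#'   for seed derivation.
#' @param marker_noise_sd isotropic marker noise SD (m).
#' @param emg_snr amplitude signal-to-noise ratio of the EMG generator.
#' @param seed base random seed; the effective seed is derived from (task,
#'   hand mass, trial) so the 18-trial battery is reproducible trial by
#'   trial.
#' @return object of class `task_spec`.
#' @export
task_spec <- function(task = c("shrug", "flexion", "abduction"),
                      hand_mass = 0, duration = 4,
                      peak = NULL, trial = 1L,
                      marker_noise_sd = 0.003, emg_snr = 10, seed = 42L) {
  task <- match.arg(task)
  stopifnot(duration > 0, trial >= 1)
  if (is.null(peak))
    peak <- if (task == "shrug") 12 * pi / 180 else 110 * pi / 180
  eff_seed <- (as.integer(seed) +
                 7L * match(task, c("shrug", "flexion", "abduction")) +
                 31L * as.integer(hand_mass > 0) + 101L * as.integer(trial)) %% 2147483647L
  structure(list(task = task, hand_mass = hand_mass, duration = duration,
                 peak = peak, trial = as.integer(trial),
                 marker_noise_sd = marker_noise_sd, emg_snr = emg_snr,
                 seed = eff_seed),
            class = "task_spec")
}

#' Minimum-jerk elevation-and-return profile
#'
#' Smooth rise to `peak` over the first half of `duration` and return over
#' the second half, using the minimum-jerk polynomial
#' `s(tau) = 10 tau^3 - 15 tau^4 + 6 tau^5`; velocity and acceleration are
#' zero at both endpoints and at the peak.
#'
#' @param t time (s), vectorized.
#' @param duration task duration (s).
#' @param peak peak amplitude.
#' @param deriv 0 (position), 1 (velocity) or 2 (acceleration).
#' @return numeric vector.
#' @export
min_jerk_profile <- function(t, duration, peak, deriv = 0) {
  Th <- duration / 2
  up <- t <= Th
  tau <- ifelse(up, t / Th, (t - Th) / Th)
  tau <- pmin(1, pmax(0, tau))
  s <- switch(as.character(deriv),
    "0" = 10 * tau^3 - 15 * tau^4 + 6 * tau^5,
    "1" = (30 * tau^2 - 60 * tau^3 + 30 * tau^4) / Th,
    "2" = (60 * tau - 180 * tau^2 + 120 * tau^3) / Th^2,
    stop("deriv must be 0, 1 or 2"))
  out <- ifelse(up, s, switch(as.character(deriv),
                              "0" = 1 - s, "1" = -s, "2" = -s))
  peak * out
}

#' Generate joint-angle kinematics for a task
#'
#' Shrug moves only scapular coordinates (elevation to the spec'd peak plus
#' a small upward rotation). Arm-elevation tasks raise the arm to the peak
#' humerothoracic elevation with scapular upward rotation coupled at 1:2 to
#' glenohumeral elevation (the scapulohumeral rhythm as an emergent target,
#' not a model constraint): the glenohumeral coordinate contributes 2/3 of
#' the peak and scapular upward rotation 1/3, so their sum reaches the peak
#' arm elevation. A small scapular elevation/protraction contribution is
#' added.
#' Abduction holds the elevation plane at -90 deg (right arm, coronal
#' plane); flexion uses the sagittal plane (0 deg).
#'
#' @param spec a [task_spec()].
#' @param model a [shoulder_model()] (for coordinate names/defaults).
#' @param fs sampling rate (Hz).
#' @return data.frame: `time` plus one column per model coordinate (rad).
#' @export
generate_task_kinematics <- function(spec, model = builtin_thoracoscapular_model(),
                                     fs = 120) {
  t <- seq(0, spec$duration, by = 1 / fs)
  prof <- function(peak, deriv = 0) min_jerk_profile(t, spec$duration, peak, deriv)
  q0 <- default_q(model)
  out <- matrix(rep(q0, each = length(t)), length(t),
                dimnames = list(NULL, names(q0)))
  if (spec$task == "shrug") {
    out[, "scap_elevation"] <- q0["scap_elevation"] + prof(spec$peak)
    out[, "scap_upward_rot"] <- q0["scap_upward_rot"] + prof(spec$peak / 2)
  } else {
    out[, "gh_elev"] <- q0["gh_elev"] + prof(spec$peak * 2 / 3)
    out[, "scap_upward_rot"] <- q0["scap_upward_rot"] + prof(spec$peak / 3)
    out[, "scap_elevation"] <- q0["scap_elevation"] + prof(5 * pi / 180)
    out[, "scap_abduction"] <- q0["scap_abduction"] +
      prof((if (spec$task == "flexion") 8 else -4) * pi / 180)
    if (spec$task == "abduction") out[, "gh_plane"] <- -pi / 2
  }
  data.frame(time = t, out, check.names = FALSE)
}

#' Synthesize marker trajectories from a coordinate trajectory
#'
#' Forward-kinematics marker positions sampled at `fs`, plus isotropic
#' Gaussian noise, as a `trc_data` object ready for [write_trc()] or
#' [solve_inverse_kinematics()].
#'
#' @param model a [shoulder_model()].
#' @param q_traj data.frame from [generate_task_kinematics()] (time +
#'   coordinates).
#' @param noise_sd isotropic Gaussian noise SD (m).
#' @param fs sampling rate (Hz); `q_traj` is interpolated if needed.
#' @param seed random seed (fixed seed => bit-reproducible output).
#' @return a `trc_data` object.
#' @export
generate_marker_data <- function(model, q_traj, noise_sd = 0.003, fs = 120,
                                 seed = 42L) {
  tin <- q_traj$time
  t <- seq(min(tin), max(tin), by = 1 / fs)
  qm <- as.matrix(q_traj[, -1, drop = FALSE])
  qi <- vapply(seq_len(ncol(qm)), function(j)
    stats::approx(tin, qm[, j], t)$y, numeric(length(t)))
  mnames <- names(model$markers)
  pos <- array(NA_real_, c(length(t), length(mnames), 3),
               dimnames = list(NULL, mnames, c("x", "y", "z")))
  for (f in seq_along(t))
    pos[f, , ] <- marker_positions(model, qi[f, ])
  if (noise_sd > 0) {
    set.seed(seed)
    pos <- pos + array(stats::rnorm(length(pos), 0, noise_sd), dim(pos))
  }
  structure(list(time = t, rate = fs, units = "m", marker_names = mnames,
                 positions = pos),
            class = "trc_data")
}

#' Generate synthetic raw EMG from activation trajectories
#'
#' Amplitude-modulated band-limited (20-450 Hz) Gaussian noise carrier
#' scaled by the activation profile, plus an additive noise floor set by
#' `snr`; designed so that [emg_envelope()] recovers the modulation.
#'
#' @param activation data.frame: `time` plus one column per channel, values
#'   in [0, 1].
#' @param fs output sampling rate (Hz), > 900 so the 20-450 Hz carrier band
#'   is representable.
#' @param snr amplitude signal-to-noise ratio.
#' @param seed random seed.
#' @return data.frame: `time` plus one raw EMG-like column per channel (mV
#'   scale is arbitrary).
#' @export
generate_synthetic_emg <- function(activation, fs = 1000, snr = 10,
                                   seed = 42L) {
  stopifnot(fs > 900)
  tin <- activation$time
  t <- seq(min(tin), max(tin), by = 1 / fs)
  set.seed(seed)
  bf <- signal::butter(4, c(20, 450) / (fs / 2), type = "pass")
  out <- data.frame(time = t)
  for (ch in names(activation)[-1]) {
    act <- stats::approx(tin, pmin(1, pmax(0, activation[[ch]])), t)$y
    carrier <- signal::filtfilt(bf, stats::rnorm(length(t)))
    carrier <- carrier / stats::sd(carrier)
    noise <- stats::rnorm(length(t), 0, 1 / snr)
    out[[ch]] <- act * carrier + noise
  }
  out
}

#' Generate the full 18-trial study battery
#'
#' Three trials of shrug, flexion and abduction, each without and with the
#' 2 kg hand-held mass.
#'
#' @param seed base seed.
#' @param trials trials per condition.
#' @param ... passed to [task_spec()].
#' @return list of [task_spec()] objects (length `3 * 2 * trials`).
#' @export
task_battery <- function(seed = 42L, trials = 3L, ...) {
  specs <- list()
  for (task in c("shrug", "flexion", "abduction"))
    for (hm in c(0, 2))
      for (tr in seq_len(trials))
        specs[[length(specs) + 1]] <- task_spec(task, hm, trial = tr,
                                                seed = seed, ...)
  specs
}
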
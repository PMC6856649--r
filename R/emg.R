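# EMG conditioning: high-pass at 100 Hz, full-wave rectification, low-pass
# at 4 Hz (zero-phase Butterworth), and MVC normalization.

#' @keywords internal
#' Zero-phase filtering with odd-reflection end padding, so the filter's
#' start-up transient decays inside the padding instead of leaking into the
#' series; pad length scales with the filter's time constant fs/cutoff.
.filtfilt_padded <- function(filt, x, fs, cutoff) {
  n <- length(x)
  pad <- min(n - 1L, as.integer(ceiling(10 * fs / cutoff)))
  if (pad < 1L) return(signal::filtfilt(filt, x))
  head_pad <- 2 * x[1] - x[seq(pad + 1L, 2L)]
  tail_pad <- 2 * x[n] - x[seq(n - 1L, n - pad)]
  y <- signal::filtfilt(filt, c(head_pad, x, tail_pad))
  y[seq(pad + 1L, pad + n)]
}

#' EMG envelope
#'
#' Conditions raw EMG with a zero-phase 4th-order Butterworth high-pass at
#' `hp` Hz, full-wave rectification, and a zero-phase 4th-order Butterworth
#' low-pass at `lp` Hz. Residual filter ringing below zero is clamped at 0.
#'
#' @param raw numeric vector of raw EMG samples.
#' @param fs sampling rate (Hz); must exceed 2 * `hp` so the high-pass
#'   corner lies inside the representable band (the study's kinematics were
#'   sampled at 120 Hz but EMG hardware samples much faster).
#' @param hp high-pass corner (Hz).
#' @param lp low-pass corner (Hz).
#' @param order Butterworth design order (applied forward-backward).
#' @return nonnegative numeric envelope, same length as `raw`.
#' @export
emg_envelope <- function(raw, fs, hp = 100, lp = 4, order = 4) {
  if (fs <= 2 * hp)
    stop(sprintf("sampling rate %g Hz too low for a %g Hz high-pass (need fs > %g)",
                 fs, hp, 2 * hp))
  bh <- signal::butter(order, hp / (fs / 2), type = "high")
  bl <- signal::butter(order, lp / (fs / 2), type = "low")
  x <- .filtfilt_padded(bh, raw, fs, hp)
  x <- abs(x)
  x <- .filtfilt_padded(bl, x, fs, lp)
  pmax(x, 0)
}

#' Rectify-and-smooth stage of the envelope chain
#'
#' The low-pass half of [emg_envelope()] without the high-pass, used to
#' process already high-passed signals and to verify idempotence of the
#' smoothing stage.
#'
#' @inheritParams emg_envelope
#' @export
emg_smooth_rectified <- function(raw, fs, lp = 4, order = 4) {
  bl <- signal::butter(order, lp / (fs / 2), type = "low")
  pmax(.filtfilt_padded(bl, abs(raw), fs, lp), 0)
}

#' Normalize an envelope by a maximum voluntary contraction value
#'
#' Element-wise division; values may exceed 1 and are reported, not
#' clamped.
#'
#' @param envelope nonnegative envelope.
#' @param mvc_peak MVC reference (> 0), typically from [mvc_peak()].
#' @return normalized envelope (unitless).
#' @export
normalize_mvc <- function(envelope, mvc_peak) {
  if (!is.finite(mvc_peak) || mvc_peak <= 0)
    stop("mvc_peak must be > 0")
  envelope / mvc_peak
}

#' MVC reference value from one or more MVC trials
#'
#' Maximum of the processed envelope across the supplied raw MVC
#' recordings for one muscle.
#'
#' @param mvc_trials list of raw EMG vectors (or a single vector).
#' @inheritParams emg_envelope
#' @return scalar MVC peak.
#' @export
mvc_peak <- function(mvc_trials, fs, hp = 100, lp = 4, order = 4) {
  if (is.numeric(mvc_trials)) mvc_trials <- list(mvc_trials)
  max(vapply(mvc_trials, function(x)
    max(emg_envelope(x, fs, hp, lp, order)), numeric(1)))
}

#' Process a multi-channel raw EMG data frame into normalized envelopes
#'
#' @param raw_df data.frame: `time` plus one raw channel per muscle.
#' @param mvc named vector of MVC peaks per channel; channels without an
#'   entry are returned unnormalized.
#' @inheritParams emg_envelope
#' @return data.frame: `time` plus one envelope column per channel.
#' @export
process_emg <- function(raw_df, mvc = NULL, fs = NULL, hp = 100, lp = 4,
                        order = 4) {
  stopifnot(names(raw_df)[1] == "time")
  if (is.null(fs)) fs <- 1 / stats::median(diff(raw_df$time))
  out <- data.frame(time = raw_df$time)
  for (ch in names(raw_df)[-1]) {
    env <- emg_envelope(raw_df[[ch]], fs, hp, lp, order)
    if (!is.null(mvc) && ch %in% names(mvc))
      env <- normalize_mvc(env, mvc[[ch]])
    out[[ch]] <- env
  }
  out
}
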
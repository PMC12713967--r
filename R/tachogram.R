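#' Detect R peaks in an ECG signal and build a tachogram
#'
#' A simple amplitude-based QRS detector sufficient for clean single-lead
#' ECG: the signal is mean-centred, candidate peaks are local maxima above
#' an adaptive threshold (a fraction of the 99th percentile of the
#' rectified signal), and a refractory period suppresses secondary peaks.
#' Beat-to-beat intervals are the successive peak-time differences in ms;
#' the resulting series has one entry per interval, timestamped at the
#' later peak of each pair.
#'
#' @param values numeric ECG samples.
#' @param rate sampling rate in Hz, >= 100.
#' @param threshold_frac fraction of the 99th percentile of the rectified
#'   signal used as detection threshold.
#' @param refractory_s minimum peak-to-peak spacing in seconds.
#' @return An [interval_series()] with `source = "ecg_rri"`. A flat or
#'   peak-free signal yields an empty series with a warning.
#' @export
detect_r_peaks <- function(values, rate, threshold_frac = 0.6,
                           refractory_s = 0.25) {
  if (rate < 100) stop("ECG sampling rate must be >= 100 Hz")
  n <- length(values)
  if (n / rate < 10) stop("insufficient data: need at least 10 s of ECG")
  x <- values - stats::median(values)
  amp <- stats::quantile(abs(x), 0.99, names = FALSE)
  empty <- interval_series(numeric(0), numeric(0), source = "ecg_rri",
                           recording_duration = n / rate)
  if (amp <= 0 || stats::sd(x) == 0) {
    warning("flat or featureless signal: no R peaks detected")
    return(empty)
  }
  thr <- threshold_frac * amp
  above <- x > thr
  # local maxima above threshold
  cand <- which(above &
                  x >= c(-Inf, x[-n]) &
                  x > c(x[-1], -Inf))
  if (length(cand) < 2) {
    warning("fewer than 2 R peaks detected")
    return(empty)
  }
  # enforce refractory period, keeping the larger peak
  keep <- cand[1]
  for (i in cand[-1]) {
    last <- keep[length(keep)]
    if ((i - last) / rate >= refractory_s) {
      keep <- c(keep, i)
    } else if (x[i] > x[last]) {
      keep[length(keep)] <- i
    }
  }
  peak_t <- (keep - 1) / rate
  if (length(peak_t) < 2) {
    warning("fewer than 2 R peaks detected")
    return(empty)
  }
  interval_series(beat_times = peak_t[-1],
                  intervals_ms = diff(peak_t) * 1000,
                  source = "ecg_rri", recording_duration = n / rate)
}

#' Convert a 1-Hz pulse-rate series to beat intervals
#'
#' Each pulse-rate sample (beats/min) is converted to the equivalent
#' heart-period interval `60000 / hr_bpm` ms, keeping the sample times as
#' beat times, so that the same dip detector runs unchanged on pulse data.
#' Gap samples become artifact-flagged beats (carrying a neutral interval
#' so the series stays valid) rather than being dropped.
#'
#' @param pulse a [pulse_series()].
#' @return An [interval_series()] with `source = "pulse_derived"`.
#' @export
pulse_to_intervals <- function(pulse) {
  stopifnot(inherits(pulse, "pulse_series"))
  ok <- !pulse$gap_mask
  if (!any(ok)) stop("pulse series contains no analyzable (non-gap) samples")
  iv <- ifelse(ok & is.finite(pulse$hr_bpm) & pulse$hr_bpm > 0,
               60000 / pulse$hr_bpm, NA_real_)
  iv[is.na(iv)] <- stats::median(iv, na.rm = TRUE)
  keep <- !duplicated(pulse$times)  # guard against repeated timestamps
  interval_series(pulse$times[keep], iv[keep],
                  artifact = (!ok)[keep], source = "pulse_derived",
                  recording_duration = max(pulse$times))
}

#' Flag non-physiological beats by interval limits
#'
#' Marks beats whose interval falls outside `[lower_ms, upper_ms]` as
#' artifacts. Existing flags are preserved; beats are never deleted. The
#' defaults 300-2000 ms correspond to 30-200 beats/min.
#'
#' @param series an [interval_series()].
#' @param lower_ms,upper_ms physiological interval limits in ms.
#' @return The series with updated artifact flags.
#' @export
exclude_artifacts <- function(series, lower_ms = 300, upper_ms = 2000) {
  stopifnot(inherits(series, "interval_series"))
  if (lower_ms >= upper_ms) stop("lower_ms must be < upper_ms")
  out <- series
  out$artifact <- series$artifact |
    series$intervals_ms < lower_ms | series$intervals_ms > upper_ms
  out
}

#' Fraction of recording time that cannot be analyzed
#'
#' Returns the fraction of the recording covered by artifact-flagged beats
#' plus inter-beat gaps longer than 3 s (including a trailing gap between
#' the last beat and the recording end). Studies with a fraction above
#' 0.10 should be rejected by the caller; this threshold is exposed as the
#' `max_fraction` argument of [run_detect()].
#'
#' Each beat accounts for the stretch of time ending at it: its interval
#' for ordinary beats, the full inter-beat spacing when that spacing
#' exceeds the gap limit.
#'
#' @param series an [interval_series()].
#' @param gap_s spacing above which time counts as unanalyzable (s).
#' @return A fraction in `[0, 1]`; an empty series returns 1.
#' @export
quality_fraction <- function(series, gap_s = 3) {
  stopifnot(inherits(series, "interval_series"))
  n <- n_beats(series)
  if (n == 0) return(1)
  dur <- series$recording_duration
  if (dur <= 0) return(1)
  # spacing ending at each beat; the first beat is preceded by its interval
  spacing <- c(series$intervals_ms[1] / 1000, diff(series$beat_times))
  bad_time <- sum(spacing[series$artifact | spacing > gap_s])
  trailing <- dur - series$beat_times[n]
  if (trailing > gap_s) bad_time <- bad_time + trailing
  leading <- series$beat_times[1] - spacing[1]
  if (leading > gap_s) bad_time <- bad_time + leading
  min(1, bad_time / dur)
}
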
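#' Beat-to-beat interval series (tachogram)
#'
#' The central container for beat-to-beat heart-rate data: each beat has a
#' timestamp (seconds from recording start), the interval that ends at that
#' beat (milliseconds), and an artifact flag. The series may originate from
#' ECG R-peak detection (`source = "ecg_rri"`) or from a 1-Hz pulse-rate
#' trace converted to intervals (`source = "pulse_derived"`).
#'
#' Artifact beats are flagged, never deleted, so that baseline computation
#' downstream can exclude them explicitly and the provenance of every beat
#' is preserved.
#'
#' @param beat_times numeric, strictly increasing, seconds from recording
#'   start (>= 0).
#' @param intervals_ms numeric, finite and > 0; `intervals_ms[i]` is the
#'   interval ending at `beat_times[i]`.
#' @param artifact logical artifact flags, recycled from a single value.
#' @param source `"ecg_rri"` or `"pulse_derived"`.
#' @param recording_duration total recording duration in seconds; must be at
#'   least the last beat time. Defaults to the last beat time.
#' @return An object of class `interval_series`: a list with elements
#'   `beat_times`, `intervals_ms`, `artifact`, `source`,
#'   `recording_duration`.
#' @examples
#' s <- interval_series(1:10, rep(1000, 10))
#' n_beats(s)
#' @export
interval_series <- function(beat_times, intervals_ms,
                            artifact = FALSE,
                            source = c("ecg_rri", "pulse_derived"),
                            recording_duration = NULL) {
  source <- match.arg(source)
  beat_times <- as.numeric(beat_times)
  intervals_ms <- as.numeric(intervals_ms)
  n <- length(beat_times)
  if (length(intervals_ms) != n)
    stop("beat_times and intervals_ms must have equal length")
  artifact <- rep_len(as.logical(artifact), n)
  if (anyNA(beat_times) || anyNA(intervals_ms) || anyNA(artifact))
    stop("interval_series fields must not contain NA")
  if (n > 1 && any(diff(beat_times) <= 0))
    stop("beat_times must be strictly increasing (violated at row ",
         which(diff(beat_times) <= 0)[1] + 1L, ")")
  if (n > 0 && (any(!is.finite(intervals_ms)) || any(intervals_ms <= 0)))
    stop("intervals_ms must be finite and > 0")
  if (n > 0 && beat_times[1] < 0)
    stop("beat_times must be >= 0")
  if (is.null(recording_duration))
    recording_duration <- if (n > 0) beat_times[n] else 0
  if (n > 0 && recording_duration < beat_times[n])
    stop("recording_duration must be >= last beat time")
  structure(
    list(beat_times = beat_times, intervals_ms = intervals_ms,
         artifact = artifact, source = source,
         recording_duration = as.numeric(recording_duration)),
    class = "interval_series")
}

#' @rdname interval_series
#' @param x an `interval_series`.
#' @export
n_beats <- function(x) length(x$beat_times)

#' @export
print.interval_series <- function(x, ...) {
  cat(sprintf("<interval_series> %d beats, source=%s, %.1f s recording\n",
              n_beats(x), x$source, x$recording_duration))
  if (n_beats(x) > 0)
    cat(sprintf("  intervals: %.0f-%.0f ms (median %.0f), %d artifact-flagged\n",
                min(x$intervals_ms), max(x$intervals_ms),
                stats::median(x$intervals_ms), sum(x$artifact)))
  invisible(x)
}

#' @export
as.data.frame.interval_series <- function(x, ...) {
  data.frame(time_s = x$beat_times, interval_ms = x$intervals_ms,
             artifact = as.integer(x$artifact))
}

#' 1-Hz pulse-rate series
#'
#' Pulse-rate recordings (beats/min, nominally one sample per second) as
#' produced by the pulse-oximetry channel of a polysomnograph. Samples with
#' spacing greater than 1.5 s to the previous sample are gap-flagged.
#'
#' @param times sample times in seconds, non-decreasing.
#' @param hr_bpm pulse rate in beats/min; must be finite and > 0 wherever
#'   `gap_mask` is `FALSE`.
#' @param gap_mask logical; `TRUE` marks samples that open after a recording
#'   gap (or invalid samples). Computed from spacing when `NULL`.
#' @return An object of class `pulse_series`.
#' @examples
#' p <- pulse_series(0:59, rep(60, 60))
#' sum(p$gap_mask)
#' @export
pulse_series <- function(times, hr_bpm, gap_mask = NULL) {
  times <- as.numeric(times)
  hr_bpm <- as.numeric(hr_bpm)
  if (length(times) != length(hr_bpm))
    stop("times and hr_bpm must have equal length")
  if (length(times) > 1 && any(diff(times) < 0))
    stop("times must be non-decreasing")
  if (is.null(gap_mask)) {
    gap_mask <- c(FALSE, diff(times) > 1.5)
  } else {
    gap_mask <- rep_len(as.logical(gap_mask), length(times))
  }
  bad <- !gap_mask & (!is.finite(hr_bpm) | hr_bpm <= 0)
  if (any(bad))
    stop("hr_bpm must be finite and > 0 on non-gap samples (first bad row ",
         which(bad)[1], ")")
  structure(list(times = times, hr_bpm = hr_bpm, gap_mask = gap_mask),
            class = "pulse_series")
}

#' @export
print.pulse_series <- function(x, ...) {
  cat(sprintf("<pulse_series> %d samples, %d gap-flagged\n",
              length(x$times), sum(x$gap_mask)))
  invisible(x)
}

# controlled vocabulary for scored respiratory events
RESP_EVENT_TYPES <- c("obstructive_apnea", "central_apnea",
                      "mixed_apnea", "hypopnea")

#' Pre-scored annotations: respiratory events and arousals
#'
#' Holds the technician-scored respiratory events (apneas/hypopneas) and
#' cortical arousals of a sleep study. Scoring is never automated here;
#' annotations come from the study files. Event windows are half-open
#' `[start, start + duration)` on a 0-based seconds axis.
#'
#' @param respiratory_events data.frame with columns `event_type` (one of
#'   `"obstructive_apnea"`, `"central_apnea"`, `"mixed_apnea"`,
#'   `"hypopnea"`), `start` (s, >= 0), `duration` (s, > 0).
#' @param arousals data.frame with columns `start`, `duration`.
#' @return An object of class `annotation_set`.
#' @examples
#' a <- annotation_set(
#'   data.frame(event_type = "hypopnea", start = 100, duration = 20),
#'   data.frame(start = 118, duration = 5))
#' @export
annotation_set <- function(respiratory_events = NULL, arousals = NULL) {
  if (is.null(respiratory_events))
    respiratory_events <- data.frame(event_type = character(),
                                     start = numeric(), duration = numeric())
  if (is.null(arousals))
    arousals <- data.frame(start = numeric(), duration = numeric())
  respiratory_events <- as.data.frame(respiratory_events)
  arousals <- as.data.frame(arousals)
  need <- c("event_type", "start", "duration")
  if (!all(need %in% names(respiratory_events)))
    stop("respiratory_events needs columns: ", paste(need, collapse = ", "))
  if (!all(c("start", "duration") %in% names(arousals)))
    stop("arousals needs columns: start, duration")
  respiratory_events$event_type <- as.character(respiratory_events$event_type)
  bad <- !respiratory_events$event_type %in% RESP_EVENT_TYPES
  if (any(bad))
    stop("unknown event_type: ",
         paste(unique(respiratory_events$event_type[bad]), collapse = ", "))
  for (df in list(respiratory_events, arousals)) {
    if (nrow(df) && (any(df$start < 0) || any(df$duration <= 0)))
      stop("annotation starts must be >= 0 and durations > 0")
  }
  o <- order(respiratory_events$start)
  respiratory_events <- respiratory_events[o, , drop = FALSE]
  rownames(respiratory_events) <- NULL
  arousals <- arousals[order(arousals$start), c("start", "duration"),
                       drop = FALSE]
  rownames(arousals) <- NULL
  structure(list(respiratory_events = respiratory_events,
                 arousals = arousals),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("<annotation_set> %d respiratory events, %d arousals\n",
              nrow(x$respiratory_events), nrow(x$arousals)))
  if (nrow(x$respiratory_events))
    print(table(x$respiratory_events$event_type))
  invisible(x)
}

#' Per-study metadata
#'
#' Recording- and subject-level metadata: the total recording time that is
#' the denominator of every dip index, total sleep time (the denominator of
#' the polysomnographic AHI), the reference AHI when available, and
#' covariates used for adjusted correlations.
#'
#' @param study_id character identifier.
#' @param total_recording_time hours, > 0.
#' @param total_sleep_time hours, 0 <= TST <= TRT (optional).
#' @param npsg_ahi reference apnea-hypopnea index, events/h (optional).
#' @param age years (optional).
#' @param sex `"male"`, `"female"` or `NA`.
#' @param bmi kg/m^2 (optional).
#' @return An object of class `recording_meta`.
#' @export
recording_meta <- function(study_id, total_recording_time,
                           total_sleep_time = NA_real_,
                           npsg_ahi = NA_real_, age = NA_real_,
                           sex = NA_character_, bmi = NA_real_) {
  trt <- as.numeric(total_recording_time)
  tst <- as.numeric(total_sleep_time)
  if (!is.finite(trt) || trt <= 0)
    stop("total_recording_time must be a positive number of hours")
  if (is.finite(tst) && (tst < 0 || tst > trt))
    stop("total_sleep_time must satisfy 0 <= TST <= TRT")
  for (v in c(npsg_ahi = npsg_ahi, age = age, bmi = bmi)) {
    if (!is.na(v) && (!is.finite(v) || v < 0))
      stop("metadata numerics must be finite and non-negative")
  }
  if (!is.na(sex) && !sex %in% c("male", "female"))
    stop("sex must be 'male', 'female' or NA")
  structure(list(study_id = as.character(study_id),
                 total_recording_time = trt, total_sleep_time = tst,
                 npsg_ahi = as.numeric(npsg_ahi), age = as.numeric(age),
                 sex = sex, bmi = as.numeric(bmi)),
            class = "recording_meta")
}

#' @export
print.recording_meta <- function(x, ...) {
  cat(sprintf("<recording_meta> %s: TRT %.2f h, TST %s h, AHI %s\n",
              x$study_id, x$total_recording_time,
              ifelse(is.na(x$total_sleep_time), "NA",
                     sprintf("%.2f", x$total_sleep_time)),
              ifelse(is.na(x$npsg_ahi), "NA", sprintf("%.1f", x$npsg_ahi))))
  invisible(x)
}
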
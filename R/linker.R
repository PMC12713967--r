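#' Link dips to scored respiratory events
#'
#' A dip is respiratory-related when its nadir falls during a scored
#' respiratory event or within `post_window` seconds after the event's
#' end, i.e. when `nadir_time` lies in the half-open window
#' `[start, start + duration + post_window)`. When several events qualify
#' the dip is attributed to the nearest preceding one (latest window
#' start); each dip links to at most one event, while one event may own
#' several dips.
#'
#' @param detection a `dip_detection` (or its `dips` data.frame).
#' @param annotations an [annotation_set()].
#' @param post_window seconds after the event end during which a dip still
#'   counts as respiratory-related (default 30).
#' @return The input with `linked_event` (row index into
#'   `annotations$respiratory_events`), `linked_event_type` and
#'   `event_lag` (nadir time minus event end; negative when the nadir is
#'   inside the event) filled in.
#' @export
link_respiratory <- function(detection, annotations, post_window = 30) {
  stopifnot(inherits(annotations, "annotation_set"))
  dips <- if (inherits(detection, "dip_detection")) detection$dips
          else detection
  ev <- annotations$respiratory_events
  idx <- link_windows(dips$nadir_time, ev$start, ev$duration, post_window)
  dips$linked_event <- idx
  dips$linked_event_type <- ifelse(is.na(idx), NA_character_,
                                   ev$event_type[idx])
  dips$event_lag <- ifelse(is.na(idx), NA_real_,
                           dips$nadir_time - (ev$start[idx] +
                                                ev$duration[idx]))
  if (inherits(detection, "dip_detection")) {
    detection$dips <- dips
    detection
  } else dips
}

#' Link dips to scored arousals
#'
#' Same windowing rule as [link_respiratory()], applied to arousal
#' records. A dip may be both respiratory- and arousal-linked. The
#' default window mirrors the respiratory rule.
#'
#' @inheritParams link_respiratory
#' @return The input with `linked_arousal` filled in.
#' @export
link_arousals <- function(detection, annotations, post_window = 30) {
  stopifnot(inherits(annotations, "annotation_set"))
  dips <- if (inherits(detection, "dip_detection")) detection$dips
          else detection
  ar <- annotations$arousals
  dips$linked_arousal <- link_windows(dips$nadir_time, ar$start,
                                      ar$duration, post_window)
  if (inherits(detection, "dip_detection")) {
    detection$dips <- dips
    detection
  } else dips
}

# for each time t, the index of the record with the latest start whose
# half-open window [start, start + duration + post) contains t, or NA
link_windows <- function(t, start, duration, post) {
  if (length(start) == 0 || length(t) == 0)
    return(rep(NA_integer_, length(t)))
  vapply(t, function(ti) {
    hit <- which(start <= ti & ti < start + duration + post)
    if (!length(hit)) return(NA_integer_)
    hit[which.max(start[hit])]
  }, integer(1))
}

#' Assemble the per-study severity indices
#'
#' Links the ECG-derived (RRI) and pulse-derived detections to the study's
#' annotations and computes the six indices: total RRDI, total HRAI, their
#' respiratory-related subsets (RE RRDI, RE HRAI), and the arousal-related
#' subsets. All indices are events per hour of total recording time.
#' Either detection may be `NULL`, leaving its indices `NA`.
#'
#' @param detection_rri `dip_detection` from the ECG tachogram, or `NULL`.
#' @param detection_pulse `dip_detection` from pulse-derived intervals, or
#'   `NULL`.
#' @param annotations an [annotation_set()].
#' @param meta a [recording_meta()] (supplies the TRT denominator).
#' @param post_window linkage window in seconds (default 30, applied to
#'   respiratory events and arousals alike).
#' @return An object of class `study_result` with fields `total_rrdi`,
#'   `total_hrai`, `re_rrdi`, `re_hrai`, `arousal_rrdi`, `arousal_hrai`,
#'   `trt_hours`, `study_id` and the linked dip data.frames
#'   `dips_rri` / `dips_pulse`.
#' @export
summarize_study <- function(detection_rri, detection_pulse, annotations,
                            meta, post_window = 30) {
  stopifnot(inherits(annotations, "annotation_set"),
            inherits(meta, "recording_meta"))
  trt <- meta$total_recording_time
  if (!is.finite(trt) || trt <= 0)
    stop("total_recording_time must be > 0")
  one <- function(det) {
    if (is.null(det)) return(NULL)
    det <- link_respiratory(det, annotations, post_window)
    det <- link_arousals(det, annotations, post_window)
    det$dips
  }
  d_rri <- one(detection_rri)
  d_pulse <- one(detection_pulse)
  idx <- function(d, which = c("total", "re", "arousal")) {
    if (is.null(d)) return(NA_real_)
    n <- switch(match.arg(which),
                total = nrow(d),
                re = sum(!is.na(d$linked_event)),
                arousal = sum(!is.na(d$linked_arousal)))
    n / trt
  }
  structure(list(study_id = meta$study_id,
                 total_rrdi = idx(d_rri, "total"),
                 re_rrdi = idx(d_rri, "re"),
                 arousal_rrdi = idx(d_rri, "arousal"),
                 total_hrai = idx(d_pulse, "total"),
                 re_hrai = idx(d_pulse, "re"),
                 arousal_hrai = idx(d_pulse, "arousal"),
                 trt_hours = trt,
                 dips_rri = d_rri, dips_pulse = d_pulse),
            class = "study_result")
}

#' @export
print.study_result <- function(x, ...) {
  f <- function(v) ifelse(is.na(v), "NA", sprintf("%.2f", v))
  cat(sprintf("<study_result> %s (TRT %.2f h)\n", x$study_id, x$trt_hours))
  cat(sprintf("  RRDI  total %s  respiratory %s  arousal %s  (events/h)\n",
              f(x$total_rrdi), f(x$re_rrdi), f(x$arousal_rrdi)))
  cat(sprintf("  HRAI  total %s  respiratory %s  arousal %s  (events/h)\n",
              f(x$total_hrai), f(x$re_hrai), f(x$arousal_hrai)))
  invisible(x)
}

#' Export a study result to JSON
#'
#' Writes the six indices, the TRT denominator and the per-dip tables.
#'
#' @param result a `study_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_study_result <- function(result, path) {
  stopifnot(inherits(result, "study_result"))
  out <- result[c("study_id", "total_rrdi", "re_rrdi", "arousal_rrdi",
                  "total_hrai", "re_hrai", "arousal_hrai", "trt_hours")]
  out$dips_rri <- result$dips_rri
  out$dips_pulse <- result$dips_pulse
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
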
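#' Detector parameters
#'
#' Parameters of the relative-threshold dip detector. One engine serves
#' both signals: RR-interval dips from ECG use `threshold_fraction = 0.90`
#' (an interval is a candidate when it is strictly below 90% of the 1-min
#' segment mean), while pulse-derived heart-rate accelerations use
#' `threshold_fraction = 0.95` (a 5% acceleration threshold applied to the
#' converted intervals). Some workflows instead express the 5% rule on the
#' heart rate itself (HR > 1.05 x baseline HR, i.e. interval below
#' 1/1.05 = 0.9524 of baseline); set `hr_relative = TRUE` for that reading.
#'
#' @param threshold_fraction fraction of the segment-mean interval below
#'   which a beat is marked; in (0, 1).
#' @param segment_length baseline segment length in seconds (default 60).
#' @param merge_gap groups closer than this many seconds are merged
#'   (strict `<`; default 10).
#' @param min_consecutive minimum run length of marked beats for a group
#'   to count as a dip rather than noise (default 2).
#' @param hr_relative if `TRUE`, re-expresses `threshold_fraction` `f` as
#'   the interval threshold `1 / (2 - f)` so that a 0.95 setting means
#'   "HR more than 5% above baseline HR".
#' @return An object of class `detector_params`.
#' @examples
#' detector_params()                       # RRI dips, 90% rule
#' detector_params(threshold_fraction = 0.95)  # pulse accelerations
#' @export
detector_params <- function(threshold_fraction = 0.90, segment_length = 60,
                            merge_gap = 10, min_consecutive = 2,
                            hr_relative = FALSE) {
  if (!(threshold_fraction > 0 && threshold_fraction < 1))
    stop("threshold_fraction must be in (0, 1)")
  if (segment_length <= 0) stop("segment_length must be > 0")
  if (merge_gap < 0) stop("merge_gap must be >= 0")
  if (min_consecutive < 1) stop("min_consecutive must be >= 1")
  eff <- if (hr_relative) 1 / (2 - threshold_fraction) else threshold_fraction
  structure(list(threshold_fraction = threshold_fraction,
                 effective_fraction = eff,
                 segment_length = segment_length,
                 merge_gap = merge_gap,
                 min_consecutive = as.integer(min_consecutive),
                 hr_relative = hr_relative),
            class = "detector_params")
}

#' @export
print.detector_params <- function(x, ...) {
  cat(sprintf(paste0("<detector_params> threshold %.4g (effective %.4g), ",
                     "%gs segments, merge < %gs, min run %d\n"),
              x$threshold_fraction, x$effective_fraction,
              x$segment_length, x$merge_gap, x$min_consecutive))
  invisible(x)
}

#' Per-beat baseline from fixed 1-minute segments
#'
#' The recording is partitioned into fixed, non-overlapping windows
#' `[k*L, (k+1)*L)` anchored at time 0. The baseline of every non-artifact
#' beat is the mean interval of the non-artifact beats in its window; a
#' window with fewer than 3 valid beats yields no baseline (`NA`), making
#' its beats unmarkable. Artifact beats always get `NA`.
#'
#' @param series an [interval_series()].
#' @param segment_length window length in seconds.
#' @return Numeric vector of per-beat baselines (ms), `NA` where none.
#' @export
segment_baselines <- function(series, segment_length = 60) {
  stopifnot(inherits(series, "interval_series"))
  n <- n_beats(series)
  if (n == 0) return(numeric(0))
  win <- floor(series$beat_times / segment_length)
  base <- rep(NA_real_, n)
  valid <- !series$artifact
  means <- tapply(series$intervals_ms[valid], win[valid], mean)
  counts <- tapply(valid[valid], win[valid], length)
  ok_win <- names(counts)[counts >= 3]
  idx <- valid & as.character(win) %in% ok_win
  base[idx] <- means[as.character(win[idx])]
  base
}

#' Mark beats strictly below the relative threshold
#'
#' `mark[i]` is `TRUE` when beat `i` is not an artifact, has a baseline,
#' and its interval is strictly less than
#' `threshold_fraction * baseline[i]`. A beat exactly at the threshold is
#' not marked.
#'
#' @param series an [interval_series()].
#' @param baselines per-beat baselines from [segment_baselines()].
#' @param threshold_fraction fraction in (0, 1).
#' @return Logical vector of marks.
#' @export
mark_subthreshold <- function(series, baselines, threshold_fraction = 0.90) {
  stopifnot(inherits(series, "interval_series"),
            length(baselines) == n_beats(series))
  !series$artifact & !is.na(baselines) &
    series$intervals_ms < threshold_fraction * baselines
}

#' Group consecutively marked beats, rejecting short runs
#'
#' Finds maximal runs of consecutively marked beats (consecutive in beat
#' order; artifact beats are unmarked and therefore break runs). Runs
#' shorter than `min_consecutive` are counted as noise and excluded.
#'
#' @param marks logical vector from [mark_subthreshold()].
#' @param min_consecutive minimum run length.
#' @return A list with `groups` (data.frame of `first`/`last` beat
#'   indices) and `n_noise` (number of rejected short runs).
#' @export
group_marks <- function(marks, min_consecutive = 2) {
  r <- rle(as.logical(marks))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  run <- r$values
  long_enough <- run & r$lengths >= min_consecutive
  list(groups = data.frame(first = starts[long_enough],
                           last = ends[long_enough]),
       n_noise = sum(run & r$lengths < min_consecutive))
}

#' Merge groups separated by less than the merge gap
#'
#' Adjacent groups whose time gap — first marked-beat time of the later
#' group minus last marked-beat time of the earlier group — is strictly
#' less than `merge_gap` seconds are unioned, transitively left to right
#' until a fixed point. Unmarked beats between merged groups are absorbed
#' into the group span but are not re-marked (the dip extremum is still
#' chosen among marked beats only).
#'
#' @param groups data.frame of `first`/`last` beat indices, time-ordered.
#' @param series the [interval_series()] the indices refer to.
#' @param merge_gap seconds; strict `<`.
#' @return A data.frame of merged `first`/`last` beat indices.
#' @export
merge_groups <- function(groups, series, merge_gap = 10) {
  stopifnot(inherits(series, "interval_series"))
  if (nrow(groups) < 2) return(groups)
  t_first <- series$beat_times[groups$first]
  t_last <- series$beat_times[groups$last]
  out_first <- groups$first[1]
  out_last <- groups$last[1]
  cur_end_t <- t_last[1]
  for (i in 2:nrow(groups)) {
    if (t_first[i] - cur_end_t < merge_gap) {
      out_last[length(out_last)] <- groups$last[i]
    } else {
      out_first <- c(out_first, groups$first[i])
      out_last <- c(out_last, groups$last[i])
    }
    cur_end_t <- t_last[i]
  }
  data.frame(first = out_first, last = out_last)
}

#' Select one dip per merged group
#'
#' The dip of a group is its extremum: the marked beat with the smallest
#' interval (ties broken by the earliest beat). Group start/end are the
#' first/last *marked* beat times; `n_beats` counts marked beats only.
#'
#' @param groups merged groups from [merge_groups()].
#' @param series the [interval_series()].
#' @param marks the mark vector the groups were built from.
#' @param baselines per-beat baselines (for the depth fraction).
#' @return A data.frame with one row per dip: `group_start`, `group_end`,
#'   `nadir_time`, `nadir_interval`, `baseline_interval`, `depth_fraction`,
#'   `n_beats`.
#' @export
select_dips <- function(groups, series, marks, baselines) {
  stopifnot(inherits(series, "interval_series"))
  out <- data.frame(group_start = numeric(0), group_end = numeric(0),
                    nadir_time = numeric(0), nadir_interval = numeric(0),
                    baseline_interval = numeric(0),
                    depth_fraction = numeric(0), n_beats = integer(0))
  for (g in seq_len(nrow(groups))) {
    idx <- groups$first[g]:groups$last[g]
    idx <- idx[marks[idx]]
    nad <- idx[which.min(series$intervals_ms[idx])]  # earliest on ties
    out[g, ] <- list(series$beat_times[idx[1]],
                     series$beat_times[idx[length(idx)]],
                     series$beat_times[nad],
                     series$intervals_ms[nad],
                     baselines[nad],
                     series$intervals_ms[nad] / baselines[nad],
                     length(idx))
  }
  out
}

#' Detect RR-interval dips / heart-rate accelerations
#'
#' The full detection pipeline: 1-minute segment baselines, strict
#' relative-threshold marking, consecutive-beat grouping with rejection of
#' runs shorter than `min_consecutive`, merging of groups separated by
#' less than `merge_gap` seconds, and selection of the per-group extremum
#' as the dip. With the default 0.90 threshold on an ECG-derived tachogram
#' this yields RR-interval dips; with 0.95 on a pulse-derived series it
#' yields heart-rate accelerations.
#'
#' @param series an [interval_series()] (should have passed the
#'   [quality_fraction()] gate).
#' @param params a [detector_params()].
#' @return An object of class `dip_detection`: list with `dips` (see
#'   [select_dips()], plus linkage columns initialised to `NA`), `params`,
#'   `n_marked`, `n_noise`, `n_groups_premerge`, and the `series` source
#'   and duration.
#' @examples
#' s <- interval_series(seq_len(120), c(rep(1000, 60), rep(1000, 55),
#'                                      rep(850, 5)))
#' detect_dips(s)
#' @export
detect_dips <- function(series, params = detector_params()) {
  stopifnot(inherits(series, "interval_series"),
            inherits(params, "detector_params"))
  base <- segment_baselines(series, params$segment_length)
  marks <- mark_subthreshold(series, base, params$effective_fraction)
  grp <- group_marks(marks, params$min_consecutive)
  # noise runs are marked but not analyzed: clear them so they can never
  # re-enter a group (or host a nadir) through merging
  kept <- rep(FALSE, length(marks))
  for (g in seq_len(nrow(grp$groups)))
    kept[grp$groups$first[g]:grp$groups$last[g]] <- TRUE
  merged <- merge_groups(grp$groups, series, params$merge_gap)
  dips <- select_dips(merged, series, kept, base)
  dips$linked_event <- rep(NA_integer_, nrow(dips))
  dips$linked_event_type <- rep(NA_character_, nrow(dips))
  dips$event_lag <- rep(NA_real_, nrow(dips))
  dips$linked_arousal <- rep(NA_integer_, nrow(dips))
  structure(list(dips = dips, params = params,
                 n_marked = sum(marks), n_noise = grp$n_noise,
                 n_groups_premerge = nrow(grp$groups),
                 source = series$source,
                 recording_duration = series$recording_duration),
            class = "dip_detection")
}

#' @export
print.dip_detection <- function(x, ...) {
  cat(sprintf(paste0("<dip_detection> %d dips (%s, threshold %.2f) over ",
                     "%.2f h; %d marked beats, %d noise runs\n"),
              nrow(x$dips), x$source, x$params$threshold_fraction,
              x$recording_duration / 3600, x$n_marked, x$n_noise))
  invisible(x)
}

#' @export
summary.dip_detection <- function(object, ...) {
  d <- object$dips
  trt_h <- object$recording_duration / 3600
  res <- list(n_dips = nrow(d),
              index = if (trt_h > 0) nrow(d) / trt_h else NA_real_,
              n_respiratory = sum(!is.na(d$linked_event)),
              n_arousal = sum(!is.na(d$linked_arousal)),
              mean_depth = if (nrow(d)) mean(d$depth_fraction) else NA_real_,
              trt_hours = trt_h)
  class(res) <- "summary.dip_detection"
  res
}

#' @export
print.summary.dip_detection <- function(x, ...) {
  cat(sprintf("dips: %d (%.2f /h); respiratory-linked %d, arousal-linked %d\n",
              x$n_dips, x$index, x$n_respiratory, x$n_arousal))
  if (!is.na(x$mean_depth))
    cat(sprintf("mean depth fraction: %.3f over %.2f h\n",
                x$mean_depth, x$trt_hours))
  invisible(x)
}

#' Plot detected dips on the tachogram
#'
#' @param x a `dip_detection`.
#' @param series the [interval_series()] it was computed from.
#' @param ... passed to [graphics::plot()].
#' @export
plot.dip_detection <- function(x, series, ...) {
  stopifnot(inherits(series, "interval_series"))
  graphics::plot(series$beat_times, series$intervals_ms, type = "l",
                 col = "grey50", xlab = "time (s)", ylab = "interval (ms)",
                 ...)
  if (any(series$artifact))
    graphics::points(series$beat_times[series$artifact],
                     series$intervals_ms[series$artifact],
                     pch = 8, col = "black")
  if (nrow(x$dips))
    graphics::points(x$dips$nadir_time, x$dips$nadir_interval,
                     pch = 19, col = "red")
  invisible(x)
}

#' Events-per-hour index
#'
#' The dip index is the number of detected dips divided by the total
#' recording time in hours (note: recording time, not sleep time).
#'
#' @param dips a `dip_detection`, or a data.frame of dips, or a count.
#' @param trt_hours total recording time in hours, > 0.
#' @return Events per hour.
#' @export
compute_index <- function(dips, trt_hours) {
  if (!is.numeric(trt_hours) || length(trt_hours) != 1 ||
      !is.finite(trt_hours) || trt_hours <= 0)
    stop("trt_hours must be a positive number of hours")
  n <- if (inherits(dips, "dip_detection")) nrow(dips$dips)
       else if (is.data.frame(dips)) nrow(dips)
       else as.numeric(dips)
  n / trt_hours
}
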
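#' Read a beat-interval CSV file
#'
#' Reads a tachogram stored as CSV with columns `time_s` and `interval_ms`
#' and an optional `artifact` column (0/1 or logical). Files must have a
#' header, use UTF-8 and '.' as the decimal separator. Times must be
#' strictly increasing.
#'
#' @param path file path.
#' @param source passed through to [interval_series()].
#' @param recording_duration optional recording duration in seconds.
#' @return An [interval_series()].
#' @seealso [write_interval_csv()]
#' @export
read_interval_csv <- function(path, source = "ecg_rri",
                              recording_duration = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "interval_ms")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("interval CSV '", path, "' is missing column(s): ",
         paste(miss, collapse = ", "))
  if (nrow(df) > 1) {
    bad <- which(diff(df$time_s) <= 0)
    if (length(bad))
      stop("non-monotone time_s in '", path, "' at row ", bad[1] + 1L)
  }
  art <- if ("artifact" %in% names(df)) as.logical(df$artifact) else FALSE
  interval_series(df$time_s, df$interval_ms, artifact = art,
                  source = source, recording_duration = recording_duration)
}

#' Write a beat-interval CSV file
#'
#' @param series an [interval_series()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_interval_csv <- function(series, path) {
  stopifnot(inherits(series, "interval_series"))
  utils::write.csv(as.data.frame(series), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read a 1-Hz pulse-rate CSV file
#'
#' Columns `time_s` and `hr_bpm`; spacing greater than 1.5 s between
#' consecutive samples is recorded in the gap mask. Non-positive pulse-rate
#' values are an error unless `permissive = TRUE`, in which case they are
#' gap-flagged (never silently dropped) and a warning reports the count.
#'
#' @param path file path.
#' @param permissive flag invalid samples instead of failing.
#' @return A [pulse_series()].
#' @seealso [write_pulse_csv()]
#' @export
read_pulse_csv <- function(path, permissive = FALSE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "hr_bpm")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("pulse CSV '", path, "' is missing column(s): ",
         paste(miss, collapse = ", "))
  gaps <- c(FALSE, diff(df$time_s) > 1.5)
  bad <- !is.finite(df$hr_bpm) | df$hr_bpm <= 0
  if (any(bad)) {
    if (!permissive)
      stop("non-positive hr_bpm in '", path, "' at row ", which(bad)[1],
           " (use permissive = TRUE to flag instead)")
    warning(sum(bad), " invalid hr_bpm sample(s) gap-flagged")
    gaps <- gaps | bad
  }
  pulse_series(df$time_s, df$hr_bpm, gap_mask = gaps)
}

#' Write a pulse-rate CSV file
#'
#' @param pulse a [pulse_series()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pulse_csv <- function(pulse, path) {
  stopifnot(inherits(pulse, "pulse_series"))
  utils::write.csv(data.frame(time_s = pulse$times, hr_bpm = pulse$hr_bpm),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# default normalization table: raw annotation strings -> controlled vocabulary
default_event_vocab <- function() {
  c("obstructive apnea" = "obstructive_apnea",
    "obstructive apnea|obstructive apnea" = "obstructive_apnea",
    "obstructive_apnea" = "obstructive_apnea",
    "central apnea" = "central_apnea",
    "central apnea|central apnea" = "central_apnea",
    "central_apnea" = "central_apnea",
    "mixed apnea" = "mixed_apnea",
    "mixed apnea|mixed apnea" = "mixed_apnea",
    "mixed_apnea" = "mixed_apnea",
    "hypopnea" = "hypopnea",
    "hypopnea|hypopnea" = "hypopnea",
    "arousal" = "arousal",
    "arousal|arousal ()" = "arousal",
    "arousal ()" = "arousal")
}

#' Read pre-scored annotations
#'
#' Loads respiratory events and arousals from either a CSV dialect
#' (columns `type`, `start`, `duration`, one row per record, `type`
#' including `"arousal"` rows) or NSRR-style annotation XML
#' (`<ScoredEvent>` elements with `EventConcept`, `Start`, `Duration`).
#' Raw type strings are normalized through a user-extendable lookup table;
#' records whose type is not in the table are skipped with a warning, and
#' the number skipped is attached as attribute `"skipped"` so that
#' loaded + skipped always equals the input record count.
#'
#' @param path file path.
#' @param dialect `"csv"` or `"nsrr_xml"`.
#' @param vocab named character vector mapping lower-cased raw type strings
#'   to the controlled vocabulary (respiratory types or `"arousal"`);
#'   entries are added to the defaults.
#' @return An [annotation_set()] with attribute `skipped`.
#' @export
read_annotations <- function(path, dialect = c("csv", "nsrr_xml"),
                             vocab = NULL) {
  dialect <- match.arg(dialect)
  tab <- default_event_vocab()
  if (!is.null(vocab)) tab[names(vocab)] <- vocab
  raw <- switch(dialect,
    csv = {
      df <- utils::read.csv(path, stringsAsFactors = FALSE)
      need <- c("type", "start", "duration")
      miss <- setdiff(need, names(df))
      if (length(miss))
        stop("annotation CSV '", path, "' is missing column(s): ",
             paste(miss, collapse = ", "))
      df[, need]
    },
    nsrr_xml = {
      doc <- xml2::read_xml(path)  # malformed XML errors here
      ev <- xml2::xml_find_all(doc, ".//ScoredEvent")
      data.frame(
        type = xml2::xml_text(xml2::xml_find_first(ev, "./EventConcept")),
        start = as.numeric(
          xml2::xml_text(xml2::xml_find_first(ev, "./Start"))),
        duration = as.numeric(
          xml2::xml_text(xml2::xml_find_first(ev, "./Duration"))),
        stringsAsFactors = FALSE)
    })
  norm <- unname(tab[tolower(trimws(raw$type))])
  skipped <- sum(is.na(norm))
  if (skipped > 0)
    warning(skipped, " annotation record(s) with unrecognized type skipped: ",
            paste(unique(raw$type[is.na(norm)]), collapse = ", "))
  keep <- !is.na(norm)
  raw <- raw[keep, , drop = FALSE]
  norm <- norm[keep]
  is_arousal <- norm == "arousal"
  out <- annotation_set(
    respiratory_events = data.frame(event_type = norm[!is_arousal],
                                    start = raw$start[!is_arousal],
                                    duration = raw$duration[!is_arousal]),
    arousals = data.frame(start = raw$start[is_arousal],
                          duration = raw$duration[is_arousal]))
  attr(out, "skipped") <- skipped
  out
}

#' Write annotations as CSV
#'
#' Writes the CSV annotation dialect read by [read_annotations()].
#'
#' @param annotations an [annotation_set()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_annotations_csv <- function(annotations, path) {
  stopifnot(inherits(annotations, "annotation_set"))
  re <- annotations$respiratory_events
  ar <- annotations$arousals
  df <- rbind(
    data.frame(type = re$event_type, start = re$start,
               duration = re$duration),
    if (nrow(ar)) data.frame(type = "arousal", start = ar$start,
                             duration = ar$duration))
  df <- df[order(df$start), , drop = FALSE]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write annotations as NSRR-style XML
#'
#' @param annotations an [annotation_set()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_annotations_xml <- function(annotations, path) {
  stopifnot(inherits(annotations, "annotation_set"))
  pretty <- c(obstructive_apnea = "Obstructive apnea|Obstructive Apnea",
              central_apnea = "Central apnea|Central Apnea",
              mixed_apnea = "Mixed apnea|Mixed Apnea",
              hypopnea = "Hypopnea|Hypopnea",
              arousal = "Arousal|Arousal ()")
  re <- annotations$respiratory_events
  ar <- annotations$arousals
  recs <- rbind(
    data.frame(concept = unname(pretty[re$event_type]), start = re$start,
               duration = re$duration,
               type = rep("Respiratory|Respiratory", nrow(re))),
    if (nrow(ar)) data.frame(concept = unname(pretty["arousal"]),
                             start = ar$start, duration = ar$duration,
                             type = "Arousals|Arousals"))
  doc <- xml2::xml_new_root("PSGAnnotation")
  events <- xml2::xml_add_child(doc, "ScoredEvents")
  if (!is.null(recs) && nrow(recs)) {
    recs <- recs[order(recs$start), , drop = FALSE]
    for (i in seq_len(nrow(recs))) {
      se <- xml2::xml_add_child(events, "ScoredEvent")
      xml2::xml_add_child(se, "EventType", recs$type[i])
      xml2::xml_add_child(se, "EventConcept", recs$concept[i])
      xml2::xml_add_child(se, "Start", format(recs$start[i], digits = 12))
      xml2::xml_add_child(se, "Duration",
                          format(recs$duration[i], digits = 12))
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read a cohort metadata CSV
#'
#' Expects one row per study with at least `study_id` and
#' `total_recording_time` (hours); `total_sleep_time`, `npsg_ahi`, `age`,
#' `sex`, `bmi` are optional.
#'
#' @param path file path.
#' @return A data.frame, one row per study.
#' @export
read_metadata_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("study_id", "total_recording_time")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("metadata CSV '", path, "' is missing column(s): ",
         paste(miss, collapse = ", "))
  df
}
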
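#' Parameters of the synthetic sleep-study generator
#'
#' Defines the synthetic study the generator emulates: a 7-8 h overnight
#' recording with respiratory events scored at a given hourly rate, each
#' event followed (with probability `response_prob`, after a short lag)
#' by a transient heart-rate acceleration — a run of `dip_width_beats`
#' beats whose interval drops to `dip_depth` of the local baseline —
#' plus spontaneous accelerations, arousal-locked accelerations, beat
#' noise and planted ectopic (non-physiological) intervals.
#'
#' Planted responses are separated by construction (a refractory margin
#' covering the event, its 30-s linkage window and the 10-s merge gap) so
#' that under noise-free settings every planted response produces exactly
#' one detectable, correctly linkable dip group.
#'
#' @param trt_hours total recording time, hours.
#' @param event_rate scored respiratory events per hour of recording.
#' @param event_duration_mean,event_duration_jitter event duration mean
#'   and half-range in seconds (uniform jitter, floored at 10 s).
#' @param response_prob probability a scored event (or arousal) produces
#'   a heart-rate response.
#' @param response_lag numeric length 2: uniform range (s) of the lag from
#'   event end to the start of the response; clipped so the whole response
#'   stays inside the 30-s linkage window.
#' @param dip_depth planted interval as a fraction of the local baseline.
#' @param dip_width_beats beats per planted response (>= 2).
#' @param spontaneous_dip_rate per-hour rate of responses not tied to any
#'   scored event or arousal.
#' @param baseline_rri_ms baseline RR interval, ms.
#' @param rri_noise_sd per-beat Gaussian noise on the interval, ms.
#' @param artifact_fraction per-beat probability of entering a
#'   signal-dropout burst: a stretch of 2-6 s of non-physiological
#'   intervals (2050-3500 ms, outside the default physiological limits),
#'   emulating periods of unanalyzable ECG. The planted unanalyzable time
#'   is recorded in the ground truth for quality-gate checks.
#' @param arousal_rate scored arousals per hour.
#' @param seed integer seed; every simulate call is fully reproducible.
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(trt_hours = 8, event_rate = 15,
                       event_duration_mean = 25, event_duration_jitter = 10,
                       response_prob = 0.9, response_lag = c(5, 20),
                       dip_depth = 0.85, dip_width_beats = 4,
                       spontaneous_dip_rate = 2, baseline_rri_ms = 1000,
                       rri_noise_sd = 25, artifact_fraction = 0.01,
                       arousal_rate = 5, seed = 1L) {
  stopifnot(trt_hours > 0, event_rate >= 0,
            response_prob >= 0, response_prob <= 1,
            length(response_lag) == 2, all(response_lag >= 0),
            all(response_lag < 30), dip_depth > 0, dip_depth < 1,
            dip_width_beats >= 2, spontaneous_dip_rate >= 0,
            baseline_rri_ms > 0, rri_noise_sd >= 0,
            artifact_fraction >= 0, artifact_fraction <= 1,
            arousal_rate >= 0)
  structure(as.list(environment()), class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat(sprintf(paste0("<sim_params> %.1f h, %g events/h (response p=%.2f, ",
                     "depth %.2f x %d beats), %g spontaneous/h, ",
                     "%g arousals/h, noise sd %g ms, seed %d\n"),
              x$trt_hours, x$event_rate, x$response_prob, x$dip_depth,
              x$dip_width_beats, x$spontaneous_dip_rate, x$arousal_rate,
              x$rri_noise_sd, x$seed))
  invisible(x)
}

# accept candidate interval [s, e] iff it intersects no interval in `zones`
# (2-column matrix); returns TRUE/FALSE
zone_free <- function(s, e, zones) {
  if (is.null(zones) || nrow(zones) == 0) return(TRUE)
  all(e < zones[, 1] | s > zones[, 2])
}

#' Simulate one synthetic sleep study with known ground truth
#'
#' Generates a full study: the scored annotations, the beat-to-beat
#' RR-interval tachogram carrying time-locked responses, the 1-Hz
#' pulse-rate trace derived from the tachogram (so ECG- and pulse-based
#' detection are comparable on the same study), metadata, and a ground
#' truth table listing every planted response with its owning event.
#'
#' Events are placed by a thinned Poisson (renewal) process with a
#' refractory margin so events never overlap and responses never merge;
#' spontaneous responses are placed outside every event's linkage window.
#'
#' @param params a [sim_params()].
#' @return A list of class `sim_study`: `series` ([interval_series()]),
#'   `pulse` ([pulse_series()]), `annotations` ([annotation_set()]),
#'   `meta` ([recording_meta()]), and `truth` (list with `dips`
#'   data.frame — columns `kind`, `anchor`, `start`, `end` —, event
#'   count, artifact beat indices, the params and seed).
#' @export
simulate_study <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  p <- params
  set.seed(p$seed)
  trt_s <- p$trt_hours * 3600
  dip_span <- p$dip_width_beats * p$dip_depth * p$baseline_rri_ms / 1000
  margin <- 30 + dip_span + 12  # linkage window + response + merge slack
  if (p$event_rate * p$trt_hours * (p$event_duration_mean + margin) >
      0.9 * trt_s)
    stop("impossible packing: event rate x (duration + response margin) ",
         "exceeds the recording")

  # --- respiratory events: thinned Poisson with refractory margin
  ev_start <- numeric(0); ev_dur <- numeric(0)
  if (p$event_rate > 0) {
    t <- 60 + stats::rexp(1, p$event_rate / 3600)
    guard <- -Inf
    while (t < trt_s - p$event_duration_mean - margin - 60) {
      if (t >= guard) {
        dur <- max(10, p$event_duration_mean +
                     stats::runif(1, -p$event_duration_jitter,
                                  p$event_duration_jitter))
        ev_start <- c(ev_start, t); ev_dur <- c(ev_dur, dur)
        guard <- t + dur + margin
      }
      t <- t + stats::rexp(1, p$event_rate / 3600)
    }
  }
  n_ev <- length(ev_start)
  ev_type <- if (n_ev) sample(RESP_EVENT_TYPES, n_ev, replace = TRUE,
                              prob = c(0.35, 0.08, 0.02, 0.55)) else character(0)
  # time spans inside which a dip nadir would be respiratory-linked
  ev_zone <- cbind(ev_start, ev_start + ev_dur + 30)

  truth <- data.frame(kind = character(0), anchor = integer(0),
                      start = numeric(0), end = numeric(0))
  add_truth <- function(kind, anchor, s) {
    rbind(truth, data.frame(kind = kind, anchor = anchor, start = s,
                            end = s + dip_span))
  }
  for (i in seq_len(n_ev)) {
    if (stats::runif(1) < p$response_prob) {
      lag <- stats::runif(1, p$response_lag[1], p$response_lag[2])
      lag <- min(lag, max(0, 29 - dip_span))
      truth <- add_truth("respiratory", i, ev_start[i] + ev_dur[i] + lag)
    }
  }

  # --- arousals, placed clear of event linkage zones
  ar_start <- numeric(0); ar_dur <- numeric(0)
  if (p$arousal_rate > 0) {
    t <- 90 + stats::rexp(1, p$arousal_rate / 3600)
    busy <- rbind(ev_zone, cbind(truth$start - 12, truth$end + 12))
    while (t < trt_s - 120) {
      dur <- max(3, stats::rnorm(1, 5, 1))
      if (zone_free(t - 12, t + dur + 30 + dip_span + 12, busy)) {
        ar_start <- c(ar_start, t); ar_dur <- c(ar_dur, dur)
        if (stats::runif(1) < p$response_prob) {
          lag <- stats::runif(1, 0, 5)
          truth <- add_truth("arousal", length(ar_start), t + dur + lag)
        }
        busy <- rbind(busy, cbind(t - 12, t + dur + 30 + dip_span + 12))
      }
      t <- t + stats::rexp(1, p$arousal_rate / 3600)
    }
  }

  # --- spontaneous responses, clear of every linkage zone
  if (p$spontaneous_dip_rate > 0) {
    busy <- rbind(ev_zone,
                  cbind(truth$start - 12, truth$end + 12),
                  if (length(ar_start))
                    cbind(ar_start - 12, ar_start + ar_dur + 30 + 12))
    t <- 120 + stats::rexp(1, p$spontaneous_dip_rate / 3600)
    while (t < trt_s - 120) {
      if (zone_free(t - 12, t + dip_span + 12, busy)) {
        truth <- add_truth("spontaneous", NA_integer_, t)
        busy <- rbind(busy, cbind(t - 12, t + dip_span + 12))
      }
      t <- t + stats::rexp(1, p$spontaneous_dip_rate / 3600)
    }
  }
  truth <- truth[order(truth$start), , drop = FALSE]
  rownames(truth) <- NULL

  # --- beat-by-beat tachogram
  n_est <- ceiling(trt_s / (p$baseline_rri_ms / 1000)) + 100
  iv <- numeric(n_est); tt <- numeric(n_est)
  artifact_idx <- integer(0)
  noise_seconds <- 0
  cur <- 0; i <- 0L; d <- 1L
  nd <- nrow(truth)
  truth$first_beat <- rep(NA_integer_, nrow(truth))
  truth$last_beat <- rep(NA_integer_, nrow(truth))
  while (cur < trt_s) {
    i <- i + 1L
    if (d <= nd && cur >= truth$start[d]) {
      # plant the whole response as one run of shortened beats
      for (w in seq_len(p$dip_width_beats)) {
        v <- p$dip_depth * p$baseline_rri_ms
        cur <- cur + v / 1000
        iv[i] <- v; tt[i] <- cur
        if (w < p$dip_width_beats) i <- i + 1L
      }
      truth$first_beat[d] <- i - p$dip_width_beats + 1L
      truth$last_beat[d] <- i
      d <- d + 1L
    } else if (p$artifact_fraction > 0 &&
               stats::runif(1) < p$artifact_fraction &&
               (d > nd || cur + 8 < truth$start[d])) {
      # signal-dropout burst: unanalyzable stretch of long garbage intervals
      blen <- stats::runif(1, 2, 6)
      t_end <- cur + blen
      first <- TRUE
      while (cur < t_end && cur < trt_s) {
        if (!first) i <- i + 1L
        v <- stats::runif(1, 2050, 3500)
        cur <- cur + v / 1000
        iv[i] <- v; tt[i] <- cur
        artifact_idx <- c(artifact_idx, i)
        noise_seconds <- noise_seconds + v / 1000
        first <- FALSE
      }
    } else {
      v <- p$baseline_rri_ms + stats::rnorm(1, 0, p$rri_noise_sd)
      v <- max(v, 0.92 * p$baseline_rri_ms)  # keep noise clear of threshold
      v <- min(v, 1.08 * p$baseline_rri_ms)
      cur <- cur + v / 1000
      iv[i] <- v; tt[i] <- cur
    }
  }
  n <- i
  if (tt[n] > trt_s) n <- n - 1L  # drop the beat that overshoots the end
  series <- interval_series(tt[1:n], iv[1:n], source = "ecg_rri",
                            recording_duration = trt_s)
  truth$first_time <- series$beat_times[truth$first_beat]
  truth$last_time <- series$beat_times[truth$last_beat]

  # --- 1-Hz pulse trace: instantaneous HR of the beat covering each second
  pt <- 0:(floor(trt_s) - 1)
  covering <- findInterval(pt, c(0, series$beat_times), left.open = TRUE)
  covering <- pmin(pmax(covering, 1L), n)
  pulse <- pulse_series(pt, 60000 / series$intervals_ms[covering])

  ann <- annotation_set(
    respiratory_events = data.frame(event_type = ev_type, start = ev_start,
                                    duration = ev_dur),
    arousals = data.frame(start = ar_start, duration = ar_dur))
  tst <- 0.8 * p$trt_hours
  meta <- recording_meta(study_id = sprintf("synthetic-%06d", p$seed),
                         total_recording_time = p$trt_hours,
                         total_sleep_time = tst,
                         npsg_ahi = if (tst > 0) n_ev / tst else NA_real_)
  structure(list(series = series, pulse = pulse, annotations = ann,
                 meta = meta,
                 truth = list(dips = truth, n_events = n_ev,
                              artifact_beats = artifact_idx,
                              noise_seconds = noise_seconds,
                              params = p, seed = p$seed)),
            class = "sim_study")
}

#' @export
print.sim_study <- function(x, ...) {
  cat(sprintf(paste0("<sim_study> %s: %d beats, %d scored events, ",
                     "%d arousals, %d planted responses\n"),
              x$meta$study_id, n_beats(x$series),
              nrow(x$annotations$respiratory_events),
              nrow(x$annotations$arousals), nrow(x$truth$dips)))
  invisible(x)
}

#' Simulate a cohort of studies
#'
#' Draws per-study severity (AHI) from a three-bin mixture (below 5,
#' 5-15, above 15 events/h) with configurable proportions, together with
#' demographics, and produces per-study index values either by running
#' the full signal pipeline per study (`simulate_signals = TRUE`) or, by
#' default, from a calibrated response model (index = detectable response
#' rate over recording time plus noise) that preserves the structural
#' relations between the indices without per-study signal synthesis.
#'
#' @param n number of studies.
#' @param ahi_probs proportions of the `<5`, `5-15`, `>15` AHI bins.
#' @param params_base a [sim_params()] supplying response probability,
#'   spontaneous and arousal rates (and, with signals, all signal
#'   settings).
#' @param seed integer seed.
#' @param simulate_signals run [simulate_study()] + [detect_dips()] +
#'   [summarize_study()] per study instead of the response model.
#' @param path optional path; when given the cohort table is written as
#'   CSV.
#' @return A data.frame with columns `study_id`, `npsg_ahi`,
#'   `total_recording_time`, `total_sleep_time`, `age`, `sex`, `bmi`,
#'   `total_rrdi`, `re_rrdi`, `total_hrai`, `re_hrai`.
#' @export
simulate_cohort <- function(n, ahi_probs = c(0.11, 0.31, 0.58),
                            params_base = sim_params(), seed = 1L,
                            simulate_signals = FALSE, path = NULL) {
  stopifnot(n >= 1, length(ahi_probs) == 3)
  set.seed(seed)
  ahi_probs <- ahi_probs / sum(ahi_probs)
  bin <- sample.int(3, n, replace = TRUE, prob = ahi_probs)
  ahi <- ifelse(bin == 1, stats::runif(n, 0.4, 5),
         ifelse(bin == 2, stats::runif(n, 5, 15),
                pmin(100, 15 + stats::rexp(n, 1 / 12))))
  trt <- pmin(9, pmax(6, stats::rnorm(n, 7.8, 1)))
  tst <- trt * stats::runif(n, 0.75, 0.85)
  age <- round(pmin(90, pmax(40, stats::rnorm(n, 62, 9))))
  sex <- sample(c("male", "female"), n, replace = TRUE,
                prob = c(0.39, 0.61))
  bmi <- round(pmin(50, pmax(17, stats::rnorm(n, 28, 5))), 1)
  p <- params_base
  if (simulate_signals) {
    res <- vector("list", n)
    for (i in seq_len(n)) {
      pi <- p
      pi$trt_hours <- trt[i]
      pi$event_rate <- ahi[i] * tst[i] / trt[i]
      pi$seed <- sample.int(.Machine$integer.max, 1)
      st <- simulate_study(pi)
      det_r <- detect_dips(exclude_artifacts(st$series),
                           detector_params(0.90))
      det_p <- detect_dips(pulse_to_intervals(st$pulse),
                           detector_params(0.95))
      res[[i]] <- summarize_study(det_r, det_p, st$annotations, st$meta)
    }
    total_rrdi <- vapply(res, `[[`, numeric(1), "total_rrdi")
    re_rrdi <- vapply(res, `[[`, numeric(1), "re_rrdi")
    total_hrai <- vapply(res, `[[`, numeric(1), "total_hrai")
    re_hrai <- vapply(res, `[[`, numeric(1), "re_hrai")
  } else {
    # response model: events occur during sleep; responses detected with
    # probability response_prob; spontaneous + arousal responses add to
    # the totals; pulse detection is less noisy than ECG detection
    ev_per_h_trt <- ahi * tst / trt
    re_hrai <- pmax(0, ev_per_h_trt * p$response_prob +
                      stats::rnorm(n, 0, 1))
    re_rrdi <- pmax(0, 0.85 * ev_per_h_trt * p$response_prob +
                      stats::rnorm(n, 0, 2))
    extra <- p$spontaneous_dip_rate +
      p$arousal_rate * p$response_prob
    total_hrai <- re_hrai + pmax(0, extra + stats::rnorm(n, 0, 1))
    total_rrdi <- re_rrdi + pmax(0, extra + stats::rnorm(n, 0, 2))
  }
  out <- data.frame(study_id = sprintf("synthetic-%05d", seq_len(n)),
                    npsg_ahi = ahi, total_recording_time = trt,
                    total_sleep_time = tst, age = age, sex = sex,
                    bmi = bmi, total_rrdi = total_rrdi,
                    re_rrdi = re_rrdi, total_hrai = total_hrai,
                    re_hrai = re_hrai)
  if (!is.null(path))
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  out
}
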
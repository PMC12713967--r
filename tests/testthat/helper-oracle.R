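# Independent straight-line reference implementation of the dip detector,
# written as a single pass with per-beat window recomputation. Deliberately
# structured differently from the package pipeline so the two can serve as
# cross-checks on random inputs.
oracle_detect <- function(series, params) {
  t <- series$beat_times
  iv <- series$intervals_ms
  art <- series$artifact
  n <- length(t)
  L <- params$segment_length
  f <- params$effective_fraction
  win <- floor(t / L)

  marks <- logical(n)
  for (i in seq_len(n)) {
    if (art[i]) next
    same <- !art & win == win[i]
    if (sum(same) < 3) next
    marks[i] <- iv[i] < f * mean(iv[same])
  }

  # maximal runs of marked beats, dropping short ones
  runs <- list()
  i <- 1L
  while (i <= n) {
    if (marks[i]) {
      j <- i
      while (j < n && marks[j + 1L]) j <- j + 1L
      if (j - i + 1L >= params$min_consecutive)
        runs[[length(runs) + 1L]] <- i:j
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }

  # transitive left-to-right merge on marked-beat time gaps (strict <)
  merged <- list()
  for (r in runs) {
    if (length(merged) > 0) {
      prev <- merged[[length(merged)]]
      if (t[r[1]] - t[prev[length(prev)]] < params$merge_gap) {
        merged[[length(merged)]] <- c(prev, r)
        next
      }
    }
    merged[[length(merged) + 1L]] <- r
  }

  dips <- data.frame(group_start = numeric(0), group_end = numeric(0),
                     nadir_time = numeric(0), nadir_interval = numeric(0),
                     n_beats = integer(0))
  for (g in merged) {
    best <- g[1]
    for (k in g) if (iv[k] < iv[best]) best <- k
    dips[nrow(dips) + 1L, ] <- list(t[g[1]], t[g[length(g)]], t[best],
                                    iv[best], length(g))
  }
  list(marks = marks, n_runs = length(runs), dips = dips)
}

# random interval series of 1-10 minutes with enough interval spread that
# sub-threshold marks, short runs and near-merge gaps all occur
random_series <- function() {
  dur <- stats::runif(1, 60, 600)
  gaps <- stats::runif(ceiling(dur / 0.4), 0.4, 1.6)
  tt <- cumsum(gaps)
  tt <- tt[tt <= dur]
  n <- length(tt)
  iv <- 1000 * exp(stats::rnorm(n, 0, 0.12))
  # occasional deep drops so groups form
  drop <- stats::runif(n) < 0.08
  iv[drop] <- iv[drop] * stats::runif(sum(drop), 0.6, 0.92)
  art <- stats::runif(n) < 0.05
  interval_series(tt, iv, artifact = art, recording_duration = dur)
}

# minimal dip table with the given nadir times, for linkage tests
fake_dips <- function(nadirs) {
  n <- length(nadirs)
  data.frame(group_start = nadirs - 1, group_end = nadirs + 1,
             nadir_time = nadirs, nadir_interval = rep(850, n),
             baseline_interval = rep(1000, n),
             depth_fraction = rep(0.85, n), n_beats = rep(3L, n))
}

# one noise-free planted study used across tests (spec of the clean
# recovery condition: 8 h, 15 events/h, certain response, depth 0.85,
# width 4 beats, lag < 30 s)
clean_sim_params <- function(seed = 11L) {
  sim_params(trt_hours = 8, event_rate = 15, response_prob = 1,
             dip_depth = 0.85, dip_width_beats = 4,
             response_lag = c(5, 20), spontaneous_dip_rate = 0,
             rri_noise_sd = 0, artifact_fraction = 0, arousal_rate = 0,
             seed = seed)
}
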
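# a window of 60 beats, optionally with a planted run of shortened beats
one_window <- function(dip_at = NULL, width = 5, depth_ms = 850,
                       base = 1000) {
  iv <- rep(base, 60)
  if (!is.null(dip_at)) iv[dip_at:(dip_at + width - 1)] <- depth_ms
  interval_series(seq(0.5, 59.5, 1), iv, recording_duration = 60)
}

test_that("segment baselines are window means of valid beats", {
  s <- one_window()
  expect_equal(segment_baselines(s), rep(1000, 60))
  # window of (1000 x 58, 500, 500): mean 983.33 for every beat
  iv <- c(rep(1000, 58), 500, 500)
  s2 <- interval_series(seq(0.5, 59.5, 1), iv)
  expect_equal(segment_baselines(s2), rep(58000 / 60 + 1000 / 60, 60),
               tolerance = 1e-12)
  # artifacts are excluded from the mean and get NA baselines
  s3 <- interval_series(seq(0.5, 59.5, 1), iv,
                        artifact = c(rep(FALSE, 58), TRUE, TRUE))
  b3 <- segment_baselines(s3)
  expect_equal(b3[1:58], rep(1000, 58))
  expect_true(all(is.na(b3[59:60])))
  # windows with < 3 valid beats yield no baseline
  s4 <- interval_series(c(0.5, 1.5, 61, 62), rep(1000, 4))
  expect_equal(is.na(segment_baselines(s4)), c(TRUE, TRUE, TRUE, TRUE))
  # brute-force window-by-window recomputation on a long random series
  set.seed(10)
  tt <- cumsum(runif(5000, 0.5, 1.5))
  iv5 <- runif(5000, 600, 1400)
  art <- runif(5000) < 0.05
  s5 <- interval_series(tt, iv5, artifact = art)
  b5 <- segment_baselines(s5)
  w <- floor(tt / 60)
  for (k in unique(w)) {
    sel <- w == k & !art
    expected <- if (sum(sel) >= 3) mean(iv5[sel]) else NA_real_
    expect_true(all(b5[sel] == expected | (is.na(b5[sel]) &
                                             is.na(expected))))
    expect_true(all(is.na(b5[w == k & art])))
  }
})

test_that("marking is strictly below threshold x baseline", {
  s <- interval_series(1:2, c(899, 900))
  b <- c(1000, 1000)
  expect_equal(mark_subthreshold(s, b, 0.90), c(TRUE, FALSE))
  # artifacts and NA baselines are never marked
  s2 <- interval_series(1:3, c(500, 500, 500), artifact = c(TRUE, FALSE, FALSE))
  expect_equal(mark_subthreshold(s2, c(1000, 1000, NA), 0.9),
               c(FALSE, TRUE, FALSE))
  # pointwise oracle on random input
  set.seed(11)
  iv <- runif(500, 500, 1500)
  art <- runif(500) < 0.1
  b3 <- runif(500, 800, 1200)
  b3[sample(500, 30)] <- NA
  s3 <- interval_series(cumsum(runif(500, 0.5, 1.5)), iv, artifact = art)
  m <- mark_subthreshold(s3, b3, 0.9)
  for (i in seq_len(500)) {
    expect_identical(m[i],
                     !art[i] && !is.na(b3[i]) && iv[i] < 0.9 * b3[i])
  }
})

test_that("grouping keeps runs of >= min_consecutive and counts noise", {
  g <- group_marks(c(FALSE, TRUE, TRUE, FALSE))
  expect_equal(nrow(g$groups), 1)
  expect_equal(g$groups$first, 2)
  expect_equal(g$groups$last, 3)
  expect_equal(g$n_noise, 0)
  g2 <- group_marks(c(FALSE, TRUE, FALSE, TRUE, FALSE))
  expect_equal(nrow(g2$groups), 0)
  expect_equal(g2$n_noise, 2)
  # run-length-encoding oracle over random mark vectors
  set.seed(12)
  for (trial in 1:1000) {
    m <- runif(sample(5:60, 1)) < 0.4
    g3 <- group_marks(m, 2)
    r <- rle(m)
    expect_equal(nrow(g3$groups), sum(r$values & r$lengths >= 2))
    expect_equal(g3$n_noise, sum(r$values & r$lengths == 1))
    if (nrow(g3$groups)) {
      expect_true(all(m[unlist(Map(seq, g3$groups$first, g3$groups$last))]))
    }
  }
})

test_that("merging uses strict sub-gap rule and is transitive", {
  mk <- function(times) interval_series(times, rep(800, length(times)))
  # two 2-beat groups 9.9 s apart -> merged
  s <- mk(c(1, 2, 11.9, 12.9))
  g <- data.frame(first = c(1, 3), last = c(2, 4))
  expect_equal(nrow(merge_groups(g, s, 10)), 1)
  # exactly 10.0 s apart -> not merged
  s2 <- mk(c(1, 2, 12, 13))
  expect_equal(nrow(merge_groups(g, s2, 10)), 2)
  # chain with gaps 5 and 5 -> one group by transitivity
  s3 <- mk(c(1, 2, 7, 8, 13, 14))
  g3 <- data.frame(first = c(1, 3, 5), last = c(2, 4, 6))
  m3 <- merge_groups(g3, s3, 10)
  expect_equal(nrow(m3), 1)
  expect_equal(m3$first, 1)
  expect_equal(m3$last, 6)
  # enumerated fixed-point oracle over all small gap patterns (gaps on a
  # binary-exact 0.5 grid so time subtraction is exact at the boundary)
  for (g1 in c(4, 9.5, 10, 10.5)) {
    for (g2 in c(4, 9.5, 10, 10.5)) {
      t1 <- c(0, 1)
      t2 <- t1[2] + g1 + c(0, 1)
      t3 <- t2[2] + g2 + c(0, 1)
      sM <- mk(c(t1, t2, t3))
      gM <- data.frame(first = c(1, 3, 5), last = c(2, 4, 6))
      got <- nrow(merge_groups(gM, sM, 10))
      expected <- 3 - (g1 < 10) - (g2 < 10)
      expect_equal(got, expected)
    }
  }
})

test_that("dip selection takes the earliest minimal marked beat", {
  s <- interval_series(1:3, c(850, 800, 870))
  g <- data.frame(first = 1, last = 3)
  d <- select_dips(g, s, marks = rep(TRUE, 3), baselines = rep(1000, 3))
  expect_equal(d$nadir_interval, 800)
  expect_equal(d$nadir_time, 2)
  expect_equal(d$depth_fraction, 0.8)
  # tie -> earlier beat
  s2 <- interval_series(1:2, c(800, 800))
  d2 <- select_dips(data.frame(first = 1, last = 2), s2, rep(TRUE, 2),
                    rep(1000, 2))
  expect_equal(d2$nadir_time, 1)
  # unmarked absorbed beats cannot host the nadir
  s3 <- interval_series(1:3, c(850, 700, 860))
  d3 <- select_dips(data.frame(first = 1, last = 3), s3,
                    marks = c(TRUE, FALSE, TRUE), baselines = rep(1000, 3))
  expect_equal(d3$nadir_interval, 850)
  expect_equal(d3$n_beats, 2)
})

test_that("full pipeline matches the hand-computed single-window case", {
  expect_equal(nrow(detect_dips(one_window())$dips), 0)
  s <- one_window(dip_at = 20, width = 5, depth_ms = 850)
  det <- detect_dips(s)
  expect_equal(nrow(det$dips), 1)
  expect_equal(det$dips$nadir_interval, 850)
  expect_equal(det$dips$baseline_interval, 987.5)  # (55*1000 + 5*850)/60
  expect_equal(det$dips$depth_fraction, 850 / 987.5)
  expect_equal(det$dips$n_beats, 5)
})

test_that("detector is scale invariant and monotone in threshold", {
  set.seed(13)
  for (trial in 1:20) {
    s <- random_series()
    p <- detector_params(0.90)
    d1 <- detect_dips(s, p)
    c_ <- runif(1, 0.3, 3)
    s2 <- interval_series(s$beat_times, s$intervals_ms * c_,
                          artifact = s$artifact,
                          recording_duration = s$recording_duration)
    d2 <- detect_dips(s2, p)
    expect_equal(nrow(d2$dips), nrow(d1$dips))
    expect_equal(d2$dips$nadir_time, d1$dips$nadir_time)
    # lowering the threshold never adds marks
    b <- segment_baselines(s)
    m_hi <- mark_subthreshold(s, b, 0.90)
    m_lo <- mark_subthreshold(s, b, 0.80)
    expect_true(all(m_hi[m_lo]))
    # dips never outnumber pre-merge groups
    expect_lte(nrow(d1$dips), d1$n_groups_premerge)
  }
})

test_that("pulse detection at 0.95 equals a >5.26% heart-rate rise rule", {
  set.seed(14)
  hr <- runif(600, 50, 110)
  p <- pulse_series(seq_along(hr) - 1, hr)
  s <- pulse_to_intervals(p)
  b <- segment_baselines(s)
  m <- mark_subthreshold(s, b, 0.95)
  hr_base <- 60000 / b
  expect_identical(m, !is.na(b) & hr > hr_base / 0.95)
})

test_that("the HR-relative threshold switch re-expresses the 5% rule", {
  p <- detector_params(0.95, hr_relative = TRUE)
  expect_equal(p$effective_fraction, 1 / 1.05)
  s <- interval_series(1:2, c(953, 951))
  b <- c(1000, 1000)
  # 1/1.05 = 0.95238...: 953 not marked, 951 marked
  expect_equal(mark_subthreshold(s, b, p$effective_fraction),
               c(FALSE, TRUE))
})

test_that("index arithmetic divides dip count by recording hours", {
  expect_equal(compute_index(10, 2), 5)
  expect_equal(compute_index(0, 3), 0)
  expect_equal(compute_index(34, 7.8), 34 / 7.8)
  expect_error(compute_index(5, 0), "positive")
  det <- detect_dips(one_window(dip_at = 10))
  expect_equal(compute_index(det, 1 / 60), 60)
})
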
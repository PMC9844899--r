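test_that("range series handles constant, alternating and partial windows", {
  w <- waveform(rep(0.5, 1600), 16000)
  expect_true(all(compute_range_series(w, 0.01) == 0))
  w2 <- waveform(rep(c(1, -1), 808), 16000)  # 1616 samples: partial window dropped
  r2 <- compute_range_series(w2, 0.01)
  expect_length(r2, 10)
  expect_true(all(r2 == 2))
  expect_error(compute_range_series(waveform(numeric(1), 16000), 0.01),
               "shorter")
})

test_that("Scott's rule fixes the bin width in closed form", {
  x <- as.numeric(scale(rnorm(1000)))  # sd exactly 1
  cal <- calibrate_cutoff(x - min(x), strategy = "index:1")
  expect_equal(cal$bin_width, 3.49 * 1000^(-1 / 3), tolerance = 1e-12)
})

test_that("valley calibration separates a clean bimodal mixture", {
  set.seed(1)
  ranges <- c(runif(6000, 0, 0.01), runif(4000, 0.2, 1))
  cal <- calibrate_cutoff(ranges, strategy = "valley")
  expect_gt(cal$cutoff, 0.01)
  expect_lt(cal$cutoff, 0.2)
  # manual override: cutoff is the upper edge of the requested bin
  cal3 <- calibrate_cutoff(ranges, strategy = "index:3")
  expect_equal(cal3$cutoff, cal3$breaks[4])
  expect_identical(cal3$cutoff_bin_index, 3L)
  expect_error(calibrate_cutoff(rep(0.3, 500)), "no speech")
  expect_error(calibrate_cutoff(ranges[1:50]), "at least 100")
})

test_that("silence classification applies the cutoff to 0.1-s windows", {
  cal <- structure(list(cutoff = 0.05, eval_window = 0.1),
                   class = "silence_calibration")
  silent <- waveform(rep(0, 8000), 8000)
  expect_true(all(classify_silence(silent, cal)))
  set.seed(2)
  noisy <- waveform(runif(8000, -0.5, 0.5), 8000)
  cal0 <- structure(list(cutoff = 0, eval_window = 0.1),
                    class = "silence_calibration")
  expect_false(any(classify_silence(noisy, cal0)))
})

test_that("silent runs merge into episodes on the window grid", {
  ep <- merge_to_episodes(c(FALSE, TRUE, TRUE, TRUE, FALSE), window = 0.1)
  expect_equal(ep, data.frame(start = 0.1, end = 0.4))
  expect_equal(nrow(merge_to_episodes(rep(FALSE, 10), window = 0.1)), 0)
  # runs below min_duration are dropped
  ep2 <- merge_to_episodes(c(TRUE, FALSE, TRUE, TRUE, TRUE, TRUE),
                           window = 0.1, min_duration = 0.3)
  expect_equal(ep2, data.frame(start = 0.2, end = 0.6))
})

test_that("the >= 3 s silence filter is inclusive and shrinking", {
  ep <- data.frame(start = c(0, 10, 20), end = c(1, 14, 23))
  f <- apply_min_duration_filter(ep, 3)
  expect_equal(f$start, c(10, 20))  # the 4-s and the exactly-3-s episodes
  expect_equal(apply_min_duration_filter(ep, 0.1), ep)
  expect_error(apply_min_duration_filter(ep, 0), "positive")
  set.seed(3)
  for (i in 1:20) {
    n <- sample(1:30, 1)
    durs <- runif(n, 0.1, 5)
    gaps <- runif(n, 0.01, 4)
    s <- cumsum(gaps + c(0, durs[-n]))
    ep <- data.frame(start = s, end = s + durs)
    thr <- runif(1, 0.1, 5)
    expect_lte(episode_total(apply_min_duration_filter(ep, thr)),
               episode_total(ep))
  }
})

test_that("raising the cutoff never decreases total silent time", {
  s <- rendered_session()
  r <- compute_range_series(s$wave, 0.1)
  prev <- -1
  for (cut in quantile(r, c(0.05, 0.25, 0.5, 0.75, 0.95))) {
    tot <- sum(r <= cut) * 0.1
    expect_gte(tot, prev)
    prev <- tot
  }
})

test_that("planted pauses are recovered from rendered audio", {
  s <- rendered_session()
  det <- detect_pauses(s$wave)
  # speech windows have larger ranges than silence windows almost always
  r <- compute_range_series(s$wave, 0.01)
  tms <- attr(r, "times")
  in_pause <- rep(FALSE, length(tms))
  for (i in seq_len(nrow(s$truth$pauses))) {
    in_pause <- in_pause | (tms >= s$truth$pauses$start[i] &
                              tms + 0.01 <= s$truth$pauses$end[i])
  }
  thresh <- max(r[in_pause])
  expect_gt(mean(r[!in_pause] > thresh), 0.95)
  # window-level agreement with truth
  flags <- classify_silence(s$wave, det$calibration)
  mid <- (seq_along(flags) - 0.5) * 0.1
  truthflag <- rep(FALSE, length(mid))
  for (i in seq_len(nrow(s$truth$pauses))) {
    truthflag <- truthflag | (mid >= s$truth$pauses$start[i] &
                                mid < s$truth$pauses$end[i])
  }
  expect_gt(mean(flags == truthflag), 0.95)
  # an isolated planted 2-s silence is recovered within one eval window
  truth <- s$truth
  truth$turns <- data.frame(start = c(0, 5), end = c(3, 9),
                            speaker = c("therapist", "patient"))
  truth$pauses <- data.frame(start = 3, end = 5, pattern = "T_P")
  truth$session_length <- 9
  w2 <- render_audio(truth, s$config)
  ep <- detect_pauses(w2)$episodes
  ep <- ep[which.max(ep$end - ep$start), ]
  expect_lt(abs(ep$start - 3), 0.1 + 1e-9)
  expect_lt(abs(ep$end - 5), 0.1 + 1e-9)
  # detected episodes are disjoint, sorted, inside the session
  epi <- det$episodes
  expect_true(all(diff(epi$start) > 0))
  expect_true(all(epi$end > epi$start))
  expect_true(all(epi$start >= 0 & epi$end <= s$wave$duration + 1e-9))
})
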
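test_that("a fixed seed reproduces sessions and corpora bit-for-bit", {
  cfg <- generator_config(n_dyads = 2, sessions_per_dyad = 2,
                          session_length = 400, seed = 42)
  expect_identical(generate_session(cfg, 1, 1), generate_session(cfg, 1, 1))
  c1 <- generate_corpus(cfg)
  c2 <- generate_corpus(cfg)
  expect_identical(c1, c2)
  cfg2 <- generator_config(n_dyads = 2, sessions_per_dyad = 2,
                           session_length = 400, seed = 43)
  expect_false(identical(generate_corpus(cfg2), c1))
})

test_that("turns and pauses tile each session exactly", {
  for (s in small_corpus()[1:6]) {
    covered <- sum(s$turns$end - s$turns$start) +
      sum(s$pauses$end - s$pauses$start)
    expect_equal(covered, s$session_length, tolerance = 1e-8)
    expect_true(all(s$ruptures$start >= 0 & s$ruptures$end <= s$session_length))
    # same-speaker turns never overlap (turns are disjoint altogether)
    o <- order(s$turns$start)
    expect_true(all(diff(s$turns$start[o]) > 0))
    expect_true(all(s$turns$end[o][-nrow(s$turns)] <=
                      s$turns$start[o][-1] + 1e-9))
  }
})

test_that("pre-assigned pause patterns agree with the turn sequence", {
  s <- small_corpus()[[1]]
  relabelled <- label_patterns(s$pauses[, c("start", "end")], s$turns)
  expect_identical(relabelled$pattern, s$pauses$pattern)
})

test_that("rupture-free sessions hit the baseline pause target", {
  cfg <- generator_config(n_dyads = 10, sessions_per_dyad = 5,
                          session_length = 600, seed = 77,
                          ruptures_per_session = 0)
  corpus <- generate_corpus(cfg)
  w <- truth_to_window_table(corpus)
  expect_gt(nrow(attr(corpus, "manifest")), 49)
  expect_lt(abs(mean(w$pause_pct) - 30.6), 3)
})

test_that("rupture type and marker mix match the configured probabilities", {
  corpus <- classifier_corpus()
  rup <- do.call(rbind, lapply(corpus, `[[`, "ruptures"))
  expect_gt(nrow(rup), 200)
  expect_lt(abs(mean(rup$dominant_type == "withdrawal") - 295 / 516), 0.05)
  wd <- rup[rup$dominant_type == "withdrawal", ]
  expect_lt(abs(mean(wd$minimal_response) - 159 / 295), 0.06)
})

test_that("corpus layout, manifest and label tracks round-trip", {
  cfg <- generator_config(n_dyads = 2, sessions_per_dyad = 3,
                          session_length = 400, seed = 3)
  corpus <- generate_corpus(cfg)
  expect_length(corpus, 6)
  man <- attr(corpus, "manifest")
  expect_setequal(unique(man$dyad_id), 1:2)
  dir <- withr::local_tempdir()
  written <- write_corpus(corpus, dir)
  back <- read_corpus_manifest(dir)
  expect_equal(back$seed, written$seed)
  expect_equal(back$n_ruptures, written$n_ruptures)
  # pause track round-trips numerically
  p <- read_label_track(file.path(dir, written$pauses_file[1]))
  expect_equal(p$start, corpus[[1]]$pauses$start, tolerance = 1e-5)
  expect_identical(p$label, corpus[[1]]$pauses$pattern)
  r <- parse_rupture_labels(read_label_track(file.path(dir, written$ruptures_file[1])))
  expect_identical(r$dominant_type, corpus[[1]]$ruptures$dominant_type)
  expect_identical(r$minimal_response, corpus[[1]]$ruptures$minimal_response)
})

test_that("sessions too short for the requested ruptures are rejected", {
  cfg <- generator_config(n_dyads = 1, sessions_per_dyad = 1,
                          session_length = 80, seed = 1,
                          ruptures_per_session = 20)
  expect_error(generate_session(cfg, 1, 1), "too short")
})

test_that("withdrawal ruptures ramp up before their onset", {
  # dyad-matched: each rupture's pre-onset pause fraction is compared with
  # its own dyad's planted baseline, so dyad heterogeneity cancels
  cfg <- generator_config(n_dyads = 20, sessions_per_dyad = 6,
                          session_length = 900, seed = 313)
  excess <- c()
  for (s in generate_corpus(cfg)) {
    wd <- s$ruptures[s$ruptures$dominant_type == "withdrawal", ]
    for (i in seq_len(nrow(wd))) {
      if (wd$start[i] < 25) next
      # skip pre-windows contaminated by another rupture
      others <- s$ruptures[s$ruptures$start != wd$start[i], ]
      if (nrow(others) > 0 &&
          any(others$end > wd$start[i] - 25 & others$start < wd$start[i])) next
      pre <- interval_overlap_frac(s, wd$start[i] - 20, wd$start[i])
      excess <- c(excess, pre - s$baseline / 100)
    }
  }
  expect_gt(length(excess), 50)
  expect_lt(t.test(excess, alternative = "greater")$p.value, 0.05)
  expect_gt(mean(excess), 0)
})

test_that("truth_to_window_table is the windowing of the truth tracks", {
  s <- small_corpus()[[2]]
  w <- truth_to_window_table(s)
  direct <- window_session(s$session_length, s$pauses, s$ruptures)
  expect_equal(w[, names(direct)], direct)
  # empty truth: all-zero pause columns
  empty <- s
  empty$pauses <- empty$pauses[0, ]
  empty$turns <- data.frame(start = 0, end = s$session_length,
                            speaker = "therapist")
  w0 <- truth_to_window_table(empty)
  expect_true(all(w0$pause_pct == 0))
  # planted 50% pause target is conserved through windowing
  cfg50 <- generator_config(n_dyads = 4, sessions_per_dyad = 3,
                            session_length = 600, seed = 55,
                            base_pause_target = 50, ruptures_per_session = 0)
  w50 <- truth_to_window_table(generate_corpus(cfg50))
  expect_lt(abs(mean(w50$pause_pct) - 50), 3)
})

test_that("rendered audio reflects the planted speech/pause structure", {
  cfg <- generator_config(n_dyads = 1, sessions_per_dyad = 1,
                          session_length = 10, seed = 8,
                          ruptures_per_session = 0)
  truth <- generate_session(cfg, 1, 1)
  truth$turns <- data.frame(start = c(0, 5), end = c(3, 8),
                            speaker = c("therapist", "patient"))
  truth$pauses <- data.frame(start = c(3, 8), end = c(5, 10),
                             pattern = c("T_P", "BOUNDARY"))
  w <- render_audio(truth, cfg)
  r <- compute_range_series(w, 0.01)
  tms <- attr(r, "times")
  cut <- max(r[tms >= 3.05 & tms < 4.95])
  expect_lt(cut, min(r[tms >= 0.5 & tms < 2.5]))
  # the low-range run brackets the planted pause within one small window
  low <- tms[r <= cut * 1.5 & tms >= 2 & tms < 6]
  expect_lt(abs(min(low) - 3), 0.06)
  expect_lt(abs(max(low) + 0.01 - 5), 0.06)
  # all-silence truth stays at the noise floor
  truth$turns <- truth$turns[0, ]
  truth$pauses <- data.frame(start = 0, end = 10, pattern = "BOUNDARY")
  ws <- render_audio(truth, cfg)
  expect_lte(max(abs(ws$samples)), cfg$noise_floor)
  # renders are reproducible
  expect_identical(render_audio(truth, cfg), render_audio(truth, cfg))
  expect_error(render_audio(truth, generator_config(sample_rate = 4000)),
               "sample_rate")
})
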
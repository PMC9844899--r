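#' Configuration for the synthetic dyadic-session generator
#'
#' The generator emulates two-speaker psychotherapy sessions recorded on a
#' single boundary-microphone channel: alternating patient/therapist turns
#' separated by inter-turn gaps (pauses), with alliance-rupture episodes
#' planted at known locations.  Its defaults encode the study conditions the
#' downstream statistics are expected to recover:
#'
#' * Outside ruptures, pauses occupy `base_pause_target` percent of the time
#'   (default 30.6).
#' * Inside a rupture, the pause target is taken from `effect_table` by
#'   rupture type and minimal-response status.  The default cells are
#'   *additive*: 32.39 (confrontation, no marker), +3.22 for withdrawal,
#'   +11.67 for the minimal-response marker, i.e. the within-dyad fixed-effect
#'   structure the mixed model estimates.
#' * Dyads differ: each dyad carries a baseline shift (sd `dyad_sd`,
#'   standardised to exact zero mean over the corpus) and its own withdrawal
#'   propensity; the two are correlated (`dyad_type_cor`), so raw cell means
#'   drift away from the within-dyad effects exactly as in clinical samples
#'   where dyad composition confounds raw summaries.
#' * For withdrawal ruptures the pause increase ramps up linearly starting
#'   `ramp_lead` seconds (default 25) before the annotated onset.
#' * In minimal-response episodes a `tt_concentration` share of pause time is
#'   realised as therapist-turn/pause/therapist-turn triples (the patient
#'   skips speaking turns).
#'
#' @param n_dyads number of patient-therapist dyads.
#' @param sessions_per_dyad sessions generated per dyad.
#' @param session_length session length in seconds (600 is a convenient test
#'   scale; clinical sessions run ~3000 s).
#' @param sample_rate audio sampling rate in Hz (only used by
#'   [render_audio()]).
#' @param seed master integer seed; fixes the whole corpus bit-for-bit.
#' @param base_pause_target percent of non-rupture time spent in pauses.
#' @param effect_table named numeric vector of target mean pause percent for
#'   the four (type x minimal-response) cells: `confrontation_no`,
#'   `confrontation_yes`, `withdrawal_no`, `withdrawal_yes`.
#' @param ramp_lead seconds before a withdrawal onset over which the pause
#'   rate ramps from baseline to the cell target.
#' @param mr_prob_given_withdrawal,mr_prob_given_confrontation probability
#'   that a rupture of the given type carries the minimal-response marker.
#' @param withdrawal_frac corpus-level probability that a rupture is of the
#'   withdrawal type (dyads vary around it, see `dyad_wfrac_sd`).
#' @param rupture_duration list with `withdrawal` and `confrontation`
#'   elements, each `c(mean =, sd =)` seconds of a lognormal duration law
#'   (the type-level mean and coefficient of variation are preserved across
#'   the marker split below).
#' @param mr_duration_ratio ratio of mean episode duration for ruptures
#'   carrying the minimal-response marker over unmarked ones (default 2.5).
#'   Marked episodes are substantially longer in clinical data: roughly a
#'   third of episodes carry the marker yet about half of all rupture
#'   windows do, which pins the duration ratio near 2.5.
#' @param ruptures_per_session Poisson rate of ruptures per session.
#' @param turn_duration_means named vector, mean speaking-turn length in
#'   seconds per speaker.
#' @param turn_sdlog,gap_sdlog log-scale sd of the lognormal turn and gap
#'   duration laws.
#' @param continuation_prob probability that, outside minimal-response
#'   episodes, the same speaker continues after a pause (produces the P_P and
#'   T_T patterns at baseline).
#' @param tt_concentration target share of within-minimal-response-episode
#'   pause time falling in the T_T pattern.
#' @param dyad_sd sd of the dyad baseline shift in pause percentage points.
#' @param dyad_wfrac_sd sd of the per-dyad withdrawal fraction.
#' @param dyad_type_cor correlation between a dyad's baseline shift and its
#'   withdrawal propensity.
#' @param noise_floor peak amplitude of the silence-floor noise in rendered
#'   audio.
#' @param speech_level nominal amplitude of rendered speech.
#' @return an object of class `generator_config`.
#' @export
generator_config <- function(n_dyads = 22L,
                             sessions_per_dyad = 11L,
                             session_length = 600,
                             sample_rate = 16000,
                             seed = 1L,
                             base_pause_target = 30.6,
                             effect_table = c(confrontation_no  = 32.39,
                                              confrontation_yes = 44.06,
                                              withdrawal_no     = 35.61,
                                              withdrawal_yes    = 47.28),
                             ramp_lead = 25,
                             mr_prob_given_withdrawal = 159 / 295,
                             mr_prob_given_confrontation = 27 / 221,
                             withdrawal_frac = 295 / 516,
                             rupture_duration = list(
                               withdrawal = c(mean = 116.1, sd = 189.9),
                               confrontation = c(mean = 133.4, sd = 215.8)),
                             mr_duration_ratio = 2.5,
                             ruptures_per_session = 2,
                             turn_duration_means = c(patient = 4.5, therapist = 3.5),
                             turn_sdlog = 0.6,
                             gap_sdlog = 0.8,
                             continuation_prob = 0.25,
                             tt_concentration = 0.7,
                             dyad_sd = 6.7,
                             dyad_wfrac_sd = 0.12,
                             dyad_type_cor = 0.55,
                             noise_floor = 0.004,
                             speech_level = 0.30) {
  probs <- c(mr_prob_given_withdrawal, mr_prob_given_confrontation,
             withdrawal_frac, continuation_prob, tt_concentration)
  stop_if_not(all(probs >= 0 & probs <= 1), "all probabilities must lie in [0, 1]")
  stop_if_not(n_dyads >= 1 && sessions_per_dyad >= 1, "need at least one dyad and session")
  stop_if_not(session_length > 0 && sample_rate > 0, "durations must be positive")
  stop_if_not(all(turn_duration_means > 0), "turn durations must be positive")
  stop_if_not(setequal(names(effect_table),
                       c("confrontation_no", "confrontation_yes",
                         "withdrawal_no", "withdrawal_yes")),
              "effect_table must name the four (type x minimal-response) cells")
  stop_if_not(all(effect_table >= 0 & effect_table <= 100),
              "effect_table values are percentages in [0, 100]")
  stop_if_not(base_pause_target > 0 && base_pause_target < 100,
              "base_pause_target is a percentage in (0, 100)")
  for (ty in c("withdrawal", "confrontation"))
    stop_if_not(all(rupture_duration[[ty]] > 0), "rupture durations must be positive")
  stop_if_not(ruptures_per_session >= 0, "ruptures_per_session must be >= 0")
  stop_if_not(mr_duration_ratio > 0, "mr_duration_ratio must be positive")
  structure(list(
    n_dyads = as.integer(n_dyads),
    sessions_per_dyad = as.integer(sessions_per_dyad),
    session_length = session_length,
    sample_rate = sample_rate,
    seed = as.integer(seed),
    base_pause_target = base_pause_target,
    effect_table = effect_table[c("confrontation_no", "confrontation_yes",
                                  "withdrawal_no", "withdrawal_yes")],
    ramp_lead = ramp_lead,
    mr_prob_given_withdrawal = mr_prob_given_withdrawal,
    mr_prob_given_confrontation = mr_prob_given_confrontation,
    withdrawal_frac = withdrawal_frac,
    rupture_duration = rupture_duration,
    mr_duration_ratio = mr_duration_ratio,
    ruptures_per_session = ruptures_per_session,
    turn_duration_means = turn_duration_means,
    turn_sdlog = turn_sdlog,
    gap_sdlog = gap_sdlog,
    continuation_prob = continuation_prob,
    tt_concentration = tt_concentration,
    dyad_sd = dyad_sd,
    dyad_wfrac_sd = dyad_wfrac_sd,
    dyad_type_cor = dyad_type_cor,
    noise_floor = noise_floor,
    speech_level = speech_level
  ), class = "generator_config")
}

#' Per-dyad latent profiles
#'
#' Deterministic in the master seed.  Baseline shifts are centred and scaled
#' to exactly zero mean / `dyad_sd` sd across the corpus's dyads so the
#' corpus-level calibration targets are hit in expectation; withdrawal
#' fractions share a latent factor with the baseline (correlation
#' `dyad_type_cor`).
#'
#' @param config a [generator_config()].
#' @return data.frame with `dyad_id`, `baseline_shift`, `withdrawal_frac`.
#' @export
dyad_profiles <- function(config) {
  n <- config$n_dyads
  with_preserved_seed(derive_seed(config$seed, 0), {
    if (n == 1L) {
      return(data.frame(dyad_id = 1L, baseline_shift = 0,
                        withdrawal_frac = config$withdrawal_frac))
    }
    z1 <- as.numeric(scale(stats::rnorm(n)))
    z2 <- as.numeric(scale(stats::rnorm(n)))
    rho <- config$dyad_type_cor
    u <- config$dyad_sd * (rho * z1 + sqrt(1 - rho^2) * z2)
    u <- u - mean(u)
    wf <- pmin(pmax(config$withdrawal_frac + config$dyad_wfrac_sd * z1, 0.05), 0.95)
    data.frame(dyad_id = seq_len(n), baseline_shift = u, withdrawal_frac = wf)
  })
}

# expected turn duration under a regime's next-speaker law
regime_turn_mean <- function(config, in_mr) {
  tm <- config$turn_duration_means
  if (in_mr) {
    q <- sqrt(config$tt_concentration)
    q * tm[["therapist"]] + (1 - q) * tm[["patient"]]
  } else {
    mean(tm)
  }
}

# gap mean that makes the long-run pause fraction equal `p`
# (renewal identity: p = E[gap] / (E[gap] + E[turn]))
solve_gap_mean <- function(p, turn_mean) {
  p <- min(max(p, 0.02), 0.95)
  p / (1 - p) * turn_mean
}

# draw rupture episodes for one session; a whole set that stochastically
# overflows the session is redrawn, and only a session that cannot host the
# requested rate at all is rejected
draw_ruptures <- function(config, wfrac, dyad_id, session_id) {
  L <- config$session_length
  lead <- 30; tail <- 10; sep <- 5
  dmin <- 15; dmax <- max(dmin, 0.3 * L)
  empty <- data.frame(rupture_id = character(), start = numeric(),
                      end = numeric(), dominant_type = character(),
                      minimal_response = logical())
  last_n <- 0L; last_total <- 0
  for (set_try in 1:60) {
    n <- stats::rpois(1, config$ruptures_per_session)
    if (n == 0) return(empty)
    type <- ifelse(stats::runif(n) < wfrac, "withdrawal", "confrontation")
    mrp <- ifelse(type == "withdrawal", config$mr_prob_given_withdrawal,
                  config$mr_prob_given_confrontation)
    mr <- stats::runif(n) < mrp
    # marker-conditional duration means preserve the type-level mean:
    # m_no * (p_mr * ratio + 1 - p_mr) = type mean, m_mr = ratio * m_no;
    # the type-level coefficient of variation is kept for both cells
    dur <- vapply(seq_len(n), function(i) {
      ty <- type[i]
      tmean <- config$rupture_duration[[ty]][["mean"]]
      cv <- config$rupture_duration[[ty]][["sd"]] / tmean
      p <- if (ty == "withdrawal") config$mr_prob_given_withdrawal
           else config$mr_prob_given_confrontation
      m_no <- tmean / (p * config$mr_duration_ratio + 1 - p)
      m <- if (mr[i]) config$mr_duration_ratio * m_no else m_no
      pars <- lnorm_params(m, cv * m)
      for (k in 1:200) {
        d <- stats::rlnorm(1, pars$meanlog, pars$sdlog)
        if (d >= dmin && d <= dmax) return(d)
      }
      dmax
    }, numeric(1))
    last_n <- n; last_total <- sum(dur)
    if (sum(dur) + lead + tail + sep * n > L) next
    for (try in 1:500) {
      s <- stats::runif(n, lead, pmax(lead + 1e-6, L - tail - dur))
      o <- order(s)
      s <- s[o]; e <- s + dur[o]
      if (all(e <= L - tail) && (n == 1 || all(s[-1] - e[-n] >= sep))) {
        return(data.frame(
          rupture_id = sprintf("d%02d_s%02d_r%02d", dyad_id, session_id,
                               seq_len(n)),
          start = s, end = e, dominant_type = type[o],
          minimal_response = mr[o], stringsAsFactors = FALSE))
      }
    }
  }
  stop(sprintf(paste0("session_length %.0f s too short to host %d rupture(s) ",
                      "totalling %.0f s (dyad %s, session %s)"),
               L, last_n, last_total, dyad_id, session_id), call. = FALSE)
}

# pause-percent target at time t, including the withdrawal pre-onset ramp
pause_target_at <- function(t, config, ruptures, baseline) {
  if (nrow(ruptures) > 0) {
    inside <- which(t >= ruptures$start & t < ruptures$end)
    if (length(inside) > 0) {
      r <- ruptures[inside[1L], ]
      cell <- if (r$dominant_type == "withdrawal") {
        if (r$minimal_response) "withdrawal_yes" else "withdrawal_no"
      } else {
        if (r$minimal_response) "confrontation_yes" else "confrontation_no"
      }
      return(config$effect_table[[cell]] + baseline - config$base_pause_target)
    }
    wd <- ruptures[ruptures$dominant_type == "withdrawal", , drop = FALSE]
    if (nrow(wd) > 0 && config$ramp_lead > 0) {
      ahead <- which(t >= wd$start - config$ramp_lead & t < wd$start)
      if (length(ahead) > 0) {
        r <- wd[ahead[1L], ]
        cell <- if (r$minimal_response) "withdrawal_yes" else "withdrawal_no"
        target <- config$effect_table[[cell]] + baseline - config$base_pause_target
        frac <- 1 - (r$start - t) / config$ramp_lead
        return(baseline + frac * (target - baseline))
      }
    }
  }
  baseline
}

in_mr_rupture <- function(t, ruptures) {
  nrow(ruptures) > 0 &&
    any(t >= ruptures$start & t < ruptures$end & ruptures$minimal_response)
}

#' Generate the ground truth of one synthetic session
#'
#' Turns and inter-turn gaps are drawn sequentially from lognormal laws; the
#' gap mean is solved per regime so that the expected pause fraction matches
#' the local target (baseline, ramp, or rupture-cell target).  See
#' [generator_config()] for the planted structure.
#'
#' @param config a [generator_config()].
#' @param dyad_id integer dyad index in `1:n_dyads`.
#' @param session_id integer session index in `1:sessions_per_dyad`.
#' @return an object of class `session_truth` with elements `turns`
#'   (start/end/speaker), `pauses` (start/end/pattern, tiling the non-speech
#'   interior), `ruptures`, `dyad_id`, `session_id`, `session_length`.
#' @export
generate_session <- function(config, dyad_id, session_id) {
  stop_if_not(inherits(config, "generator_config"), "config must be a generator_config")
  stop_if_not(dyad_id >= 1 && dyad_id <= config$n_dyads, "dyad_id out of range")
  prof <- dyad_profiles(config)[dyad_id, ]
  baseline <- min(max(config$base_pause_target + prof$baseline_shift, 2), 95)
  sseed <- derive_seed(config$seed,
                       (dyad_id - 1) * max(config$sessions_per_dyad, session_id) + session_id)
  L <- config$session_length
  with_preserved_seed(sseed, {
    ruptures <- draw_ruptures(config, prof$withdrawal_frac, dyad_id, session_id)
    q_tt <- sqrt(config$tt_concentration)
    tm <- config$turn_duration_means

    cap <- ceiling(L / 0.5) + 10  # generous upper bound on events
    t_start <- numeric(cap); t_end <- numeric(cap); t_spk <- character(cap)
    p_start <- numeric(cap); p_end <- numeric(cap)
    p_prev <- character(cap); p_next <- character(cap)
    nt <- 0L; np <- 0L

    t <- 0; spk <- "therapist"  # therapist opens the session
    while (t < L) {
      dur <- rlnorm_mean(1, tm[[spk]], config$turn_sdlog)
      te <- min(t + dur, L)
      nt <- nt + 1L
      t_start[nt] <- t; t_end[nt] <- te; t_spk[nt] <- spk
      t <- te
      if (t >= L) break
      in_mr <- in_mr_rupture(t, ruptures)
      nxt <- if (in_mr) {
        if (stats::runif(1) < q_tt) "therapist" else "patient"
      } else {
        if (stats::runif(1) < config$continuation_prob) spk else other_speaker(spk)
      }
      target <- pause_target_at(t, config, ruptures, baseline)
      gm <- solve_gap_mean(target / 100, regime_turn_mean(config, in_mr))
      gap <- rlnorm_mean(1, gm, config$gap_sdlog)
      ge <- min(t + gap, L)
      np <- np + 1L
      p_start[np] <- t; p_end[np] <- ge
      p_prev[np] <- spk
      p_next[np] <- if (ge >= L) NA_character_ else nxt
      t <- ge
      spk <- nxt
    }
    turns <- data.frame(start = t_start[seq_len(nt)], end = t_end[seq_len(nt)],
                        speaker = t_spk[seq_len(nt)], stringsAsFactors = FALSE)
    pauses <- if (np > 0) {
      pat <- ifelse(is.na(p_next[seq_len(np)]), "BOUNDARY",
                    paste0(toupper(substr(p_prev[seq_len(np)], 1, 1)), "_",
                           toupper(substr(p_next[seq_len(np)], 1, 1))))
      data.frame(start = p_start[seq_len(np)], end = p_end[seq_len(np)],
                 pattern = pat, stringsAsFactors = FALSE)
    } else {
      data.frame(start = numeric(), end = numeric(), pattern = character())
    }
    pauses <- pauses[pauses$end > pauses$start, , drop = FALSE]
    rownames(pauses) <- NULL
    structure(list(dyad_id = as.integer(dyad_id),
                   session_id = as.integer(session_id),
                   session_length = L,
                   sample_rate = config$sample_rate,
                   seed = sseed,
                   baseline = baseline,
                   turns = turns, pauses = pauses, ruptures = ruptures),
              class = "session_truth")
  })
}

#' @export
print.session_truth <- function(x, ...) {
  cat(sprintf("<session_truth> dyad %d session %d: %.0f s, %d turns, %d pauses, %d ruptures\n",
              x$dyad_id, x$session_id, x$session_length,
              nrow(x$turns), nrow(x$pauses), nrow(x$ruptures)))
  invisible(x)
}

#' Generate a corpus of synthetic sessions
#'
#' Per-session seeds are derived deterministically from the master seed, so a
#' corpus is reproducible bit-for-bit and any one session can be regenerated
#' in isolation.
#'
#' @param config a [generator_config()].
#' @return a list of [generate_session()] results with a `manifest`
#'   attribute (data.frame: dyad_id, session_id, seed, n_ruptures,
#'   n_withdrawal, n_minimal_response).
#' @export
generate_corpus <- function(config) {
  stop_if_not(inherits(config, "generator_config"), "config must be a generator_config")
  grid <- expand.grid(session_id = seq_len(config$sessions_per_dyad),
                      dyad_id = seq_len(config$n_dyads))
  sessions <- mapply(function(d, s) generate_session(config, d, s),
                     grid$dyad_id, grid$session_id, SIMPLIFY = FALSE)
  manifest <- do.call(rbind, lapply(sessions, function(x) {
    data.frame(dyad_id = x$dyad_id, session_id = x$session_id, seed = x$seed,
               session_length = x$session_length,
               n_ruptures = nrow(x$ruptures),
               n_withdrawal = sum(x$ruptures$dominant_type == "withdrawal"),
               n_minimal_response = sum(x$ruptures$minimal_response))
  }))
  attr(sessions, "manifest") <- manifest
  attr(sessions, "config") <- config
  class(sessions) <- c("session_corpus", "list")
  sessions
}

#' Write a corpus to disk as label tracks plus a JSON manifest
#'
#' Each session yields three Audacity-dialect TSV label tracks (speakers,
#' pauses, ruptures); `render` additionally writes a PCM-16 WAV per session.
#'
#' @param corpus result of [generate_corpus()].
#' @param dir output directory (created if missing).
#' @param render logical; also render and write audio.
#' @return the manifest data.frame (with file names), invisibly.
#' @export
write_corpus <- function(corpus, dir, render = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  config <- attr(corpus, "config")
  manifest <- attr(corpus, "manifest")
  stem <- sprintf("d%02d_s%02d", manifest$dyad_id, manifest$session_id)
  manifest$speakers_file <- paste0(stem, "_speakers.txt")
  manifest$pauses_file <- paste0(stem, "_pauses.txt")
  manifest$ruptures_file <- paste0(stem, "_ruptures.txt")
  if (render) manifest$audio_file <- paste0(stem, ".wav")
  for (i in seq_along(corpus)) {
    x <- corpus[[i]]
    write_label_track(data.frame(start = x$turns$start, end = x$turns$end,
                                 label = x$turns$speaker),
                      file.path(dir, manifest$speakers_file[i]))
    write_label_track(data.frame(start = x$pauses$start, end = x$pauses$end,
                                 label = x$pauses$pattern),
                      file.path(dir, manifest$pauses_file[i]))
    write_label_track(x$ruptures, file.path(dir, manifest$ruptures_file[i]))
    if (render) {
      write_wav(render_audio(x, config), file.path(dir, manifest$audio_file[i]))
    }
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       dataframe = "rows", digits = NA)
  invisible(manifest)
}

#' Read a corpus manifest written by [write_corpus()]
#'
#' @param dir corpus directory.
#' @return the manifest data.frame.
#' @export
read_corpus_manifest <- function(dir) {
  path <- file.path(dir, "manifest.json")
  stop_if_not(file.exists(path), "no manifest.json under %s", dir)
  as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' Render the stylised audio of a session
#'
#' Speech intervals are rendered as an amplitude-modulated harmonic source
#' (fundamental ~110 Hz for the therapist, ~220 Hz for the patient) plus
#' broadband noise; pauses carry only a low noise floor.  The rendering is
#' deliberately stylised (no phonetics): the silence detector keys on
#' amplitude variability and the diariser on coarse spectral shape, which
#' this reproduces.
#'
#' @param truth a [generate_session()] result.
#' @param config a [generator_config()] (for sample rate and levels).
#' @param seed integer seed (defaults to a value derived from the session's
#'   own seed, so renders are reproducible).
#' @return a [waveform()].
#' @export
render_audio <- function(truth, config, seed = NULL) {
  stop_if_not(inherits(truth, "session_truth"), "truth must be a session_truth")
  sr <- config$sample_rate
  stop_if_not(sr >= 8000, "sample_rate below 8000 Hz is rejected")
  seed <- seed %||% derive_seed(truth$seed, 104729)
  n <- round(truth$session_length * sr)
  f0 <- c(therapist = 110, patient = 220)
  with_preserved_seed(seed, {
    x <- stats::runif(n, -config$noise_floor, config$noise_floor)
    for (i in seq_len(nrow(truth$turns))) {
      i0 <- floor(truth$turns$start[i] * sr) + 1
      i1 <- min(ceiling(truth$turns$end[i] * sr), n)
      if (i1 < i0) next
      tau <- (seq.int(i0, i1) - 1) / sr
      f <- f0[[truth$turns$speaker[i]]] * stats::runif(1, 0.96, 1.04)
      ph <- stats::runif(3, 0, 2 * pi)
      env <- 0.65 + 0.35 * sin(2 * pi * stats::runif(1, 2.5, 4) * tau + ph[3])
      sig <- 0.6 * sin(2 * pi * f * tau + ph[1]) +
        0.3 * sin(2 * pi * 2 * f * tau + ph[2]) +
        0.15 * sin(2 * pi * 3 * f * tau)
      x[i0:i1] <- config$speech_level * env * sig +
        stats::rnorm(i1 - i0 + 1, 0, 0.08 * config$speech_level)
    }
    waveform(pmin(pmax(x, -1), 1), sr)
  })
}

#' Window table straight from ground truth (bypass path)
#'
#' Applies the 10-second windowing to the generator's own pause and rupture
#' tracks, skipping acoustic estimation entirely.  Statistical recovery
#' analyses use this path so that planted-parameter checks are not confounded
#' with detection error.
#'
#' @param truth a [generate_session()] result, or a whole corpus from
#'   [generate_corpus()].
#' @param window window length in seconds.
#' @return a window table as from [window_session()], with `dyad_id` and
#'   `session_id` columns.
#' @export
truth_to_window_table <- function(truth, window = 10) {
  if (inherits(truth, "session_corpus")) {
    return(do.call(rbind, lapply(truth, truth_to_window_table, window = window)))
  }
  stop_if_not(inherits(truth, "session_truth"), "truth must be a session_truth")
  w <- window_session(truth$session_length, truth$pauses, truth$ruptures,
                      window = window)
  cbind(data.frame(dyad_id = truth$dyad_id, session_id = truth$session_id), w)
}
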
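# Shared fixtures, built once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, build(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# small ground-truth corpus for structural and pattern tests
small_corpus <- function() fixture("small_corpus", function() {
  generate_corpus(generator_config(n_dyads = 6, sessions_per_dyad = 3,
                                   session_length = 900, seed = 101))
})

# medium corpus for classifier recovery (>= 300 planted ruptures)
classifier_corpus <- function() fixture("classifier_corpus", function() {
  generate_corpus(generator_config(n_dyads = 22, sessions_per_dyad = 8,
                                   session_length = 1500, seed = 202))
})

# study-scale corpus for the mixed-model recovery checks
recovery_corpus <- function() fixture("recovery_corpus", function() {
  generate_corpus(generator_config(n_dyads = 22, sessions_per_dyad = 33,
                                   session_length = 3000, seed = 303))
})

recovery_windows <- function() fixture("recovery_windows", function() {
  truth_to_window_table(recovery_corpus())
})

# short rendered session without ruptures, for acoustic tests
rendered_session <- function() fixture("rendered_session", function() {
  cfg <- generator_config(n_dyads = 2, sessions_per_dyad = 1,
                          session_length = 120, sample_rate = 16000,
                          seed = 5, ruptures_per_session = 0)
  truth <- generate_session(cfg, 1, 1)
  list(config = cfg, truth = truth, wave = render_audio(truth, cfg))
})

# longer rendered session at 8 kHz for diarisation tests
diarisation_session <- function() fixture("diarisation_session", function() {
  cfg <- generator_config(n_dyads = 1, sessions_per_dyad = 1,
                          session_length = 300, sample_rate = 8000,
                          seed = 9, ruptures_per_session = 0)
  truth <- generate_session(cfg, 1, 1)
  wave <- render_audio(truth, cfg)
  list(config = cfg, truth = truth, wave = wave,
       features = extract_features(wave))
})

# truth speaker at the centre of each feature window (NA inside pauses)
truth_speaker_at <- function(times, turns) {
  out <- rep(NA_character_, length(times))
  for (i in seq_len(nrow(turns))) {
    sel <- times >= turns$start[i] & times < turns$end[i]
    out[sel] <- turns$speaker[i]
  }
  out
}

episode_total <- function(df) if (nrow(df) == 0) 0 else sum(df$end - df$start)

# fraction of [a, b] covered by a session's truth pauses
interval_overlap_frac <- function(s, a, b) {
  ov <- pmax(0, pmin(b, s$pauses$end) - pmax(a, s$pauses$start))
  sum(ov) / (b - a)
}

# duration-weighted intersection-over-union of two episode sets
episode_iou <- function(a, b, duration, step = 0.05) {
  mid <- seq(step / 2, duration, by = step)
  ina <- rep(FALSE, length(mid))
  for (i in seq_len(nrow(a))) ina <- ina | (mid >= a$start[i] & mid < a$end[i])
  inb <- rep(FALSE, length(mid))
  for (i in seq_len(nrow(b))) inb <- inb | (mid >= b$start[i] & mid < b$end[i])
  sum(ina & inb) / sum(ina | inb)
}
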
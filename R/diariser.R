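#' Assemble a diarisation learning set
#'
#' A learning set is a list of human-labelled speech segments (`start`,
#' `end`, `speaker`) sampled across a dyad's sessions; the workflow this
#' emulates requires at least five minutes of voice per speaker.
#'
#' @param segments data.frame with `start`, `end` and `speaker` (or `label`)
#'   in `{patient, therapist}`.
#' @param min_per_speaker minimum labelled seconds per speaker (300 by
#'   default).
#' @param strict if `TRUE` an under-sized learning set is an error; if
#'   `FALSE` (default) a warning, so that short test fixtures are usable.
#' @return an object of class `learning_set`.
#' @export
learning_set <- function(segments, min_per_speaker = 300, strict = FALSE) {
  if ("label" %in% names(segments) && !"speaker" %in% names(segments)) {
    segments$speaker <- segments$label
  }
  stop_if_not(all(c("start", "end", "speaker") %in% names(segments)),
              "segments need start, end, speaker columns")
  stop_if_not(all(segments$speaker %in% c("patient", "therapist")),
              "speaker labels must be 'patient' or 'therapist'")
  check_episodes(segments, "learning segments")
  per <- tapply(segments$end - segments$start, segments$speaker, sum)
  short <- setdiff(c("patient", "therapist"), names(per))
  low <- c(short, names(per)[per < min_per_speaker])
  if (length(low) > 0) {
    msg <- sprintf("learning set below %g s of speech for: %s",
                   min_per_speaker, paste(low, collapse = ", "))
    if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  structure(list(segments = segments,
                 seconds_per_speaker = per,
                 min_per_speaker = min_per_speaker),
            class = "learning_set")
}

# indices of feature windows whose centre falls inside labelled segments
windows_in_segments <- function(times, segments) {
  hit <- rep(NA_character_, length(times))
  for (i in seq_len(nrow(segments))) {
    sel <- times >= segments$start[i] & times < segments$end[i]
    hit[sel] <- segments$speaker[i]
  }
  hit
}

#' Train the speaker diariser
#'
#' A random-forest classifier over per-window acoustic features, trained on
#' the windows falling inside the learning set's labelled segments.
#'
#' @param features a [extract_features()] matrix.
#' @param learning a [learning_set()].
#' @param seed integer seed (mandatory: the forest is stochastic).
#' @param n_trees number of trees (500 default; odd values avoid vote ties).
#' @return an object of class `diariser_model` with the fitted forest, the
#'   feature spec and training metadata.
#' @export
train_diariser <- function(features, learning, seed, n_trees = 500) {
  stop_if_not(inherits(learning, "learning_set"), "learning must be a learning_set")
  stop_if_not(!missing(seed), "seed is mandatory")
  times <- attr(features, "times")
  lab <- windows_in_segments(times, learning$segments)
  keep <- !is.na(lab)
  stop_if_not(any(keep), "no feature windows fall inside the learning set")
  y <- factor(lab[keep], levels = c("patient", "therapist"))
  stop_if_not(nlevels(droplevels(y)) == 2,
              "learning set covers a single speaker class")
  x <- as.data.frame(unclass(features)[keep, , drop = FALSE])
  fit <- with_preserved_seed(seed, {
    randomForest::randomForest(x = x, y = y, ntree = n_trees)
  })
  structure(list(forest = fit,
                 feature_names = colnames(features),
                 seed = as.integer(seed),
                 n_trees = n_trees,
                 class_counts = table(y)),
            class = "diariser_model")
}

#' @export
print.diariser_model <- function(x, ...) {
  cat(sprintf("<diariser_model> %d trees, %d features; training windows: %s\n",
              x$n_trees, length(x$feature_names),
              paste(names(x$class_counts), as.integer(x$class_counts),
                    sep = "=", collapse = ", ")))
  invisible(x)
}

#' Classify feature windows by speaker
#'
#' @param model a [train_diariser()] result.
#' @param features a [extract_features()] matrix with the same feature spec.
#' @return data.frame with `time` (window centre) and `speaker`.
#' @export
classify_windows <- function(model, features) {
  stop_if_not(inherits(model, "diariser_model"), "model must be a diariser_model")
  stop_if_not(identical(colnames(features), model$feature_names),
              "feature spec mismatch between model and features")
  x <- as.data.frame(unclass(features))
  pred <- stats::predict(model$forest, newdata = x)
  data.frame(time = attr(features, "times"),
             speaker = as.character(pred), stringsAsFactors = FALSE)
}

#' Segment speech into speaker turns
#'
#' Each maximal speech interval between detected pauses becomes one
#' utterance, attributed by majority vote over the 0.2 s window labels it
#' contains; ties go to the previous turn's speaker, or to the therapist for
#' the session opener.
#'
#' @param window_labels data.frame from [classify_windows()].
#' @param pauses pause episodes (`start`, `end`).
#' @param duration session duration in seconds.
#' @return data.frame of speaker turns (`start`, `end`, `speaker`).
#' @export
segment_turns <- function(window_labels, pauses, duration) {
  check_episodes(pauses, "pauses")
  pauses <- pauses[order(pauses$start), , drop = FALSE]
  # speech runs = complement of the pauses within [0, duration]
  edges <- c(0, as.vector(rbind(pauses$start, pauses$end)), duration)
  runs <- matrix(edges, ncol = 2, byrow = TRUE)
  runs <- runs[runs[, 2] - runs[, 1] > 1e-9, , drop = FALSE]
  if (nrow(runs) == 0) {
    return(data.frame(start = numeric(), end = numeric(), speaker = character()))
  }
  prev <- "therapist"
  out_spk <- character(nrow(runs))
  for (i in seq_len(nrow(runs))) {
    sel <- window_labels$time >= runs[i, 1] & window_labels$time < runs[i, 2]
    votes <- table(factor(window_labels$speaker[sel],
                          levels = c("patient", "therapist")))
    spk <- if (sum(votes) == 0 || votes[["patient"]] == votes[["therapist"]]) {
      prev
    } else {
      names(votes)[which.max(votes)]
    }
    out_spk[i] <- spk
    prev <- spk
  }
  data.frame(start = runs[, 1], end = runs[, 2], speaker = out_spk,
             stringsAsFactors = FALSE)
}

#' Diarise a session waveform
#'
#' Wrapper: feature extraction, window classification, and turn segmentation
#' against an existing pause track.
#'
#' @param w a [waveform()].
#' @param model a [train_diariser()] result.
#' @param pauses pause episodes from [detect_pauses()].
#' @return list with `turns` and `window_labels`.
#' @export
diarise_session <- function(w, model, pauses) {
  feats <- extract_features(w)
  labels <- classify_windows(model, feats)
  list(turns = segment_turns(labels, pauses, w$duration),
       window_labels = labels)
}
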
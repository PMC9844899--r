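#' Amplitude-range series of a waveform
#'
#' Speech yields a highly variable signal while its absence leaves only the
#' recording-chain noise floor, so the absolute difference between the signal
#' maximum and minimum inside short non-overlapping windows separates the two
#' regimes.  The final partial window is dropped.
#'
#' @param w a [waveform()].
#' @param window window length in seconds (0.01 for calibration, 0.1 for
#'   classification).
#' @return numeric vector of per-window ranges, with attributes `window` and
#'   `times` (window start times).
#' @export
compute_range_series <- function(w, window = 0.01) {
  stop_if_not(inherits(w, "waveform"), "w must be a waveform")
  stop_if_not(length(w$samples) > 0, "empty waveform")
  k <- round(window * w$sample_rate)
  stop_if_not(k >= 1 && w$duration >= window,
              "waveform shorter than one %g s window", window)
  nwin <- floor(length(w$samples) / k)
  m <- matrix(w$samples[seq_len(nwin * k)], nrow = k)
  hi <- m[1, ]; lo <- m[1, ]
  if (k > 1) {
    for (i in 2:k) {          # columnwise max/min via repeated pmax: fast, no copies of m
      hi <- pmax(hi, m[i, ])
      lo <- pmin(lo, m[i, ])
    }
  }
  r <- hi - lo
  attr(r, "window") <- window
  attr(r, "times") <- (seq_len(nwin) - 1) * window
  r
}

#' Calibrate the silence cut-off from a range histogram
#'
#' The range distribution of a session is positively skewed: silent windows
#' pile up in a narrow peak at the left while speech spreads far to the
#' right.  The histogram is binned with Scott's rule
#' (`bin_width = 3.49 * sd * n^(-1/3)`) and the cut-off is the upper edge of
#' a selected bin.  The default `valley` strategy picks the leftmost bin
#' whose (moving-average smoothed) count is a local minimum after the
#' leftmost mode, automating what is otherwise done with auditory probes; a
#' manual `"index:k"` strategy overrides with bin `k` for parity with
#' ear-calibrated workflows.
#'
#' @param ranges range series from [compute_range_series()].
#' @param strategy `"valley"` or `"index:k"` (k a positive integer).
#' @param smooth_bins width of the moving average used before valley
#'   detection (odd integer; 3 by default).
#' @return an object of class `silence_calibration`: `bin_width`, `breaks`,
#'   `counts`, `cutoff`, `cutoff_bin_index`, `strategy`.
#' @export
calibrate_cutoff <- function(ranges, strategy = "valley", smooth_bins = 3) {
  stop_if_not(length(ranges) >= 100, "need at least 100 range values to calibrate")
  s <- stats::sd(ranges)
  stop_if_not(is.finite(s) && s > 0, "no speech detected: zero-variance range series")
  bw <- 3.49 * s * length(ranges)^(-1 / 3)
  nb <- max(2L, ceiling(max(ranges) / bw))
  breaks <- seq(0, nb * bw, by = bw)
  counts <- tabulate(pmin(pmax(ceiling(ranges / bw), 1L), nb), nbins = nb)

  if (grepl("^index:", strategy)) {
    k <- as.integer(sub("^index:", "", strategy))
    stop_if_not(is.finite(k) && k >= 1 && k <= nb, "bin index out of range")
    idx <- k
  } else if (identical(strategy, "valley")) {
    sm <- as.numeric(stats::filter(counts, rep(1 / smooth_bins, smooth_bins),
                                   sides = 2))
    sm[is.na(sm)] <- counts[is.na(sm)]
    # leftmost mode: first bin not exceeded by its right neighbour
    mode1 <- 1L
    while (mode1 < nb && sm[mode1 + 1L] > sm[mode1]) mode1 <- mode1 + 1L
    # first bin after the mode where the descent has stopped
    idx <- NA_integer_
    j <- mode1 + 1L
    while (j < nb) {
      if (sm[j] <= sm[j + 1L]) { idx <- j; break }
      j <- j + 1L
    }
    if (is.na(idx)) {
      warning("no valley found in range histogram; falling back to bin 1")
      idx <- 1L
    }
  } else {
    stop("unknown calibration strategy: ", strategy, call. = FALSE)
  }
  structure(list(bin_width = bw, breaks = breaks, counts = counts,
                 cutoff = breaks[idx + 1L], cutoff_bin_index = idx,
                 strategy = strategy,
                 small_window = attr(ranges, "window") %||% 0.01,
                 eval_window = 0.1),
            class = "silence_calibration")
}

#' @export
print.silence_calibration <- function(x, ...) {
  cat(sprintf("<silence_calibration> bin_width=%.5f cutoff=%.5f (bin %d, %s)\n",
              x$bin_width, x$cutoff, x$cutoff_bin_index, x$strategy))
  invisible(x)
}

#' Classify evaluation windows as silent
#'
#' The calibrated cut-off is applied to larger non-overlapping windows
#' (0.1 s by default): a window is silent iff its amplitude range does not
#' exceed the cut-off.
#'
#' @param w a [waveform()].
#' @param cal a [calibrate_cutoff()] result.
#' @return logical vector, one flag per evaluation window, with attribute
#'   `window`.
#' @export
classify_silence <- function(w, cal) {
  stop_if_not(inherits(cal, "silence_calibration"), "cal must be a silence_calibration")
  r <- compute_range_series(w, window = cal$eval_window)
  flags <- as.vector(r <= cal$cutoff)
  attr(flags, "window") <- cal$eval_window
  flags
}

#' Merge silent windows into pause episodes
#'
#' Maximal runs of silent windows become episodes with start/stop times on
#' the window grid; runs shorter than `min_duration` are dropped.
#'
#' @param flags logical series from [classify_silence()].
#' @param window grid step in seconds (taken from `flags` if present).
#' @param min_duration minimal episode duration in seconds.
#' @return data.frame of pause episodes (`start`, `end`), sorted, disjoint.
#' @export
merge_to_episodes <- function(flags, window = NULL, min_duration = 0.1) {
  window <- window %||% attr(flags, "window") %||% 0.1
  if (length(flags) == 0 || !any(flags)) {
    return(data.frame(start = numeric(), end = numeric()))
  }
  r <- rle(as.logical(flags))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  out <- data.frame(start = (starts[keep] - 1L) * window,
                    end = ends[keep] * window)
  out <- out[out$end - out$start >= min_duration - 1e-9, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Keep only pauses at least `threshold` seconds long
#'
#' Psychotherapy research often addresses "silence" as opposed to mere
#' pauses by keeping only episodes of at least 3 seconds; the comparison is
#' inclusive at the threshold.
#'
#' @param episodes pause episode data.frame (`start`, `end`), sorted.
#' @param threshold minimal duration in seconds (default 3).
#' @return the filtered episodes.
#' @export
apply_min_duration_filter <- function(episodes, threshold = 3) {
  stop_if_not(threshold > 0, "threshold must be positive")
  check_episodes(episodes, "pause episodes")
  out <- episodes[episodes$end - episodes$start >= threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect pauses in a session waveform
#'
#' Convenience wrapper: range calibration on 0.01 s windows, cut-off
#' classification on 0.1 s windows, merging into episodes.
#'
#' @param w a [waveform()].
#' @param strategy cut-off strategy, see [calibrate_cutoff()].
#' @param min_duration minimal episode duration in seconds.
#' @return list with `episodes` (data.frame) and `calibration`.
#' @export
detect_pauses <- function(w, strategy = "valley", min_duration = 0.1) {
  cal <- calibrate_cutoff(compute_range_series(w, 0.01), strategy = strategy)
  flags <- classify_silence(w, cal)
  list(episodes = merge_to_episodes(flags, min_duration = min_duration),
       calibration = cal)
}

#' Write a calibration report as JSON
#'
#' @param cal a [calibrate_cutoff()] result.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_calibration_report <- function(cal, path) {
  jsonlite::write_json(
    list(bin_width = cal$bin_width, cutoff = cal$cutoff,
         cutoff_bin_index = cal$cutoff_bin_index, strategy = cal$strategy,
         histogram = list(breaks = cal$breaks, counts = cal$counts)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
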
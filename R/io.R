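#' Read an Audacity-dialect label track
#'
#' Label tracks are tab-separated text files with one row per labelled
#' interval: `start<TAB>end<TAB>label`, times in seconds, no header.  This is
#' the format in which human annotations (diarisation learning sets, rupture
#' episodes) are consumed and in which detected pauses and speaker turns are
#' written.
#'
#' @param path path to a TSV label track.
#' @return a data.frame with columns `start`, `end`, `label`.
#' @export
read_label_track <- function(path) {
  stop_if_not(file.exists(path), "label track not found: %s", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("start", "end", "label"),
                          colClasses = c("numeric", "numeric", "character"),
                          quote = "", comment.char = "")
  stop_if_not(all(df$end >= df$start), "label track %s has end < start", path)
  df
}

#' Write an Audacity-dialect label track
#'
#' @param df data.frame with columns `start`, `end` and a label column
#'   (`label`, `speaker`, `pattern`, or built from rupture columns).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_label_track <- function(df, path) {
  lab <- if ("label" %in% names(df)) df$label
  else if ("speaker" %in% names(df)) df$speaker
  else if ("pattern" %in% names(df)) df$pattern
  else if ("dominant_type" %in% names(df)) {
    paste0(df$dominant_type, ifelse(df$minimal_response, ",minimal_response", ""))
  } else stop("no label column found", call. = FALSE)
  out <- data.frame(start = sprintf("%.6f", df$start),
                    end = sprintf("%.6f", df$end), label = lab)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Parse a rupture label track into rupture episodes
#'
#' Labels follow `withdrawal|confrontation[,minimal_response]`.
#'
#' @param df data.frame as returned by [read_label_track()].
#' @return data.frame with `start`, `end`, `dominant_type`, `minimal_response`.
#' @export
parse_rupture_labels <- function(df) {
  parts <- strsplit(df$label, ",", fixed = TRUE)
  type <- vapply(parts, `[[`, "", 1L)
  stop_if_not(all(type %in% c("withdrawal", "confrontation")),
              "rupture labels must start with withdrawal|confrontation")
  mr <- vapply(parts, function(p) any(p[-1] == "minimal_response"), logical(1))
  data.frame(start = df$start, end = df$end,
             dominant_type = type, minimal_response = mr)
}

#' Read a mono PCM-16 WAV file
#'
#' Minimal RIFF reader for the single-channel 16-bit PCM recordings this
#' pipeline consumes; samples are rescaled to \[-1, 1\].
#'
#' @param path path to a WAV file.
#' @return a [waveform()] object.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  stop_if_not(identical(riff, "RIFF"), "%s is not a RIFF file", path)
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  stop_if_not(identical(wave, "WAVE"), "%s is not a WAVE file", path)
  sr <- NULL; bits <- NULL; channels <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", 2, size = 2, endian = "little")
      channels <- fmt[2]
      sr <- readBin(con, "integer", 1, size = 4, endian = "little")
      invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
      block <- readBin(con, "integer", 1, size = 2, endian = "little")
      bits <- readBin(con, "integer", 1, size = 2, endian = "little")
      extra <- size - 16
      if (extra > 0) invisible(readBin(con, "raw", extra))
    } else if (identical(id, "data")) {
      samples <- readBin(con, "integer", size / 2, size = 2,
                         signed = TRUE, endian = "little")
      break
    } else {
      invisible(readBin(con, "raw", size))
    }
  }
  stop_if_not(!is.null(sr) && !is.null(samples), "malformed WAV: %s", path)
  stop_if_not(channels == 1L, "only mono WAV supported (got %d channels)", channels)
  stop_if_not(bits == 16L, "only PCM-16 WAV supported (got %d bits)", bits)
  waveform(samples / 32767, sr)
}

#' Write a mono PCM-16 WAV file
#'
#' @param w a [waveform()] object.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_wav <- function(w, path) {
  stop_if_not(inherits(w, "waveform"), "w must be a waveform")
  x <- pmin(pmax(w$samples, -1), 1)
  pcm <- as.integer(round(x * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  n <- length(pcm)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + 2 * n), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(as.integer(16), con, size = 4, endian = "little")
  writeBin(as.integer(c(1, 1)), con, size = 2, endian = "little")  # PCM, mono
  writeBin(as.integer(w$sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(w$sample_rate * 2), con, size = 4, endian = "little")
  writeBin(as.integer(c(2, 16)), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2 * n), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Session waveform container
#'
#' @param samples numeric amplitude series in \[-1, 1\].
#' @param sample_rate sampling rate in Hz.
#' @return an object of class `waveform` with fields `samples`,
#'   `sample_rate` and `duration` (seconds).
#' @export
waveform <- function(samples, sample_rate) {
  stop_if_not(is.numeric(samples), "samples must be numeric")
  stop_if_not(all(is.finite(samples)), "samples must be finite")
  stop_if_not(sample_rate > 0, "sample_rate must be positive")
  structure(list(samples = as.numeric(samples),
                 sample_rate = sample_rate,
                 duration = length(samples) / sample_rate),
            class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform> %.2f s @ %d Hz (%d samples)\n",
              x$duration, as.integer(x$sample_rate), length(x$samples)))
  invisible(x)
}
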
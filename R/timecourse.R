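#' Rupture-aligned time course of pauses
#'
#' Overlaps all ruptures at their annotated onset and re-bins the raw pause
#' tracks in 10-s bins aligned to each onset (not to the session grid):
#' offsets -20..-1 cover the 200 s before onset, 0..29 the 300 s after.
#' For every offset and rupture type the mean pause percentage and its
#' standard error *over ruptures* are reported, together with the number of
#' ruptures contributing; a single contributing rupture leaves the SEM
#' missing rather than zero.  The overall mean pause percentage across all
#' session time (the reference line of the time-course figure) and the
#' rupture-length quartiles per type are attached as attributes.
#'
#' @param sessions a `session_corpus`, a single `session_truth`, or a list
#'   of lists each holding `pauses`, `ruptures` and `session_length`.
#' @param offsets integer window offsets relative to onset.
#' @param window bin length in seconds.
#' @return data.frame `offset`, `rupture_type`, `mean_pause_pct`, `sem`,
#'   `n_ruptures`; attributes `overall_mean` and `length_summary`.
#' @export
rupture_timecourse <- function(sessions, offsets = -20:29, window = 10) {
  if (inherits(sessions, "session_truth")) sessions <- list(sessions)
  stop_if_not(length(sessions) > 0, "no sessions")
  vals <- list(); k <- 0L
  total_pause <- 0; total_time <- 0
  lens <- list()
  for (s in sessions) {
    L <- s$session_length
    ps <- s$pauses$start; pe <- s$pauses$end
    total_pause <- total_pause + sum(pe - ps)
    total_time <- total_time + L
    rup <- s$ruptures
    if (is.null(rup) || nrow(rup) == 0) next
    lens[[length(lens) + 1L]] <-
      data.frame(rupture_type = rup$dominant_type, length = rup$end - rup$start)
    for (i in seq_len(nrow(rup))) {
      b0 <- rup$start[i] + offsets * window
      b1 <- b0 + window
      ok <- b0 >= 0 & b1 <= L  # only bins fully inside the session
      if (!any(ok)) next
      ov <- vapply(which(ok), function(j) {
        interval_overlap(b0[j], b1[j], ps, pe)
      }, numeric(1))
      k <- k + 1L
      vals[[k]] <- data.frame(offset = offsets[ok],
                              rupture_type = rup$dominant_type[i],
                              pause_pct = ov / window * 100)
    }
  }
  stop_if_not(k > 0, "no ruptures with in-session bins")
  long <- do.call(rbind, vals)
  agg <- stats::aggregate(pause_pct ~ offset + rupture_type, data = long,
                          FUN = function(v) c(mean = mean(v),
                                              sem = if (length(v) > 1)
                                                stats::sd(v) / sqrt(length(v))
                                              else NA_real_,
                                              n = length(v)))
  out <- data.frame(offset = agg$offset, rupture_type = agg$rupture_type,
                    mean_pause_pct = agg$pause_pct[, "mean"],
                    sem = agg$pause_pct[, "sem"],
                    n_ruptures = as.integer(agg$pause_pct[, "n"]))
  out <- out[order(out$rupture_type, out$offset), , drop = FALSE]
  rownames(out) <- NULL
  lens <- do.call(rbind, lens)
  length_summary <- do.call(rbind, lapply(split(lens$length, lens$rupture_type),
                                          function(v) {
    q <- stats::quantile(v, c(0.25, 0.5, 0.75))
    data.frame(n = length(v), mean = mean(v), q25 = q[[1]], median = q[[2]],
               q75 = q[[3]])
  }))
  length_summary$rupture_type <- rownames(length_summary)
  rownames(length_summary) <- NULL
  attr(out, "overall_mean") <- total_pause / total_time * 100
  attr(out, "length_summary") <- length_summary
  out
}
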
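#' Build the 10-second window table of a session
#'
#' Session time is divided into non-overlapping windows (trailing partial
#' window dropped).  Pause time is apportioned to windows exactly by
#' overlap, so a pause stretching over several windows contributes to each
#' in proportion; per-pattern percentages are kept alongside the total.  A
#' window is flagged `in_rupture` when rupture episodes cover at least half
#' of it, and then carries the covering episode's dominant type,
#' minimal-response status and id.
#'
#' @param session_length session duration in seconds.
#' @param pauses labelled pause episodes (`start`, `end`, `pattern`); a
#'   track without a `pattern` column is accepted and counted entirely under
#'   `BOUNDARY`.
#' @param ruptures optional rupture episodes (`start`, `end`,
#'   `dominant_type`, `minimal_response`, optional `rupture_id`).
#' @param window window length in seconds.
#' @param rupture_threshold fraction of a window that rupture time must
#'   cover for the window to count as rupture (ties count as rupture).
#' @return data.frame with one row per window: `window_index` (1-based),
#'   `window_start`, `pause_pct`, `pct_P_P`, `pct_P_T`, `pct_T_P`,
#'   `pct_T_T`, `pct_BOUNDARY`, `in_rupture`, `dominant_type`,
#'   `minimal_response`, `rupture_id`.
#' @export
window_session <- function(session_length, pauses, ruptures = NULL,
                           window = 10, rupture_threshold = 0.5) {
  stop_if_not(session_length >= window, "session shorter than one window")
  check_episodes(pauses, "pauses")
  nw <- floor(session_length / window)
  pats <- c("P_P", "P_T", "T_P", "T_T", "BOUNDARY")
  acc <- matrix(0, nw, length(pats), dimnames = list(NULL, pats))

  if (nrow(pauses) > 0) {
    pat <- if ("pattern" %in% names(pauses)) pauses$pattern else
      rep("BOUNDARY", nrow(pauses))
    stop_if_not(all(pat %in% pats), "unknown pause pattern label")
    ps <- pmax(pauses$start, 0); pe <- pmin(pauses$end, nw * window)
    keep <- pe > ps
    ps <- ps[keep]; pe <- pe[keep]; pat <- pat[keep]
    if (length(ps) > 0) {
      i0 <- pmin(floor(ps / window), nw - 1)
      i1 <- pmin(ceiling(pe / window) - 1, nw - 1)
      reps <- i1 - i0 + 1L
      wi <- unlist(mapply(seq.int, i0, i1, SIMPLIFY = FALSE))
      es <- rep(ps, reps); ee <- rep(pe, reps); ep <- rep(pat, reps)
      ov <- pmin(ee, (wi + 1) * window) - pmax(es, wi * window)
      pos <- ov > 0
      for (p in pats) {
        sel <- pos & ep == p
        if (any(sel)) {
          add <- rowsum(ov[sel], wi[sel])
          acc[as.integer(rownames(add)) + 1L, p] <-
            acc[as.integer(rownames(add)) + 1L, p] + add[, 1]
        }
      }
    }
  }
  out <- data.frame(window_index = seq_len(nw),
                    window_start = (seq_len(nw) - 1) * window)
  out$pause_pct <- rowSums(acc) / window * 100
  for (p in pats) out[[paste0("pct_", p)]] <- acc[, p] / window * 100

  out$in_rupture <- FALSE
  out$dominant_type <- NA_character_
  out$minimal_response <- FALSE
  out$rupture_id <- NA_character_
  if (!is.null(ruptures) && nrow(ruptures) > 0) {
    check_episodes(ruptures, "ruptures")
    rid <- ruptures$rupture_id %||% sprintf("r%03d", seq_len(nrow(ruptures)))
    cover <- matrix(0, nw, nrow(ruptures))
    ws <- (seq_len(nw) - 1) * window
    for (j in seq_len(nrow(ruptures))) {
      cover[, j] <- pmax(0, pmin(ws + window, ruptures$end[j]) -
                           pmax(ws, ruptures$start[j]))
    }
    tot_cover <- rowSums(cover)
    flag <- tot_cover >= rupture_threshold * window
    best <- max.col(cover, ties.method = "first")
    out$in_rupture <- flag
    out$dominant_type[flag] <- ruptures$dominant_type[best[flag]]
    out$minimal_response[flag] <- ruptures$minimal_response[best[flag]]
    out$rupture_id[flag] <- rid[best[flag]]
  }
  out
}

#' Z-score pattern percentages within dyad
#'
#' Standardisation is per dyad and per pattern, over *all* of the dyad's
#' windows (rupture and non-rupture) before any subsetting; the order
#' matters and is fixed here: scale first, subset later.
#'
#' @param rows window table with a `dyad_id` column.
#' @param cols columns to standardise (the four pattern percentages by
#'   default).
#' @return `rows` with the selected columns replaced by z-scores, prefixed
#'   `z_`.
#' @export
zscore_by_dyad <- function(rows,
                           cols = c("pct_P_P", "pct_P_T", "pct_T_P", "pct_T_T")) {
  stop_if_not("dyad_id" %in% names(rows), "rows need a dyad_id column")
  stop_if_not(all(cols %in% names(rows)), "missing pattern columns")
  for (cc in cols) {
    z <- stats::ave(rows[[cc]], rows$dyad_id, FUN = function(v) {
      s <- stats::sd(v)
      if (!is.finite(s) || s == 0) rep(NA_real_, length(v))
      else (v - mean(v)) / s
    })
    if (anyNA(z)) {
      warning(sprintf("zero variance in %s for at least one dyad; z set to 0", cc))
      z[is.na(z)] <- 0
    }
    rows[[paste0("z_", sub("^pct_", "", cc))]] <- z
  }
  rows[cols] <- NULL
  rows
}

#' Add lag/lead features within session
#'
#' Each z-scored pattern column is shifted by -5..+5 windows within its
#' session (`lag_m5` .. `lag_0` .. `lag_p5`); offsets that would cross a
#' session edge are imputed with 0 (the per-dyad z mean) and counted in the
#' `n_imputed` attribute.
#'
#' @param rows output of [zscore_by_dyad()], with `dyad_id`, `session_id`,
#'   `window_index`.
#' @param max_lag maximal shift in windows (5).
#' @param cols z-scored columns to shift.
#' @return feature table with `4 * (2 * max_lag + 1)` feature columns plus
#'   the label and grouping columns; attribute `n_imputed` reports the
#'   edge-imputed cell count.
#' @export
add_lags <- function(rows, max_lag = 5,
                     cols = c("z_P_P", "z_P_T", "z_T_P", "z_T_T")) {
  stop_if_not(all(c("dyad_id", "session_id", "window_index") %in% names(rows)),
              "rows need dyad_id, session_id, window_index")
  stop_if_not(all(cols %in% names(rows)), "missing z-scored pattern columns")
  o <- order(rows$dyad_id, rows$session_id, rows$window_index)
  rows <- rows[o, , drop = FALSE]
  sess <- paste(rows$dyad_id, rows$session_id, sep = "\r")
  n <- nrow(rows)
  n_imputed <- 0L
  for (cc in cols) {
    v <- rows[[cc]]
    for (k in -max_lag:max_lag) {
      nm <- sprintf("%s_lag_%s", cc, if (k < 0) paste0("m", -k)
                    else if (k > 0) paste0("p", k) else "0")
      if (k == 0) {
        rows[[nm]] <- v
      } else {
        # value k windows later (k > 0) or earlier (k < 0), same session only
        j <- seq_len(n) + k
        ok <- j >= 1 & j <= n
        ok[ok] <- sess[j[ok]] == sess[which(ok)]
        val <- numeric(n)
        val[ok] <- v[j[ok]]
        rows[[nm]] <- val
        n_imputed <- n_imputed + sum(!ok)
      }
    }
  }
  rows[cols] <- NULL
  attr(rows, "n_imputed") <- n_imputed
  attr(rows, "feature_cols") <- grep("^z_.*_lag_", names(rows), value = TRUE)
  rows
}
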
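#' Label pauses with their speaker-switching pattern
#'
#' Every pause is classified by the speakers of the adjacent utterances:
#' `P_P` (patient continues), `P_T` (patient then therapist), `T_P`
#' (therapist then patient) and `T_T` (therapist continues).  A pause with no
#' speech neighbour on one side (session edge) is labelled `BOUNDARY` and is
#' excluded from the four pattern features downstream.
#'
#' @param pauses pause episodes (`start`, `end`).
#' @param turns speaker turns (`start`, `end`, `speaker`).
#' @param tol timeline tolerance in seconds when matching neighbours.
#' @return `pauses` with a `pattern` column.
#' @export
label_patterns <- function(pauses, turns, tol = 1e-6) {
  check_episodes(pauses, "pauses")
  check_episodes(turns, "turns")
  if (nrow(pauses) == 0) {
    pauses$pattern <- character(0)
    return(pauses)
  }
  turns <- turns[order(turns$start), , drop = FALSE]
  # pauses must not overlap speech interiors
  for (i in seq_len(nrow(turns))) {
    bad <- pauses$start < turns$end[i] - tol & pauses$end > turns$start[i] + tol
    stop_if_not(!any(bad), "pauses overlap speech turns: inputs are inconsistent")
  }
  prev_idx <- findInterval(pauses$start + tol, turns$end)
  next_idx <- findInterval(pauses$end - tol, turns$start) + 1L
  has_prev <- prev_idx >= 1
  has_next <- next_idx <= nrow(turns)
  pat <- rep("BOUNDARY", nrow(pauses))
  both <- has_prev & has_next
  pat[both] <- paste0(toupper(substr(turns$speaker[prev_idx[both]], 1, 1)), "_",
                      toupper(substr(turns$speaker[next_idx[both]], 1, 1)))
  pauses$pattern <- pat
  pauses
}

#' Per-pattern pause time as percent of session time
#'
#' @param pauses labelled pauses from [label_patterns()].
#' @param total_time session (or aggregation) duration in seconds.
#' @return named numeric vector with percentages for `P_P`, `P_T`, `T_P`,
#'   `T_T`, `BOUNDARY` and their sum `total`.
#' @export
pattern_summary <- function(pauses, total_time) {
  stop_if_not(total_time > 0, "total_time must be positive")
  pats <- c("P_P", "P_T", "T_P", "T_T", "BOUNDARY")
  out <- stats::setNames(numeric(length(pats)), pats)
  if (nrow(pauses) > 0) {
    stop_if_not("pattern" %in% names(pauses), "pauses must be labelled first")
    agg <- tapply(pauses$end - pauses$start, pauses$pattern, sum)
    out[names(agg)] <- agg / total_time * 100
  }
  c(out, total = sum(out))
}
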
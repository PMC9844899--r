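#' Planted-parameter recovery summary
#'
#' Generates a default-calibrated synthetic corpus, windows it through the
#' ground-truth bypass path and recomputes the quantities the generator
#' plants: the mean pause percentage of non-rupture and rupture windows, the
#' fixed effects of Model B on the rupture windows, and the cell mean for
#' withdrawal ruptures carrying the minimal-response marker.  This is the
#' package's own recovery benchmark: with clinical recordings unavailable,
#' the planted defaults stand in for the published summary statistics and
#' the pipeline is expected to recover them up to Monte-Carlo error.
#'
#' @param seed master seed for the corpus.
#' @param n_dyads,sessions_per_dyad,session_length corpus dimensions; the
#'   defaults reproduce the clinical study's design (22 dyads, ~50-minute
#'   sessions) with enough sessions to make Monte-Carlo error small
#'   relative to the planted effects.
#' @return a list of `list(value =, n =)` entries: `nonrupture_pause_mean`,
#'   `rupture_pause_mean`, `model_b_intercept`, `model_b_withdrawal`,
#'   `model_b_minimal_response`, `withdrawal_mr_cell_mean`; plus the fitted
#'   `model_b` and the window table as attributes.
#' @export
planted_recovery <- function(seed, n_dyads = 22, sessions_per_dyad = 33,
                             session_length = 3000) {
  cfg <- generator_config(n_dyads = n_dyads,
                          sessions_per_dyad = sessions_per_dyad,
                          session_length = session_length,
                          seed = seed)
  corpus <- generate_corpus(cfg)
  w <- truth_to_window_table(corpus)
  r <- w[w$in_rupture, , drop = FALSE]
  fb <- fit_model_b(r)
  est <- fb$coefficients$estimate
  names(est) <- fb$coefficients$term
  cell <- r$dominant_type == "withdrawal" & r$minimal_response
  out <- list(
    nonrupture_pause_mean = list(value = mean(w$pause_pct[!w$in_rupture]),
                                 n = sum(!w$in_rupture)),
    rupture_pause_mean = list(value = mean(r$pause_pct), n = nrow(r)),
    model_b_intercept = list(value = unname(est[["(Intercept)"]]),
                             n = fb$n_obs),
    model_b_withdrawal = list(value = unname(est[["rupture_typewithdrawal"]]),
                              n = fb$n_obs),
    model_b_minimal_response = list(value = unname(est[["minimal_responseyes"]]),
                                    n = fb$n_obs),
    withdrawal_mr_cell_mean = list(value = mean(r$pause_pct[cell]),
                                   n = sum(cell)))
  attr(out, "model_b") <- fb
  attr(out, "windows") <- w
  out
}
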
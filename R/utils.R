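# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

other_speaker <- function(s) ifelse(s == "patient", "therapist", "patient")

#' @noRd
stop_if_not <- function(cond, msg, ...) {
  if (!isTRUE(cond)) stop(sprintf(msg, ...), call. = FALSE)
}

# lognormal draws parameterised by the arithmetic mean and the log-scale sd
rlnorm_mean <- function(n, mean, sdlog) {
  stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

# meanlog/sdlog of a lognormal with given arithmetic mean and sd
lnorm_params <- function(mean, sd) {
  s2 <- log(1 + (sd / mean)^2)
  list(meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

# deterministic 31-bit stream seed derived from a master seed and an index
derive_seed <- function(master, index) {
  m <- 2147483647
  x <- (as.numeric(master) %% m) + 1
  x <- (x * 48271 + 11 * (as.numeric(index) + 1)) %% m
  x <- (x * 48271 + 7919) %% m
  as.integer(x)
}

# evaluate `code` under a fixed seed, restoring the caller's RNG state
with_preserved_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# total duration of [start, end] episodes in a data.frame (0 for empty)
episode_seconds <- function(df) {
  if (is.null(df) || nrow(df) == 0) return(0)
  sum(df$end - df$start)
}

# overlap of one interval [a, b] with a set of episodes
interval_overlap <- function(a, b, starts, ends) {
  if (length(starts) == 0) return(0)
  sum(pmax(0, pmin(b, ends) - pmax(a, starts)))
}

check_episodes <- function(df, what = "episodes", tol = 1e-9) {
  if (nrow(df) == 0) return(invisible(df))
  stop_if_not(all(df$end > df$start), "%s must have end > start", what)
  if (nrow(df) > 1) {
    o <- order(df$start)
    s <- df$start[o]; e <- df$end[o]
    stop_if_not(all(s[-1] >= e[-nrow(df)] - tol), "%s must be non-overlapping", what)
  }
  invisible(df)
}
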
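# simulate window-level data with a known fixed effect and dyad intercepts
simulate_windows <- function(n_dyads = 8, n_per = 60, effect = 8,
                             tau = 5, sigma = 15, base = 30) {
  dyad <- rep(seq_len(n_dyads), each = n_per)
  u <- rnorm(n_dyads, 0, tau)[dyad]
  is_r <- rep(c(FALSE, TRUE), length.out = n_dyads * n_per)
  data.frame(dyad_id = dyad, in_rupture = is_r,
             pause_pct = base + u + effect * is_r + rnorm(n_dyads * n_per, 0, sigma))
}

test_that("estimates match closed-form group means on balanced noiseless data", {
  d <- expand.grid(dyad_id = 1:4, rep = 1:10,
                   dominant_type = c("confrontation", "withdrawal"),
                   minimal_response = c(FALSE, TRUE))
  d$pause_pct <- 30 + 3 * (d$dominant_type == "withdrawal") +
    12 * d$minimal_response
  d$in_rupture <- TRUE
  # noiseless data makes the optimiser grumble; only the estimates matter
  fb <- suppressWarnings(fit_model_b(d))
  est <- fb$coefficients$estimate
  names(est) <- fb$coefficients$term
  expect_equal(unname(est["(Intercept)"]), 30, tolerance = 1e-6)
  expect_equal(unname(est["rupture_typewithdrawal"]), 3, tolerance = 1e-6)
  expect_equal(unname(est["minimal_responseyes"]), 12, tolerance = 1e-6)
  # Model A, balanced noiseless
  d$in_rupture <- d$minimal_response
  d$pause_pct <- 20 + 7 * d$in_rupture
  fa <- suppressWarnings(fit_model_a(d))
  expect_equal(fa$coefficients$estimate, c(20, 7), tolerance = 1e-6)
})

test_that("a single dyad degrades to the two-group mean difference", {
  set.seed(31)
  d <- simulate_windows(n_dyads = 1, n_per = 80, effect = 6, tau = 0)
  fa <- fit_model_a(d)
  expect_equal(fa$convergence, "single_group")
  diff_means <- mean(d$pause_pct[d$in_rupture]) - mean(d$pause_pct[!d$in_rupture])
  expect_equal(fa$coefficients$estimate[2], diff_means, tolerance = 1e-8)
})

test_that("the null model keeps its nominal type-I rate", {
  set.seed(32)
  p <- replicate(120, {
    d <- simulate_windows(n_dyads = 6, n_per = 40, effect = 0)
    f <- fit_model_a(d)
    f$coefficients$p_value[f$coefficients$term == "is_rupture"]
  })
  rate <- mean(p < 0.05)
  expect_gt(rate, 0.005)
  expect_lt(rate, 0.12)
  # standardised effect is near zero on average
  set.seed(33)
  d0 <- simulate_windows(n_dyads = 10, n_per = 100, effect = 0)
  f0 <- fit_model_a(d0)
  expect_lt(abs(f0$coefficients$std_beta[2]), 0.15)
})

test_that("confidence intervals cover a planted effect at ~95%", {
  set.seed(34)
  hits <- replicate(200, {
    d <- simulate_windows(n_dyads = 6, n_per = 30, effect = 8)
    f <- fit_model_a(d)
    co <- f$coefficients[f$coefficients$term == "is_rupture", ]
    co$ci_low <= 8 && 8 <= co$ci_high
  })
  expect_gt(mean(hits), 0.90)
  expect_lt(mean(hits), 0.99)
})

test_that("the planted rupture-vs-baseline gap is recovered by Model A", {
  # a corpus whose every rupture cell targets 41.5% pauses plants a
  # 41.5 - 30.6 = 10.9 point gap between rupture and non-rupture windows
  cfg <- generator_config(n_dyads = 10, sessions_per_dyad = 5,
                          session_length = 1500, seed = 404,
                          effect_table = c(confrontation_no = 41.5,
                                           confrontation_yes = 41.5,
                                           withdrawal_no = 41.5,
                                           withdrawal_yes = 41.5))
  w <- truth_to_window_table(generate_corpus(cfg))
  fa <- fit_model_a(w)
  co <- fa$coefficients[fa$coefficients$term == "is_rupture", ]
  expect_lt(abs(co$estimate - 10.9), 2.5)
  expect_lt(co$p_value, 0.001)
  expect_true(fa$icc >= 0 && fa$icc < 1)
  expect_lte(fa$marginal_r2, fa$conditional_r2)
})

test_that("permuting rupture type within dyad nulls the type effect", {
  w <- recovery_windows()
  r <- w[w$in_rupture, ]
  set.seed(35)
  r$dominant_type <- sample(r$dominant_type)
  fb <- fit_model_b(r)
  co <- fb$coefficients[fb$coefficients$term == "rupture_typewithdrawal", ]
  expect_lt(abs(co$estimate), 3 * co$std_error)
})

test_that("an all-confrontation, no-marker input reduces to the intercept", {
  set.seed(36)
  d <- data.frame(dyad_id = rep(1:5, each = 30),
                  dominant_type = "confrontation", minimal_response = FALSE,
                  in_rupture = TRUE,
                  pause_pct = rnorm(150, 33, 10))
  fb <- fit_model_b(d)
  expect_equal(nrow(fb$coefficients), 1)
  expect_equal(fb$coefficients$estimate[1], mean(d$pause_pct), tolerance = 0.5)
})

test_that("Bonferroni adjustment caps at one and sqrt refits keep signs", {
  w <- recovery_windows()
  fa <- fit_model_a(w)
  fb <- fit_model_b(w[w$in_rupture, ])
  res <- adjust_and_sensitivity(fa, fb)
  expect_equal(res$model_a$coefficients$p_adjusted,
               pmin(1, 2 * res$model_a$coefficients$p_value))
  # sqrt sensitivity refit preserves the direction of the planted effects
  raw <- res$model_b$coefficients$estimate
  sq <- res$model_b_sqrt$coefficients$estimate
  expect_equal(sign(raw), sign(sq))
  expect_identical(res$model_b_sqrt$response, "sqrt_pause_pct")
  # the capping rule itself
  expect_equal(pmin(1, 2 * c(0.03, 0.7)), c(0.06, 1))
})

test_that("the time course is onset-aligned with SEM over ruptures", {
  # pauses laid out with exact 10-s periodicity: every onset-aligned bin
  # holds exactly 30% pause whatever the onset phase
  mk <- function(onset) {
    list(session_length = 600,
         pauses = data.frame(start = seq(0, 590, by = 10),
                             end = seq(0, 590, by = 10) + 3),
         ruptures = data.frame(start = onset, end = onset + 100,
                               dominant_type = "withdrawal",
                               minimal_response = TRUE))
  }
  tc <- rupture_timecourse(list(mk(237.3), mk(341.8)))
  expect_true(all(abs(tc$mean_pause_pct - 30) < 1e-9))
  expect_true(all(is.na(tc$sem) | tc$sem < 1e-9))
  expect_equal(attr(tc, "overall_mean"), 30, tolerance = 1e-9)
  # a single rupture leaves the SEM missing, not zero
  tc1 <- rupture_timecourse(list(mk(250)))
  expect_true(all(is.na(tc1$sem)))
  expect_true(all(tc1$n_ruptures == 1))
})

test_that("withdrawal ruptures show the pre-onset rise, confrontation does not", {
  # sparse corpus (one rupture per session) so pre-onset bins are not
  # contaminated by neighbouring episodes
  cfg <- generator_config(n_dyads = 8, sessions_per_dyad = 6,
                          session_length = 1800, seed = 909,
                          ruptures_per_session = 1)
  tc <- rupture_timecourse(generate_corpus(cfg))
  rise <- function(type) {
    x <- tc[tc$rupture_type == type, ]
    mean(x$mean_pause_pct[x$offset %in% c(-2, -1)]) -
      mean(x$mean_pause_pct[x$offset <= -5])
  }
  expect_gt(rise("withdrawal"), 2)
  expect_gt(rise("withdrawal"), rise("confrontation"))
  ls <- attr(tc, "length_summary")
  expect_setequal(ls$rupture_type, c("withdrawal", "confrontation"))
  expect_true(all(ls$q25 <= ls$median & ls$median <= ls$q75))
})
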
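# Linear mixed-effects analyses of the pause-rupture association.
#
# Two models, both with percent of pauses per 10-s window as the response
# and a random intercept by dyad, estimated by REML with
# Satterthwaite-style degrees of freedom for the fixed-effect p-values:
#   Model A: pause_pct ~ is_rupture            (all windows)
#   Model B: pause_pct ~ type + minimal_response   (rupture windows only)
# Standardised betas follow the refit convention of common reporting tools:
# the response is z-scored, binary predictors are left on their 0/1 scale.

fit_mixed <- function(data, rhs, response = "pause_pct") {
  single <- length(unique(data$dyad_id)) < 2
  fml <- if (single) {
    stats::as.formula(paste(response, "~", rhs))
  } else {
    stats::as.formula(paste(response, "~", rhs, "+ (1 | dyad_id)"))
  }
  if (single) {
    fit <- stats::lm(fml, data = data)
  } else {
    fit <- lmerTest::lmer(fml, data = data, REML = TRUE)
  }
  fit
}

extract_fit <- function(fit, data, response, model_label) {
  single <- inherits(fit, "lm")
  if (single) {
    sm <- summary(fit)$coefficients
    est <- stats::setNames(sm[, "Estimate"], rownames(sm))
    se <- sm[, "Std. Error"]; pv <- sm[, "Pr(>|t|)"]
    sigma2 <- summary(fit)$sigma^2
    tau2 <- 0
    n_groups <- 1L
    conv <- "single_group"
  } else {
    sm <- stats::coef(summary(fit))
    est <- stats::setNames(sm[, "Estimate"], rownames(sm))
    se <- sm[, "Std. Error"]; pv <- sm[, "Pr(>|t|)"]
    vc <- as.data.frame(lme4::VarCorr(fit))
    tau2 <- vc$vcov[vc$grp == "dyad_id"]
    sigma2 <- vc$vcov[vc$grp == "Residual"]
    n_groups <- lme4::ngrps(fit)[["dyad_id"]]
    conv <- if (lme4::isSingular(fit)) "singular" else "ok"
  }
  y <- data[[response]]
  sdy <- stats::sd(y)
  std_est <- est / sdy
  std_est["(Intercept)"] <- (est[["(Intercept)"]] - mean(y)) / sdy
  std_se <- se / sdy
  z <- stats::qnorm(0.975)
  coefs <- data.frame(
    term = rownames(sm),
    estimate = unname(est), std_error = unname(se),
    std_beta = unname(std_est), std_std_error = unname(std_se),
    ci_low = unname(est - z * se), ci_high = unname(est + z * se),
    std_ci_low = unname(std_est - z * std_se),
    std_ci_high = unname(std_est + z * std_se),
    p_value = unname(pv), p_adjusted = NA_real_,
    row.names = NULL)
  var_fixed <- stats::var(as.numeric(stats::model.matrix(fit) %*%
                                       (if (single) stats::coef(fit) else lme4::fixef(fit))))
  total <- var_fixed + tau2 + sigma2
  structure(list(model = model_label,
                 coefficients = coefs,
                 sigma2 = sigma2, tau2 = tau2,
                 icc = tau2 / (tau2 + sigma2),
                 n_groups = n_groups, n_obs = nrow(data),
                 marginal_r2 = var_fixed / total,
                 conditional_r2 = (var_fixed + tau2) / total,
                 convergence = conv,
                 response = response,
                 fit = fit, data = data),
            class = "mixed_model_fit")
}

#' @export
print.mixed_model_fit <- function(x, digits = 3, ...) {
  cat(sprintf("<mixed_model_fit> %s (%s; response %s)\n", x$model,
              x$convergence, x$response))
  print(format(x$coefficients[, c("term", "estimate", "std_error", "std_beta",
                                  "ci_low", "ci_high", "p_value", "p_adjusted")],
               digits = digits), row.names = FALSE)
  cat(sprintf("  sigma2 %.2f | ICC %.3f | N_dyads %d | observations %d\n",
              x$sigma2, x$icc, x$n_groups, x$n_obs))
  cat(sprintf("  marginal R2 %.3f / conditional R2 %.3f\n",
              x$marginal_r2, x$conditional_r2))
  invisible(x)
}

#' Model A: pauses in ruptures vs. non-ruptures
#'
#' `pause_pct ~ is_rupture + (1 | dyad_id)` over all windows of the corpus.
#'
#' @param windows window table (e.g. from [truth_to_window_table()]) with
#'   `dyad_id`, `pause_pct`, `in_rupture`.
#' @param response response column (`pause_pct`; the square-root sensitivity
#'   refit passes a transformed column).
#' @return a `mixed_model_fit`.
#' @export
fit_model_a <- function(windows, response = "pause_pct") {
  stop_if_not(all(c("dyad_id", response, "in_rupture") %in% names(windows)),
              "windows must carry dyad_id, %s, in_rupture", response)
  stop_if_not(any(windows$in_rupture) && any(!windows$in_rupture),
              "need both rupture and non-rupture windows")
  data <- windows
  data$is_rupture <- as.integer(data$in_rupture)
  fit <- fit_mixed(data, "is_rupture", response)
  extract_fit(fit, data, response, "Model A (ruptures vs non-ruptures)")
}

#' Model B: pauses by rupture type and minimal-response marker
#'
#' `pause_pct ~ rupture_type + minimal_response + (1 | dyad_id)`, estimated
#' exclusively on rupture windows.  The reference cell is a confrontation
#' window without the minimal-response marker.  Constant predictors (e.g.
#' an all-confrontation input) are dropped, degrading gracefully to an
#' intercept-only model.
#'
#' @param rupture_windows window table restricted to rupture windows, with
#'   `dominant_type` and `minimal_response`.
#' @param response response column.
#' @return a `mixed_model_fit`.
#' @export
fit_model_b <- function(rupture_windows, response = "pause_pct") {
  stop_if_not(all(c("dyad_id", response, "dominant_type", "minimal_response")
                  %in% names(rupture_windows)), "missing columns")
  stop_if_not(all(rupture_windows$in_rupture %||% TRUE),
              "Model B is fit on rupture windows only")
  data <- rupture_windows
  data$rupture_type <- factor(as.character(data$dominant_type),
                              levels = c("confrontation", "withdrawal"))
  mr <- data$minimal_response
  if (is.factor(mr)) mr <- mr == "yes"
  data$minimal_response <- factor(ifelse(mr, "yes", "no"),
                                  levels = c("no", "yes"))
  terms <- c()
  if (nlevels(droplevels(data$rupture_type)) > 1) terms <- c(terms, "rupture_type")
  if (nlevels(droplevels(data$minimal_response)) > 1) {
    terms <- c(terms, "minimal_response")
  }
  rhs <- if (length(terms) == 0) "1" else paste(terms, collapse = " + ")
  fit <- fit_mixed(data, rhs, response)
  extract_fit(fit, data, response, "Model B (rupture type + minimal response)")
}

#' Bonferroni adjustment and square-root sensitivity refits
#'
#' Adjusts the two primary models' p-values for the two tests performed
#' (`p_adj = min(1, 2p)`) and refits both with a square-root transformed
#' response, the standard robustness check for the positively skewed pause
#' percentages.
#'
#' @param model_a,model_b the two primary `mixed_model_fit`s.
#' @return list with `model_a`, `model_b` (p-adjusted) and `model_a_sqrt`,
#'   `model_b_sqrt` refits.
#' @export
adjust_and_sensitivity <- function(model_a, model_b) {
  stop_if_not(inherits(model_a, "mixed_model_fit") &&
                inherits(model_b, "mixed_model_fit"),
              "expects the two primary mixed_model_fits")
  n_models <- 2
  for (nm in c("model_a", "model_b")) {
    m <- get(nm)
    m$coefficients$p_adjusted <- pmin(1, n_models * m$coefficients$p_value)
    assign(nm, m)
  }
  refit_sqrt <- function(m) {
    data <- m$data
    data$sqrt_pause_pct <- sqrt(pmax(data[[m$response]], 0))
    if (grepl("Model A", m$model)) fit_model_a(data, response = "sqrt_pause_pct")
    else fit_model_b(data, response = "sqrt_pause_pct")
  }
  list(model_a = model_a, model_b = model_b,
       model_a_sqrt = refit_sqrt(model_a),
       model_b_sqrt = refit_sqrt(model_b))
}

#' Write a mixed-model report
#'
#' CSV of the coefficient table plus a JSON with the variance components.
#'
#' @param fit a `mixed_model_fit`.
#' @param stem output path stem (writes `<stem>.csv` and `<stem>.json`).
#' @return paths, invisibly.
#' @export
write_model_report <- function(fit, stem) {
  utils::write.csv(fit$coefficients, paste0(stem, ".csv"), row.names = FALSE)
  jsonlite::write_json(
    list(model = fit$model, sigma2 = fit$sigma2, icc = fit$icc,
         n_groups = fit$n_groups, n_obs = fit$n_obs,
         marginal_r2 = fit$marginal_r2, conditional_r2 = fit$conditional_r2,
         convergence = fit$convergence),
    paste0(stem, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(c(paste0(stem, ".csv"), paste0(stem, ".json")))
}
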
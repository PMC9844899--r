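# build a toy feature table shaped like the add_lags() output
toy_features <- function(n_ruptures = 30, windows_each = 6, effect = 2,
                         seed = 1) {
  set.seed(seed)
  rows <- do.call(rbind, lapply(seq_len(n_ruptures), function(r) {
    mr <- r %% 2 == 0
    data.frame(dyad_id = (r %% 5) + 1, session_id = 1,
               window_index = seq_len(windows_each) + r * 100,
               rupture_id = sprintf("r%03d", r),
               minimal_response = mr,
               in_rupture = TRUE,
               z_T_T_lag_0 = rnorm(windows_each, ifelse(mr, effect, 0)),
               z_P_P_lag_0 = rnorm(windows_each))
  }))
  attr(rows, "feature_cols") <- c("z_T_T_lag_0", "z_P_P_lag_0")
  rows
}

test_that("rupture splits are episode-level, stratified, length-weighted", {
  # 3 equal-length ruptures in one stratum: exactly 2 go to training
  rows <- toy_features(n_ruptures = 3, windows_each = 5)
  rows$dyad_id <- 1
  rows$minimal_response <- FALSE
  sp <- suppressWarnings(split_ruptures(rows, seed = 2))
  expect_equal(length(unique(sp$train$rupture_id)), 2)
  expect_equal(length(unique(sp$validation$rupture_id)), 1)
  # no window (episode) on both sides
  rows <- toy_features(n_ruptures = 40)
  sp <- split_ruptures(rows, seed = 3)
  expect_length(intersect(sp$train$rupture_id, sp$validation$rupture_id), 0)
  expect_equal(nrow(sp$train) + nrow(sp$validation), nrow(rows))
  # over seeds the training share of rupture seconds is ~ 2/3
  set.seed(4)
  share <- vapply(1:40, function(s) {
    rows <- toy_features(n_ruptures = 30, windows_each = sample(3:12, 1),
                         seed = s)
    sp <- split_ruptures(rows, seed = s)
    a <- sp$allocation
    sum(a$seconds[a$side == "train"]) / sum(a$seconds)
  }, numeric(1))
  expect_lt(abs(mean(share) - 2 / 3), 0.05)
})

test_that("training degenerates sensibly at the extremes", {
  rows <- toy_features(effect = 50)  # perfectly separable
  m <- train_rupture_classifier(rows, n_trees = 100, mtry = 2, seed = 5)
  expect_lt(m$oob_error, 2)
  rows1 <- rows[!rows$minimal_response, ]
  expect_error(train_rupture_classifier(rows1, seed = 1), "single class")
})

test_that("shuffled labels yield chance-level validation AUC", {
  rows <- toy_features(n_ruptures = 120, windows_each = 8, effect = 2,
                       seed = 6)
  set.seed(7)
  shuf <- sample(nrow(rows))
  rows$minimal_response <- rows$minimal_response[shuf]
  sp <- split_ruptures(rows, seed = 8)
  m <- train_rupture_classifier(sp$train, n_trees = 300, mtry = 2, seed = 9)
  rep <- evaluate_classifier(m, sp$validation)
  expect_lt(abs(rep$auc_ruptures_only - 0.5), 0.05)
})

test_that("permutation importance isolates informative features", {
  rows <- toy_features(n_ruptures = 80, windows_each = 6, effect = 2, seed = 10)
  m <- train_rupture_classifier(rows, n_trees = 300, mtry = 2, seed = 11)
  imp <- marker_importance(m)
  expect_equal(imp$feature[1], "z_T_T_lag_0")
  expect_lt(abs(imp$mean_decrease_accuracy[imp$feature == "z_P_P_lag_0"]), 1)
  # duplicating a useless feature leaves the informative one on top
  rows2 <- rows
  rows2$z_P_P_dup_lag_1 <- rows$z_P_P_lag_0 +
    rnorm(nrow(rows), 0, 1e-6)
  attr(rows2, "feature_cols") <- c(attr(rows, "feature_cols"),
                                   "z_P_P_dup_lag_1")
  m2 <- train_rupture_classifier(rows2, n_trees = 300, mtry = 2, seed = 11)
  expect_equal(marker_importance(m2)$feature[1], "z_T_T_lag_0")
})

test_that("AUC agrees between rank form, swept ROC and an external oracle", {
  expect_equal(auc_rank(c(0.9, 0.8, 0.1, 0.2), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(auc_rank(-c(0.9, 0.8, 0.1, 0.2), c(TRUE, TRUE, FALSE, FALSE)), 0)
  s <- c(0.9, 0.4, 0.4, 0.2, 0.1)
  y <- c(TRUE, TRUE, FALSE, FALSE, FALSE)
  expect_equal(auc_rank(s, y), 1 - auc_rank(-s, y))
  set.seed(13)
  for (i in 1:25) {
    n <- sample(20:200, 1)
    sc <- round(runif(n), sample(c(1, 2, 6), 1))  # ties at low precision
    yy <- runif(n) < 0.4
    if (!any(yy) || all(yy)) next
    a_rank <- auc_rank(sc, yy)
    a_trap <- auc_trapezoid(roc_points(sc, yy))
    expect_equal(a_rank, a_trap, tolerance = 1e-9)
    a_oracle <- as.numeric(pROC::auc(pROC::roc(yy, sc, quiet = TRUE,
                                               direction = "<")))
    expect_equal(a_rank, a_oracle, tolerance = 1e-9)
  }
  # ROC is monotone in both coordinates
  rc <- roc_points(runif(50), runif(50) < 0.5)
  expect_true(all(diff(rc$fpr) >= 0))
  expect_true(all(diff(rc$tpr) >= 0))
})

test_that("evaluation requires both classes in the validation set", {
  rows <- toy_features(n_ruptures = 20, seed = 14)
  m <- train_rupture_classifier(rows, n_trees = 50, mtry = 2, seed = 15)
  only_pos <- rows[rows$minimal_response, ]
  expect_error(evaluate_classifier(m, only_pos), "both positive and negative")
})
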
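#' Split rupture episodes into training and validation sets
#'
#' Allocation is at the *episode* level (all windows of one rupture land on
#' the same side), stratified by dyad and minimal-response status, and
#' weighted by rupture length: within each stratum, episodes are shuffled
#' and the training side receives the prefix whose total rupture seconds is
#' closest to `train_fraction` of the stratum's seconds.  Degenerate strata
#' holding a single episode go to training with a warning.
#'
#' @param rows feature rows (from [add_lags()]) restricted or not to
#'   ruptures; only rows with a `rupture_id` are split.
#' @param train_fraction target share of rupture seconds in training (2/3).
#' @param seed integer seed.
#' @param window window length in seconds (to convert window counts to
#'   seconds).
#' @return list with `train`, `validation` (row subsets) and `allocation`
#'   (episode-level data.frame with a `side` column).
#' @export
split_ruptures <- function(rows, train_fraction = 2 / 3, seed = 1L, window = 10) {
  stop_if_not(nrow(rows) > 0, "empty input")
  rows <- rows[!is.na(rows$rupture_id), , drop = FALSE]
  stop_if_not(nrow(rows) > 0, "no rupture windows in input")
  epi <- stats::aggregate(list(n_windows = rows$window_index),
                          by = list(rupture_id = rows$rupture_id,
                                    dyad_id = rows$dyad_id,
                                    minimal_response = rows$minimal_response),
                          FUN = length)
  epi$seconds <- epi$n_windows * window
  epi$stratum <- paste(epi$dyad_id, epi$minimal_response, sep = "|")
  degenerate <- FALSE
  side <- character(nrow(epi))
  with_preserved_seed(seed, {
    for (st in unique(epi$stratum)) {
      i <- which(epi$stratum == st)
      if (length(i) == 1L) {
        side[i] <- "train"
        degenerate <- TRUE
        next
      }
      i <- sample(i)
      cs <- cumsum(epi$seconds[i])
      target <- train_fraction * cs[length(cs)]
      k <- which.min(abs(cs - target))
      k <- min(max(k, 1L), length(i) - 1L)  # leave at least one for validation
      side[i[seq_len(k)]] <- "train"
      side[i[-seq_len(k)]] <- "validation"
    }
  })
  if (degenerate) {
    warning("strata with a single rupture were assigned to training")
  }
  epi$side <- side
  rows$side <- side[match(rows$rupture_id, epi$rupture_id)]
  list(train = rows[rows$side == "train", , drop = FALSE],
       validation = rows[rows$side == "validation", , drop = FALSE],
       allocation = epi)
}

#' Train the minimal-response marker classifier
#'
#' A random forest over the 44 z-scored, lagged pattern-pause features,
#' trained on rupture windows only; out-of-bag votes give the OOB error and
#' the permutation (mean-decrease-accuracy) feature importances.
#'
#' @param train feature rows (training side of [split_ruptures()]).
#' @param n_trees number of trees (500).
#' @param mtry variables tried at each split (6).
#' @param seed integer seed.
#' @return object of class `rupture_model`: the forest, feature names,
#'   `oob_error` (percent), `n_trees`, `mtry`.
#' @export
train_rupture_classifier <- function(train, n_trees = 500, mtry = 6, seed = 1L) {
  fc <- attr(train, "feature_cols") %||%
    grep("^z_.*_lag_", names(train), value = TRUE)
  stop_if_not(length(fc) > 0, "no lagged pattern features in input")
  y <- factor(ifelse(train$minimal_response, "yes", "no"), levels = c("no", "yes"))
  stop_if_not(nlevels(droplevels(y)) == 2, "training set holds a single class")
  x <- train[, fc, drop = FALSE]
  fit <- with_preserved_seed(seed, {
    randomForest::randomForest(x = x, y = y, ntree = n_trees, mtry = mtry,
                               importance = TRUE)
  })
  oob <- unname(fit$err.rate[n_trees, "OOB"]) * 100
  structure(list(forest = fit, feature_names = fc,
                 oob_error = oob, n_trees = n_trees, mtry = mtry,
                 seed = as.integer(seed)),
            class = "rupture_model")
}

#' @export
print.rupture_model <- function(x, ...) {
  cat(sprintf("<rupture_model> %d trees, mtry=%d, OOB error %.2f%%\n",
              x$n_trees, x$mtry, x$oob_error))
  invisible(x)
}

#' Permutation feature importance
#'
#' Mean decrease in accuracy (percent) when each feature is permuted in the
#' out-of-bag samples, ranked from most to least important.
#'
#' @param model a [train_rupture_classifier()] result.
#' @return data.frame `feature`, `mean_decrease_accuracy`, sorted
#'   decreasingly.
#' @export
marker_importance <- function(model) {
  stop_if_not(inherits(model, "rupture_model"), "model must be a rupture_model")
  imp <- randomForest::importance(model$forest, type = 1, scale = FALSE)
  out <- data.frame(feature = rownames(imp),
                    mean_decrease_accuracy = imp[, 1] * 100,
                    row.names = NULL)
  out[order(-out$mean_decrease_accuracy), , drop = FALSE]
}

#' Evaluate the marker classifier
#'
#' Scores the validation windows with out-of-forest vote fractions, sweeps
#' the ROC and reports the rank-based AUC, both on rupture windows alone and
#' (optionally) with all non-rupture windows added as negatives — windows
#' outside ruptures by definition contain no minimal-response marker.
#'
#' @param model a [train_rupture_classifier()] result.
#' @param validation validation feature rows.
#' @param nonrupture optional non-rupture feature rows appended as
#'   negatives.
#' @return object of class `classifier_report`: `oob_error`, `n_trees`,
#'   `mtry`, `auc_ruptures_only`, `roc_ruptures_only`, and when non-rupture
#'   rows are supplied `auc_with_nonruptures`, `roc_with_nonruptures`;
#'   plus `importance`.
#' @export
evaluate_classifier <- function(model, validation, nonrupture = NULL) {
  stop_if_not(inherits(model, "rupture_model"), "model must be a rupture_model")
  stop_if_not(all(model$feature_names %in% names(validation)),
              "feature spec mismatch")
  score <- function(rows) {
    stats::predict(model$forest, newdata = rows[, model$feature_names,
                                                drop = FALSE],
                   type = "prob")[, "yes"]
  }
  y <- validation$minimal_response
  stop_if_not(any(y) && any(!y),
              "validation set needs both positive and negative windows")
  s <- score(validation)
  rep <- list(oob_error = model$oob_error, n_trees = model$n_trees,
              mtry = model$mtry,
              auc_ruptures_only = auc_rank(s, y),
              roc_ruptures_only = roc_points(s, y),
              importance = marker_importance(model))
  if (!is.null(nonrupture) && nrow(nonrupture) > 0) {
    s2 <- c(s, score(nonrupture))
    y2 <- c(y, rep(FALSE, nrow(nonrupture)))
    rep$auc_with_nonruptures <- auc_rank(s2, y2)
    rep$roc_with_nonruptures <- roc_points(s2, y2)
  }
  structure(rep, class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf("<classifier_report> OOB %.2f%% | AUC (ruptures only) %.3f",
              x$oob_error, x$auc_ruptures_only))
  if (!is.null(x$auc_with_nonruptures)) {
    cat(sprintf(" | AUC (+non-ruptures) %.3f", x$auc_with_nonruptures))
  }
  cat(sprintf("\n  top feature: %s\n", x$importance$feature[1]))
  invisible(x)
}

#' Write a classifier report to disk
#'
#' JSON summary plus ROC-point and ranked-importance CSVs.
#'
#' @param report a [evaluate_classifier()] result.
#' @param dir output directory.
#' @return paths written, invisibly.
#' @export
write_classifier_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(json = file.path(dir, "classifier_report.json"),
             roc = file.path(dir, "roc_ruptures_only.csv"),
             importance = file.path(dir, "importance.csv"))
  jsonlite::write_json(
    list(oob_error = report$oob_error, n_trees = report$n_trees,
         mtry = report$mtry,
         auc_ruptures_only = report$auc_ruptures_only,
         auc_with_nonruptures = report$auc_with_nonruptures),
    paths["json"], auto_unbox = TRUE, digits = NA)
  utils::write.csv(report$roc_ruptures_only, paths["roc"], row.names = FALSE)
  if (!is.null(report$roc_with_nonruptures)) {
    p <- file.path(dir, "roc_with_nonruptures.csv")
    utils::write.csv(report$roc_with_nonruptures, p, row.names = FALSE)
    paths <- c(paths, roc_nonrupture = p)
  }
  utils::write.csv(report$importance, paths["importance"], row.names = FALSE)
  invisible(paths)
}
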
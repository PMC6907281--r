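# Random-Forest outcome classifier with leave-one-patient-out evaluation.

#' Model configuration
#'
#' Forest and evaluation settings: 100 trees with terminal-node growth
#' capped at 20 (chosen by the out-of-bag error in the original analysis),
#' the Breiman default sqrt(p) candidate features per split, top-10
#' feature selection, and a mandatory seed so every stochastic result is
#' reproducible.
#'
#' @param n_trees trees in the forest.
#' @param max_nodes maximum terminal nodes per tree.
#' @param top_k number of features kept by importance selection.
#' @param seed RNG seed used for every fit/bootstrap in this config.
#' @param scheme GOSE dichotomy, `"1-2"` or `"1-4"`.
#' @param boot_n bootstrap resamples for the 50% AUC confidence interval.
#' @return Named list of class `model_config`.
#' @export
model_config <- function(n_trees = 100, max_nodes = 20, top_k = 10,
                         seed = 1, scheme = "1-2", boot_n = 2000) {
  stopifnot(n_trees >= 1, max_nodes >= 2)
  structure(list(n_trees = n_trees, max_nodes = max_nodes, top_k = top_k,
                 seed = seed, scheme = scheme, boot_n = boot_n),
            class = "model_config")
}

obs_matrix <- function(table) {
  cols <- attr(table, "feature_cols")
  if (is.null(cols))
    cols <- setdiff(names(table), c("patient_id", "window_index", "label"))
  as.matrix(table[, cols, drop = FALSE])
}

#' Fit the Random-Forest classifier
#'
#' Breiman classification forest (package `randomForest`, as in the
#' original analysis): bootstrap per tree, `maxnodes` terminal-node cap,
#' sqrt(p) candidates per split.  Predictions are poor-outcome vote
#' fractions.  Deterministic given the config seed.
#'
#' @param table an observation table from [assemble()].
#' @param config a [model_config()].
#' @return Object of class `rf_fit`: the forest plus normalised
#'   mean-decrease-in-impurity importances.
#' @export
fit_rf <- function(table, config = model_config()) {
  x <- obs_matrix(table)
  y <- table$label
  if (nlevels(droplevels(y)) < 2)
    stop("degenerate labels: both outcome classes are required for fitting")
  set.seed(config$seed)
  # class-balanced bootstrap per tree: without it, leave-one-patient-out
  # systematically skews the class prior against the held-out patient's
  # class, which under exchangeable features drives patient scores by the
  # prior alone and biases the null AUC far below 0.5
  n_min <- min(table(y))
  fit <- withCallingHandlers(
    randomForest::randomForest(
      x = x, y = y, ntree = config$n_trees, maxnodes = config$max_nodes,
      strata = y, sampsize = c(n_min, n_min)),
    # benign on small training sets: the node cap cannot be reached
    warning = function(w) {
      if (grepl("maxnodes", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  imp <- fit$importance[, "MeanDecreaseGini"]
  imp <- if (sum(imp) > 0) imp / sum(imp) else imp
  structure(list(forest = fit, importances = imp, config = config),
            class = "rf_fit")
}

#' Poor-outcome vote fractions for new observations
#' @param fit an `rf_fit`.
#' @param table observation table with the same feature columns.
#' @return Numeric vector in `[0, 1]`.
#' @export
predict_votes <- function(fit, table) {
  x <- obs_matrix(table)
  x <- x[, rownames(fit$forest$importance), drop = FALSE]
  as.numeric(stats::predict(fit$forest, x, type = "prob")[, "poor"])
}

# patient-level ROC machinery -------------------------------------------

# ROC/AUC with pROC; the operating threshold maximises Youden's J with
# ties broken towards higher specificity.
score_roc <- function(scores, labels, boot_n = 2000, seed = 1) {
  roc <- pROC::roc(response = labels, predictor = scores,
                   levels = c("good", "poor"), direction = "<", quiet = TRUE)
  auc <- as.numeric(pROC::auc(roc))
  set.seed(seed)
  ci <- tryCatch(
    suppressWarnings(
      as.numeric(pROC::ci.auc(roc, conf.level = 0.5, method = "bootstrap",
                              boot.n = boot_n))),
    error = function(e) c(auc, auc, auc))
  j <- roc$sensitivities + roc$specificities - 1
  best <- which(j == max(j))
  best <- best[which.max(roc$specificities[best])]
  list(roc_points = data.frame(fpr = 1 - roc$specificities,
                               tpr = roc$sensitivities,
                               threshold = roc$thresholds),
       auc = auc, auc_ci50 = c(lower = ci[1], upper = ci[3]),
       threshold_star = roc$thresholds[best],
       sensitivity = roc$sensitivities[best],
       specificity = roc$specificities[best])
}

#' Leave-one-patient-out evaluation
#'
#' For each patient, a forest is trained on all other patients'
#' observations and the held-out patient's windows are scored; the mean
#' vote fraction over those windows is the patient's score.  ROC and AUC
#' are computed over patient scores with poor outcome as the positive
#' class; the 50% confidence interval is a 2000-resample patient-level
#' bootstrap (25th-75th AUC percentiles); the operating threshold
#' maximises Youden's J (ties towards specificity).  Feature importances
#' come from one fit on the full table.
#'
#' @param table an observation table from [assemble()].
#' @param config a [model_config()].
#' @return An `evaluation_report`: `per_patient_score` (data.frame with
#'   patient_id, score, label), `roc_points`, `auc`, `auc_ci50`,
#'   `threshold_star`, `sensitivity`, `specificity`, `importances`.
#' @export
lopo <- function(table, config = model_config()) {
  pts <- unique(table$patient_id)
  if (length(pts) < 3) stop("leave-one-patient-out needs at least 3 patients")
  scores <- labels <- setNames(rep(NA_real_, length(pts)), pts)
  for (p in pts) {
    train <- table[table$patient_id != p, , drop = FALSE]
    test <- table[table$patient_id == p, , drop = FALSE]
    attr(train, "feature_cols") <- attr(table, "feature_cols")
    attr(test, "feature_cols") <- attr(table, "feature_cols")
    fit <- fit_rf(train, config)
    scores[p] <- mean(predict_votes(fit, test))
    labels[p] <- as.character(unique(test$label))
  }
  lab <- factor(labels, levels = c("good", "poor"))
  r <- score_roc(scores, lab, config$boot_n, config$seed)
  full_fit <- fit_rf(table, config)
  structure(
    c(list(per_patient_score = data.frame(patient_id = pts, score = scores,
                                          label = lab, row.names = NULL),
           importances = full_fit$importances,
           n_patients = length(pts), n_obs = nrow(table),
           config = config),
      r),
    class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %d patients, %d observations\n",
              x$n_patients, x$n_obs))
  cat(sprintf("  AUC %.3f (50%% CI %.3f-%.3f); threshold %.3f, sens %.2f, spec %.2f\n",
              x$auc, x$auc_ci50[1], x$auc_ci50[2],
              x$threshold_star, x$sensitivity, x$specificity))
  top <- sort(x$importances, decreasing = TRUE)[1:min(5, length(x$importances))]
  cat("  top importances:", paste(names(top), collapse = ", "), "\n")
  invisible(x)
}

#' Select the most important features
#'
#' The k features with the highest mean-decrease-in-impurity importance;
#' ties are broken deterministically by original column order.
#'
#' @param importances named importance vector (e.g. from an
#'   `evaluation_report` or `rf_fit`).
#' @param k subset size.
#' @return Character vector of k feature names.
#' @export
select_top_k <- function(importances, k = 10) {
  if (k > length(importances))
    stop("k exceeds the number of available features")
  ord <- order(-importances, seq_along(importances))
  names(importances)[ord][seq_len(k)]
}

interval_sets <- function(intervals = c(24, 48, 72, 96)) {
  singles <- as.list(intervals)
  pairs <- utils::combn(intervals, 2, simplify = FALSE)
  c(singles, pairs)
}

#' Three-stage modelling protocol
#'
#' Stage 1: full-feature models (23 qEEG features + MAP + age) on each
#' single interval and each of the six two-interval combinations.  Stage
#' 2: each model refit on its 10 most important features (ranked by a fit
#' on the full training table).  Stage 3: the stage-2 feature sets
#' augmented with the nine non-age IMPACT admission parameters.  Every
#' model is evaluated by leave-one-patient-out.
#'
#' @param features per-window feature table.
#' @param clin validated clinical table.
#' @param map_df long MAP table.
#' @param config a [model_config()].
#' @param intervals intervals with data (missing combinations are skipped
#'   with a warning).
#' @return A `protocol_report`: `models` (one row per stage x interval
#'   set: stage, intervals, n_features, n_patients, auc, ci, threshold,
#'   sensitivity, specificity), `reports` (the evaluation_report list),
#'   `feature_sets`, and the indices of the best stage-2/stage-3 models.
#' @export
run_protocol <- function(features, clin, map_df, config = model_config(),
                         intervals = c(24, 48, 72, 96)) {
  sets <- interval_sets(intervals)
  rows <- list(); reports <- list(); fsets <- list()
  for (st in 1:3) for (si in seq_along(sets)) {
    ivs <- sets[[si]]
    key <- paste0("stage", st, ":", paste(ivs, collapse = "+"))
    tab <- tryCatch(
      assemble(features, clin, map_df, ivs,
               include_impact = (st == 3), scheme = config$scheme),
      error = function(e) NULL)
    if (is.null(tab)) {
      warning("skipping ", key, ": no complete observations")
      next
    }
    if (st >= 2) {
      base_key <- paste0("stage1:", paste(ivs, collapse = "+"))
      base_rep <- reports[[base_key]]
      if (is.null(base_rep)) next
      keep <- select_top_k(base_rep$importances, config$top_k)
      if (st == 3) keep <- c(keep, IMPACT_COLUMNS)
      attr(tab, "feature_cols") <- keep
    }
    rep <- lopo(tab, config)
    reports[[key]] <- rep
    fsets[[key]] <- attr(tab, "feature_cols")
    rows[[key]] <- data.frame(
      stage = st, intervals = paste(ivs, collapse = "+"),
      n_features = length(attr(tab, "feature_cols")),
      n_patients = rep$n_patients, n_obs = rep$n_obs,
      auc = rep$auc, ci_lo = rep$auc_ci50[["lower"]],
      ci_hi = rep$auc_ci50[["upper"]],
      threshold = rep$threshold_star,
      sensitivity = rep$sensitivity, specificity = rep$specificity,
      stringsAsFactors = FALSE)
  }
  models <- do.call(rbind, rows)
  rownames(models) <- NULL
  best_of_stage <- function(s) {
    m <- models[models$stage == s, , drop = FALSE]
    if (!nrow(m)) return(NA_character_)
    paste0("stage", s, ":", m$intervals[which.max(m$auc)])
  }
  structure(list(models = models, reports = reports, feature_sets = fsets,
                 best_stage2 = best_of_stage(2), best_stage3 = best_of_stage(3),
                 config = config),
            class = "protocol_report")
}

#' @export
print.protocol_report <- function(x, ...) {
  cat("<protocol_report>\n")
  print(x$models[order(-x$models$auc), c("stage", "intervals", "n_features",
                                         "auc", "ci_lo", "ci_hi",
                                         "sensitivity", "specificity")],
        row.names = FALSE, digits = 3)
  cat("best stage-2:", x$best_stage2, " best stage-3:", x$best_stage3, "\n")
  invisible(x)
}

#' Score a held-out validation cohort
#'
#' Trains one forest on the full training table (never on validation
#' rows) and evaluates patient-level scores on the validation table.
#'
#' @param train_table,valid_table observation tables sharing feature
#'   columns.
#' @param config a [model_config()].
#' @return List with the fitted model and a `score_roc` evaluation of the
#'   validation patients.
#' @export
validate_model <- function(train_table, valid_table, config = model_config()) {
  fit <- fit_rf(train_table, config)
  attr(valid_table, "feature_cols") <- attr(train_table, "feature_cols")
  pts <- unique(valid_table$patient_id)
  scores <- vapply(pts, function(p) {
    mean(predict_votes(fit, valid_table[valid_table$patient_id == p, , drop = FALSE]))
  }, numeric(1))
  labels <- factor(vapply(pts, function(p) {
    as.character(unique(valid_table$label[valid_table$patient_id == p]))
  }, ""), levels = c("good", "poor"))
  list(fit = fit,
       evaluation = score_roc(scores, labels, config$boot_n, config$seed),
       per_patient_score = data.frame(patient_id = pts, score = scores,
                                      label = labels, row.names = NULL))
}
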
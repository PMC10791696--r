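# Gradient-boosted insertion-site classifier: nested leave-one-out
# cross-validation for hyperparameter tuning (per-fold grid search with a
# majority vote across folds), LOOCV evaluation (accuracy and pooled AUC),
# permutation feature importance, and candidate ranking. The boosted-tree
# ensemble itself is xgboost with the binary log-loss objective.

#' Read a labeled insertion-site table
#'
#' CSV with a `site_id` column, one column per descriptor, and a 0/1
#' `label` column (1 = permissive/regulatable, 0 = failed).
#'
#' @param path CSV path.
#' @return a `labeled_site_table` data.frame.
#' @export
read_site_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("site_id", "label") %in% names(tab)))
    stop("site table must have 'site_id' and 'label' columns")
  if (!all(tab$label %in% c(0, 1))) stop("labels must be 0/1")
  class(tab) <- c("labeled_site_table", class(tab))
  tab
}

.feature_names <- function(table) {
  setdiff(names(table), c("site_id", "label"))
}

.feature_matrix <- function(table, features = .feature_names(table)) {
  m <- as.matrix(table[features])
  storage.mode(m) <- "double"
  m
}

# Median imputation fitted on training rows; medians stored with the model.
.fit_imputer <- function(X) apply(X, 2, function(v) {
  m <- median(v, na.rm = TRUE)
  if (is.na(m)) 0 else m
})
.impute <- function(X, med) {
  for (j in seq_len(ncol(X))) X[is.na(X[, j]), j] <- med[j]
  X
}

#' Default hyperparameter grid
#'
#' The three tuned parameters of the boosted ensemble: learning rate,
#' minimum samples to split a node, and number of trees.
#'
#' @return data.frame grid (expand.grid of the defaults).
#' @export
default_hyper_grid <- function() {
  expand.grid(learning_rate = c(0.01, 0.05, 0.1, 0.2),
              min_samples_split = c(2, 4, 6, 8),
              n_estimators = c(50, 100, 200, 400))
}

# One boosted fit. min_samples_split is mapped to xgboost's
# min_child_weight via the logistic-hessian bound (<= 1/4 per sample), so
# the count threshold becomes a hessian threshold at p = 0.5.
.fit_gbt <- function(X, y, params, seed = 0) {
  dtrain <- xgboost::xgb.DMatrix(X, label = y, nthread = 1)
  xgboost::xgb.train(
    params = list(objective = "binary:logistic",
                  eval_metric = "logloss",
                  eta = params$learning_rate,
                  min_child_weight = params$min_samples_split / 4,
                  max_depth = 3, subsample = 1, colsample_bytree = 1,
                  nthread = 1, seed = seed),
    data = dtrain, nrounds = params$n_estimators, verbose = 0)
}

.predict_gbt <- function(booster, X) {
  as.numeric(predict(booster, xgboost::xgb.DMatrix(X, nthread = 1)))
}

.logloss <- function(y, p, eps = 1e-15) {
  p <- pmin(pmax(p, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

# Per-parameter majority vote across folds; ties go to the lower-complexity
# value (smaller learning rate / fewer trees, i.e. prefer_large = FALSE;
# larger minimum split size, prefer_large = TRUE).
.majority_vote <- function(vals, prefer_large) {
  counts <- table(vals)
  top <- as.numeric(names(counts)[counts == max(counts)])
  sort(top, decreasing = prefer_large)[1]
}

# Stratified row split: returns indices of the tuning portion.
.stratified_split <- function(y, fraction, seed) {
  set.seed(seed)
  idx <- unlist(lapply(unique(y), function(cl) {
    rows <- which(y == cl)
    sample(rows, max(1, round(fraction * length(rows))))
  }))
  sort(idx)
}

#' Tune hyperparameters by nested LOOCV with a majority vote
#'
#' Holds out a stratified testing fraction, then runs leave-one-out
#' cross-validation over the tuning rows: in each fold every grid point is
#' fit on the remaining rows and scored by log-loss on the held-out row;
#' the fold's winner is recorded and the final value of each parameter is
#' the majority vote across folds. Ties (within folds and in the vote) are
#' broken toward lower complexity: fewer trees, larger minimum split size,
#' smaller learning rate.
#'
#' @param table a `labeled_site_table`.
#' @param grid data.frame of hyperparameter combinations
#'   ([default_hyper_grid()]).
#' @param split_fraction tuning fraction (default 0.8; the rest is the
#'   untouched testing split).
#' @param seed RNG seed for the stratified split.
#' @return list of class `hyper_params`: learning_rate, min_samples_split,
#'   n_estimators, plus `votes` (per-fold winners) and `test_rows`.
#' @export
tune_hyperparameters <- function(table, grid = default_hyper_grid(),
                                 split_fraction = 0.8, seed = 0) {
  stopifnot(nrow(grid) >= 1, split_fraction > 0, split_fraction < 1)
  y <- table$label
  feats <- .feature_names(table)
  tune_rows <- .stratified_split(y, split_fraction, seed)
  if (length(unique(y[tune_rows])) < 2)
    stop("stratification error: tuning split contains a single class")
  Xall <- .feature_matrix(table)

  # complexity order for tie-breaks: fewer trees, larger min split,
  # smaller learning rate
  cmplx <- order(grid$n_estimators, -grid$min_samples_split,
                 grid$learning_rate)
  grid_ord <- grid[cmplx, , drop = FALSE]

  winners <- data.frame()
  for (i in tune_rows) {
    tr <- setdiff(tune_rows, i)
    med <- .fit_imputer(Xall[tr, , drop = FALSE])
    Xtr <- .impute(Xall[tr, , drop = FALSE], med)
    Xte <- .impute(Xall[i, , drop = FALSE], med)
    losses <- vapply(seq_len(nrow(grid_ord)), function(g) {
      fit <- .fit_gbt(Xtr, y[tr], grid_ord[g, ], seed)
      .logloss(y[i], .predict_gbt(fit, Xte))
    }, numeric(1))
    best <- which.min(losses)  # first minimum = lowest complexity
    winners <- rbind(winners, grid_ord[best, , drop = FALSE])
  }

  out <- list(
    learning_rate = .majority_vote(winners$learning_rate,
                                   prefer_large = FALSE),
    min_samples_split = .majority_vote(winners$min_samples_split,
                                       prefer_large = TRUE),
    n_estimators = .majority_vote(winners$n_estimators,
                                  prefer_large = FALSE),
    votes = winners,
    test_rows = setdiff(seq_len(nrow(table)), tune_rows))
  class(out) <- "hyper_params"
  out
}

#' @export
print.hyper_params <- function(x, ...) {
  cat("hyper_params: learning_rate =", x$learning_rate,
      "| min_samples_split =", x$min_samples_split,
      "| n_estimators =", x$n_estimators, "\n")
  invisible(x)
}

#' Train the insertion-site model on a full table
#'
#' @param table a `labeled_site_table`.
#' @param params a `hyper_params` (or plain list with learning_rate,
#'   min_samples_split, n_estimators); tuned via [tune_hyperparameters()]
#'   when NULL.
#' @param grid grid used when tuning.
#' @param seed RNG seed.
#' @return object of class `trained_site_model`: booster, params, feature
#'   schema, imputation medians, seed.
#' @export
train_site_model <- function(table, params = NULL,
                             grid = default_hyper_grid(), seed = 0) {
  if (length(unique(table$label)) < 2)
    stop("training table must contain both classes")
  if (is.null(params)) params <- tune_hyperparameters(table, grid, seed = seed)
  feats <- .feature_names(table)
  X <- .feature_matrix(table)
  med <- .fit_imputer(X)
  booster <- .fit_gbt(.impute(X, med), table$label, params, seed)
  structure(list(booster = booster, params = params[
    c("learning_rate", "min_samples_split", "n_estimators")],
    features = feats, medians = med, seed = seed),
    class = "trained_site_model")
}

# schema-checked prediction matrix for new candidates
.conform <- function(model, candidates) {
  feats <- model$features
  missing <- setdiff(feats, names(candidates))
  extra <- setdiff(names(candidates),
                   c(feats, "site_id", "label", "chain", "after_resno"))
  if (length(missing))
    stop("schema mismatch: missing feature(s): ",
         paste(missing, collapse = ", "),
         if (length(extra)) paste0("; extra: ", paste(extra, collapse = ", ")))
  .impute(.feature_matrix(candidates, feats), model$medians)
}

#' Predict permissive probabilities for candidate sites
#'
#' @param object a `trained_site_model`.
#' @param candidates data.frame with the model's feature columns.
#' @param ... unused.
#' @return numeric probabilities in [0, 1].
#' @export
predict.trained_site_model <- function(object, candidates, ...) {
  .predict_gbt(object$booster, .conform(object, candidates))
}

#' Evaluate the tuned model by leave-one-out cross-validation
#'
#' Each row is held out once; the ensemble (and the imputation medians) is
#' refit on the remaining rows and the held-out probability recorded.
#' Accuracy is the fraction of correct held-out calls at threshold 0.5;
#' AUC is computed once from the pooled held-out probabilities (per-fold
#' AUC is undefined for single samples).
#'
#' @param table a `labeled_site_table` (>= 3 rows, both classes).
#' @param params hyperparameters (list or `hyper_params`).
#' @param seed RNG seed.
#' @return list of class `eval_report`: loocv_accuracy, loocv_auc,
#'   predictions (data.frame site_id, label, prob).
#' @export
evaluate_loocv <- function(table, params, seed = 0) {
  n <- nrow(table)
  if (n < 3) stop("insufficient data: need at least 3 rows for LOOCV")
  if (length(unique(table$label)) < 2)
    stop("table must contain both classes")
  y <- table$label
  Xall <- .feature_matrix(table)
  prob <- numeric(n)
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    med <- .fit_imputer(Xall[tr, , drop = FALSE])
    fit <- .fit_gbt(.impute(Xall[tr, , drop = FALSE], med), y[tr], params,
                    seed)
    prob[i] <- .predict_gbt(fit, .impute(Xall[i, , drop = FALSE], med))
  }
  acc <- mean((prob > 0.5) == y)
  auc <- as.numeric(pROC::auc(pROC::roc(response = y, predictor = prob,
                                        levels = c(0, 1),
                                        direction = "<", quiet = TRUE)))
  structure(list(loocv_accuracy = acc, loocv_auc = auc,
                 predictions = data.frame(site_id = table$site_id,
                                          label = y, prob = prob)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("LOOCV accuracy %.3f | AUC %.3f | n = %d\n",
              x$loocv_accuracy, x$loocv_auc, nrow(x$predictions)))
  invisible(x)
}

#' Permutation feature importance
#'
#' Importance of a feature is the decrease in model accuracy on the table
#' when that feature's values are randomly shuffled, averaged over
#' repeats. Constant features have importance exactly 0 and are flagged.
#'
#' @param model a `trained_site_model`.
#' @param table a `labeled_site_table`.
#' @param n_repeats shuffles per feature (>= 1, default 30).
#' @param seed RNG seed.
#' @return data.frame sorted by decreasing mean importance: feature,
#'   importance_mean, importance_sd, constant.
#' @export
permutation_importance <- function(model, table, n_repeats = 30, seed = 0) {
  stopifnot(n_repeats >= 1)
  set.seed(seed)
  X <- .conform(model, table)
  y <- table$label
  base <- mean((.predict_gbt(model$booster, X) > 0.5) == y)
  feats <- model$features
  res <- lapply(feats, function(f) {
    j <- match(f, feats)
    if (length(unique(X[, j])) <= 1)
      return(data.frame(feature = f, importance_mean = 0, importance_sd = 0,
                        constant = TRUE))
    drops <- vapply(seq_len(n_repeats), function(r) {
      Xp <- X
      Xp[, j] <- sample(Xp[, j])
      base - mean((.predict_gbt(model$booster, Xp) > 0.5) == y)
    }, numeric(1))
    data.frame(feature = f, importance_mean = mean(drops),
               importance_sd = sd(drops), constant = FALSE)
  })
  out <- do.call(rbind, res)
  out <- out[order(-out$importance_mean, out$feature), ]
  rownames(out) <- NULL
  out
}

#' Rank candidate sites by predicted permissive probability
#'
#' @param model a `trained_site_model`.
#' @param candidates data.frame of descriptor vectors (e.g., from
#'   [compute_descriptor_table()]), optionally carrying heuristic flag
#'   columns which are passed through.
#' @return `candidates` with a `prob_permissive` column, sorted by
#'   decreasing probability; ties broken by increasing
#'   `dist_active_site_nm` where present, then by row order.
#' @export
rank_sites <- function(model, candidates) {
  if (nrow(candidates) == 0) {
    candidates$prob_permissive <- numeric(0)
    return(candidates)
  }
  p <- predict(model, candidates)
  candidates$prob_permissive <- p
  tie <- if ("dist_active_site_nm" %in% names(candidates))
    candidates$dist_active_site_nm else seq_len(nrow(candidates))
  out <- candidates[order(-p, tie, seq_len(nrow(candidates))), , drop = FALSE]
  rownames(out) <- NULL
  out
}
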
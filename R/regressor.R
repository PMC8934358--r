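## Gradient-boosted regression trees (xgboost backend) with a small grid
## tuner. Squared-error objective throughout; single-threaded and seeded so
## fits are reproducible.

#' Boosting hyperparameters
#'
#' @param n_trees maximum boosting rounds (early stopping may use fewer).
#' @param max_depth tree depth.
#' @param learning_rate shrinkage (eta).
#' @param subsample row fraction per tree, in (0, 1].
#' @param colsample_bytree feature fraction per tree, in (0, 1]; 1 uses all
#'   features.
#' @param seed RNG seed for the fit.
#' @return object of class `boost_params`.
#' @export
boost_params <- function(n_trees = 500L, max_depth = 6L, learning_rate = 0.05,
                         subsample = 0.8, colsample_bytree = 1,
                         seed = 1L) {
  structure(list(
    n_trees = as.integer(check_number(n_trees, "n_trees", 1)),
    max_depth = as.integer(check_number(max_depth, "max_depth", 1)),
    learning_rate = check_number(learning_rate, "learning_rate", 1e-6, 1),
    subsample = check_number(subsample, "subsample", 1e-6, 1),
    colsample_bytree = check_number(colsample_bytree, "colsample_bytree",
                                    1e-6, 1),
    seed = as.integer(seed)), class = "boost_params")
}

#' Fit a gradient-boosted affinity regressor
#'
#' Minimises mean squared error. When a validation set is supplied, training
#' stops early once validation RMSE fails to improve for
#' `early_stopping_rounds` rounds; otherwise all `n_trees` rounds run.
#'
#' @param features numeric training matrix (rows = pairs).
#' @param labels numeric affinity labels, finite, one per row.
#' @param params a [boost_params()].
#' @param valid_features,valid_labels optional validation split for early
#'   stopping.
#' @param early_stopping_rounds patience (default 30).
#' @return object of class `boost_fit` with elements `booster`, `params`,
#'   `feature_names`, `train_mse`, `best_iteration`.
#' @export
fit_boost <- function(features, labels, params = boost_params(),
                      valid_features = NULL, valid_labels = NULL,
                      early_stopping_rounds = 30L) {
  stopifnot(inherits(params, "boost_params"))
  features <- as.matrix(features)
  if (length(labels) != nrow(features)) {
    stop2("need one label per feature row")
  }
  if (any(!is.finite(labels))) stop2("non-finite label")
  dtrain <- xgboost::xgb.DMatrix(features, label = labels, nthread = 1)
  xgb_par <- list(objective = "reg:squarederror",
                  max_depth = params$max_depth,
                  eta = params$learning_rate,
                  subsample = params$subsample,
                  colsample_bytree = params$colsample_bytree,
                  nthread = 1)
  evals <- list(train = dtrain)
  esr <- NULL
  if (!is.null(valid_features)) {
    dvalid <- xgboost::xgb.DMatrix(as.matrix(valid_features),
                                   label = valid_labels, nthread = 1)
    evals <- list(train = dtrain, valid = dvalid)
    esr <- as.integer(early_stopping_rounds)
  }
  booster <- with_seed(params$seed,
    xgboost::xgb.train(params = xgb_par, data = dtrain,
                       nrounds = params$n_trees, evals = evals,
                       early_stopping_rounds = esr, verbose = 0))
  pred <- predict(booster, dtrain)
  best_it <- tryCatch(xgboost::xgb.attributes(booster)$best_iteration,
                      error = function(e) NULL)
  structure(list(booster = booster, params = params,
                 feature_names = colnames(features),
                 train_mse = mean((pred - labels)^2),
                 best_iteration = if (!is.null(best_it))
                   as.integer(best_it) else NULL),
            class = "boost_fit")
}

#' @export
predict.boost_fit <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (!is.null(object$feature_names) && !is.null(colnames(newdata)) &&
      !identical(colnames(newdata), object$feature_names)) {
    stop2("feature columns do not match the training columns")
  }
  if (nrow(newdata) == 0L) return(numeric(0))
  predict(object$booster, xgboost::xgb.DMatrix(newdata, nthread = 1))
}

#' @export
print.boost_fit <- function(x, ...) {
  cat("Gradient-boosted regressor: ", x$params$n_trees, " max rounds, depth ",
      x$params$max_depth, ", eta ", x$params$learning_rate, "\n", sep = "")
  cat(sprintf("  training MSE %.6g\n", x$train_mse))
  invisible(x)
}

#' Grid-search boosting hyperparameters by k-fold CV
#'
#' Selects the grid point minimising mean cross-validated MSE; ties are
#' broken by fewer trees, then shallower depth.
#'
#' @param features,labels training data.
#' @param grid list of [boost_params()] candidates.
#' @param folds number of CV folds (>= 2).
#' @param seed seed for the fold assignment.
#' @return the winning `boost_params`, with attribute `cv_mse` (vector of
#'   mean CV MSE per grid point).
#' @export
tune_boost <- function(features, labels, grid, folds = 5L, seed = 1L) {
  if (length(grid) == 0L) stop2("empty hyperparameter grid")
  folds <- as.integer(check_number(folds, "folds", 2))
  features <- as.matrix(features)
  n <- nrow(features)
  fold_id <- with_seed(seed, sample(rep_len(seq_len(folds), n)))
  cv_mse <- vapply(grid, function(p) {
    errs <- vapply(seq_len(folds), function(f) {
      tr <- fold_id != f
      fit <- fit_boost(features[tr, , drop = FALSE], labels[tr], p)
      mean((predict(fit, features[!tr, , drop = FALSE]) - labels[!tr])^2)
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  n_trees <- vapply(grid, `[[`, integer(1), "n_trees")
  depth <- vapply(grid, `[[`, integer(1), "max_depth")
  best <- order(cv_mse, n_trees, depth)[1L]
  out <- grid[[best]]
  attr(out, "cv_mse") <- cv_mse
  out
}
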
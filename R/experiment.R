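## End-to-end orchestration: the dtba_model fitting function with its S3
## methods, leakage-safe split construction, the nested-CV harness and the
## time-based split harness.

#' Fit a drug-target binding-affinity model
#'
#' The central fitting function. From an affinity dataset and similarity
#' sources it (1) normalises and thresholds the similarity matrices,
#' (2) assembles the weighted heterogeneous graph(s) using *only* the
#' training pairs' affinity edges — every other observed edge is masked so
#' no validation or test affinity can leak into a feature —
#' (3) extracts the requested feature variant for the training pairs,
#' (4) min-max normalises, and (5) fits a gradient-boosted regressor.
#'
#' Feature variants: `"pscore"` uses the 12 (or 24, with two graphs)
#' meta-path sum/max scores; `"embed"` concatenates drug and protein
#' embedding vectors; `"hybrid"` concatenates both blocks.
#'
#' Graph sources: `"g1"` uses the supplied `drug_sim` / `target_sim`
#' (e.g. 2D-structure and Smith-Waterman similarities); `"g2"` uses
#' cosine similarities derived from the supplied embeddings; `"g1g2"` uses
#' both graphs.
#'
#' @param dataset an [affinity_dataset()].
#' @param drug_sim,target_sim [similarity_matrix()] objects (required for
#'   graph source g1).
#' @param variant `"pscore"`, `"embed"` or `"hybrid"`.
#' @param graphs `"g1"`, `"g2"` or `"g1g2"` (pscore/hybrid only).
#' @param drug_emb,prot_emb `embedding_matrix` objects (required for
#'   embed/hybrid variants and for graph source g2).
#' @param train_pairs integer matrix (columns drug, target) of the observed
#'   pairs to train on; all other observed edges are masked from the graph.
#' @param valid_pairs optional pair matrix for early stopping.
#' @param transform a [transform_config()].
#' @param params a [boost_params()].
#' @param tune_grid optional list of [boost_params()] candidates; when
#'   given, [tune_boost()] selects among them on the training pairs first.
#' @param norm_mode feature normalisation protocol, see
#'   [normalize_train_test()].
#' @param semantics meta-path semantics, see [sum_scores()].
#' @return object of class `dtba_model`.
#' @seealso [dtba_nested_cv()], [dtba_time_split()]
#' @export
dtba_fit <- function(dataset, drug_sim = NULL, target_sim = NULL,
                     variant = c("pscore", "embed", "hybrid"),
                     graphs = c("g1", "g2", "g1g2"),
                     drug_emb = NULL, prot_emb = NULL,
                     train_pairs = observed_pairs(dataset),
                     valid_pairs = NULL,
                     transform = transform_config(),
                     params = boost_params(),
                     tune_grid = NULL,
                     norm_mode = c("independent", "fit_on_train"),
                     semantics = c("simple", "walk")) {
  variant <- match.arg(variant)
  graphs <- match.arg(graphs)
  norm_mode <- match.arg(norm_mode)
  semantics <- match.arg(semantics)
  stopifnot(inherits(dataset, "affinity_dataset"))
  train_pairs <- as.matrix(train_pairs)

  need_emb <- variant %in% c("embed", "hybrid") || graphs %in% c("g2", "g1g2")
  if (need_emb && (is.null(drug_emb) || is.null(prot_emb))) {
    stop2("drug_emb and prot_emb are required for variant '", variant,
          "' with graphs '", graphs, "'")
  }
  if (need_emb) {
    if (!identical(drug_emb$entity_ids, dataset$drug_ids) ||
        !identical(prot_emb$entity_ids, dataset$target_ids)) {
      stop2("embedding entity orderings must match the dataset IDs")
    }
  }

  ## holdout = every observed pair not in the training set
  mask <- dataset$observed
  mask[train_pairs] <- FALSE
  holdout_pairs <- which(mask, arr.ind = TRUE)

  g1 <- g2 <- NULL
  if (variant != "embed") {
    if (graphs %in% c("g1", "g1g2")) {
      if (is.null(drug_sim) || is.null(target_sim)) {
        stop2("drug_sim and target_sim are required for graph source g1")
      }
      dd <- filter_similarity(minmax_normalize(drug_sim$values),
                              transform$drug_threshold)
      tt <- filter_similarity(minmax_normalize(target_sim$values),
                              transform$target_threshold)
      g1 <- assemble_graph(dd, tt, dataset, transform, holdout_pairs)
    }
    if (graphs %in% c("g2", "g1g2")) {
      dd2 <- filter_similarity(cosine_similarity_matrix(drug_emb)$values,
                               transform$drug_threshold)
      tt2 <- filter_similarity(cosine_similarity_matrix(prot_emb)$values,
                               transform$target_threshold)
      g2 <- assemble_graph(dd2, tt2, dataset, transform, holdout_pairs)
    }
    if (graphs == "g2") { g1 <- g2; g2 <- NULL }
  }

  ## leakage guard: no masked edge may carry weight in any graph
  for (g in Filter(Negate(is.null), list(g1, g2))) {
    stopifnot(all(g$dt[holdout_pairs] == 0),
              !any(g$edge_mask[holdout_pairs]))
  }

  model <- structure(
    list(dataset_info = list(drug_ids = dataset$drug_ids,
                             target_ids = dataset$target_ids,
                             orientation = dataset$orientation,
                             unit_label = dataset$unit_label),
         variant = variant, graphs = graphs, semantics = semantics,
         g1 = g1, g2 = g2, drug_emb = drug_emb, prot_emb = prot_emb,
         transform = transform, norm_mode = norm_mode,
         train_pairs = train_pairs),
    class = "dtba_model")

  raw_train <- pair_raw_features(model, train_pairs)
  labels <- dataset$affinities[train_pairs]

  vf <- vl <- NULL
  if (!is.null(valid_pairs)) {
    valid_pairs <- as.matrix(valid_pairs)
    raw_valid <- pair_raw_features(model, valid_pairs)
    nrm <- normalize_train_test(raw_train, raw_valid, norm_mode)
    vf <- nrm$test; vl <- dataset$affinities[valid_pairs]
  } else {
    nrm <- normalize_train_test(raw_train, raw_train[0, , drop = FALSE],
                                norm_mode)
  }

  if (!is.null(tune_grid)) {
    params <- tune_boost(nrm$train, labels, tune_grid, seed = params$seed)
  }
  fit <- fit_boost(nrm$train, labels, params,
                   valid_features = vf, valid_labels = vl)

  model$fit <- fit
  model$params <- params
  model$norm_lo <- nrm$lo
  model$norm_hi <- nrm$hi
  model$train_labels <- labels
  model$feature_dim <- ncol(raw_train)
  model
}

## raw (un-normalised) features for arbitrary pairs under a fitted/partial
## model; used at fit and predict time
pair_raw_features <- function(model, pairs) {
  pairs <- as.matrix(pairs)
  blocks <- list()
  if (model$variant != "embed") {
    blocks$pscore <- pair_features(model$g1, model$g2, pairs,
                                   semantics = model$semantics)
  }
  if (model$variant != "pscore") {
    blocks$embed <- build_embed_features(model$drug_emb, model$prot_emb,
                                         pairs)
  }
  if (length(blocks) == 2L) {
    build_hybrid_features(blocks$pscore, blocks$embed)
  } else blocks[[1L]]
}

#' Predict binding affinities for drug-target pairs
#'
#' Features for the requested pairs are computed from the training graph
#' (test edges were never present in it) and normalised per the model's
#' protocol: under `"independent"` the prediction block is min-max scaled by
#' its own column ranges; under `"fit_on_train"` the stored training ranges
#' are applied with clipping.
#'
#' @param object a `dtba_model`.
#' @param pairs integer matrix (columns drug, target); defaults to the
#'   model's training pairs.
#' @param ... unused.
#' @return numeric vector of predicted affinities.
#' @export
predict.dtba_model <- function(object, pairs = object$train_pairs, ...) {
  pairs <- as.matrix(pairs)
  if (nrow(pairs) == 0L) return(numeric(0))
  raw <- pair_raw_features(object, pairs)
  X <- if (object$norm_mode == "fit_on_train") {
    rng <- object$norm_hi - object$norm_lo
    rng[rng <= 0] <- Inf
    out <- sweep(sweep(raw, 2L, object$norm_lo, "-"), 2L, rng, "/")
    out[out < 0] <- 0; out[out > 1] <- 1
    out
  } else {
    normalize_train_test(raw, raw[0, , drop = FALSE], "independent")$train
  }
  as.numeric(predict(object$fit, X))
}

#' @export
print.dtba_model <- function(x, ...) {
  cat("Drug-target binding affinity model (", x$variant, ", graphs: ",
      x$graphs, ")\n", sep = "")
  cat("  ", length(x$dataset_info$drug_ids), " drugs x ",
      length(x$dataset_info$target_ids), " targets; ",
      nrow(x$train_pairs), " training pairs; ",
      x$feature_dim, " features\n", sep = "")
  cat(sprintf("  training MSE %.4f\n", x$fit$train_mse))
  invisible(x)
}

#' @export
summary.dtba_model <- function(object, ...) {
  pred <- predict(object)
  rep <- eval_report(pred, object$train_labels)
  cat("Training-set fit (optimistic; use dtba_nested_cv for honest error):\n")
  print(rep)
  invisible(rep)
}

#' @export
residuals.dtba_model <- function(object, ...) {
  object$train_labels - predict(object)
}

## ---- splits -----------------------------------------------------------------

#' Nested cross-validation split: 6-way partition + 5 inner folds
#'
#' Randomly partitions the labelled pairs into `n_partitions` near-equal
#' disjoint sets (sizes differ by at most one); one is the hold-out test
#' set, the remaining `n_partitions - 1` are the inner CV folds.
#'
#' @param n_pairs number of labelled pairs to partition.
#' @param n_partitions total partitions (default 6: 1 hold-out + 5 folds).
#' @param seed RNG seed.
#' @return list with `holdout` (integer indices) and `folds` (list of
#'   `n_partitions - 1` integer index vectors).
#' @export
make_nested_cv_splits <- function(n_pairs, n_partitions = 6L, seed = 1L) {
  n_partitions <- as.integer(check_number(n_partitions, "n_partitions", 2))
  if (n_pairs < n_partitions) {
    stop2("need at least ", n_partitions, " labelled pairs, got ", n_pairs)
  }
  part <- with_seed(seed, sample(rep_len(seq_len(n_partitions), n_pairs)))
  list(holdout = which(part == 1L),
       folds = lapply(2:n_partitions, function(p) which(part == p)))
}

#' Time-based train/validation/test split
#'
#' Training = pairs from `train_max_year` and before; validation = pairs
#' from exactly `valid_year`; test = pairs from `test_min_year` and after
#' (the 2011 / 2012 / 2013+ protocol by default). Pairs falling in none of
#' the ranges are dropped with a message.
#'
#' @param years integer vector, one acquisition year per pair.
#' @param train_max_year,valid_year,test_min_year split boundaries.
#' @return list with integer index vectors `train`, `valid`, `test` and the
#'   `dropped` count.
#' @export
make_time_split <- function(years, train_max_year = 2011L,
                            valid_year = 2012L, test_min_year = 2013L) {
  if (any(is.na(years))) stop2("missing year for pair(s) ",
                               paste(utils::head(which(is.na(years)), 5),
                                     collapse = ", "))
  train <- which(years <= train_max_year)
  valid <- which(years == valid_year)
  test <- which(years >= test_min_year)
  dropped <- length(years) - length(train) - length(valid) - length(test)
  if (dropped > 0) message(dropped, " pairs outside all year ranges dropped")
  if (length(valid) == 0L || length(test) == 0L) {
    stop2("degenerate time split: ", length(train), " train / ",
          length(valid), " valid / ", length(test), " test")
  }
  list(train = train, valid = valid, test = test, dropped = dropped)
}

## ---- nested-CV and time-split harnesses -------------------------------------

#' Nested cross-validation evaluation
#'
#' The full experimental protocol: the labelled pairs are partitioned into
#' six near-equal sets; one is the hold-out test set and the other five are
#' the inner CV folds. For each inner fold a model is fitted on the other
#' four folds — with that fold's *and* the hold-out's affinity edges masked
#' from the graph — using the fold as the early-stopping validation set,
#' then evaluated on the hold-out. The reported metrics are, by default,
#' the mean of the five models' hold-out metric values
#' (`aggregate = "mean_metrics"`); `aggregate = "mean_predictions"`
#' instead averages the five prediction vectors and evaluates once. Both
#' aggregations are stored.
#'
#' @inheritParams dtba_fit
#' @param n_partitions partitions (default 6).
#' @param seed global seed; deterministically fanned out to the split and
#'   the per-fold fits.
#' @param thresholds optional AUPR binarisation cutoffs.
#' @param positive_rule AUPR positive-class rule (see
#'   [thresholded_aupr()]).
#' @param aggregate hold-out aggregation rule.
#' @return object of class `dtba_cv`: list with `report` (the aggregated
#'   `eval_report`-style list), `fold_reports`, `report_mean_predictions`,
#'   `splits`, `predictions` (5 x holdout matrix), `holdout_labels`,
#'   `baseline_mse` (predict-the-training-mean reference), `config`.
#' @export
dtba_nested_cv <- function(dataset, drug_sim = NULL, target_sim = NULL,
                           variant = "pscore", graphs = "g1",
                           drug_emb = NULL, prot_emb = NULL,
                           transform = transform_config(),
                           params = boost_params(), tune_grid = NULL,
                           norm_mode = "independent",
                           semantics = "simple",
                           n_partitions = 6L, seed = 1L,
                           thresholds = NULL, positive_rule = "ge",
                           aggregate = c("mean_metrics",
                                         "mean_predictions")) {
  aggregate <- match.arg(aggregate)
  pairs <- observed_pairs(dataset)
  seeds <- seed_stream(seed, n_partitions)
  splits <- make_nested_cv_splits(nrow(pairs), n_partitions, seeds[1L])
  holdout <- pairs[splits$holdout, , drop = FALSE]
  holdout_labels <- dataset$affinities[holdout]
  n_folds <- length(splits$folds)

  fold_models <- vector("list", n_folds)
  fold_reports <- vector("list", n_folds)
  preds <- matrix(NA_real_, n_folds, nrow(holdout))
  for (f in seq_len(n_folds)) {
    train_idx <- unlist(splits$folds[-f])
    p2 <- params; p2$seed <- seeds[f + 1L]
    model <- dtba_fit(dataset, drug_sim, target_sim,
                      variant = variant, graphs = graphs,
                      drug_emb = drug_emb, prot_emb = prot_emb,
                      train_pairs = pairs[train_idx, , drop = FALSE],
                      valid_pairs = pairs[splits$folds[[f]], , drop = FALSE],
                      transform = transform, params = p2,
                      tune_grid = tune_grid, norm_mode = norm_mode,
                      semantics = semantics)
    ## programmatic leakage assertion: the hold-out edges are absent from
    ## this fold's graph
    for (g in Filter(Negate(is.null), list(model$g1, model$g2))) {
      stopifnot(all(g$dt[holdout] == 0))
    }
    preds[f, ] <- predict(model, holdout)
    fold_reports[[f]] <- eval_report(preds[f, ], holdout_labels,
                                     thresholds, positive_rule)
    fold_models[[f]] <- model
  }

  mean_metric <- function(name) {
    mean(vapply(fold_reports, function(r) r[[name]], numeric(1)))
  }
  report_mm <- list(mse = mean_metric("mse"), rmse = mean_metric("rmse"),
                    ci = mean_metric("ci"), r2 = mean_metric("r2"),
                    r0_2 = mean_metric("r0_2"), rm2 = mean_metric("rm2"),
                    aupr_mean = if (!is.null(thresholds))
                      mean_metric("aupr_mean") else NULL,
                    n = length(holdout_labels))
  report_mp <- eval_report(colMeans(preds), holdout_labels,
                           thresholds, positive_rule)

  train_mean <- mean(dataset$affinities[pairs[unlist(splits$folds), ,
                                              drop = FALSE]])
  baseline_mse <- mean((train_mean - holdout_labels)^2)

  structure(list(
    report = if (aggregate == "mean_metrics") report_mm else report_mp,
    fold_reports = fold_reports,
    report_mean_metrics = report_mm,
    report_mean_predictions = report_mp,
    splits = splits, predictions = preds,
    holdout_labels = holdout_labels, holdout_pairs = holdout,
    baseline_mse = baseline_mse,
    models = fold_models,
    config = list(variant = variant, graphs = graphs,
                  transform = transform, params = params,
                  norm_mode = norm_mode, semantics = semantics,
                  aggregate = aggregate, seed = seed)),
    class = "dtba_cv")
}

#' @export
print.dtba_cv <- function(x, ...) {
  r <- x$report
  cat("Nested cross-validation (", length(x$fold_reports),
      " inner folds, hold-out n = ", r$n, ", ", x$config$variant,
      "/", x$config$graphs, ")\n", sep = "")
  cat(sprintf("  hold-out MSE %.4f   CI %.4f   rm2 %.4f\n",
              r$mse, r$ci, r$rm2))
  if (!is.null(r$aupr_mean)) cat(sprintf("  mean AUPR %.4f\n", r$aupr_mean))
  cat(sprintf("  mean-predictor baseline MSE %.4f (model/baseline = %.2f)\n",
              x$baseline_mse, r$mse / x$baseline_mse))
  invisible(x)
}

#' @export
summary.dtba_cv <- function(object, ...) {
  print(object)
  cat("\nPer-fold hold-out metrics:\n")
  for (f in seq_along(object$fold_reports)) {
    r <- object$fold_reports[[f]]
    cat(sprintf("  fold %d: MSE %.4f  CI %.4f  rm2 %.4f\n",
                f, r$mse, r$ci, r$rm2))
  }
  invisible(object)
}

#' Predicted-versus-actual plot for a nested-CV run
#'
#' Scatter of the (fold-averaged) hold-out predictions against the true
#' affinities with the identity line.
#'
#' @param x a `dtba_cv`.
#' @param ... passed to [plot()].
#' @export
plot.dtba_cv <- function(x, ...) {
  pred <- colMeans(x$predictions)
  plot(x$holdout_labels, pred,
       xlab = "actual affinity", ylab = "predicted affinity",
       main = "Hold-out predictions (5-model average)", pch = 16,
       col = grDevices::rgb(0.2, 0.4, 0.7, 0.5), ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Time-based split evaluation
#'
#' Fits on all pairs up to `train_max_year` (validation-year edges and
#' later are masked from the graph), early-stops on the validation year and
#' evaluates on the test years.
#'
#' @inheritParams dtba_nested_cv
#' @inheritParams make_time_split
#' @param years integer vector of years, one per *observed pair* in the
#'   order of [observed_pairs()].
#' @return list with `report` (`eval_report` on the test set), `split`,
#'   `model`, `predictions`.
#' @export
dtba_time_split <- function(dataset, years, drug_sim = NULL,
                            target_sim = NULL,
                            variant = "pscore", graphs = "g1",
                            drug_emb = NULL, prot_emb = NULL,
                            transform = transform_config(),
                            params = boost_params(),
                            norm_mode = "independent",
                            semantics = "simple",
                            train_max_year = 2011L, valid_year = 2012L,
                            test_min_year = 2013L,
                            thresholds = NULL, positive_rule = "ge") {
  pairs <- observed_pairs(dataset)
  if (length(years) != nrow(pairs)) {
    stop2("need one year per observed pair (", nrow(pairs), ")")
  }
  split <- make_time_split(years, train_max_year, valid_year, test_min_year)
  model <- dtba_fit(dataset, drug_sim, target_sim,
                    variant = variant, graphs = graphs,
                    drug_emb = drug_emb, prot_emb = prot_emb,
                    train_pairs = pairs[split$train, , drop = FALSE],
                    valid_pairs = pairs[split$valid, , drop = FALSE],
                    transform = transform, params = params,
                    norm_mode = norm_mode, semantics = semantics)
  test_pairs <- pairs[split$test, , drop = FALSE]
  pred <- predict(model, test_pairs)
  actual <- dataset$affinities[test_pairs]
  list(report = eval_report(pred, actual, thresholds, positive_rule),
       split = split, model = model, predictions = pred)
}
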
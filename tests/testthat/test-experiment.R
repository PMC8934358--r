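test_that("nested-CV partitions are balanced, disjoint, covering, seeded", {
  sp <- make_nested_cv_splits(600, 6, seed = 3)
  sizes <- c(length(sp$holdout), lengths(sp$folds))
  expect_equal(sizes, rep(100L, 6))
  sp2 <- make_nested_cv_splits(601, 6, seed = 3)
  sizes2 <- c(length(sp2$holdout), lengths(sp2$folds))
  expect_lte(diff(range(sizes2)), 1L)
  all_idx <- c(sp2$holdout, unlist(sp2$folds))
  expect_setequal(all_idx, 1:601)
  expect_equal(anyDuplicated(all_idx), 0L)
  expect_identical(make_nested_cv_splits(601, 6, seed = 3), sp2)
  expect_error(make_nested_cv_splits(5, 6), "at least")
})

test_that("time-based split follows the year-boundary protocol", {
  years <- c(rep(2010, 5), rep(2012, 2), rep(2014, 3))
  sp <- make_time_split(years)
  expect_equal(lengths(sp[c("train", "valid", "test")]),
               c(train = 5L, valid = 2L, test = 3L))
  expect_true(all(years[sp$train] <= 2011))
  expect_true(all(years[sp$valid] == 2012))
  expect_true(all(years[sp$test] >= 2013))
  expect_error(make_time_split(rep(2009, 10)), "degenerate")
  expect_error(make_time_split(c(2010, NA)), "missing year")
})

test_that("dtba_fit produces a working model with the declared feature dim", {
  sim <- small_study(seed = 21L)
  ds <- sim$dataset
  pairs <- observed_pairs(ds)
  tr <- pairs[1:250, ]
  m <- dtba_fit(ds, sim$drug_sim, sim$target_sim, train_pairs = tr,
                params = boost_params(n_trees = 60))
  expect_s3_class(m, "dtba_model")
  expect_equal(m$feature_dim, 12L)
  pred <- predict(m, pairs[251:300, ])
  expect_length(pred, 50L)
  expect_true(all(is.finite(pred)))
  expect_length(residuals(m), 250L)
  expect_output(print(m), "binding affinity model")

  # g1g2 doubles the meta-path block; hybrid adds the embedding block
  demb <- embedding_matrix(ds$drug_ids,
                           matrix(rnorm(length(ds$drug_ids) * 16), ncol = 16))
  pemb <- embedding_matrix(ds$target_ids,
                           matrix(rnorm(length(ds$target_ids) * 10), ncol = 10))
  m2 <- dtba_fit(ds, sim$drug_sim, sim$target_sim, graphs = "g1g2",
                 drug_emb = demb, prot_emb = pemb, train_pairs = tr,
                 params = boost_params(n_trees = 30))
  expect_equal(m2$feature_dim, 24L)
  m3 <- dtba_fit(ds, sim$drug_sim, sim$target_sim, variant = "hybrid",
                 drug_emb = demb, prot_emb = pemb, train_pairs = tr,
                 params = boost_params(n_trees = 30))
  expect_equal(m3$feature_dim, 12L + 16L + 10L)
  m4 <- dtba_fit(ds, variant = "embed", drug_emb = demb, prot_emb = pemb,
                 train_pairs = tr, params = boost_params(n_trees = 30))
  expect_equal(m4$feature_dim, 26L)
  expect_error(dtba_fit(ds, sim$drug_sim, sim$target_sim, variant = "embed",
                        train_pairs = tr), "required")
})

test_that("no holdout affinity leaks into any training feature", {
  # perturbation audit: changing a holdout pair's affinity must leave every
  # training-pair feature bit-identical
  sim <- small_study(seed = 22L)
  ds <- sim$dataset
  pairs <- observed_pairs(ds)
  hold_rows <- 1:40
  tr <- pairs[-hold_rows, ]
  feats <- function(dataset) {
    m <- list(variant = "pscore", graphs = "g1", semantics = "simple",
              g1 = assemble_graph(
                filter_similarity(sim$drug_sim$values, 0.3),
                filter_similarity(sim$target_sim$values, 0.04),
                dataset, transform_config(), pairs[hold_rows, ]),
              g2 = NULL)
    dtbanet:::pair_raw_features(m, tr)
  }
  base <- feats(ds)
  ds2 <- ds
  ds2$affinities[pairs[3, , drop = FALSE]] <- 99
  expect_identical(feats(ds2), base)
  # and the holdout edge weights are exactly zero in the graph
  g <- assemble_graph(filter_similarity(sim$drug_sim$values, 0.3),
                      filter_similarity(sim$target_sim$values, 0.04),
                      ds, transform_config(), pairs[hold_rows, ])
  expect_true(all(g$dt[pairs[hold_rows, ]] == 0))
})

test_that("nested CV recovers signal and is byte-reproducible", {
  sim <- small_study(seed = 23L, n = 18L, m = 14L, noise_sd = 0.3)
  cv <- dtba_nested_cv(sim$dataset, sim$drug_sim, sim$target_sim,
                       params = boost_params(n_trees = 80), seed = 5,
                       thresholds = 8)
  expect_s3_class(cv, "dtba_cv")
  expect_gt(cv$report$ci, 0.5)
  expect_lt(cv$report$mse, cv$baseline_mse)
  expect_length(cv$fold_reports, 5L)
  expect_equal(nrow(cv$predictions), 5L)
  # both aggregations present and consistent with their inputs
  expect_equal(cv$report_mean_metrics$mse,
               mean(vapply(cv$fold_reports, `[[`, numeric(1), "mse")))
  expect_equal(cv$report_mean_predictions$mse,
               mse(colMeans(cv$predictions), cv$holdout_labels))
  # identical config + seed: identical reports
  cv2 <- dtba_nested_cv(sim$dataset, sim$drug_sim, sim$target_sim,
                        params = boost_params(n_trees = 80), seed = 5,
                        thresholds = 8)
  expect_identical(cv$report, cv2$report)
  expect_identical(cv$predictions, cv2$predictions)
  expect_output(print(cv), "Nested cross-validation")
})

test_that("time-split harness trains on the past and scores the future", {
  sim <- small_study(seed = 24L)
  ds <- sim$dataset
  n_pairs <- nrow(observed_pairs(ds))
  years <- withr::with_seed(1, sample(c(2009:2011, 2012, 2013:2015), n_pairs,
                               replace = TRUE))
  ts <- dtba_time_split(ds, years, sim$drug_sim, sim$target_sim,
                        params = boost_params(n_trees = 60))
  expect_s3_class(ts$report, "eval_report")
  expect_length(ts$predictions, length(ts$split$test))
  expect_true(all(years[ts$split$train] <= 2011))
})
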
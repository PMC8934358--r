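test_that("mse matches its definition and scales quadratically", {
  expect_equal(mse(c(1, 2), c(0, 2)), 0.5)
  expect_equal(mse(1:5, 1:5), 0)
  set.seed(1)
  p <- rnorm(30); a <- rnorm(30)
  expect_equal(mse(a + 3 * (p - a), a), 9 * mse(p, a))
  expect_error(mse(1:3, 1:4), "length")
})

test_that("concordance index handles perfect, reversed and tied predictions", {
  a <- c(1, 2, 3, 4)
  expect_equal(concordance_index(a, a), 1)
  expect_equal(concordance_index(rev(a), a), 0)
  expect_equal(concordance_index(rep(1, 4), a), 0.5)
  expect_equal(concordance_index(c(1, 3, 2), c(1, 2, 3)), 2 / 3)
  expect_error(concordance_index(c(1, 2), c(5, 5)), "tied")
})

test_that("fast concordance index equals the quadratic oracle exactly", {
  set.seed(2024)
  for (case in 1:500) {
    n <- sample(3:60, 1)
    # mix continuous and heavily tied integer-valued vectors
    actual <- if (runif(1) < 0.5) rnorm(n) else sample(1:4, n, replace = TRUE)
    pred <- if (runif(1) < 0.5) rnorm(n) else sample(1:4, n, replace = TRUE)
    if (length(unique(actual)) < 2) actual[1] <- actual[1] + 1
    expect_identical(concordance_index(pred, actual),
                     oracle_ci(pred, actual))
  }
})

test_that("ci and rm2 are invariant to joint permutation; ci to monotone maps", {
  set.seed(5)
  p <- rnorm(40); a <- rnorm(40)
  perm <- sample(40)
  expect_equal(concordance_index(p[perm], a[perm]), concordance_index(p, a))
  expect_equal(mse(p[perm], a[perm]), mse(p, a))
  expect_equal(rm2_index(p[perm], a[perm])$rm2, rm2_index(p, a)$rm2)
  expect_equal(concordance_index(exp(2 * p) + 1, a), concordance_index(p, a))
})

test_that("rm2 agrees with an independent lm-based computation", {
  expect_equal(rm2_index(1:10, 1:10),
               list(r2 = 1, r0_2 = 1, rm2 = 1, r0_2_alt = 1))
  set.seed(6)
  for (case in 1:20) {
    a <- rnorm(25, mean = 5)
    p <- a + rnorm(25, sd = 0.8)
    got <- rm2_index(p, a)
    r2_ref <- summary(stats::lm(a ~ p))$r.squared
    fit0 <- stats::lm(a ~ p + 0)
    r0_ref <- 1 - sum(residuals(fit0)^2) / sum((a - mean(a))^2)
    expect_equal(got$r2, r2_ref, tolerance = 1e-10)
    expect_equal(got$r0_2, r0_ref, tolerance = 1e-10)
    expect_equal(got$rm2, r2_ref * (1 - sqrt(max(r2_ref - r0_ref, 0))),
                 tolerance = 1e-10)
  }
  # closed form: r2 = 0.8, r0^2 = 0.64 gives rm2 = 0.8 * (1 - 0.4) = 0.48
  rm2_closed <- function(r2, r0) r2 * (1 - sqrt(max(r2 - r0, 0)))
  expect_equal(rm2_closed(0.8, 0.64), 0.48)
  # uncorrelated noise: rm2 near zero
  set.seed(7)
  vals <- replicate(40, rm2_index(rnorm(50), rnorm(50))$rm2)
  expect_lt(median(vals), 0.08)
  expect_error(rm2_index(rep(1, 5), 1:5), "variance")
})

test_that("thresholded AUPR is 1 for perfect scores and ~prevalence for noise", {
  set.seed(8)
  a <- rnorm(300, mean = 7)
  got <- thresholded_aupr(a, a, thresholds = 7)
  expect_equal(unname(got$per_threshold), 1)
  # null behaviour: random scores, balanced classes at n = 10,000
  a2 <- rnorm(10000, mean = 7, sd = 1)
  p2 <- runif(10000)
  prev <- mean(a2 >= 7)
  null_aupr <- thresholded_aupr(p2, a2, 7)$mean
  expect_lt(abs(null_aupr - prev), 0.02)
  # averaged thresholds
  multi <- thresholded_aupr(a + rnorm(300, sd = 0.3), a, c(6, 7, 8))
  expect_length(multi$per_threshold, 3L)
  expect_equal(multi$mean, mean(multi$per_threshold))
  # le rule mirrors ge on negated data
  ge <- thresholded_aupr(a, a, 7, "ge")$mean
  le <- thresholded_aupr(-a, -a, -7, "le")$mean
  expect_equal(ge, le)
  # degenerate threshold excluded with a warning
  expect_warning(one <- thresholded_aupr(a, a, c(7, 100)), "single class")
  expect_true(is.na(one$per_threshold[2]))
  expect_equal(one$mean, unname(one$per_threshold[1]))
  expect_error(thresholded_aupr(a, a, numeric(0)), "threshold")
})

test_that("aupr step interpolation matches a direct PR-curve computation", {
  set.seed(9)
  for (case in 1:25) {
    n <- sample(10:60, 1)
    labels <- rbinom(n, 1, 0.4)
    if (sum(labels) %in% c(0, n)) labels[1:2] <- c(0, 1)
    scores <- sample(seq_len(n %/% 2), n, replace = TRUE)  # many ties
    got <- thresholded_aupr(scores, labels, 0.5)$mean
    # reference: step-wise average precision over distinct score cutoffs
    cuts <- sort(unique(scores), decreasing = TRUE)
    prec <- rec <- numeric(length(cuts))
    for (i in seq_along(cuts)) {
      sel <- scores >= cuts[i]
      prec[i] <- sum(labels[sel]) / sum(sel)
      rec[i] <- sum(labels[sel]) / sum(labels)
    }
    ref <- sum(diff(c(0, rec)) * prec)
    expect_equal(got, ref, tolerance = 1e-12)
  }
})

test_that("y-randomization separates signal from scrambled labels", {
  set.seed(10)
  X <- matrix(runif(150 * 4), 150, 4,
              dimnames = list(NULL, paste0("f", 1:4)))
  y <- 2 * X[, 1] - X[, 2] + rnorm(150, sd = 0.1)
  tr <- 1:100; te <- 101:150
  params <- boost_params(n_trees = 40, max_depth = 3)
  res <- y_randomization(X[tr, ], y[tr], X[te, ], y[te], params,
                         n_iter = 30, seed = 4)
  expect_equal(res$p_empirical, 1 / 31)          # observed beats all shuffles
  expect_lt(res$p_normal, 0.05)
  expect_gt(res$observed_r2, 0.8)
  expect_length(res$permuted_r2, 30L)
  # permuted fits typically have non-positive held-out r2
  expect_lt(median(res$permuted_r2), 0.05)
  expect_error(y_randomization(X[tr, ], y[tr], X[te, ], y[te], params,
                               n_iter = 5), "n_iter")
})

test_that("eval_report bundles consistent values", {
  set.seed(11)
  a <- rnorm(100, 7); p <- a + rnorm(100, sd = 0.5)
  rep <- eval_report(p, a, thresholds = 7)
  expect_equal(rep$rmse, sqrt(rep$mse))
  expect_true(rep$ci >= 0 && rep$ci <= 1)
  expect_equal(rep$mse, mse(p, a))
  expect_equal(rep$rm2, rm2_index(p, a)$rm2)
  expect_equal(rep$n, 100L)
})
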
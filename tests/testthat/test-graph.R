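test_that("pKd transform matches its closed form", {
  expect_equal(transform_pkd(10000), 5)
  expect_equal(transform_pkd(1e9), 0)
  expect_equal(transform_pkd(1), 9)
  expect_error(transform_pkd(0), "positive")
  expect_error(transform_pkd(-3), "positive")
})

test_that("min-max normalisation is an order-preserving map onto [0,1]", {
  expect_equal(minmax_normalize(c(2, 4, 6)), c(0, 0.5, 1))
  expect_equal(minmax_normalize(c(3, 3)), c(0, 0))
  x <- c(0, 0.25, 1)
  expect_equal(minmax_normalize(x, lo = 0, hi = 1), x)
  set.seed(1)
  y <- rnorm(50)
  expect_equal(order(minmax_normalize(y)), order(y))
})

test_that("similarity filtering zeroes weak edges and the diagonal, idempotently", {
  set.seed(2)
  s <- matrix(runif(36), 6); s <- (s + t(s)) / 2
  f <- filter_similarity(s, 0.3)
  expect_true(all(f[f > 0] >= 0.3))
  expect_true(all(diag(f) == 0))
  expect_identical(filter_similarity(f, 0.3), f)
  f0 <- filter_similarity(s, 0)
  expect_equal(f0[upper.tri(f0)], s[upper.tri(s)])
  expect_true(all(filter_similarity(s * 0.9, 1) == 0))
})

test_that("exponential transform is a strictly antitone map into (0,1]", {
  expect_equal(transform_affinity_exponential(0, 2), 1)
  expect_equal(transform_affinity_exponential(log(2), 1), 0.5)
  z <- sort(runif(20, 0, 5))
  w <- transform_affinity_exponential(z, 0.7)
  expect_true(all(diff(w) < 0))
  expect_true(all(w > 0 & w <= 1))
})

test_that("softmax transform is a shift-invariant probability vector", {
  set.seed(3)
  z <- rnorm(40)
  p <- transform_affinity_softmax(z)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_true(all(p >= 0))
  expect_equal(transform_affinity_softmax(z + 17.3), p)
  expect_equal(transform_affinity_softmax(rep(2, 5)), rep(0.2, 5))
  expect_error(transform_affinity_softmax(numeric(0)), "empty")
  # extreme values do not overflow
  expect_equal(sum(transform_affinity_softmax(c(1e4, 0, -1e4))), 1)
})

test_that("graph assembly masks holdout edges and orients weights by strength", {
  sim <- small_study(seed = 5L, n = 8L, m = 6L)
  ds <- sim$dataset
  dd <- filter_similarity(sim$drug_sim$values, 0.3)
  tt <- filter_similarity(sim$target_sim$values, 0.04)
  pairs <- observed_pairs(ds)
  hold <- pairs[1:10, ]
  g <- assemble_graph(dd, tt, ds, transform_config(), hold)
  expect_true(all(g$dt[hold] == 0))
  expect_false(any(g$edge_mask[hold]))
  expect_true(all(g$dt >= 0 & g$dt <= 1))
  # strongest training binder gets the largest weight (higher_is_stronger)
  train_mask <- ds$observed; train_mask[hold] <- FALSE
  best <- which(ds$affinities == max(ds$affinities[train_mask]) & train_mask,
                arr.ind = TRUE)[1, , drop = FALSE]
  expect_equal(g$dt[best], max(g$dt))

  # lower_is_stronger datasets orient the other way
  ds2 <- ds; ds2$orientation <- "lower_is_stronger"
  g2 <- assemble_graph(dd, tt, ds2, transform_config())
  worst <- which(ds2$affinities == min(ds2$affinities[ds2$observed]) &
                   ds2$observed, arr.ind = TRUE)[1, , drop = FALSE]
  expect_equal(g2$dt[worst], max(g2$dt))

  # holdout of everything zeroes dt; unobserved holdout pair errors
  g3 <- assemble_graph(dd, tt, ds, transform_config(), pairs)
  expect_true(all(g3$dt == 0))
  unobs <- which(!ds$observed, arr.ind = TRUE)
  if (nrow(unobs) > 0) {
    expect_error(assemble_graph(dd, tt, ds, transform_config(),
                                unobs[1, , drop = FALSE]), "not observed")
  }

  # two graphs differing in one holdout pair differ in exactly that cell
  g4 <- assemble_graph(dd, tt, ds, transform_config(), hold[-1, , drop = FALSE])
  diffs <- which(g4$dt != g$dt, arr.ind = TRUE)
  expect_equal(nrow(diffs), 1L)
  expect_equal(unname(diffs[1, ]), unname(hold[1, ]))
})
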
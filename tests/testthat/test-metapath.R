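# A fixed 2x2 toy graph with known path products, worked out by hand:
# DD(d1,d2)=0.5, TT(t1,t2)=0.4, A(d1,t1)=0.9, A(d2,t1)=0.8, all else 0.
toy_graph <- function() {
  g <- list(dd = matrix(c(0, .5, .5, 0), 2),
            tt = matrix(c(0, .4, .4, 0), 2),
            dt = matrix(c(.9, .8, 0, 0), 2),
            edge_mask = matrix(c(TRUE, TRUE, FALSE, FALSE), 2),
            drug_ids = c("d1", "d2"), target_ids = c("t1", "t2"))
  class(g) <- "hetero_graph"
  g
}

test_that("structure enumeration yields the canonical six (two at length 2)", {
  expect_equal(enumerate_structures(3),
               c("DDT", "DTT", "DDDT", "DTTT", "DDTT", "DTDT"))
  expect_equal(enumerate_structures(2), c("DDT", "DTT"))
  expect_false("DT" %in% enumerate_structures(3))
  expect_error(enumerate_structures(4), "2 or 3")
})

test_that("toy-graph sum scores match hand-enumerated path products", {
  g <- toy_graph()
  S <- sum_scores(g)
  expect_equal(S[1, 1, 1], 0.5 * 0.8)          # d1-d2-t1
  expect_equal(S[1, 2, 2], 0.9 * 0.4)          # d1-t1-t2
  expect_equal(S[1, 2, 5], 0.5 * 0.8 * 0.4)    # d1-d2-t1-t2
  # C6 from d1 to t1 has no simple path (all walks revisit d1 or t1) ...
  expect_equal(S[1, 1, 6], 0)
  # ... while the uncorrected walk count is 0.9^3 + 0.9*0.8^2
  expect_equal(sum_scores(g, "walk")[1, 1, 6], 1.305)
  # zero affinity block kills every structure
  g0 <- g; g0$dt[] <- 0
  expect_true(all(sum_scores(g0) == 0))
  expect_true(all(max_scores(g0) == 0))
})

test_that("single-path structures give identical sum and max", {
  g <- toy_graph()
  M <- max_scores(g)
  expect_equal(M[1, 1, 1], 0.4)
  expect_equal(M[1, 2, 5], 0.16)
  # 3-drug variant with two C1 paths: products 0.4 and 0.3
  g3 <- list(dd = matrix(0, 3, 3), tt = matrix(0, 1, 1),
             dt = matrix(c(0, .8, .6), 3, 1),
             edge_mask = matrix(c(FALSE, TRUE, TRUE), 3, 1),
             drug_ids = paste0("d", 1:3), target_ids = "t1")
  g3$dd[1, 2] <- g3$dd[2, 1] <- 0.5
  g3$dd[1, 3] <- g3$dd[3, 1] <- 0.5
  class(g3) <- "hetero_graph"
  expect_equal(sum_scores(g3)[1, 1, 1], 0.4 + 0.3)
  expect_equal(max_scores(g3)[1, 1, 1], 0.4)
})

test_that("matrix-product scores equal exhaustive simple-path enumeration", {
  set.seed(123)
  n_cases <- 200
  for (case in seq_len(n_cases)) {
    n <- sample(2:8, 1); m <- sample(2:8, 1)
    g <- random_graph(n, m, density = runif(1, 0.2, 0.6))
    oracle <- oracle_path_scores(g$dd, g$tt, g$dt, "simple")
    expect_lt(max(abs(sum_scores(g) - oracle$sum)), 1e-10)
    expect_lt(max(abs(max_scores(g) - oracle$max)), 1e-10)
  }
})

test_that("walk-semantics scores equal unconstrained enumeration", {
  set.seed(321)
  for (case in 1:40) {
    g <- random_graph(sample(2:7, 1), sample(2:7, 1), density = 0.5)
    oracle <- oracle_path_scores(g$dd, g$tt, g$dt, "walk")
    expect_lt(max(abs(sum_scores(g, "walk") - oracle$sum)), 1e-10)
    expect_lt(max(abs(max_scores(g, "walk") - oracle$max)), 1e-10)
  }
})

test_that("scores are monotone in edge weights and scale by path length", {
  set.seed(77)
  g <- random_graph(6, 5, density = 0.5)
  S0 <- sum_scores(g); M0 <- max_scores(g)
  # bump one existing edge weight upward
  idx <- which(g$dt > 0 & g$dt < 0.9)[1]
  g2 <- g; g2$dt[idx] <- g2$dt[idx] + 0.05
  expect_true(all(sum_scores(g2) - S0 >= -1e-12))
  expect_true(all(max_scores(g2) - M0 >= -1e-12))
  # global scaling: 2-edge structures by c^2, 3-edge structures by c^3
  cc <- 0.7
  g3 <- g
  g3$dd <- g$dd * cc; g3$tt <- g$tt * cc; g3$dt <- g$dt * cc
  S3 <- sum_scores(g3); M3 <- max_scores(g3)
  for (h in 1:2) {
    expect_equal(S3[, , h], S0[, , h] * cc^2, tolerance = 1e-12)
    expect_equal(M3[, , h], M0[, , h] * cc^2, tolerance = 1e-12)
  }
  for (h in 3:6) {
    expect_equal(S3[, , h], S0[, , h] * cc^3, tolerance = 1e-12)
    expect_equal(M3[, , h], M0[, , h] * cc^3, tolerance = 1e-12)
  }
  # max never exceeds sum
  expect_true(all(M0 <= S0 + 1e-12))
})

test_that("pair feature blocks have 12 or 24 named columns", {
  g <- toy_graph()
  pairs <- rbind(c(1, 1), c(2, 2), c(1, 2))
  f1 <- pair_features(g, pairs = pairs)
  expect_equal(dim(f1), c(3L, 12L))
  expect_equal(colnames(f1)[1], "G1_Sum_C1")
  expect_equal(colnames(f1)[12], "G1_Max_C6")
  f2 <- pair_features(g, g, pairs)
  expect_equal(ncol(f2), 24L)
  expect_equal(colnames(f2)[13], "G2_Sum_C1")
  expect_identical(unname(f2[, 1:12]), unname(f2[, 13:24]))
  f0 <- pair_features(g, pairs = matrix(integer(0), 0, 2))
  expect_equal(dim(f0), c(0L, 12L))
  g_bad <- g; g_bad$drug_ids <- rev(g$drug_ids)
  expect_error(pair_features(g, g_bad, pairs), "orderings")
})
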
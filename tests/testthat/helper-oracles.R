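# Independent brute-force oracles used across the suite. These deliberately
# share no code with the package internals they check.

# Exhaustive simple-path (or walk) enumeration of the six meta-path scores.
# Nested loops over explicit node indices; product of edge weights per path.
oracle_path_scores <- function(dd, tt, dt, semantics = "simple") {
  n <- nrow(dt); m <- ncol(dt)
  simple <- semantics == "simple"
  S <- array(0, c(n, m, 6)); M <- array(0, c(n, m, 6))
  add <- function(i, j, h, p) {
    S[i, j, h] <<- S[i, j, h] + p
    M[i, j, h] <<- max(M[i, j, h], p)
  }
  for (i in 1:n) for (j in 1:m) {
    for (k in 1:n) {                       # C1: d_i - d_k - t_j
      if (simple && k == i) next
      add(i, j, 1, dd[i, k] * dt[k, j])
    }
    for (k in 1:m) {                       # C2: d_i - t_k - t_j
      if (simple && k == j) next
      add(i, j, 2, dt[i, k] * tt[k, j])
    }
    for (k in 1:n) for (l in 1:n) {        # C3: d_i - d_k - d_l - t_j
      if (simple && (k == i || l == i || l == k)) next
      add(i, j, 3, dd[i, k] * dd[k, l] * dt[l, j])
    }
    for (k in 1:m) for (l in 1:m) {        # C4: d_i - t_k - t_l - t_j
      if (simple && (k == j || l == j || l == k)) next
      add(i, j, 4, dt[i, k] * tt[k, l] * tt[l, j])
    }
    for (k in 1:n) for (l in 1:m) {        # C5: d_i - d_k - t_l - t_j
      if (simple && (k == i || l == j)) next
      add(i, j, 5, dd[i, k] * dt[k, l] * tt[l, j])
    }
    for (k in 1:m) for (l in 1:n) {        # C6: d_i - t_k - d_l - t_j
      if (simple && (k == j || l == i)) next
      add(i, j, 6, dt[i, k] * dt[l, k] * dt[l, j])
    }
  }
  list(sum = S, max = M)
}

# Random weighted heterogeneous graph for property tests.
random_graph <- function(n, m, density = 0.5) {
  sym01 <- function(k) {
    x <- matrix(runif(k * k), k)
    x[matrix(runif(k * k), k) > density] <- 0
    x <- (x + t(x)) / 2
    diag(x) <- 0
    x
  }
  dt <- matrix(runif(n * m), n)
  dt[matrix(runif(n * m), n) > density] <- 0
  g <- list(dd = sym01(n), tt = sym01(m), dt = dt,
            edge_mask = dt > 0,
            drug_ids = paste0("d", seq_len(n)),
            target_ids = paste0("t", seq_len(m)))
  class(g) <- "hetero_graph"
  g
}

# O(n^2) concordance index reference.
oracle_ci <- function(pred, actual) {
  conc <- 0; z <- 0
  n <- length(pred)
  for (a in 1:(n - 1)) for (b in (a + 1):n) {
    if (actual[a] == actual[b]) next
    z <- z + 1
    hi <- if (actual[a] > actual[b]) a else b
    lo <- if (actual[a] > actual[b]) b else a
    d <- pred[hi] - pred[lo]
    conc <- conc + if (d > 0) 1 else if (d == 0) 0.5 else 0
  }
  conc / z
}

# Small dense synthetic study shared by the heavier tests.
small_study <- function(seed = 11L, n = 20L, m = 15L, noise_sd = 0.3) {
  generate_synthetic(synthetic_spec(n_drugs = n, m_targets = m,
                                    latent_dim = 3L, noise_sd = noise_sd,
                                    seed = seed))
}
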
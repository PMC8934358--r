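## Meta-path sum/max score features over the weighted heterogeneous graph.
## Sums are (plus, times) commuting-matrix products; maxima use (max, times)
## semiring products. Under the default simple-path semantics, closed-form
## revisit corrections remove walks that re-visit a node: C1..C5 endpoint
## revisits of the immediate kind are already excluded by the zero dd/tt
## diagonals, and the remaining offenders are
##   C3: d_i -> d_k -> d_i -> t_j        (subtract diag(DD^2)_i * A_ij)
##   C4: d_i -> t_j -> t_l -> t_j        (subtract A_ij * diag(TT^2)_j)
##   C6: d_i -> t_k -> d_i -> t_j  and   d_i -> t_j -> d_l -> t_j
##       (inclusion-exclusion: subtract A_ij*(AA')_ii and A_ij*(A'A)_jj,
##        add back the doubly-counted A_ij^3)

METAPATH_STRUCTURES <- c("DDT", "DTT", "DDDT", "DTTT", "DDTT", "DTDT")

#' Enumerate drug-to-target meta-path structures
#'
#' All type sequences that start at a drug node, end at a target node, use
#' 2..`max_len` edges, and step only along existing edge classes (D-D, T-T,
#' D-T). With the default `max_len = 3` there are exactly six:
#' `C1 = D-D-T`, `C2 = D-T-T`, `C3 = D-D-D-T`, `C4 = D-T-T-T`,
#' `C5 = D-D-T-T`, `C6 = D-T-D-T`. Direct one-edge D-T paths are excluded.
#'
#' @param max_len maximum number of edges (2 or 3).
#' @return character vector of node-type sequences.
#' @export
enumerate_structures <- function(max_len = 3L) {
  max_len <- as.integer(max_len)
  if (!max_len %in% c(2L, 3L)) stop2("max_len must be 2 or 3")
  out <- character(0)
  grow <- function(seq_types) {
    last <- substring(seq_types, nchar(seq_types), nchar(seq_types))
    n_edges <- nchar(seq_types) - 1L
    if (last == "T" && n_edges >= 2L) out <<- c(out, seq_types)
    if (n_edges >= max_len) return(invisible())
    for (nxt in c("D", "T")) grow(paste0(seq_types, nxt))
  }
  grow("D")
  ## canonical order: 2-edge structures first, then 3-edge in C3..C6 order
  ord <- METAPATH_STRUCTURES[METAPATH_STRUCTURES %in% out]
  stopifnot(setequal(ord, out))
  ord
}

## column-wise max of each row of (vec * M): max_k vec[k] * M[k, j]
max_times_vec <- function(vec, M) {
  ## vec: length K, M: K x J  -> length J
  apply(M * vec, 2L, max)
}

#' Meta-path sum scores
#'
#' For each drug-target pair and each structure `C_h`, the sum over paths of
#' that structure of the product of edge weights along the path, computed
#' with commuting-matrix products (`C1: DD A`, `C2: A TT`, `C3: DD DD A`,
#' `C4: A TT TT`, `C5: DD A TT`, `C6: A A' A`). Under
#' `semantics = "simple"` (default) the closed-form revisit corrections are
#' applied so each node appears at most once per path; `"walk"` keeps the
#' raw products.
#'
#' @param g a `hetero_graph` from [assemble_graph()].
#' @param semantics `"simple"` or `"walk"`.
#' @return `n x m x 6` array, third dimension named `C1..C6`.
#' @export
sum_scores <- function(g, semantics = c("simple", "walk")) {
  semantics <- match.arg(semantics)
  D <- g$dd; Tt <- g$tt; A <- g$dt
  n <- nrow(A); m <- ncol(A)
  DA <- D %*% A
  AT <- A %*% Tt
  S <- array(0, dim = c(n, m, 6L),
             dimnames = list(g$drug_ids, g$target_ids, paste0("C", 1:6)))
  S[, , 1L] <- DA
  S[, , 2L] <- AT
  S[, , 3L] <- D %*% DA
  S[, , 4L] <- AT %*% Tt
  S[, , 5L] <- DA %*% Tt
  S[, , 6L] <- A %*% crossprod(A, A)
  if (semantics == "simple") {
    d2 <- diag(D %*% D)          # (DD^2)_ii
    t2 <- diag(Tt %*% Tt)        # (TT^2)_jj
    S[, , 3L] <- S[, , 3L] - d2 * A
    S[, , 4L] <- S[, , 4L] - A * rep(t2, each = n)
    aa_i <- rowSums(A^2)         # (A A')_ii
    aa_j <- colSums(A^2)         # (A' A)_jj
    S[, , 6L] <- S[, , 6L] - A * aa_i - A * rep(aa_j, each = n) + A^3
  }
  ## tiny negatives from floating cancellation
  S[S < 0 & S > -1e-12] <- 0
  S
}

#' Meta-path max scores
#'
#' For each pair and structure, the maximum path product, computed with
#' (max, times) semiring products. Under simple-path semantics the
#' candidates that would revisit a node are excluded exactly (via
#' second-best bookkeeping for the structures whose exclusion couples the
#' endpoints); equals the sum score whenever at most one path exists.
#'
#' @inheritParams sum_scores
#' @return `n x m x 6` array, third dimension named `C1..C6`.
#' @export
max_scores <- function(g, semantics = c("simple", "walk")) {
  semantics <- match.arg(semantics)
  D <- g$dd; Tt <- g$tt; A <- g$dt
  n <- nrow(A); m <- ncol(A)
  M <- array(0, dim = c(n, m, 6L),
             dimnames = list(g$drug_ids, g$target_ids, paste0("C", 1:6)))
  simple <- semantics == "simple"

  ## top-2 values and argmax over rows of each column
  top2_cols <- function(X) {
    arg1 <- max.col(t(X), ties.method = "first")
    m1 <- X[cbind(arg1, seq_len(ncol(X)))]
    X2 <- X
    X2[cbind(arg1, seq_len(ncol(X)))] <- -Inf
    m2 <- apply(X2, 2L, max)
    m2[!is.finite(m2)] <- 0
    list(m1 = m1, arg1 = arg1, m2 = m2)
  }

  for (i in seq_len(n)) {
    Di <- D[i, ]
    ## C1: max_k D[i,k] A[k,j]
    M[i, , 1L] <- max_times_vec(Di, A)
    ## C2: max_k A[i,k] T[k,j]
    M[i, , 2L] <- max_times_vec(A[i, ], Tt)
    ## C3: max_{k, l != i} D[i,k] D[k,l] A[l,j]
    P <- D * Di                      # P[k, l] = D[i,k] D[k,l]
    if (simple) P[, i] <- 0
    v3 <- apply(P, 2L, max)          # best over k for each intermediate l
    M[i, , 3L] <- max_times_vec(v3, A)
    ## C5: max_{k,l} D[i,k] A[k,l] T[l,j]
    v5 <- max_times_vec(Di, A)       # best over k for each l (targets)
    M[i, , 5L] <- max_times_vec(v5, Tt)
    ## C4: max_{k != j, l} A[i,k] T[k,l] T[l,j]
    Q <- Tt * A[i, ]                 # Q[k, l] = A[i,k] T[k,l]
    if (simple) {
      tq <- top2_cols(Q)             # per intermediate l: best origin k
      ## where the best origin k equals the endpoint j, fall back to 2nd best
      for (j in seq_len(m)) {
        w <- tq$m1 * Tt[, j]
        hit <- tq$arg1 == j
        if (any(hit)) w[hit] <- tq$m2[hit] * Tt[hit, j]
        M[i, j, 4L] <- max(w, 0)
      }
    } else {
      v4 <- apply(Q, 2L, max)
      M[i, , 4L] <- max_times_vec(v4, Tt)
    }
    ## C6: max_{k != j, l != i} A[i,k] A[l,k] A[l,j]
    S6 <- t(A) * A[i, ]              # S6[k, l] = A[i,k] A[l,k]
    if (simple) S6[, i] <- 0
    if (simple) {
      tq <- top2_cols(S6)            # per intermediate drug l: best target k
      for (j in seq_len(m)) {
        w <- tq$m1 * A[, j]
        hit <- tq$arg1 == j
        if (any(hit)) w[hit] <- tq$m2[hit] * A[hit, j]
        M[i, j, 6L] <- max(w, 0)
      }
    } else {
      v6 <- apply(S6, 2L, max)
      M[i, , 6L] <- max_times_vec(v6, A)
    }
  }
  M
}

#' Per-pair meta-path feature set
#'
#' Twelve features per pair per source graph — `Sum_C1..Sum_C6` then
#' `Max_C1..Max_C6` — concatenated `g1`-then-`g2` when two graphs are given
#' (24 columns), matching the 12/24-dimensional score feature vectors.
#'
#' @param g1 a `hetero_graph`.
#' @param g2 optional second `hetero_graph` over the same entities.
#' @param pairs integer matrix (columns drug, target) of pair indices; may
#'   have zero rows.
#' @inheritParams sum_scores
#' @return numeric matrix `nrow(pairs) x 12` (or 24), columns
#'   `G1_Sum_C1 ... G2_Max_C6`.
#' @export
pair_features <- function(g1, g2 = NULL, pairs, semantics = "simple") {
  stopifnot(inherits(g1, "hetero_graph"))
  pairs <- as.matrix(pairs)
  if (ncol(pairs) != 2L && nrow(pairs) > 0L) stop2("pairs needs two columns")
  graphs <- list(G1 = g1)
  if (!is.null(g2)) {
    stopifnot(inherits(g2, "hetero_graph"))
    if (!identical(g1$drug_ids, g2$drug_ids) ||
        !identical(g1$target_ids, g2$target_ids)) {
      stop2("g1 and g2 must share entity orderings")
    }
    graphs$G2 <- g2
  }
  blocks <- lapply(names(graphs), function(nm) {
    g <- graphs[[nm]]
    S <- sum_scores(g, semantics)
    M <- max_scores(g, semantics)
    block <- matrix(0, nrow(pairs), 12L)
    for (h in 1:6) {
      block[, h] <- S[, , h][pairs]
      block[, 6L + h] <- M[, , h][pairs]
    }
    colnames(block) <- paste0(nm, "_", rep(c("Sum", "Max"), each = 6L),
                              "_C", rep(1:6, 2L))
    block
  })
  out <- do.call(cbind, blocks)
  if (nrow(pairs) == 0L) out <- out[0, , drop = FALSE]
  out
}
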
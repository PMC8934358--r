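## Normalisation, similarity-edge filtering, affinity-to-weight transforms and
## assembly of the weighted heterogeneous drug-target graph.

#' Convert a dissociation constant (nM) to pKd
#'
#' `pKd = -log10(Kd / 1e9)` with Kd in nanomolar, i.e. the negative decadic
#' log of the molar dissociation constant. Larger pKd means stronger binding
#' (10 uM -> 5.0, 1 nM -> 9.0).
#'
#' @param kd_nM positive dissociation constant(s) in nanomolar.
#' @return pKd value(s).
#' @export
transform_pkd <- function(kd_nM) {
  if (any(!is.finite(kd_nM)) || any(kd_nM <= 0)) {
    stop2("Kd must be positive and finite (nanomolar)")
  }
  -log10(kd_nM / 1e9)
}

#' Min-max normalisation to [0, 1]
#'
#' Affine, order-preserving rescale. By default the data range is used; an
#' all-constant input (degenerate range) maps to all zeros.
#'
#' @param values numeric vector or matrix.
#' @param lo,hi optional fixed range; default data min/max.
#' @return Object of the same shape with entries in `[0, 1]`.
#' @export
minmax_normalize <- function(values, lo = NULL, hi = NULL) {
  if (any(!is.finite(values))) stop2("non-finite value in minmax_normalize")
  lo <- lo %||% min(values)
  hi <- hi %||% max(values)
  if (hi <= lo) {
    values[] <- 0
    return(values)
  }
  values[] <- (values - lo) / (hi - lo)
  values
}

#' Remove weak similarity edges
#'
#' Entries below `threshold` are set to zero; the diagonal is always forced
#' to zero so a node never transitions to itself inside a meta-path.
#' Idempotent.
#'
#' @param sim a [similarity_matrix()] or square numeric matrix normalised to
#'   `[0, 1]`.
#' @param threshold removal cutoff in `[0, 1]` (e.g. 0.3 for 2D-structure
#'   drug similarity, 0.04 for normalised Smith-Waterman target similarity).
#' @return Square numeric matrix of retained edge weights.
#' @export
filter_similarity <- function(sim, threshold) {
  threshold <- check_number(threshold, "threshold", 0, 1)
  m <- if (inherits(sim, "similarity_matrix")) sim$values else as.matrix(sim)
  if (min(m) < 0 || max(m) > 1) {
    stop2("similarity matrix must be normalised to [0,1] before filtering")
  }
  m[m < threshold] <- 0
  diag(m) <- 0
  m
}

#' Exponential affinity-to-weight transform
#'
#' `f(z) = exp(-alpha * z)` applied elementwise to distance-like affinity
#' values `z >= 0` (smaller z = stronger binding), yielding edge weights in
#' `(0, 1]` that decrease strictly in z.
#'
#' @param values finite numeric vector of distance-like affinities.
#' @param alpha positive rate; tunable (grid `c(0.1, 0.5, 1)` used by the
#'   pipeline's validation).
#' @return weights, same length as `values`.
#' @export
transform_affinity_exponential <- function(values, alpha) {
  alpha <- check_number(alpha, "alpha", lo = .Machine$double.xmin)
  if (any(!is.finite(values))) stop2("non-finite affinity value")
  exp(-alpha * values)
}

#' SoftMax affinity-to-weight transform
#'
#' `sigma(z)_i = exp(z_i) / sum_j exp(z_j)` over the single vector of all
#' observed affinity edges (global normalisation, not per drug row),
#' computed with a max-shift for numerical stability. The output is a
#' probability vector: nonnegative, summing to one, shift-invariant.
#'
#' @param values finite numeric vector (strength-oriented: larger = stronger).
#' @return weights summing to 1.
#' @export
transform_affinity_softmax <- function(values) {
  if (length(values) == 0L) stop2("softmax of an empty vector")
  if (any(!is.finite(values))) stop2("non-finite affinity value")
  e <- exp(values - max(values))
  e / sum(e)
}

#' Edge-transform configuration
#'
#' @param method `"exponential"` (default) or `"softmax"`.
#' @param alpha exponential rate (> 0); ignored by softmax.
#' @param drug_threshold,target_threshold similarity-edge cutoffs in `[0,1]`.
#'   Defaults 0.3 / 0.04 (2D chemical structure and normalised
#'   Smith-Waterman conventions).
#' @return Object of class `transform_config`.
#' @export
transform_config <- function(method = c("exponential", "softmax"),
                             alpha = 0.5,
                             drug_threshold = 0.3,
                             target_threshold = 0.04) {
  method <- match.arg(method)
  structure(list(method = method,
                 alpha = check_number(alpha, "alpha", lo = 1e-12),
                 drug_threshold = check_number(drug_threshold,
                                               "drug_threshold", 0, 1),
                 target_threshold = check_number(target_threshold,
                                                 "target_threshold", 0, 1)),
            class = "transform_config")
}

#' Assemble the weighted heterogeneous drug-target graph
#'
#' Combines thresholded drug-drug (`dd`) and target-target (`tt`) similarity
#' blocks with a transformed drug-target affinity block (`dt`). Affinities
#' are first oriented into a distance-like quantity (0 = strongest observed
#' binding): `max - value` when the dataset orientation is
#' `higher_is_stronger`, `value - min` otherwise. The configured transform
#' then maps distance to a `[0, 1]` weight that increases with binding
#' strength. Holdout (test) pairs are masked: their edges are removed from
#' the graph before any feature is computed, and the orientation statistics
#' (min/max) are taken over training edges only, so no test information
#' leaks into the graph.
#'
#' @param dd `n x n` drug-drug weights, already normalised and thresholded
#'   (see [filter_similarity()]).
#' @param tt `m x m` target-target weights, likewise.
#' @param dataset an [affinity_dataset()].
#' @param cfg a [transform_config()].
#' @param holdout_pairs optional integer matrix (columns drug, target) of
#'   observed pairs whose affinity edges must be excluded from this graph.
#' @return Object of class `hetero_graph` with elements `dd`, `tt`, `dt`,
#'   `edge_mask`, `drug_ids`, `target_ids`, `cfg`.
#' @export
assemble_graph <- function(dd, tt, dataset, cfg = transform_config(),
                           holdout_pairs = NULL) {
  stopifnot(inherits(dataset, "affinity_dataset"),
            inherits(cfg, "transform_config"))
  dd <- as.matrix(dd); tt <- as.matrix(tt)
  n <- length(dataset$drug_ids); m <- length(dataset$target_ids)
  if (!all(dim(dd) == c(n, n))) stop2("dd must be ", n, "x", n)
  if (!all(dim(tt) == c(m, m))) stop2("tt must be ", m, "x", m)
  if (any(diag(dd) != 0) || any(diag(tt) != 0)) {
    stop2("dd/tt must have zero diagonals (run filter_similarity first)")
  }
  if (min(dd) < 0 || max(dd) > 1 || min(tt) < 0 || max(tt) > 1) {
    stop2("dd/tt entries must lie in [0,1]")
  }

  edge_mask <- dataset$observed
  if (!is.null(holdout_pairs)) {
    holdout_pairs <- as.matrix(holdout_pairs)
    if (ncol(holdout_pairs) != 2L) stop2("holdout_pairs needs 2 columns")
    obs_at <- dataset$observed[holdout_pairs]
    if (any(!obs_at)) {
      k <- which(!obs_at)[1L]
      stop2("holdout pair (", dataset$drug_ids[holdout_pairs[k, 1]], ", ",
            dataset$target_ids[holdout_pairs[k, 2]], ") is not observed")
    }
    edge_mask[holdout_pairs] <- FALSE
  }

  dt <- matrix(0, n, m, dimnames = dimnames(dataset$affinities))
  if (any(edge_mask)) {
    vals <- dataset$affinities[edge_mask]
    dist <- if (dataset$orientation == "higher_is_stronger") {
      max(vals) - vals
    } else {
      vals - min(vals)
    }
    w <- switch(cfg$method,
                exponential = transform_affinity_exponential(dist, cfg$alpha),
                softmax = transform_affinity_softmax(-dist))
    dt[edge_mask] <- w
  }

  structure(list(dd = dd, tt = tt, dt = dt, edge_mask = edge_mask,
                 drug_ids = dataset$drug_ids, target_ids = dataset$target_ids,
                 cfg = cfg),
            class = "hetero_graph")
}

#' @export
print.hetero_graph <- function(x, ...) {
  cat("Weighted heterogeneous graph: ", length(x$drug_ids), " drugs, ",
      length(x$target_ids), " targets\n", sep = "")
  cat("  D-D edges: ", sum(x$dd > 0) / 2, "   T-T edges: ",
      sum(x$tt > 0) / 2, "   D-T edges: ", sum(x$edge_mask), "\n", sep = "")
  cat("  transform: ", x$cfg$method,
      if (x$cfg$method == "exponential") sprintf(" (alpha = %g)", x$cfg$alpha),
      "\n", sep = "")
  invisible(x)
}
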
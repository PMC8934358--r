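## Metric suite: MSE, concordance index (fast O(n log n) with Heaviside tie
## handling), r2 / r0^2 / rm2, thresholded + averaged AUPR, coefficient of
## determination, and the Y-randomization validation.

#' Mean squared error
#' @param pred,actual numeric vectors of equal nonzero length.
#' @return `mean((pred - actual)^2)`.
#' @export
mse <- function(pred, actual) {
  if (length(pred) != length(actual) || length(pred) == 0L) {
    stop2("pred and actual must have equal nonzero length")
  }
  mean((pred - actual)^2)
}

#' Coefficient of determination (goodness of fit)
#'
#' `R^2 = 1 - SS_res / SS_tot`. Unlike squared Pearson correlation this can
#' go negative when the predictions fit worse than the mean — the behaviour
#' the Y-randomization check relies on.
#'
#' @inheritParams mse
#' @export
r2_score <- function(pred, actual) {
  if (length(pred) != length(actual) || length(pred) < 2L) {
    stop2("need at least two paired values")
  }
  ss_tot <- sum((actual - mean(actual))^2)
  if (ss_tot == 0) stop2("actual values have zero variance")
  1 - sum((actual - pred)^2) / ss_tot
}

## Fenwick (binary indexed) tree helpers for the fast concordance index
fenwick_add <- function(tree, i) {
  n <- length(tree)
  while (i <= n) {
    tree[i] <- tree[i] + 1
    i <- i + bitwAnd(i, -i)
  }
  tree
}
fenwick_sum <- function(tree, i) {
  s <- 0
  while (i > 0) {
    s <- s + tree[i]
    i <- i - bitwAnd(i, -i)
  }
  s
}

#' Concordance index
#'
#' Over all ordered pairs whose actual affinities differ
#' (`actual_x > actual_y`), the average of the Heaviside step
#' `h(pred_x - pred_y)` with `h(m) = 1` for `m > 0`, `0.5` for `m = 0`, `0`
#' for `m < 0`; the pair count is the normaliser Z. Equals the probability
#' that two randomly drawn pairs with different labels are predicted in the
#' correct order, with half-credit for prediction ties. Computed in
#' O(n log n) by sweeping actual-value groups over a Fenwick tree of
#' prediction ranks; invariant to any strictly increasing transform of the
#' predictions.
#'
#' @inheritParams mse
#' @export
concordance_index <- function(pred, actual) {
  n <- length(pred)
  if (n != length(actual) || n < 2L) stop2("need >= 2 paired values")
  if (length(unique(actual)) < 2L) {
    stop2("all actual values tied; concordance undefined (Z = 0)")
  }
  pr <- match(pred, sort(unique(pred)))   # compressed prediction ranks
  R <- max(pr)
  ord <- order(actual, pr)
  pr <- pr[ord]; act <- actual[ord]
  tree <- numeric(R)
  inserted <- 0L
  conc <- 0; tied <- 0; z <- 0
  ## count of already-inserted items per prediction rank (for exact ties)
  rank_count <- numeric(R)
  i <- 1L
  while (i <= n) {
    j <- i
    while (j <= n && act[j] == act[i]) j <- j + 1L
    ## items i..(j-1) share an actual value: compare against all previously
    ## inserted (strictly smaller actual) items
    for (k in i:(j - 1L)) {
      below <- fenwick_sum(tree, pr[k] - 1L)
      eq <- rank_count[pr[k]]
      conc <- conc + below
      tied <- tied + eq
      z <- z + inserted
    }
    for (k in i:(j - 1L)) {
      tree <- fenwick_add(tree, pr[k])
      rank_count[pr[k]] <- rank_count[pr[k]] + 1
      inserted <- inserted + 1L
    }
    i <- j
  }
  (conc + 0.5 * tied) / z
}

#' rm2 external-validation statistic
#'
#' `rm2 = r2 * (1 - sqrt(r2 - r0^2))` where `r2` is the squared Pearson
#' correlation between predicted and actual values and `r0^2` is the squared
#' correlation coefficient of the least-squares regression through the
#' origin. By QSAR convention the through-origin fit regresses the observed
#' values on the predictions (`axis = "actual_on_pred"`, default:
#' `k = sum(y*yhat)/sum(yhat^2)`, `r0^2 = 1 - sum((y - k*yhat)^2) /
#' sum((y - mean(y))^2)`); the alternate axis is available and both are
#' returned. The radicand `r2 - r0^2` is floored at zero before the square
#' root (it can dip below zero numerically).
#'
#' @inheritParams mse
#' @param axis which variable is regressed through the origin on the other.
#' @return named list: `r2`, `r0_2`, `rm2`, plus `r0_2_alt` for the other
#'   axis.
#' @export
rm2_index <- function(pred, actual, axis = c("actual_on_pred",
                                             "pred_on_actual")) {
  axis <- match.arg(axis)
  if (length(pred) != length(actual) || length(pred) < 3L) {
    stop2("need >= 3 paired values")
  }
  if (stats::sd(pred) == 0 || stats::sd(actual) == 0) {
    stop2("zero variance in pred or actual")
  }
  r2 <- stats::cor(pred, actual)^2
  r0_through_origin <- function(y, x) {
    k <- sum(y * x) / sum(x^2)
    1 - sum((y - k * x)^2) / sum((y - mean(y))^2)
  }
  r0_a <- r0_through_origin(actual, pred)   # actual on predicted
  r0_b <- r0_through_origin(pred, actual)   # predicted on actual
  r0 <- if (axis == "actual_on_pred") r0_a else r0_b
  rm2 <- r2 * (1 - sqrt(max(r2 - r0, 0)))
  list(r2 = r2, r0_2 = r0, rm2 = rm2,
       r0_2_alt = if (axis == "actual_on_pred") r0_b else r0_a)
}

## area under the precision-recall curve by step interpolation
## (average precision: sum over recall increments of the precision there)
aupr_step <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  P <- sum(labels)
  if (P == 0L || P == length(labels)) return(NA_real_)
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]; sc <- scores[ord]
  ## group tied scores: the operating points sit at group boundaries
  grp_end <- which(diff(sc) != 0)
  grp_end <- c(grp_end, length(sc))
  tp <- cumsum(lab)[grp_end]
  fp <- grp_end - tp
  prec <- tp / (tp + fp)
  rec <- tp / P
  drec <- diff(c(0, rec))
  sum(prec * drec)
}

#' Thresholded and averaged AUPR
#'
#' The continuous affinities are binarised at each threshold
#' (`positive_rule = "ge"`: actual >= threshold is a positive, the pKd-style
#' convention; `"le"` for raw distance-style scales) and the area under the
#' precision-recall curve of the predictions is computed by step
#' interpolation, with the prediction scores oriented so that larger means
#' more likely positive. Thresholds at which only one class exists are
#' reported as `NA` and excluded from the mean with a warning.
#'
#' @inheritParams mse
#' @param thresholds numeric vector of binarisation cutoffs (e.g. 7 for a
#'   pKd scale; 12.1 for KIBA-style scores; `c(6, 7, 10)` averaged).
#' @param positive_rule `"ge"` or `"le"`.
#' @return list with `per_threshold` (named numeric) and `mean`.
#' @export
thresholded_aupr <- function(pred, actual, thresholds,
                             positive_rule = c("ge", "le")) {
  positive_rule <- match.arg(positive_rule)
  if (length(thresholds) == 0L) stop2("no thresholds given")
  if (length(pred) != length(actual)) stop2("length mismatch")
  per <- vapply(thresholds, function(th) {
    labels <- if (positive_rule == "ge") actual >= th else actual <= th
    scores <- if (positive_rule == "ge") pred else -pred
    aupr_step(scores, as.integer(labels))
  }, numeric(1))
  names(per) <- format(thresholds)
  if (anyNA(per)) {
    warning("threshold(s) ", paste(names(per)[is.na(per)], collapse = ", "),
            " leave a single class; excluded from the mean")
  }
  list(per_threshold = per, mean = mean(per, na.rm = TRUE))
}

#' Y-randomization validation
#'
#' Fits the model on the true training labels and on `n_iter` label-shuffled
#' copies (features fixed), evaluating the coefficient of determination r2
#' on a fixed held-out test split each time. Reports a parametric p-value
#' (upper-tail of a normal fitted to the permuted r2 distribution) and the
#' empirical rank p-value `(count(permuted >= observed) + 1) / (n_iter + 1)`.
#'
#' @param train_features,train_labels training split.
#' @param test_features,test_labels held-out split used for every r2.
#' @param params a [boost_params()].
#' @param n_iter number of label shuffles (>= 10; 100 is conventional).
#' @param seed RNG seed for the shuffles.
#' @return list: `observed_r2`, `permuted_r2` (length `n_iter`),
#'   `p_normal`, `p_empirical`.
#' @export
y_randomization <- function(train_features, train_labels,
                            test_features, test_labels,
                            params = boost_params(), n_iter = 100L,
                            seed = 1L) {
  n_iter <- as.integer(n_iter)
  if (n_iter < 10L) stop2("n_iter must be >= 10")
  fit <- fit_boost(train_features, train_labels, params)
  observed <- r2_score(predict(fit, test_features), test_labels)
  seeds <- seed_stream(seed, n_iter)
  permuted <- vapply(seq_len(n_iter), function(i) {
    shuffled <- with_seed(seeds[i], sample(train_labels))
    p2 <- params; p2$seed <- seeds[i]
    f <- fit_boost(train_features, shuffled, p2)
    r2_score(predict(f, test_features), test_labels)
  }, numeric(1))
  mu <- mean(permuted); s <- stats::sd(permuted)
  p_normal <- if (s > 0) stats::pnorm(observed, mu, s, lower.tail = FALSE)
              else as.numeric(observed <= mu)
  list(observed_r2 = observed, permuted_r2 = permuted,
       p_normal = p_normal,
       p_empirical = (sum(permuted >= observed) + 1) / (n_iter + 1))
}

#' Full evaluation report
#'
#' Bundles the whole metric suite for one prediction vector.
#'
#' @inheritParams thresholded_aupr
#' @param thresholds optional AUPR cutoffs; omit to skip AUPR.
#' @return object of class `eval_report`.
#' @export
eval_report <- function(pred, actual, thresholds = NULL,
                        positive_rule = "ge") {
  m <- mse(pred, actual)
  ci <- concordance_index(pred, actual)
  rm2 <- rm2_index(pred, actual)
  aupr <- if (!is.null(thresholds)) {
    thresholded_aupr(pred, actual, thresholds, positive_rule)
  } else NULL
  structure(list(mse = m, rmse = sqrt(m), ci = ci,
                 r2 = rm2$r2, r0_2 = rm2$r0_2, rm2 = rm2$rm2,
                 aupr_per_threshold = aupr$per_threshold,
                 aupr_mean = aupr$mean, n = length(pred)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Evaluation on %d pairs:\n", x$n))
  cat(sprintf("  MSE %.4f   RMSE %.4f   CI %.4f\n", x$mse, x$rmse, x$ci))
  cat(sprintf("  r2 %.4f   r0^2 %.4f   rm2 %.4f\n", x$r2, x$r0_2, x$rm2))
  if (!is.null(x$aupr_mean)) {
    cat(sprintf("  AUPR %s  (mean %.4f)\n",
                paste(sprintf("%s: %.3f", names(x$aupr_per_threshold),
                              x$aupr_per_threshold), collapse = ", "),
                x$aupr_mean))
  }
  invisible(x)
}
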
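## Assembly of the three per-pair feature variants (pscore / embed / hybrid)
## and the train/test normalisation protocol.

#' Concatenated drug + protein embedding features
#'
#' One row per drug-target pair: the drug fingerprint (length d) followed by
#' the protein embedding (length k), giving d + k columns (e.g. 128 + 100 =
#' 228).
#'
#' @param drug_emb,prot_emb `embedding_matrix` objects covering every drug /
#'   target appearing in `pairs`.
#' @param pairs integer matrix (columns drug, target) of positional indices
#'   into `drug_emb$entity_ids` / `prot_emb$entity_ids`.
#' @return numeric matrix `nrow(pairs) x (d + k)` with columns
#'   `drug_1..drug_d, prot_1..prot_k` and attribute `variant = "embed"`.
#' @export
build_embed_features <- function(drug_emb, prot_emb, pairs) {
  stopifnot(inherits(drug_emb, "embedding_matrix"),
            inherits(prot_emb, "embedding_matrix"))
  pairs <- as.matrix(pairs)
  if (nrow(pairs) > 0L) {
    if (max(pairs[, 1]) > nrow(drug_emb$vectors)) {
      stop2("pair references drug index ", max(pairs[, 1]),
            " but only ", nrow(drug_emb$vectors), " drug embeddings exist")
    }
    if (max(pairs[, 2]) > nrow(prot_emb$vectors)) {
      stop2("pair references target index ", max(pairs[, 2]),
            " but only ", nrow(prot_emb$vectors), " protein embeddings exist")
    }
  }
  out <- cbind(drug_emb$vectors[pairs[, 1], , drop = FALSE],
               prot_emb$vectors[pairs[, 2], , drop = FALSE])
  colnames(out) <- c(paste0("drug_", seq_len(drug_emb$dim)),
                     paste0("prot_", seq_len(prot_emb$dim)))
  rownames(out) <- NULL
  attr(out, "variant") <- "embed"
  out
}

#' Hybrid features: meta-path scores then embeddings
#'
#' Column-wise concatenation of a meta-path score block
#' ([pair_features()]) and an embedding block ([build_embed_features()])
#' computed over the identical pair ordering, e.g. 12 + 228 = 240 columns.
#'
#' @param pscore meta-path feature matrix (12 or 24 columns).
#' @param embed embedding feature matrix with the same number of rows.
#' @return combined matrix with attribute `variant = "hybrid"`.
#' @export
build_hybrid_features <- function(pscore, embed) {
  if (nrow(pscore) != nrow(embed)) {
    stop2("pscore has ", nrow(pscore), " rows but embed has ", nrow(embed),
          "; pair orderings must match")
  }
  out <- cbind(pscore, embed)
  attr(out, "variant") <- "hybrid"
  out
}

#' Min-max normalise train and test feature blocks
#'
#' `mode = "independent"` (default) rescales each block with its own
#' per-column min/max — the literal reading of normalising training and
#' testing sets separately. `mode = "fit_on_train"` learns the ranges on the
#' training block, applies them to both, and clips the test block to
#' `[0, 1]`; this is the leakage-safer protocol and the one we recommend.
#' A column constant on the fitted block maps to all zeros.
#'
#' @param train,test numeric feature matrices with identical columns.
#' @param mode `"independent"` or `"fit_on_train"`.
#' @return list with elements `train`, `test`, `lo`, `hi`.
#' @export
normalize_train_test <- function(train, test,
                                 mode = c("independent", "fit_on_train")) {
  mode <- match.arg(mode)
  if (ncol(train) != ncol(test)) stop2("train/test column mismatch")
  scale_block <- function(x, lo, hi) {
    rng <- hi - lo
    rng[rng <= 0] <- Inf              # constant column -> zeros
    out <- sweep(sweep(x, 2L, lo, "-"), 2L, rng, "/")
    out
  }
  lo <- apply(train, 2L, min); hi <- apply(train, 2L, max)
  tr <- scale_block(train, lo, hi)
  if (mode == "fit_on_train") {
    te <- scale_block(test, lo, hi)
    te[te < 0] <- 0; te[te > 1] <- 1
  } else {
    te <- if (nrow(test) > 0L) {
      scale_block(test, apply(test, 2L, min), apply(test, 2L, max))
    } else test
  }
  list(train = tr, test = te, lo = lo, hi = hi, mode = mode)
}
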
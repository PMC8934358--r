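## Trainable seq2seq SMILES fingerprint: a stacked-GRU autoencoder whose
## encoder bottleneck (final top-layer hidden state) is the drug fingerprint.
## Written directly in R with hand-derived backpropagation-through-time and
## Adam updates; the analytic gradients are validated against numerical
## differentiation in the test suite. Intended for modest corpora — the
## deterministic hashed-n-gram encoder remains the default for large runs.

SOS <- "<sos>"; EOS <- "<eos>"; UNK <- "<unk>"

#' Canonical hyperparameter search space for the GRU fingerprint
#'
#' Fingerprint length, learning rate, layer count and dropout grids used
#' when tuning the sequence autoencoder.
#' @return named list of candidate values.
#' @export
gru_search_space <- function() {
  list(dim = c(128L, 256L, 512L, 1024L),
       lr = c(0.1, 0.01, 0.001),
       layers = 2:4,
       dropout = c(0, 0.1, 0.2, 0.3))
}

#' GRU sequence-autoencoder drug encoder
#'
#' A stacked-GRU encoder reads the tokenised SMILES; its final top-layer
#' hidden state (length `dim`) is the fingerprint. A stacked-GRU decoder,
#' initialised from the encoder's final hidden states, reconstructs the
#' token sequence under teacher forcing with a softmax output layer; the
#' training objective is summed cross-entropy, optimised with Adam.
#' Implements the drug-encoder contract (`fit_corpus`, `encode`).
#'
#' @param dim fingerprint / hidden length (canonical grid
#'   `c(128, 256, 512, 1024)`; small values are fine for toy corpora).
#' @param layers stacked GRU layers, 2-4.
#' @param lr Adam learning rate (canonical grid `c(0.1, 0.01, 0.001)`).
#' @param dropout inter-layer dropout probability in `[0, 0.3]`.
#' @param epochs maximum training passes over the corpus.
#' @param target_accuracy stop early once teacher-forced reconstruction
#'   accuracy reaches this fraction (default 0.99).
#' @param seed RNG seed (initialisation, dropout, shuffling).
#' @return Object of class `c("gru_autoencoder", "drug_encoder")`.
#' @export
gru_autoencoder <- function(dim = 128L, layers = 2L, lr = 0.001,
                            dropout = 0, epochs = 200L,
                            target_accuracy = 0.99, seed = 1L) {
  layers <- as.integer(check_number(layers, "layers", 2, 4))
  dropout <- check_number(dropout, "dropout", 0, 0.3)
  structure(list(dim = as.integer(check_number(dim, "dim", 2)),
                 layers = layers, lr = check_number(lr, "lr", 1e-8, 1),
                 dropout = dropout, epochs = as.integer(epochs),
                 target_accuracy = target_accuracy, seed = seed,
                 vocab = NULL, params = NULL, trained = FALSE),
            class = c("gru_autoencoder", "drug_encoder"))
}

## parameter initialisation for one GRU layer
init_gru_layer <- function(in_dim, H) {
  g <- function(r, c) matrix(stats::rnorm(r * c, sd = 1 / sqrt(c)), r, c)
  list(Wz = g(H, in_dim), Uz = g(H, H), bz = numeric(H),
       Wr = g(H, in_dim), Ur = g(H, H), br = numeric(H),
       Wh = g(H, in_dim), Uh = g(H, H), bh = numeric(H))
}

init_gru_params <- function(V, H, layers) {
  enc <- lapply(seq_len(layers), function(l) {
    init_gru_layer(if (l == 1L) V else H, H)
  })
  dec <- lapply(seq_len(layers), function(l) {
    init_gru_layer(if (l == 1L) V else H, H)
  })
  g <- function(r, c) matrix(stats::rnorm(r * c, sd = 1 / sqrt(c)), r, c)
  list(enc = enc, dec = dec, Wy = g(V, H), by = numeric(V))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

## forward through one GRU step; returns new hidden + cache for backprop
gru_step <- function(p, x, h_prev) {
  z <- sigmoid(p$Wz %*% x + p$Uz %*% h_prev + p$bz)
  r <- sigmoid(p$Wr %*% x + p$Ur %*% h_prev + p$br)
  rh <- r * h_prev
  hh <- tanh(p$Wh %*% x + p$Uh %*% rh + p$bh)
  h <- (1 - z) * h_prev + z * hh
  list(h = h, cache = list(x = x, h_prev = h_prev, z = z, r = r,
                           rh = rh, hh = hh))
}

## backward through one GRU step. dh: gradient wrt h. Returns dx, dh_prev and
## accumulates into grad (same shape as p).
gru_step_back <- function(p, cache, dh, grad) {
  z <- cache$z; r <- cache$r; hh <- cache$hh; h_prev <- cache$h_prev
  dhh <- dh * z
  dz <- dh * (hh - h_prev)
  dh_prev <- dh * (1 - z)
  da_h <- dhh * (1 - hh^2)
  drh <- crossprod(p$Uh, da_h)
  dr <- drh * h_prev
  dh_prev <- dh_prev + drh * r
  da_z <- dz * z * (1 - z)
  da_r <- dr * r * (1 - r)
  grad$Wh <- grad$Wh + tcrossprod(da_h, cache$x)
  grad$Uh <- grad$Uh + tcrossprod(da_h, cache$rh)
  grad$bh <- grad$bh + as.numeric(da_h)
  grad$Wz <- grad$Wz + tcrossprod(da_z, cache$x)
  grad$Uz <- grad$Uz + tcrossprod(da_z, h_prev)
  grad$bz <- grad$bz + as.numeric(da_z)
  grad$Wr <- grad$Wr + tcrossprod(da_r, cache$x)
  grad$Ur <- grad$Ur + tcrossprod(da_r, h_prev)
  grad$br <- grad$br + as.numeric(da_r)
  dh_prev <- dh_prev + crossprod(p$Uz, da_z) + crossprod(p$Ur, da_r)
  dx <- crossprod(p$Wz, da_z) + crossprod(p$Wr, da_r) +
    crossprod(p$Wh, da_h)
  list(dx = dx, dh_prev = dh_prev, grad = grad)
}

one_hot <- function(i, V) { v <- numeric(V); v[i] <- 1; v }

## run the stacked encoder; returns final hidden per layer and caches
run_encoder <- function(params, ids, V, H, layers, drop_masks = NULL) {
  Tn <- length(ids)
  h <- lapply(seq_len(layers), function(l) matrix(0, H, 1))
  caches <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    x <- matrix(one_hot(ids[t], V), ncol = 1)
    step_caches <- vector("list", layers)
    for (l in seq_len(layers)) {
      st <- gru_step(params$enc[[l]], x, h[[l]])
      h[[l]] <- st$h
      step_caches[[l]] <- st$cache
      x <- st$h
      if (!is.null(drop_masks) && l < layers) x <- x * drop_masks[[l]]
    }
    caches[[t]] <- step_caches
  }
  list(h = h, caches = caches)
}

## full teacher-forced forward+backward for one sequence; returns loss,
## token accuracy and gradients
seq_loss_grad <- function(params, ids, V, H, layers, dropout = 0,
                          compute_grad = TRUE) {
  drop_masks <- if (dropout > 0 && layers > 1L) {
    lapply(seq_len(layers - 1L), function(l) {
      matrix(stats::rbinom(H, 1, 1 - dropout) / (1 - dropout), H, 1)
    })
  } else NULL
  enc <- run_encoder(params, ids, V, H, layers, drop_masks)

  ## decoder inputs: <sos>, tok1..tokT ; targets: tok1..tokT, <eos>
  dec_in <- c(1L, ids)          # id 1 is <sos> by construction
  targets <- c(ids, 2L)         # id 2 is <eos>
  Td <- length(dec_in)
  h <- enc$h
  dcaches <- vector("list", Td)
  probs <- vector("list", Td)
  loss <- 0; correct <- 0
  for (t in seq_len(Td)) {
    x <- matrix(one_hot(dec_in[t], V), ncol = 1)
    step_caches <- vector("list", layers)
    for (l in seq_len(layers)) {
      st <- gru_step(params$dec[[l]], x, h[[l]])
      h[[l]] <- st$h
      step_caches[[l]] <- st$cache
      x <- st$h
      if (!is.null(drop_masks) && l < layers) x <- x * drop_masks[[l]]
    }
    dcaches[[t]] <- step_caches
    logits <- params$Wy %*% h[[layers]] + params$by
    logits <- logits - max(logits)
    p <- exp(logits); p <- p / sum(p)
    probs[[t]] <- p
    loss <- loss - log(max(p[targets[t]], 1e-300))
    if (which.max(p) == targets[t]) correct <- correct + 1
  }
  acc <- correct / Td
  if (!compute_grad) return(list(loss = loss, acc = acc))

  zero_like <- function(p) lapply(p, function(m) { m[] <- 0; m })
  grad <- list(enc = lapply(params$enc, zero_like),
               dec = lapply(params$dec, zero_like),
               Wy = params$Wy * 0, by = params$by * 0)

  dh_next <- lapply(seq_len(layers), function(l) matrix(0, H, 1))
  for (t in rev(seq_len(Td))) {
    dlogits <- probs[[t]]
    dlogits[targets[t]] <- dlogits[targets[t]] - 1
    h_top <- if (t == Td) {
      ## recompute top hidden from cache of this step
      cc <- dcaches[[t]][[layers]]
      (1 - cc$z) * cc$h_prev + cc$z * cc$hh
    } else dcaches[[t + 1L]][[layers]]$h_prev
    grad$Wy <- grad$Wy + tcrossprod(dlogits, h_top)
    grad$by <- grad$by + as.numeric(dlogits)
    dh_above <- crossprod(params$Wy, dlogits)
    for (l in rev(seq_len(layers))) {
      dh <- dh_next[[l]]
      if (l == layers) {
        dh <- dh + dh_above
      } else {
        if (!is.null(drop_masks)) dh_above <- dh_above * drop_masks[[l]]
        dh <- dh + dh_above
      }
      bk <- gru_step_back(params$dec[[l]], dcaches[[t]][[l]], dh,
                          grad$dec[[l]])
      grad$dec[[l]] <- bk$grad
      dh_next[[l]] <- bk$dh_prev
      dh_above <- bk$dx
    }
  }

  ## gradient flows into encoder final hiddens (= decoder initial hiddens)
  Tn <- length(ids)
  for (t in rev(seq_len(Tn))) {
    dh_above <- matrix(0, H, 1)
    for (l in rev(seq_len(layers))) {
      dh <- dh_next[[l]]
      if (l < layers && !is.null(drop_masks)) dh_above <- dh_above * drop_masks[[l]]
      dh <- dh + dh_above
      bk <- gru_step_back(params$enc[[l]], enc$caches[[t]][[l]], dh,
                          grad$enc[[l]])
      grad$enc[[l]] <- bk$grad
      dh_next[[l]] <- bk$dh_prev
      dh_above <- bk$dx
    }
  }
  list(loss = loss, acc = acc, grad = grad)
}

## flatten/unflatten parameter trees for Adam and gradient checking
flatten_params <- function(p) unlist(p, use.names = FALSE)
unflatten_params <- function(vec, template) {
  out <- template; i <- 0L
  assign_rec <- function(x) {
    if (is.list(x)) return(lapply(x, assign_rec))
    k <- length(x)
    v <- vec[(i + 1L):(i + k)]
    i <<- i + k
    if (is.matrix(x)) matrix(v, nrow(x), ncol(x)) else v
  }
  assign_rec(out)
}

#' @export
fit_corpus.gru_autoencoder <- function(encoder, smiles_list, verbose = FALSE,
                                       ...) {
  stopifnot(length(smiles_list) > 0L)
  token_lists <- lapply(smiles_list, smiles_tokenize)
  vocab <- c(SOS, EOS, UNK, sort(unique(unlist(token_lists))))
  V <- length(vocab); H <- encoder$dim; L <- encoder$layers
  seqs <- lapply(token_lists, function(tk) match(tk, vocab))

  with_seed(encoder$seed, {
    params <- init_gru_params(V, H, L)
    theta <- flatten_params(params)
    m <- numeric(length(theta)); v <- numeric(length(theta))
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8; step <- 0L
    for (ep in seq_len(encoder$epochs)) {
      ord <- sample.int(length(seqs))
      accs <- numeric(length(seqs))
      for (si in seq_along(ord)) {
        ids <- seqs[[ord[si]]]
        res <- seq_loss_grad(params, ids, V, H, L, encoder$dropout)
        accs[si] <- res$acc
        g <- flatten_params(res$grad)
        g <- pmin(pmax(g, -5), 5)
        step <- step + 1L
        m <- beta1 * m + (1 - beta1) * g
        v <- beta2 * v + (1 - beta2) * g^2
        mh <- m / (1 - beta1^step); vh <- v / (1 - beta2^step)
        theta <- flatten_params(params) - encoder$lr * mh / (sqrt(vh) + eps)
        params <- unflatten_params(theta, params)
      }
      if (verbose && ep %% 10L == 0L) {
        message(sprintf("epoch %d: mean token accuracy %.3f", ep, mean(accs)))
      }
      if (mean(accs) >= encoder$target_accuracy) break
    }
    encoder$vocab <- vocab
    encoder$params <- params
    encoder$trained <- TRUE
    encoder
  })
}

#' @export
encode.gru_autoencoder <- function(encoder, smiles, ...) {
  if (!isTRUE(encoder$trained)) stop2("GRU encoder not trained; run fit_corpus()")
  ids <- match(smiles_tokenize(smiles), encoder$vocab)
  ids[is.na(ids)] <- match(UNK, encoder$vocab)
  enc <- run_encoder(encoder$params, ids, length(encoder$vocab),
                     encoder$dim, encoder$layers)
  as.numeric(enc$h[[encoder$layers]])
}

#' Teacher-forced reconstruction accuracy of a trained autoencoder
#'
#' Fraction of tokens (including the end-of-sequence token) whose softmax
#' argmax matches the true token when the decoder is fed the true prefix.
#'
#' @param encoder a trained [gru_autoencoder()].
#' @param smiles_list character vector of SMILES.
#' @return mean per-sequence token accuracy in `[0, 1]`.
#' @export
reconstruction_accuracy <- function(encoder, smiles_list) {
  stopifnot(inherits(encoder, "gru_autoencoder"), isTRUE(encoder$trained))
  accs <- vapply(smiles_list, function(s) {
    ids <- match(smiles_tokenize(s), encoder$vocab)
    ids[is.na(ids)] <- match(UNK, encoder$vocab)
    seq_loss_grad(encoder$params, ids, length(encoder$vocab), encoder$dim,
                  encoder$layers, dropout = 0, compute_grad = FALSE)$acc
  }, numeric(1))
  mean(accs)
}
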
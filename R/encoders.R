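## Sequence encoders: ProtVec-style 3-gram skip-gram embeddings for proteins,
## a pluggable SMILES encoder contract for drugs (deterministic hashed n-gram
## default; trainable GRU autoencoder in gru.R), and embedding-derived cosine
## similarity matrices.

AA_ALPHABET <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X")

#' Split a sequence into three lists of shifted non-overlapping k-mers
#'
#' For shifts s = 0, 1, 2 the sequence is cut into consecutive
#' non-overlapping k-mers starting at position s + 1, truncating any trailing
#' fragment shorter than k. A corpus of N sequences therefore yields 3N
#' "sentences" of biological words for embedding training.
#'
#' @param seq character scalar (amino-acid sequence).
#' @param k word length (default 3).
#' @return List of three character vectors (shifts 0, 1, 2). If
#'   `nchar(seq) < k` all lists are empty, with a warning.
#' @export
build_shifted_corpus <- function(seq, k = 3L) {
  check_string(seq, "seq")
  k <- as.integer(check_number(k, "k", 1))
  L <- nchar(seq)
  if (L < k) {
    warning("sequence shorter than k = ", k, "; empty corpus")
    return(list(character(0), character(0), character(0)))
  }
  lapply(0:2, function(s) {
    starts <- seq.int(s + 1L, by = k, length.out = (L - s) %/% k)
    if (length(starts) == 0L) return(character(0))
    substring(seq, starts, starts + k - 1L)
  })
}

#' Train skip-gram k-mer embeddings
#'
#' A compact skip-gram with negative sampling (SGNS) trainer over token
#' "sentences" (e.g. the shifted 3-gram lists of [build_shifted_corpus()]).
#' For each centre token, context tokens within a dynamic window are drawn
#' as positive examples; `negative` noise tokens are sampled from the
#' unigram^(3/4) distribution. Single-threaded and fully deterministic
#' given `seed`.
#'
#' @param corpus list of character vectors (one token sentence each).
#' @param dim embedding dimension (default 100).
#' @param window maximum context window (default 5).
#' @param min_count minimum token frequency to enter the vocabulary
#'   (default 1).
#' @param epochs training passes over the corpus (default 10).
#' @param negative negative samples per positive pair (default 5).
#' @param lr initial learning rate, linearly decayed to `lr/10`.
#' @param seed RNG seed.
#' @return Object of class `kmer_vocabulary`: list with `k`, `tokens`,
#'   `vectors` (vocab x dim matrix, rownames = tokens), `dim`.
#' @export
train_kmer_embeddings <- function(corpus, dim = 100L, window = 5L,
                                  min_count = 1L, epochs = 10L,
                                  negative = 5L, lr = 0.025, seed = 1L) {
  if (!is.list(corpus) || length(corpus) == 0L ||
      all(lengths(corpus) == 0L)) {
    stop2("empty corpus")
  }
  toks <- unlist(corpus, use.names = FALSE)
  freq <- table(toks)
  vocab <- names(freq)[freq >= min_count]
  if (length(vocab) == 0L) stop2("no token reaches min_count = ", min_count)
  vocab <- sort(vocab)
  kk <- unique(nchar(vocab))
  V <- length(vocab)
  dim <- as.integer(dim)

  with_seed(seed, {
    W_in <- matrix(stats::runif(V * dim, -0.5, 0.5) / dim, V, dim)
    W_out <- matrix(0, V, dim)
    noise_p <- as.numeric(freq[vocab])^0.75
    noise_p <- noise_p / sum(noise_p)
    sentences <- lapply(corpus, function(s) {
      i <- match(s, vocab)
      i[!is.na(i)]
    })
    sentences <- sentences[lengths(sentences) > 0L]
    total_steps <- epochs * length(sentences)
    step <- 0L
    for (ep in seq_len(epochs)) {
      for (sent in sentences) {
        step <- step + 1L
        cur_lr <- lr * (1 - 0.9 * (step - 1) / max(1, total_steps - 1))
        ns <- length(sent)
        for (pos in seq_len(ns)) {
          b <- sample.int(window, 1L)
          ctx <- sent[max(1L, pos - b):min(ns, pos + b)]
          ctx <- ctx[seq_along(ctx) != (pos - max(1L, pos - b) + 1L)]
          if (length(ctx) == 0L) next
          centre <- sent[pos]
          v <- W_in[centre, ]
          grad_v <- numeric(dim)
          for (o in ctx) {
            negs <- sample.int(V, negative, replace = TRUE, prob = noise_p)
            outs <- c(o, negs)
            labels <- c(1, numeric(negative))
            U <- W_out[outs, , drop = FALSE]
            s <- 1 / (1 + exp(-(U %*% v)))
            g <- (labels - as.numeric(s)) * cur_lr
            grad_v <- grad_v + as.numeric(crossprod(U, g))
            W_out[outs, ] <- U + g %*% t(v)
          }
          W_in[centre, ] <- v + grad_v
        }
      }
    }
    rownames(W_in) <- vocab
    structure(list(k = if (length(kk) == 1L) kk else NA_integer_,
                   tokens = vocab, vectors = W_in, dim = dim),
              class = "kmer_vocabulary")
  })
}

#' Look up k-mer vectors
#'
#' @param vocab a `kmer_vocabulary`.
#' @param tokens character vector.
#' @return numeric matrix (tokens x dim); rows for unknown tokens are `NA`
#'   (missing is explicit, never a silent zero).
#' @export
lookup_kmer <- function(vocab, tokens) {
  stopifnot(inherits(vocab, "kmer_vocabulary"))
  idx <- match(tokens, vocab$tokens)
  out <- matrix(NA_real_, length(tokens), vocab$dim,
                dimnames = list(tokens, NULL))
  hit <- !is.na(idx)
  out[hit, ] <- vocab$vectors[idx[hit], , drop = FALSE]
  out
}

#' Embed a protein sequence by summed overlapping 3-grams
#'
#' The sequence representation is the sum of the embedding vectors of every
#' overlapping k-mer `seq[i..i+k-1]`, i = 1..L-k+1. Unknown k-mers contribute
#' zero and are reported through the `coverage` attribute (fraction of
#' windows found in the vocabulary).
#'
#' @param seq amino-acid string with `nchar(seq) >= k`.
#' @param vocab a `kmer_vocabulary` from [train_kmer_embeddings()] or
#'   [read_word_vectors()].
#' @param average if `TRUE` divide by the number of known windows instead of
#'   summing (default `FALSE`: plain summation).
#' @return numeric vector of length `vocab$dim` with attribute `coverage`.
#' @export
embed_protein <- function(seq, vocab, average = FALSE) {
  stopifnot(inherits(vocab, "kmer_vocabulary"))
  k <- if (is.na(vocab$k)) 3L else vocab$k
  L <- nchar(seq)
  if (L < k) stop2("sequence length ", L, " < k = ", k)
  starts <- seq_len(L - k + 1L)
  grams <- substring(seq, starts, starts + k - 1L)
  vecs <- lookup_kmer(vocab, grams)
  known <- !is.na(vecs[, 1L])
  out <- if (any(known)) colSums(vecs[known, , drop = FALSE]) else
    numeric(vocab$dim)
  if (average && sum(known) > 0L) out <- out / sum(known)
  attr(out, "coverage") <- mean(known)
  out
}

#' Build an embedding matrix for a set of sequences
#'
#' @param records data frame with columns `id` and `sequence` (see
#'   [load_fasta()]).
#' @param vocab a `kmer_vocabulary`.
#' @inheritParams embed_protein
#' @return Object of class `embedding_matrix`: list with `entity_ids`,
#'   `vectors` (ids x dim), `dim`.
#' @export
embed_proteins <- function(records, vocab, average = FALSE) {
  vecs <- t(vapply(records$sequence,
                   function(s) as.numeric(embed_protein(s, vocab, average)),
                   numeric(vocab$dim)))
  embedding_matrix(records$id, vecs)
}

#' Construct an embedding matrix
#' @param entity_ids character IDs (unique).
#' @param vectors numeric matrix, one row per ID, finite entries.
#' @export
embedding_matrix <- function(entity_ids, vectors) {
  entity_ids <- as.character(entity_ids)
  if (anyDuplicated(entity_ids)) stop2("duplicate entity IDs")
  vectors <- as.matrix(vectors)
  if (nrow(vectors) != length(entity_ids)) stop2("one row per entity required")
  if (any(!is.finite(vectors))) stop2("non-finite embedding entry")
  rownames(vectors) <- entity_ids
  structure(list(entity_ids = entity_ids, vectors = vectors,
                 dim = ncol(vectors)),
            class = "embedding_matrix")
}

## ---- SMILES tokenisation and the default drug encoder -----------------------

#' Tokenise a SMILES string
#'
#' Character-level with two-character element tokens (`Cl`, `Br`) and bracket
#' atoms (`[...]`) kept atomic, plus multi-digit ring-closure tokens
#' (`%nn`).
#'
#' @param smiles SMILES string.
#' @return character vector of tokens.
#' @export
smiles_tokenize <- function(smiles) {
  check_string(smiles, "smiles")
  pattern <- "\\[[^]]*\\]|Br|Cl|%[0-9]{2}|."
  regmatches(smiles, gregexpr(pattern, smiles))[[1]]
}

#' Deterministic hashed n-gram drug encoder
#'
#' The default SMILES encoder: counts of hashed token n-grams (n = 1..3) of
#' the tokenised SMILES, projected to `dim` via a seeded random +-1
#' projection. Fully deterministic, needs no training, and gives distinct
#' molecules distinct fingerprints with high probability. It implements the
#' drug-encoder contract (`fit_corpus`, `encode`) so a trained sequence
#' autoencoder ([gru_autoencoder()]) can be slotted in without changing
#' downstream code.
#'
#' @param dim fingerprint length (default 128).
#' @param n_buckets hash-bucket count before projection.
#' @param seed seed for the projection matrix.
#' @return Object of class `c("hash_drug_encoder", "drug_encoder")`.
#' @export
hash_drug_encoder <- function(dim = 128L, n_buckets = 4096L, seed = 1L) {
  dim <- as.integer(check_number(dim, "dim", 1))
  n_buckets <- as.integer(check_number(n_buckets, "n_buckets", dim))
  proj <- with_seed(seed, matrix(sample(c(-1, 1), n_buckets * dim,
                                        replace = TRUE) / sqrt(dim),
                                 n_buckets, dim))
  structure(list(dim = dim, n_buckets = n_buckets, proj = proj, seed = seed),
            class = c("hash_drug_encoder", "drug_encoder"))
}

## stable 32-bit FNV-1a string hash; arithmetic split to stay exact in doubles
hash_string <- function(s, mod) {
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  (h %% mod) + 1
}

#' @export
encode.hash_drug_encoder <- function(encoder, smiles, ...) {
  toks <- smiles_tokenize(smiles)
  counts <- numeric(encoder$n_buckets)
  for (n in 1:3) {
    if (length(toks) < n) break
    for (i in seq_len(length(toks) - n + 1L)) {
      key <- paste(toks[i:(i + n - 1L)], collapse = "\x1f")
      j <- hash_string(key, encoder$n_buckets)
      counts[j] <- counts[j] + 1
    }
  }
  as.numeric(counts %*% encoder$proj)
}

#' @export
fit_corpus.hash_drug_encoder <- function(encoder, smiles_list, ...) encoder

#' Drug encoder contract
#'
#' `fit_corpus()` (optionally) trains an encoder on a SMILES corpus;
#' `encode()` maps one SMILES string to a fixed-length numeric fingerprint
#' of length `encoder$dim`.
#'
#' @param encoder a `drug_encoder` object.
#' @param smiles_list character vector of SMILES for training.
#' @param smiles single SMILES string.
#' @param ... method-specific arguments.
#' @return `fit_corpus()`: a (possibly trained) encoder; `encode()`: a
#'   numeric vector of length `encoder$dim`.
#' @export
fit_corpus <- function(encoder, smiles_list, ...) UseMethod("fit_corpus")

#' @rdname fit_corpus
#' @export
encode <- function(encoder, smiles, ...) UseMethod("encode")

#' Embed a drug SMILES with a given encoder
#'
#' @param smiles nonempty SMILES string.
#' @param encoder a `drug_encoder` (default [hash_drug_encoder()]).
#' @return numeric fingerprint of length `encoder$dim`.
#' @export
embed_drug <- function(smiles, encoder = hash_drug_encoder()) {
  check_string(smiles, "smiles")
  v <- encode(encoder, smiles)
  stopifnot(length(v) == encoder$dim, all(is.finite(v)))
  v
}

#' Embed a table of drugs
#' @param smiles_table data frame with columns `id`, `smiles` (see
#'   [load_smiles_table()]).
#' @inheritParams embed_drug
#' @return an `embedding_matrix`.
#' @export
embed_drugs <- function(smiles_table, encoder = hash_drug_encoder()) {
  vecs <- t(vapply(smiles_table$smiles, function(s) embed_drug(s, encoder),
                   numeric(encoder$dim)))
  embedding_matrix(smiles_table$id, vecs)
}

#' Cosine-similarity matrix from embeddings
#'
#' Pairwise `cos(v_i, v_j) = (v_i . v_j) / (|v_i| |v_j|)`, then min-max
#' normalised to `[0, 1]` so the scores can serve directly as similarity
#' edge weights. Similarities involving an all-zero vector are defined as 0
#' (with a warning). Raw cosines are kept in attribute `raw`.
#'
#' @param emb an `embedding_matrix`.
#' @return a [similarity_matrix()] with attribute `raw` (pre-normalisation
#'   cosines).
#' @export
cosine_similarity_matrix <- function(emb) {
  stopifnot(inherits(emb, "embedding_matrix"))
  V <- emb$vectors
  nrm <- sqrt(rowSums(V^2))
  zero <- nrm == 0
  if (any(zero)) {
    warning(sum(zero), " all-zero embedding row(s); their similarities set to 0")
    nrm[zero] <- 1
  }
  Vn <- V / nrm
  raw <- tcrossprod(Vn)
  raw[zero, ] <- 0; raw[, zero] <- 0
  raw <- pmin(pmax(raw, -1), 1)
  raw <- (raw + t(raw)) / 2
  sm <- similarity_matrix(emb$entity_ids, minmax_normalize(raw))
  attr(sm, "raw") <- raw
  sm
}

## ---- embedding / vocabulary text I/O (word2vec text format) -----------------

#' Read word vectors in word2vec text format
#'
#' First line `"<vocab> <dim>"`, then one `token v1 ... vdim` line each —
#' the format published ProtVec-style models ship in.
#'
#' @param path file path.
#' @return a `kmer_vocabulary`.
#' @export
read_word_vectors <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
  if (length(hdr) != 2L || any(is.na(hdr))) stop2("bad word2vec header")
  body <- strsplit(trimws(lines[-1]), "\\s+")
  body <- body[lengths(body) == hdr[2] + 1L]
  if (length(body) != hdr[1]) {
    stop2("expected ", hdr[1], " vectors, found ", length(body))
  }
  tokens <- vapply(body, `[[`, character(1), 1L)
  vecs <- t(vapply(body, function(x) as.numeric(x[-1]), numeric(hdr[2])))
  rownames(vecs) <- tokens
  kk <- unique(nchar(tokens))
  structure(list(k = if (length(kk) == 1L) kk else NA_integer_,
                 tokens = tokens, vectors = vecs, dim = hdr[2]),
            class = "kmer_vocabulary")
}

#' Write word vectors in word2vec text format
#' @param vocab a `kmer_vocabulary`.
#' @param path output path.
#' @export
write_word_vectors <- function(vocab, path) {
  lines <- c(paste(length(vocab$tokens), vocab$dim),
             vapply(seq_along(vocab$tokens), function(i) {
               paste(c(vocab$tokens[i], sprintf("%.17g", vocab$vectors[i, ])),
                     collapse = " ")
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Read / write embedding matrices as delimited tables
#' @param emb an `embedding_matrix`.
#' @param path file path.
#' @param delim field delimiter.
#' @export
write_embedding_matrix <- function(emb, path, delim = "\t") {
  lines <- c(paste(c("id", paste0("v", seq_len(emb$dim))), collapse = delim),
             vapply(seq_along(emb$entity_ids), function(i) {
               paste(c(emb$entity_ids[i], sprintf("%.17g", emb$vectors[i, ])),
                     collapse = delim)
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_embedding_matrix
#' @export
read_embedding_matrix <- function(path) {
  delim <- detect_delim(path)
  df <- utils::read.table(path, sep = delim, header = TRUE,
                          check.names = FALSE)
  embedding_matrix(as.character(df[[1]]),
                   as.matrix(df[, -1, drop = FALSE]))
}
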
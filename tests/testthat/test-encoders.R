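test_that("shifted non-overlapping corpus construction matches direct slicing", {
  expect_equal(build_shifted_corpus("MAFSA"),
               list("MAF", "AFS", "FSA"))
  expect_equal(build_shifted_corpus("ABCDEF"),
               list(c("ABC", "DEF"), "BCD", "CDE"))
  expect_warning(out <- build_shifted_corpus("AB"), "shorter")
  expect_equal(lengths(out), c(0L, 0L, 0L))

  # concatenating list s reproduces seq[s+1 : s + 3*floor((L-s)/3)]
  set.seed(8)
  for (rep in 1:20) {
    L <- sample(3:40, 1)
    s <- paste(sample(LETTERS[1:20], L, replace = TRUE), collapse = "")
    lists <- build_shifted_corpus(s)
    for (sh in 0:2) {
      take <- 3L * ((L - sh) %/% 3L)
      expect_identical(paste(lists[[sh + 1]], collapse = ""),
                       substr(s, sh + 1L, sh + take))
    }
  }
  # a corpus of N sequences yields 3N token lists
  seqs <- replicate(25, paste(sample(LETTERS[1:20], 12, replace = TRUE),
                              collapse = ""))
  corpus <- unlist(lapply(seqs, build_shifted_corpus), recursive = FALSE)
  expect_length(corpus, 75L)
})

test_that("skip-gram training is deterministic with an explicit vocabulary", {
  corp <- unlist(lapply(c("MAFSAMAFSA", "AFSAMAFSAM", "FSAMAFSAMA"),
                        build_shifted_corpus), recursive = FALSE)
  v1 <- train_kmer_embeddings(corp, dim = 12, epochs = 4, seed = 9)
  v2 <- train_kmer_embeddings(corp, dim = 12, epochs = 4, seed = 9)
  expect_identical(v1$vectors, v2$vectors)
  expect_equal(v1$dim, 12L)
  expect_true(all(nchar(v1$tokens) == 3L))
  # unknown tokens come back as explicit NA rows, not silent zeros
  lk <- lookup_kmer(v1, c(v1$tokens[1], "QQQ"))
  expect_false(anyNA(lk[1, ]))
  expect_true(all(is.na(lk[2, ])))
  expect_error(train_kmer_embeddings(list()), "empty")
})

test_that("protein embedding is the sum over overlapping 3-gram windows", {
  corp <- unlist(lapply(c("MAFSAMAFSA", "AAAAAAA", "AFSAMAFSAM"),
                        build_shifted_corpus), recursive = FALSE)
  vocab <- train_kmer_embeddings(corp, dim = 8, epochs = 3, seed = 2)
  # length-4 sequence = two windows
  e <- embed_protein("MAFS", vocab)
  expect_equal(as.numeric(e),
               as.numeric(lookup_kmer(vocab, "MAF") +
                            lookup_kmer(vocab, "AFS")))
  # repeated pattern: (L-2) copies of one vector
  e2 <- embed_protein("AAAAAA", vocab)
  expect_equal(as.numeric(e2),
               4 * as.numeric(lookup_kmer(vocab, "AAA")))
  # all-unknown sequence: zero vector, coverage 0
  e3 <- embed_protein("WWWWW", vocab)
  expect_equal(as.numeric(e3), numeric(8))
  expect_equal(attr(e3, "coverage"), 0)
  expect_error(embed_protein("AB", vocab), "length")
  # averaging flag divides by the known-window count
  e4 <- embed_protein("MAFS", vocab, average = TRUE)
  expect_equal(as.numeric(e4), as.numeric(e) / 2)
  # anagrams with different 3-gram multisets embed differently
  expect_false(isTRUE(all.equal(as.numeric(embed_protein("MAFSA", vocab)),
                                as.numeric(embed_protein("MASFA", vocab)))))
})

test_that("SMILES tokenisation keeps multi-character tokens atomic", {
  expect_equal(smiles_tokenize("CCl"), c("C", "Cl"))
  expect_equal(smiles_tokenize("BrC[nH]1"), c("Br", "C", "[nH]", "1"))
  expect_equal(smiles_tokenize("C%12O"), c("C", "%12", "O"))
})

test_that("the hashed n-gram drug encoder is deterministic with fixed dim", {
  enc <- hash_drug_encoder(dim = 64, seed = 4)
  v1 <- embed_drug("CC(=O)Oc1ccccc1C(=O)O", enc)
  v2 <- embed_drug("CC(=O)Oc1ccccc1C(=O)O", enc)
  expect_identical(v1, v2)
  expect_length(v1, 64L)
  expect_true(all(is.finite(v1)))
  expect_false(identical(v1, embed_drug("CCO", enc)))
  expect_error(embed_drug("", enc), "smiles")
})

test_that("cosine similarity matches a direct dot-product computation", {
  set.seed(6)
  V <- matrix(rnorm(15), 3)
  emb <- embedding_matrix(c("a", "b", "c"), V)
  sm <- cosine_similarity_matrix(emb)
  raw <- attr(sm, "raw")
  for (i in 1:3) for (j in 1:3) {
    expect_equal(raw[i, j],
                 sum(V[i, ] * V[j, ]) /
                   (sqrt(sum(V[i, ]^2)) * sqrt(sum(V[j, ]^2))),
                 tolerance = 1e-12)
  }
  expect_equal(diag(raw), rep(1, 3), ignore_attr = TRUE)
  expect_true(all(sm$values >= 0 & sm$values <= 1))
  # scale invariance of the raw cosines
  emb2 <- embedding_matrix(c("a", "b", "c"), V * c(3, 1, 1))
  expect_equal(attr(cosine_similarity_matrix(emb2), "raw"), raw)
  # orthogonal vectors give raw cosine 0
  emb3 <- embedding_matrix(c("x", "y"), rbind(c(1, 0), c(0, 2)))
  expect_equal(attr(cosine_similarity_matrix(emb3), "raw")[1, 2], 0)
  # all-zero row warns and gets zero similarities
  emb4 <- embedding_matrix(c("x", "y"), rbind(c(1, 1), c(0, 0)))
  expect_warning(sm4 <- cosine_similarity_matrix(emb4), "all-zero")
  expect_equal(attr(sm4, "raw")[2, ], c(0, 0), ignore_attr = TRUE)
})

test_that("vocabulary and embedding text formats round-trip", {
  corp <- build_shifted_corpus("MAFSAMAFSA")
  vocab <- train_kmer_embeddings(corp, dim = 5, epochs = 2, seed = 1)
  tmp <- withr::local_tempfile(fileext = ".vec")
  write_word_vectors(vocab, tmp)
  back <- read_word_vectors(tmp)
  expect_equal(back$tokens, vocab$tokens)
  expect_identical(back$vectors, vocab$vectors)

  emb <- embedding_matrix(c("a", "b"), matrix(rnorm(6), 2))
  tmp2 <- withr::local_tempfile(fileext = ".tsv")
  write_embedding_matrix(emb, tmp2)
  back2 <- read_embedding_matrix(tmp2)
  expect_identical(back2$vectors, emb$vectors, ignore_attr = TRUE)
  expect_equal(back2$entity_ids, emb$entity_ids)
})
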
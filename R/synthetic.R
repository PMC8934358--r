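## Seeded latent-factor synthetic data with guilt-by-association structure:
## similar drugs (in latent space) bind similar targets, so network-based
## inference has real signal to recover. Sequences/SMILES are random strings
## that exercise tokenisation and encoding, not chemistry.

#' Synthetic dataset specification
#'
#' Defaults emulate a Davis-scale dense study: 60 drugs x 50 kinase-like
#' targets, 5 latent factors, full density, pKd-style affinities on
#' `[5, 11]` with measurement noise of sd 0.6 (10% of the value range).
#'
#' @param n_drugs,m_targets entity counts.
#' @param latent_dim latent factor dimension.
#' @param density fraction of pairs observed, in (0, 1] (1 = dense
#'   Davis-style; 0.244 mimics KIBA-style sparsity).
#' @param noise_sd Gaussian measurement noise sd on the affinity scale.
#' @param orientation affinity orientation (default pKd-style,
#'   higher = stronger).
#' @param affinity_range length-2 numeric `(lo, hi)`.
#' @param seed RNG seed.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_drugs = 60L, m_targets = 50L, latent_dim = 5L,
                           density = 1, noise_sd = 0.6,
                           orientation = "higher_is_stronger",
                           affinity_range = c(5, 11), seed = 1L) {
  stopifnot(length(affinity_range) == 2L,
            affinity_range[1] < affinity_range[2])
  structure(list(
    n_drugs = as.integer(check_number(n_drugs, "n_drugs", 2)),
    m_targets = as.integer(check_number(m_targets, "m_targets", 2)),
    latent_dim = as.integer(check_number(latent_dim, "latent_dim", 1)),
    density = check_number(density, "density", 1e-9, 1),
    noise_sd = check_number(noise_sd, "noise_sd", 0),
    orientation = match.arg(orientation, c("higher_is_stronger",
                                           "lower_is_stronger")),
    affinity_range = as.numeric(affinity_range),
    seed = as.integer(seed)), class = "synthetic_spec")
}

random_sequences <- function(n, alphabet, len_range) {
  vapply(seq_len(n), function(i) {
    L <- sample(len_range[1]:len_range[2], 1L)
    paste(sample(alphabet, L, replace = TRUE), collapse = "")
  }, character(1))
}

#' Generate a synthetic affinity study
#'
#' Drug latents `u_i` and target latents `w_j` are i.i.d. standard normal in
#' `latent_dim`; the noise-free affinity is an affine map of the inner
#' product `u_i . w_j` onto `affinity_range`, and observed affinities add
#' `N(0, noise_sd^2)` noise. A uniformly random subset of
#' `round(density * n * m)` pairs is observed. Similarity matrices are the
#' min-max-normalised cosine similarities of the latents, so that the
#' guilt-by-association premise holds by construction. Random protein-like
#' sequences and SMILES-like strings are attached for encoder smoke tests.
#'
#' @param spec a [synthetic_spec()].
#' @return list: `dataset` ([affinity_dataset()]), `drug_sim`, `target_sim`
#'   ([similarity_matrix()]s), `drug_latents`, `target_latents`,
#'   `noise_free` (matrix), `sequences` (data frame id/sequence),
#'   `smiles` (data frame id/smiles), `spec`.
#' @export
generate_synthetic <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_drugs; m <- spec$m_targets
  n_obs <- round(spec$density * n * m)
  if (n_obs < 1) stop2("density * n * m < 1: nothing to observe")
  with_seed(spec$seed, {
    U <- matrix(stats::rnorm(n * spec$latent_dim), n)
    W <- matrix(stats::rnorm(m * spec$latent_dim), m)
    ip <- tcrossprod(U, W)
    lo <- spec$affinity_range[1]; hi <- spec$affinity_range[2]
    noise_free <- lo + (hi - lo) * (ip - min(ip)) / (max(ip) - min(ip))
    vals <- noise_free + matrix(stats::rnorm(n * m, sd = spec$noise_sd), n)
    observed <- matrix(FALSE, n, m)
    observed[sample.int(n * m, n_obs)] <- TRUE
    drug_ids <- sprintf("D%03d", seq_len(n))
    target_ids <- sprintf("T%03d", seq_len(m))
    vals_masked <- vals
    vals_masked[!observed] <- NA_real_
    dataset <- affinity_dataset(drug_ids, target_ids, vals_masked, observed,
                                orientation = spec$orientation,
                                unit_label = "synthetic pKd-like")
    rownames(U) <- drug_ids; rownames(W) <- target_ids
    drug_sim <- cosine_similarity_matrix(embedding_matrix(drug_ids, U))
    target_sim <- cosine_similarity_matrix(embedding_matrix(target_ids, W))
    aa <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])
    smiles_alpha <- c("C", "c", "N", "O", "S", "F", "Cl", "Br", "=", "#",
                      "(", ")", "1", "2", "3", "[nH]", "n", "o")
    sequences <- data.frame(
      id = target_ids,
      sequence = random_sequences(m, aa, c(120L, 300L)),
      stringsAsFactors = FALSE)
    smiles <- data.frame(
      id = drug_ids,
      smiles = vapply(seq_len(n), function(i) {
        L <- sample(15:40, 1L)
        paste(sample(smiles_alpha, L, replace = TRUE), collapse = "")
      }, character(1)),
      stringsAsFactors = FALSE)
    list(dataset = dataset, drug_sim = drug_sim, target_sim = target_sim,
         drug_latents = U, target_latents = W, noise_free = noise_free,
         sequences = sequences, smiles = smiles, spec = spec)
  })
}

#' Write the synthetic study as standard input files
#'
#' Emits the affinity matrix, both similarity matrices, a FASTA of the
#' protein-like sequences, the SMILES table, and a ground-truth noise-free
#' affinity matrix, under `dir`.
#'
#' @param sim output of [generate_synthetic()].
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of file paths.
#' @export
write_synthetic <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(affinity = file.path(dir, "affinities.tsv"),
             drug_sim = file.path(dir, "drug_similarity.tsv"),
             target_sim = file.path(dir, "target_similarity.tsv"),
             fasta = file.path(dir, "targets.fasta"),
             smiles = file.path(dir, "drugs_smiles.tsv"),
             truth = file.path(dir, "ground_truth.tsv"))
  write_affinity_table(sim$dataset, paths["affinity"])
  write_similarity_matrix(sim$drug_sim, paths["drug_sim"])
  write_similarity_matrix(sim$target_sim, paths["target_sim"])
  writeLines(paste0(">", sim$sequences$id, "\n", sim$sequences$sequence),
             paths["fasta"])
  utils::write.table(sim$smiles, paths["smiles"], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  truth <- sim$dataset
  truth$affinities[] <- sim$noise_free
  truth$observed[] <- TRUE
  write_affinity_table(truth, paths["truth"])
  invisible(paths)
}
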
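## Readers and writers for every external representation the pipeline touches,
## plus the central dataset container. All internal indexing is positional
## against the ordered ID vectors; IDs are opaque strings.

#' Construct an affinity dataset
#'
#' The central container: an `n x m` matrix of continuous binding affinities
#' between `n` drugs and `m` protein targets, together with an observed-value
#' mask (missing labels are never imputed downstream) and an orientation flag
#' stating whether larger values mean stronger binding (pKd-style) or weaker
#' binding (raw Kd / distance-style).
#'
#' @param drug_ids character vector of unique drug identifiers (rows).
#' @param target_ids character vector of unique target identifiers (columns).
#' @param affinities numeric `n x m` matrix; entries at unobserved cells are
#'   ignored (stored as `NA`).
#' @param observed logical `n x m` mask, `TRUE` where the affinity is a real
#'   measurement. Defaults to `!is.na(affinities)`.
#' @param orientation `"higher_is_stronger"` (e.g. pKd, KIBA-transformed) or
#'   `"lower_is_stronger"` (e.g. raw Kd in nM).
#' @param unit_label free-text label for the affinity scale, e.g. `"pKd"`.
#' @return An object of class `affinity_dataset`.
#' @export
affinity_dataset <- function(drug_ids, target_ids, affinities,
                             observed = NULL,
                             orientation = c("higher_is_stronger",
                                             "lower_is_stronger"),
                             unit_label = "affinity") {
  orientation <- match.arg(orientation)
  drug_ids <- as.character(drug_ids)
  target_ids <- as.character(target_ids)
  if (anyDuplicated(drug_ids)) {
    stop2("duplicate drug IDs: ",
          paste(unique(drug_ids[duplicated(drug_ids)]), collapse = ", "))
  }
  if (anyDuplicated(target_ids)) {
    stop2("duplicate target IDs: ",
          paste(unique(target_ids[duplicated(target_ids)]), collapse = ", "))
  }
  affinities <- as.matrix(affinities)
  storage.mode(affinities) <- "double"
  if (nrow(affinities) != length(drug_ids) ||
      ncol(affinities) != length(target_ids)) {
    stop2("affinity matrix is ", nrow(affinities), "x", ncol(affinities),
          " but there are ", length(drug_ids), " drugs and ",
          length(target_ids), " targets")
  }
  if (is.null(observed)) observed <- !is.na(affinities)
  observed <- matrix(as.logical(observed), nrow(affinities), ncol(affinities))
  if (any(is.na(observed))) stop2("observed mask contains NA")
  if (any(!is.finite(affinities[observed]))) {
    stop2("non-finite affinity at an observed cell")
  }
  affinities[!observed] <- NA_real_
  dimnames(affinities) <- list(drug_ids, target_ids)
  structure(
    list(drug_ids = drug_ids, target_ids = target_ids,
         affinities = affinities, observed = observed,
         orientation = orientation, unit_label = unit_label),
    class = "affinity_dataset")
}

#' @export
print.affinity_dataset <- function(x, ...) {
  cat("Affinity dataset: ", length(x$drug_ids), " drugs x ",
      length(x$target_ids), " targets (", x$unit_label, ", ",
      x$orientation, ")\n", sep = "")
  n_obs <- sum(x$observed)
  cat(sprintf("  %d observed affinities (%.1f%% density)\n", n_obs,
              100 * n_obs / length(x$observed)))
  if (n_obs > 0) {
    r <- range(x$affinities[x$observed])
    cat(sprintf("  value range [%.4g, %.4g]\n", r[1], r[2]))
  }
  invisible(x)
}

#' Observed drug-target pairs of a dataset
#'
#' @param dataset an [affinity_dataset()].
#' @return Integer matrix with columns `drug`, `target` (1-based positional
#'   indices), one row per observed pair, in column-major matrix order.
#' @export
observed_pairs <- function(dataset) {
  idx <- which(dataset$observed, arr.ind = TRUE)
  colnames(idx) <- c("drug", "target")
  idx
}

## choose between tab and comma by inspecting the header line
detect_delim <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0L) stop2("empty file: ", path)
  if (grepl("\t", first)) "\t" else ","
}

#' Load a labelled affinity matrix from a delimited file
#'
#' Expects a rectangular table with drug IDs as row labels and target IDs as
#' column labels. The delimiter (tab or comma) is auto-detected from the
#' header. Cells equal to `missing_token` are masked as unobserved; such
#' labels are excluded from all downstream training and evaluation, never
#' imputed.
#'
#' @inheritParams affinity_dataset
#' @param path file path.
#' @param missing_token string marking an unobserved cell (default `"NaN"`).
#' @return An [affinity_dataset()]; a message reports the observed count.
#' @export
load_affinity_table <- function(path,
                                orientation = c("higher_is_stronger",
                                                "lower_is_stronger"),
                                missing_token = "NaN",
                                unit_label = "affinity") {
  orientation <- match.arg(orientation)
  delim <- detect_delim(path)
  df <- utils::read.table(path, sep = delim, header = TRUE, row.names = NULL,
                          colClasses = "character", check.names = FALSE,
                          quote = "\"", comment.char = "")
  if (nrow(df) == 0L || ncol(df) < 2L) stop2("affinity table is empty")
  drug_ids <- df[[1L]]
  target_ids <- colnames(df)[-1L]
  raw <- as.matrix(df[, -1L, drop = FALSE])
  observed <- !(raw == missing_token | is.na(raw))
  vals <- suppressWarnings(array(as.numeric(raw), dim = dim(raw)))
  bad <- which(observed & is.na(vals), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop2("non-numeric affinity at cell (", drug_ids[bad[1, 1]], ", ",
          target_ids[bad[1, 2]], "): '", raw[bad[1, , drop = FALSE]], "'")
  }
  vals[!observed] <- NA_real_
  ds <- affinity_dataset(drug_ids, target_ids, vals, observed,
                         orientation = orientation, unit_label = unit_label)
  message(sum(ds$observed), " observed affinities (",
          length(ds$observed) - sum(ds$observed), " masked)")
  ds
}

#' Write an affinity dataset as a delimited labelled matrix
#'
#' Values are written with full double precision so a write/read round trip
#' is bit-exact; masked cells are written as `missing_token`.
#'
#' @inheritParams load_affinity_table
#' @param dataset an [affinity_dataset()].
#' @param delim field delimiter.
#' @export
write_affinity_table <- function(dataset, path, missing_token = "NaN",
                                 delim = "\t") {
  vals <- dataset$affinities
  chr <- matrix(missing_token, nrow(vals), ncol(vals))
  chr[dataset$observed] <- sprintf("%.17g", vals[dataset$observed])
  lines <- c(paste(c("id", dataset$target_ids), collapse = delim),
             vapply(seq_len(nrow(chr)), function(i) {
               paste(c(dataset$drug_ids[i], chr[i, ]), collapse = delim)
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Load protein sequences from FASTA
#'
#' Multi-line records are concatenated; sequences are uppercased and
#' whitespace-stripped. Windows line endings are handled transparently.
#'
#' @param path FASTA file path.
#' @return Data frame with columns `id`, `sequence`, in file order.
#' @export
load_fasta <- function(path) {
  head_lines <- readLines(path, warn = FALSE)
  head_lines <- trimws(head_lines)
  nonempty <- head_lines[nzchar(head_lines)]
  if (length(nonempty) == 0L) stop2("empty FASTA file: ", path)
  if (!startsWith(nonempty[1L], ">")) {
    stop2("sequence data before first FASTA header in ", path)
  }
  set <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[[`, character(1), 1L)
  seqs <- toupper(gsub("\\s", "", as.character(set)))
  if (any(!nzchar(seqs))) stop2("empty sequence for record ",
                                ids[which(!nzchar(seqs))[1L]])
  data.frame(id = ids, sequence = unname(seqs), stringsAsFactors = FALSE)
}

#' Load a two-column ID to SMILES table
#'
#' SMILES are kept verbatim (no canonicalisation at load time); quoting is
#' honoured so delimiters inside quoted SMILES survive.
#'
#' @param path delimited file with columns ID, SMILES (header required).
#' @return Data frame with columns `id`, `smiles`, in input order.
#' @export
load_smiles_table <- function(path) {
  delim <- detect_delim(path)
  df <- utils::read.table(path, sep = delim, header = TRUE,
                          colClasses = "character", check.names = FALSE,
                          quote = "\"", comment.char = "")
  if (ncol(df) < 2L) stop2("SMILES table needs two columns (id, smiles), got ",
                           ncol(df))
  out <- data.frame(id = df[[1L]], smiles = df[[2L]], stringsAsFactors = FALSE)
  if (anyDuplicated(out$id)) {
    stop2("duplicate drug IDs in SMILES table: ",
          paste(unique(out$id[duplicated(out$id)]), collapse = ", "))
  }
  out
}

#' Construct / validate a labelled similarity matrix
#'
#' @param entity_ids character vector of unique IDs.
#' @param values square numeric matrix of pairwise similarity scores.
#' @param tol absolute symmetry tolerance.
#' @return Object of class `similarity_matrix` (list with `entity_ids`,
#'   `values`).
#' @export
similarity_matrix <- function(entity_ids, values, tol = 1e-9) {
  entity_ids <- as.character(entity_ids)
  if (anyDuplicated(entity_ids)) stop2("duplicate entity IDs")
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) != ncol(values)) {
    stop2("similarity matrix must be square, got ",
          nrow(values), "x", ncol(values))
  }
  if (nrow(values) != length(entity_ids)) {
    stop2("similarity matrix size does not match number of IDs")
  }
  if (any(!is.finite(values))) stop2("non-finite similarity value")
  asym <- max(abs(values - t(values)))
  if (asym > tol) {
    stop2("similarity matrix asymmetric (max |S - t(S)| = ",
          format(asym), " > ", format(tol), ")")
  }
  values <- (values + t(values)) / 2
  dimnames(values) <- list(entity_ids, entity_ids)
  structure(list(entity_ids = entity_ids, values = values),
            class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat("Similarity matrix: ", length(x$entity_ids), " entities, range [",
      sprintf("%.4g", min(x$values)), ", ",
      sprintf("%.4g", max(x$values)), "]\n", sep = "")
  invisible(x)
}

#' Load a square labelled similarity matrix
#'
#' @inheritParams similarity_matrix
#' @param path delimited file: header of entity IDs, one labelled row each.
#' @export
load_similarity_matrix <- function(path, tol = 1e-9) {
  delim <- detect_delim(path)
  df <- utils::read.table(path, sep = delim, header = TRUE, check.names = FALSE,
                          quote = "\"", comment.char = "")
  ids <- as.character(df[[1L]])
  vals <- as.matrix(df[, -1L, drop = FALSE])
  if (!all(colnames(vals) == ids)) {
    if (nrow(vals) != ncol(vals)) {
      stop2("similarity matrix must be square, got ",
            nrow(vals), "x", ncol(vals))
    }
  }
  similarity_matrix(ids, vals, tol = tol)
}

#' Write a similarity matrix
#' @inheritParams load_similarity_matrix
#' @param sim a [similarity_matrix()].
#' @param delim field delimiter.
#' @export
write_similarity_matrix <- function(sim, path, delim = "\t") {
  lines <- c(paste(c("id", sim$entity_ids), collapse = delim),
             vapply(seq_along(sim$entity_ids), function(i) {
               paste(c(sim$entity_ids[i], sprintf("%.17g", sim$values[i, ])),
                     collapse = delim)
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Write a per-pair feature table
#'
#' Pairs are written as a `"drugID|targetID"` key column followed by the
#' feature columns.
#'
#' @param features numeric matrix with column names.
#' @param pair_ids character vector `"drug|target"`, one per row.
#' @param path output path.
#' @param delim field delimiter.
#' @export
write_feature_table <- function(features, pair_ids, path, delim = "\t") {
  stopifnot(length(pair_ids) == nrow(features))
  df <- data.frame(pair = pair_ids, features, check.names = FALSE)
  utils::write.table(df, path, sep = delim, row.names = FALSE, quote = FALSE)
  invisible(path)
}
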
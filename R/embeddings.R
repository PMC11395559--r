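new_embedding_matrix <- function(E, k, source, missing_kmers = character()) {
  structure(E, k = k, source = source, missing_kmers = missing_kmers,
            class = c("embedding_matrix", "matrix", "array"))
}

#' @exportS3Method base::print
print.embedding_matrix <- function(x, ...) {
  cat(sprintf("<embedding_matrix> %d x %d (k = %d, source = %s)\n",
              nrow(x), ncol(x), attr(x, "k"), attr(x, "source")))
  invisible(x)
}

#' Extract the token embedding matrix of a model for analysis
#'
#' Pulls the model's token embedding table (the analogue of a BERT
#' `word_embeddings` layer), ordered by vocabulary id, and drops the five
#' special-token rows: embedding analyses operate on the `4^k` k-mer tokens
#' only.
#'
#' @param model A contract-satisfying model.
#' @param vocab The model's vocabulary (defaults to `model$vocab`).
#' @return An `embedding_matrix` with `4^k` rows named by k-mer.
#' @export
extract_model_embeddings <- function(model, vocab = NULL) {
  vocab <- vocab %||% model$vocab
  stopifnot(inherits(vocab, "kmer_vocab"))
  E <- token_embeddings(model)
  if (nrow(E) != vocab$size) {
    abort(sprintf(
      "Model embedding has %d rows but the vocabulary has %d entries.",
      nrow(E), vocab$size), class = "dnalm_contract_error")
  }
  Ek <- E[seq_along(vocab$kmers), , drop = FALSE]
  rownames(Ek) <- vocab$kmers
  new_embedding_matrix(Ek, k = vocab$k, source = "model")
}

#' Maximum explainable variance (MEV)
#'
#' Fraction of total variance captured by the first principal component of
#' the embedding rows. PCA is computed on column-mean-centred rows with no
#' variance scaling, so the statistic reflects the raw covariance
#' structure. A high MEV indicates that a single linear direction — in
#' practice, token identity — dominates the representation; contextual
#' learning spreads variance across components and lowers MEV.
#'
#' @param E An `embedding_matrix` or plain numeric matrix (rows = tokens).
#' @return A `mev_result` with elements `mev`, `eigenvalues` (the full
#'   explained-variance spectrum) and `n_tokens`.
#' @export
compute_mev <- function(E) {
  if (!is.matrix(E)) abort("`E` must be a matrix.", class = "dnalm_parameter_error")
  if (nrow(E) < 2L || ncol(E) < 2L) {
    abort("MEV needs at least 2 rows and 2 columns.",
          class = "dnalm_parameter_error")
  }
  if (!all(is.finite(E))) abort("Non-finite embedding entries.",
                                class = "dnalm_data_error")
  pc <- stats::prcomp(unclass(E), center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  tot <- sum(ev)
  if (tot <= 0) {
    abort("Degenerate embedding: all rows identical.",
          class = "dnalm_degenerate_error")
  }
  structure(list(mev = ev[1] / tot, eigenvalues = ev, n_tokens = nrow(E)),
            class = "mev_result")
}

#' @exportS3Method base::print
print.mev_result <- function(x, ...) {
  cat(sprintf("<mev_result> MEV = %.4f over %d tokens (%d components)\n",
              x$mev, x$n_tokens, length(x$eigenvalues)))
  invisible(x)
}

#' Compare MEV of a contextual model embedding and a static baseline
#'
#' Runs [compute_mev()] on both matrices through the same analysis path.
#' When the static matrix misses k-mers (small corpora), both matrices are
#' restricted to the shared k-mers so the comparison is like-for-like.
#'
#' @param model_E,w2v_E `embedding_matrix` objects.
#' @return A tibble with `source`, `mev`, `n_tokens`.
#' @export
compare_mev <- function(model_E, w2v_E) {
  shared <- intersect(rownames(model_E), rownames(w2v_E))
  if (length(shared) < nrow(model_E)) {
    inform(sprintf("Restricting MEV comparison to %d shared k-mers.",
                   length(shared)))
  }
  m <- compute_mev(model_E[shared, , drop = FALSE])
  w <- compute_mev(w2v_E[shared, , drop = FALSE])
  tibble(source = c("model", "word2vec"),
         mev = c(m$mev, w$mev),
         n_tokens = c(m$n_tokens, w$n_tokens))
}

#' Purine/pyrimidine annotation of a k-mer's central n-mer
#'
#' Extracts the central `central_width` nucleotides of each k-mer and maps
#' them to the purine/pyrimidine alphabet (`A,G -> R`; `C,T -> Y`). Used to
#' annotate embedding projections: BERT-style k-mer embeddings cluster by
#' the central di-/tri-/tetramer and by its R/Y pattern.
#'
#' @param kmers Character vector of equal-length k-mers.
#' @param central_width Width of the central substring; `k - central_width`
#'   must be even so the centre is well defined.
#' @return A tibble `kmer`, `central`, `ry_pattern`.
#' @examples
#' ry_annotation("ACGT", 2)  # central "CG", pattern "YR"
#' @export
ry_annotation <- function(kmers, central_width) {
  k <- unique(nchar(kmers))
  if (length(k) != 1L) {
    abort("All k-mers must have the same length.", class = "dnalm_parameter_error")
  }
  central_width <- assert_scalar_int(central_width, "central_width",
                                     min = 1, max = k)
  if ((k - central_width) %% 2L != 0L) {
    abort(sprintf(
      "k - central_width must be even (got k = %d, central_width = %d).",
      k, central_width), class = "dnalm_parameter_error")
  }
  off <- (k - central_width) %/% 2L
  central <- substr(kmers, off + 1L, off + central_width)
  tibble(kmer = kmers, central = central,
         ry_pattern = chartr("AGCT", "RRYY", central))
}

#' Project token embeddings to 2-D with UMAP
#'
#' Non-linear dimensionality reduction of the embedding rows, annotated
#' with each k-mer's central n-mer and purine/pyrimidine pattern for
#' cluster interpretation. Deterministic under the given seed
#' (single-threaded optimisation).
#'
#' @param E An `embedding_matrix` with k-mer rownames.
#' @param n_neighbors,min_dist UMAP parameters.
#' @param seed RNG seed.
#' @param central_width Central n-mer width for annotation; defaults to
#'   `k - 2` (dimer for 4-mers, trimer for 5-mers, tetramer for 6-mers).
#' @return A `token_projection` tibble: `token`, `x`, `y`, `central`,
#'   `ry_pattern`.
#' @export
umap_project <- function(E, n_neighbors = 15L, min_dist = 0.1, seed = 42L,
                         central_width = NULL) {
  if (nrow(E) < n_neighbors + 1L) {
    abort(sprintf("UMAP needs more than n_neighbors = %d rows, got %d.",
                  n_neighbors, nrow(E)), class = "dnalm_parameter_error")
  }
  k <- attr(E, "k") %||% unique(nchar(rownames(E)))
  central_width <- central_width %||% max(1L, k - 2L)
  coords <- uwot::umap(unclass(E), n_neighbors = n_neighbors,
                       min_dist = min_dist, n_threads = 1,
                       n_sgd_threads = 0, seed = seed)
  ann <- ry_annotation(rownames(E), central_width)
  out <- tibble(token = rownames(E), x = coords[, 1], y = coords[, 2],
                central = ann$central, ry_pattern = ann$ry_pattern)
  class(out) <- c("token_projection", class(out))
  out
}

#' Write / read an embedding matrix as TSV
#'
#' Columns `token, v1..vD`; round-trips exactly at full precision.
#'
#' @param E An `embedding_matrix`.
#' @param path File path.
#' @param k,source Metadata restored on read.
#' @export
write_embedding_tsv <- function(E, path) {
  df <- data.frame(token = rownames(E), unclass(E), check.names = FALSE)
  names(df) <- c("token", paste0("v", seq_len(ncol(E))))
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_embedding_tsv
#' @export
read_embedding_tsv <- function(path, k = NULL, source = "model") {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  E <- as.matrix(df[, -1, drop = FALSE])
  rownames(E) <- df$token
  colnames(E) <- NULL
  new_embedding_matrix(E, k = k %||% unique(nchar(df$token)), source = source)
}
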
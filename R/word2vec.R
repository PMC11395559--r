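#' Train static Word2Vec (CBOW) k-mer embeddings
#'
#' Continuous bag-of-words baseline: tokenized sub-sequences form the
#' corpus, and for every position the mean of the input vectors of the
#' context tokens (a window of `window` tokens on each side) predicts the
#' centre token through a full softmax. This yields static, context-free
#' k-mer vectors against which contextual model embeddings are compared.
#' The published parameters are honoured (`min_count = 1`,
#' `vector_size = 768`, `window = 5`); optimisation details beyond those
#' are this implementation's own (vectorised minibatch Adam over
#' input-vector means, `epochs` passes over all positions).
#'
#' K-mers never observed in the corpus (possible on small corpora) are
#' reported via the `missing_kmers` attribute and excluded from the matrix
#' rather than zero-filled.
#'
#' @param subseqs Character vector of nucleotide strings (or tibble with
#'   `seq`).
#' @param vocab A [build_vocabulary()] vocabulary.
#' @param window Context window half-width in tokens.
#' @param dim Embedding dimension (`vector_size`).
#' @param min_count Minimum corpus count for a k-mer to receive a vector.
#' @param epochs Passes over the corpus positions.
#' @param learning_rate Adam learning rate.
#' @param batch_size Positions per minibatch.
#' @param seed RNG seed; training is deterministic under a fixed seed.
#' @return An `embedding_matrix`: observed-k-mer rows x `dim`, rownames the
#'   k-mer strings, with attributes `k`, `source = "word2vec"` and
#'   `missing_kmers`.
#' @export
train_word2vec_embeddings <- function(subseqs, vocab, window = 5L, dim = 768L,
                                      min_count = 1L, epochs = 3L,
                                      learning_rate = 0.025,
                                      batch_size = 256L, seed = 1L) {
  stopifnot(inherits(vocab, "kmer_vocab"))
  if (is.data.frame(subseqs)) subseqs <- subseqs$seq
  if (!length(subseqs)) abort("Empty corpus.", class = "dnalm_data_error")
  window <- assert_scalar_int(window, "window", min = 1)
  dim <- assert_scalar_int(dim, "dim", min = 1)
  sentences <- purrr::map(subseqs, function(s) tokenize(s, vocab)$ids)
  sentences <- sentences[lengths(sentences) >= window + 1L]
  if (!length(sentences)) {
    abort("No sub-sequence tokenizes to more than `window` tokens.",
          class = "dnalm_data_error")
  }
  counts <- tabulate(unlist(sentences), nbins = length(vocab$kmers))
  used <- which(counts >= min_count & counts > 0L)
  Vu <- length(used)
  remap <- integer(length(vocab$kmers))
  remap[used] <- seq_len(Vu)
  # (centre, context-slot) pairs; contexts padded with 0 = absent
  ctx_rows <- purrr::map(sentences, function(ids) {
    n <- length(ids)
    centre <- seq_len(n)
    slots <- purrr::map(c(-(window:1), 1:window), function(o) {
      j <- centre + o
      ifelse(j >= 1L & j <= n, remap[ids[pmax(pmin(j, n), 1L)]], 0L)
    })
    cbind(remap[ids], do.call(cbind, slots))
  })
  M <- do.call(rbind, ctx_rows)
  M <- M[M[, 1] > 0L & rowSums(M[, -1, drop = FALSE] > 0L) > 0L, , drop = FALSE]
  n_pos <- nrow(M)
  with_seed(seed, {
    Win <- matrix(runif(Vu * dim, -0.5, 0.5) / dim, Vu, dim)
    Wout <- matrix(0, Vu, dim)
    opt <- adam_init(list(Win = Win, Wout = Wout))
    n_ctx <- rowSums(M[, -1, drop = FALSE] > 0L)
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n_pos)
      for (st in seq(1L, n_pos, by = batch_size)) {
        take <- ord[st:min(st + batch_size - 1L, n_pos)]
        B <- length(take)
        ctx <- M[take, -1, drop = FALSE]
        centre <- M[take, 1]
        H <- matrix(0, B, dim)
        for (j in seq_len(ncol(ctx))) {
          nz <- ctx[, j] > 0L
          if (any(nz)) H[nz, ] <- H[nz, ] + Win[ctx[nz, j], , drop = FALSE]
        }
        H <- H / n_ctx[take]
        logits <- H %*% t(Wout)
        P <- softmax_rows(logits)
        dlogits <- P
        dlogits[cbind(seq_len(B), centre)] <-
          dlogits[cbind(seq_len(B), centre)] - 1
        dlogits <- dlogits / B
        gWout <- t(dlogits) %*% H
        dH <- (dlogits %*% Wout) / n_ctx[take]
        gWin <- matrix(0, Vu, dim)
        for (j in seq_len(ncol(ctx))) {
          nz <- ctx[, j] > 0L
          if (any(nz)) {
            agg <- rowsum(dH[nz, , drop = FALSE], group = ctx[nz, j])
            ridx <- as.integer(rownames(agg))
            gWin[ridx, ] <- gWin[ridx, ] + agg
          }
        }
        upd <- adam_step(list(Win = Win, Wout = Wout),
                         list(Win = gWin, Wout = gWout),
                         opt, learning_rate, 0.9, 0.999, 1e-8)
        Win <- upd$params$Win; Wout <- upd$params$Wout; opt <- upd$state
      }
    }
    E <- Win
    rownames(E) <- vocab$kmers[used]
    missing <- vocab$kmers[setdiff(seq_along(vocab$kmers), used)]
    if (length(missing)) {
      inform(sprintf("%d of %d k-mers never occurred in the corpus.",
                     length(missing), length(vocab$kmers)))
    }
    new_embedding_matrix(E, k = vocab$k, source = "word2vec",
                         missing_kmers = missing)
  })
}
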
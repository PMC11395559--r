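# Independent oracles used to check the implementation by brute force.

# Which nucleotide positions of a tokenized sequence are covered ONLY by
# masked tokens? Enumerates token->nucleotide coverage directly.
coverage_oracle <- function(n_tokens, k, masked_idx) {
  n_nt <- n_tokens + k - 1L
  fully_masked <- integer(0)
  covered_by_masked <- logical(n_nt)
  for (p in seq_len(n_nt)) {
    covering <- max(1L, p - k + 1L):min(n_tokens, p)
    if (all(covering %in% masked_idx)) fully_masked <- c(fully_masked, p)
    if (any(covering %in% masked_idx)) covered_by_masked[p] <- TRUE
  }
  span <- range(which(covered_by_masked))
  list(fully_masked = fully_masked,
       span_nt = span[2] - span[1] + 1L)
}

# Confusion-matrix metrics computed directly from the four counts.
metrics_oracle <- function(pred, truth, positive) {
  p <- pred == positive
  t <- truth == positive
  tp <- sum(p & t); fp <- sum(p & !t); tn <- sum(!p & !t); fn <- sum(!p & t)
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  den <- sqrt(as.numeric(tp + fp)) * sqrt(as.numeric(tp + fn)) *
    sqrt(as.numeric(tn + fp)) * sqrt(as.numeric(tn + fn))
  mcc <- if (den > 0) (as.numeric(tp) * tn - as.numeric(fp) * fn) / den else 0
  c(accuracy = (tp + tn) / length(t), precision = prec, recall = rec,
    f1 = f1, mcc = mcc)
}

# Leading explained-variance fraction via direct covariance eigendecomposition.
mev_oracle <- function(E) {
  ev <- eigen(stats::cov(E), symmetric = TRUE, only.values = TRUE)$values
  ev[1] / sum(ev)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# All k-mers consistent with the unmasked flanking tokens at a masked
# position: known nucleotides pinned, free nucleotides enumerated.
compatible_kmers_oracle <- function(seq, k, known_nt_idx, token_start) {
  chars <- strsplit(seq, "")[[1]]
  pos <- token_start:(token_start + k - 1L)
  free <- !(pos %in% known_nt_idx)
  if (!any(free)) return(paste(chars[pos], collapse = ""))
  grid <- do.call(expand.grid,
                  c(rep(list(c("A", "C", "G", "T")), sum(free)),
                    list(stringsAsFactors = FALSE)))
  apply(grid, 1, function(fill) {
    x <- chars[pos]
    x[free] <- fill
    paste(x, collapse = "")
  })
}
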
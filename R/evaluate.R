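#' Masked-token prediction accuracy by mask offset
#'
#' Scores each masked position of each sample (a prediction is correct iff
#' the argmax token id equals the ground truth; ties are broken toward the
#' lowest id and counted) and aggregates per mask offset relative to the
#' chosen token. Two overall aggregations are attached: `overall`
#' (pooled over all predictions, i.e. the count-weighted mean of the
#' per-offset accuracies) and `overall_by_sample` (mean of per-sample
#' accuracies).
#'
#' @param predictions List of per-sample probability matrices (rows =
#'   masked positions in pattern order), e.g. from [predict_masked_all()].
#' @param dataset The `masked_dataset` the predictions correspond to.
#' @return An `offset_accuracy` tibble: `offset`, `n`, `n_correct`,
#'   `accuracy`, with attributes `overall`, `overall_by_sample`, `n_ties`.
#' @export
masked_accuracy_by_offset <- function(predictions, dataset) {
  stopifnot(inherits(dataset, "masked_dataset"),
            length(predictions) == nrow(dataset))
  pattern <- attr(dataset, "pattern")
  k <- attr(dataset, "k")
  n_ties <- 0L
  correct <- purrr::map2(predictions, dataset$truth_ids, function(P, truth) {
    if (nrow(P) != length(truth)) {
      abort("Prediction matrix rows do not match the number of masked tokens.",
            class = "dnalm_contract_error")
    }
    pred <- apply(P, 1, function(p) {
      m <- which(p == max(p))
      if (length(m) > 1L) n_ties <<- n_ties + 1L
      m[1]
    })
    pred == truth
  })
  C <- do.call(rbind, correct)
  if (n_ties > 0) inform(sprintf("%d argmax tie(s) broken toward the lowest id.",
                                 n_ties))
  out <- tibble(offset = pattern$offsets,
                n = nrow(C),
                n_correct = colSums(C),
                accuracy = colMeans(C))
  attr(out, "overall") <- mean(C)
  attr(out, "overall_by_sample") <- mean(rowMeans(C))
  attr(out, "n_ties") <- n_ties
  attr(out, "k") <- k
  class(out) <- c("offset_accuracy", class(out))
  out
}

#' Rank/probability profile of a masked prediction
#'
#' For each masked position, sorts the vocabulary by predicted probability,
#' assigns 1-based ranks, flags the ground truth, and counts tokens above a
#' negligible-probability floor. A well-trained overlapping-k-mer model
#' concentrates its mass on the few tokens compatible with the unmasked
#' flanks (four at the central position), so the above-floor count is a
#' direct readout of that behaviour.
#'
#' @param P A `(masked positions) x (vocab size)` probability matrix.
#' @param sample The corresponding `masked_dataset` row (list with
#'   `masked_idx`, `truth_ids`).
#' @param vocab The vocabulary (names the tokens).
#' @param floor Probability floor (default 0.01).
#' @param top_n Keep only the `top_n` highest-probability tokens per
#'   position in the profile (`Inf` keeps all).
#' @return A `rank_profile` tibble: `position` (index among the masked
#'   positions), `rank`, `token`, `probability`, `is_truth`; attributes
#'   `n_above_floor` (per position), `truth_rank`, `is_top1`.
#' @export
rank_probability_profile <- function(P, sample, vocab, floor = 0.01,
                                     top_n = Inf) {
  sample <- if (is.data.frame(sample)) {
    list(masked_idx = sample$masked_idx[[1]], truth_ids = sample$truth_ids[[1]])
  } else sample
  if (nrow(P) != length(sample$masked_idx)) {
    abort("Matrix rows do not match the number of masked positions.",
          class = "dnalm_contract_error")
  }
  token_names <- c(vocab$kmers, names(vocab$special_ids))
  if (ncol(P) != length(token_names)) {
    abort("Matrix columns do not match the vocabulary size.",
          class = "dnalm_contract_error")
  }
  rows <- purrr::map(seq_len(nrow(P)), function(i) {
    ord <- order(P[i, ], decreasing = TRUE)
    keep <- seq_len(min(top_n, length(ord)))
    tibble(position = i,
           rank = keep,
           token = token_names[ord[keep]],
           probability = P[i, ord[keep]],
           is_truth = ord[keep] == sample$truth_ids[i])
  })
  out <- dplyr::bind_rows(rows)
  truth_rank <- purrr::map_int(seq_len(nrow(P)), function(i) {
    ord <- order(P[i, ], decreasing = TRUE)
    which(ord == sample$truth_ids[i])
  })
  attr(out, "n_above_floor") <- rowSums(P > floor)
  attr(out, "truth_rank") <- truth_rank
  attr(out, "is_top1") <- truth_rank == 1L
  attr(out, "floor") <- floor
  class(out) <- c("rank_profile", class(out))
  out
}

#' Accuracy of a next-k-mer classifier on the test split
#'
#' @param classifier A `next_kmer_classifier` (or any object whose
#'   `predict()` returns a class-probability matrix for contexts).
#' @param dataset A `next_kmer_dataset`.
#' @return Test-split accuracy (fraction of argmax classes equal to the
#'   true class; ties toward the lowest class id).
#' @export
next_kmer_accuracy <- function(classifier, dataset) {
  stopifnot(inherits(dataset, "next_kmer_dataset"))
  test <- dataset[dataset$split == "test", ]
  if (!nrow(test)) abort("Empty test split.", class = "dnalm_data_error")
  P <- predict(classifier, test$context)
  if (ncol(P) != 4L^attr(dataset, "k")) {
    abort("Classifier head size does not match the dataset's 4^k classes.",
          class = "dnalm_parameter_error")
  }
  pred <- max.col(P, ties.method = "first")
  mean(pred == test$label_id)
}

#' Random-guess baseline for next-k-mer prediction
#'
#' Accuracy of a uniform random pick among the `4^k` classes.
#'
#' @param k Label length.
#' @return `4^-k` exactly (0.0625 for k = 2, ~0.004 for k = 4).
#' @export
random_baseline <- function(k) {
  k <- assert_scalar_int(k, "k", min = 1)
  4^(-k)
}

#' Binary classification metrics including MCC
#'
#' Standard confusion-matrix metrics: accuracy, precision, recall, F1 and
#' the Matthews correlation coefficient
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`.
#' If any factor of the MCC denominator is zero the coefficient is defined
#' as 0 (logged); precision/recall with empty denominators are likewise 0.
#'
#' @param predicted,truth Equal-length binary label vectors (logical,
#'   factor, character or 0/1).
#' @param positive The positive-class label (defaults to the first factor
#'   level of `truth`, or `TRUE`/`1` for logical/numeric input).
#' @return A `metrics_report` tibble with one row: `accuracy`, `precision`,
#'   `recall`, `f1`, `mcc`, plus the confusion counts `tp`, `fp`, `tn`,
#'   `fn`.
#' @export
classification_metrics <- function(predicted, truth, positive = NULL) {
  if (length(predicted) != length(truth) || !length(truth)) {
    abort("`predicted` and `truth` must be non-empty and of equal length.",
          class = "dnalm_parameter_error")
  }
  lv <- unique(c(as.character(truth), as.character(predicted)))
  if (length(lv) > 2L) {
    abort("Labels are not binary.", class = "dnalm_parameter_error")
  }
  positive <- as.character(
    positive %||% if (is.factor(truth)) levels(truth)[1]
    else if (is.logical(truth)) TRUE
    else if (is.numeric(truth)) 1
    else lv[1])
  p <- as.character(predicted) == positive
  t <- as.character(truth) == positive
  tp <- sum(p & t); fp <- sum(p & !t); tn <- sum(!p & !t); fn <- sum(!p & t)
  precision <- if (tp + fp > 0) tp / (tp + fp) else {
    inform("No positive predictions; precision defined as 0."); 0 }
  recall <- if (tp + fn > 0) tp / (tp + fn) else {
    inform("No positive truths; recall defined as 0."); 0 }
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  denom <- as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (denom > 0) {
    (as.numeric(tp) * tn - as.numeric(fp) * fn) / sqrt(denom)
  } else {
    inform("Zero MCC denominator factor; MCC defined as 0.")
    0
  }
  out <- tibble(accuracy = (tp + tn) / length(t),
                precision = precision, recall = recall, f1 = f1, mcc = mcc,
                tp = tp, fp = fp, tn = tn, fn = fn)
  attr(out, "positive") <- positive
  class(out) <- c("metrics_report", class(out))
  out
}

#' Evaluate a Prom300 classifier
#'
#' Thresholds predicted probabilities at the classifier's decision
#' threshold (0.5) and computes [classification_metrics()] with `real` as
#' the positive class. For diagnostics the metrics at the F1-maximising
#' threshold are attached as attribute `best_f1` (clearly non-default).
#'
#' @param classifier A `prom300_classifier`.
#' @param dataset A `prom300_dataset`.
#' @return A `metrics_report` tibble.
#' @export
prom300_metrics <- function(classifier, dataset) {
  stopifnot(inherits(dataset, "prom300_dataset"))
  p <- predict(classifier, dataset, type = "prob")
  pred <- ifelse(p >= classifier$threshold, "real", "shuffled")
  out <- classification_metrics(pred, as.character(dataset$label),
                                positive = "real")
  cand <- sort(unique(p))
  f1s <- vapply(cand, function(th) {
    pr <- ifelse(p >= th, "real", "shuffled")
    classification_metrics(pr, as.character(dataset$label),
                           positive = "real")$f1
  }, numeric(1))
  attr(out, "best_f1") <- list(threshold = cand[which.max(f1s)],
                               f1 = max(f1s))
  out
}
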
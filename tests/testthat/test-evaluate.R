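make_masked_fixture <- function(n, len = 23, seed = 1) {
  v <- build_vocabulary(4)
  set.seed(seed)
  subs <- vapply(seq_len(n), function(i) random_dna(len), character(1))
  list(vocab = v, ds = build_masked_dataset(subs, v, seed = seed + 1))
}

oracle_predictions <- function(ds, V = 261L) {
  lapply(seq_len(nrow(ds)), function(i) {
    truth <- ds$truth_ids[[i]]
    P <- matrix(0, length(truth), V)
    P[cbind(seq_along(truth), truth)] <- 1
    P
  })
}

test_that("per-offset accuracy is exact for a perfect oracle and for a hand fixture", {
  fx <- make_masked_fixture(30)
  acc <- masked_accuracy_by_offset(oracle_predictions(fx$ds), fx$ds)
  expect_identical(acc$offset, -1:2)
  expect_true(all(acc$accuracy == 1))
  expect_equal(attr(acc, "overall"), 1)

  # hand-built 3-sample fixture: rig argmaxes so offsets differ
  fx3 <- make_masked_fixture(3, seed = 7)
  preds <- oracle_predictions(fx3$ds)
  # sample 1: miss at offset -1 (row 1); sample 2: miss rows 1,2; sample 3: all hit
  wrong <- function(P, rows) {
    for (r in rows) { P[r, ] <- 0; P[r, 1] <- 1 }
    P
  }
  preds[[1]] <- wrong(preds[[1]], 1)
  # guard: make sure class 1 is not accidentally the truth
  stopifnot(fx3$ds$truth_ids[[1]][1] != 1, all(fx3$ds$truth_ids[[2]][1:2] != 1))
  preds[[2]] <- wrong(preds[[2]], 1:2)
  acc3 <- masked_accuracy_by_offset(preds, fx3$ds)
  expect_equal(acc3$accuracy, c(1/3, 2/3, 1, 1))
  expect_equal(attr(acc3, "overall"), mean(c(1/3, 2/3, 1, 1)))
  expect_equal(attr(acc3, "overall_by_sample"), mean(c(3/4, 2/4, 1)))
})

test_that("overall accuracy equals the count-weighted mean of per-offset accuracies", {
  fx <- make_masked_fixture(40, seed = 3)
  stub <- uniform_stub_model(fx$vocab)
  acc <- suppressMessages(
    masked_accuracy_by_offset(predict_masked_all(stub, fx$ds), fx$ds))
  expect_equal(attr(acc, "overall"),
               sum(acc$n_correct) / sum(acc$n))
})

test_that("uniform stub accuracy sits at the ties-to-lowest-id chance level", {
  fx <- make_masked_fixture(500, seed = 5)
  stub <- uniform_stub_model(fx$vocab)
  acc <- suppressMessages(
    masked_accuracy_by_offset(predict_masked_all(stub, fx$ds), fx$ds))
  p <- 1 / 256
  sd3 <- 3 * sqrt(p * (1 - p) / 500)
  for (a in acc$accuracy) expect_lt(abs(a - p), sd3)
})

test_that("rank profiles sort probabilities, rank the truth, and count above-floor tokens", {
  fx <- make_masked_fixture(1, seed = 9)
  v <- fx$vocab
  stub <- uniform_stub_model(v)
  P <- predict_masked(stub, fx$ds[1, ])
  rp <- rank_probability_profile(P, fx$ds[1, ], v, floor = 0.001)
  expect_identical(attr(rp, "n_above_floor"), rep(261, 4))
  rp2 <- rank_probability_profile(P, fx$ds[1, ], v, floor = 0.01)
  expect_identical(attr(rp2, "n_above_floor"), rep(0, 4))

  # truth at rank 1
  Po <- oracle_predictions(fx$ds)[[1]]
  rpo <- rank_probability_profile(Po, fx$ds[1, ], v)
  expect_true(all(attr(rpo, "is_top1")))
  expect_identical(attr(rpo, "truth_rank"), rep(1L, 4))
  probs <- dplyr::filter(tibble::as_tibble(rpo), position == 1)$probability
  expect_identical(probs, sort(probs, decreasing = TRUE))

  expect_error(rank_probability_profile(Po[1:2, ], fx$ds[1, ], v),
               class = "dnalm_contract_error")
})

test_that("a prediction confined to flank-compatible tokens has four above-floor tokens", {
  v <- build_vocabulary(4)
  seq <- "ACGTAACGTTACGTAACGTTACG"
  ds <- build_masked_dataset(seq, v, seed = 12)
  pat <- attr(ds, "pattern")
  t <- ds$chosen_index[1]
  central_nt <- t + pat$central_nt_offset
  # central masked token: only the central nucleotide is unknown
  central_row <- which(pat$offsets == 0)
  known <- setdiff(seq_len(nchar(seq)), central_nt)
  compat <- compatible_kmers_oracle(seq, 4, known, token_start = t)
  expect_length(compat, 4)
  P <- matrix(0, 4, 261)
  P[central_row, v$kmer_ids[compat]] <- 0.25
  rp <- rank_probability_profile(P, ds[1, ], v, floor = 0.01)
  expect_equal(attr(rp, "n_above_floor")[central_row], 4)
})

test_that("next-k-mer accuracy scores the test split against 4^k classes", {
  # synthetic dataset object with known labels
  make_ds <- function(n, k, labels) {
    ds <- tibble::tibble(
      context = vapply(seq_len(n), function(i) random_dna(50), character(1)),
      label = strrep("A", k),
      label_id = labels,
      split = rep(c("train", "test"), c(0, n)))
    attr(ds, "k") <- k
    class(ds) <- c("next_kmer_dataset", class(ds))
    ds
  }
  registerS3method("predict", "oracle_clf",
                   function(object, contexts, ...) object$P,
                   envir = asNamespace("stats"))
  set.seed(31)
  labels <- sample.int(256, 400, replace = TRUE)
  ds <- make_ds(400, 4, labels)
  P <- matrix(0, 400, 256)
  P[cbind(1:400, labels)] <- 1
  oracle <- structure(list(P = P), class = "oracle_clf")
  expect_equal(next_kmer_accuracy(oracle, ds), 1.0)

  # majority-class classifier on a skewed fixture
  skew <- c(rep(7L, 300), sample.int(256, 100, replace = TRUE))
  ds_skew <- make_ds(400, 4, skew)
  Pm <- matrix(0, 400, 256); Pm[, 7] <- 1
  maj <- structure(list(P = Pm), class = "oracle_clf")
  expect_equal(next_kmer_accuracy(maj, ds_skew), mean(skew == 7L))

  # uniform random guesser converges to the 4^-k baseline
  for (n in c(1e3, 1e4, 1e5)) {
    lab <- sample.int(256, n, replace = TRUE)
    dsn <- make_ds(n, 4, lab)
    Pr <- matrix(stats::runif(n * 256), n, 256)
    rnd <- structure(list(P = Pr), class = "oracle_clf")
    a <- next_kmer_accuracy(rnd, dsn)
    sd3 <- 3 * sqrt((1 / 256) * (255 / 256) / n)
    expect_lt(abs(a - random_baseline(4)), sd3 + 1e-9)
  }
})

test_that("the random baseline is exactly 4^-k", {
  expect_identical(random_baseline(2), 1 / 16)
  expect_identical(random_baseline(4), 1 / 256)
  expect_identical(random_baseline(6), 1 / 4096)
  expect_equal(round(random_baseline(4), 3), 0.004)
})

test_that("classification metrics match a brute-force confusion-matrix oracle", {
  m <- classification_metrics(c("a", "a", "b", "b"), c("a", "a", "b", "b"),
                              positive = "a")
  expect_true(all(unlist(m[, c("accuracy", "precision", "recall", "f1", "mcc")]) == 1))

  # TP=40 TN=45 FP=5 FN=10
  truth <- c(rep("pos", 50), rep("neg", 50))
  pred <- c(rep("pos", 40), rep("neg", 10), rep("pos", 5), rep("neg", 45))
  m2 <- classification_metrics(pred, truth, positive = "pos")
  expect_equal(m2$tp, 40); expect_equal(m2$tn, 45)
  expect_equal(m2$fp, 5); expect_equal(m2$fn, 10)
  ora <- metrics_oracle(pred, truth, "pos")
  expect_equal(unlist(m2[, names(ora)]), ora, tolerance = 1e-12,
               ignore_attr = TRUE)

  # inverting the labels flips the MCC sign
  inv <- ifelse(truth == "pos", "neg", "pos")
  m3 <- classification_metrics(pred, inv, positive = "pos")
  expect_equal(m3$mcc, -m2$mcc, tolerance = 1e-12)

  # independence null: |mcc| small
  set.seed(17)
  a <- sample(c("x", "y"), 10000, replace = TRUE)
  b <- sample(c("x", "y"), 10000, replace = TRUE)
  expect_lt(abs(classification_metrics(a, b, positive = "x")$mcc), 0.05)

  # degenerate denominator
  m4 <- suppressMessages(classification_metrics(rep("a", 5),
                                                c("a", "a", "a", "b", "b"),
                                                positive = "a"))
  expect_identical(m4$mcc, 0)
  expect_error(classification_metrics("a", c("a", "b")),
               class = "dnalm_parameter_error")
  expect_error(classification_metrics(c("a", "b", "c"), c("a", "b", "c")),
               class = "dnalm_parameter_error")
})

test_that("metrics agree with the oracle across random label vectors", {
  set.seed(23)
  for (i in 1:30) {
    n <- sample(20:200, 1)
    truth <- sample(c("pos", "neg"), n, replace = TRUE)
    pred <- sample(c("pos", "neg"), n, replace = TRUE)
    m <- suppressMessages(classification_metrics(pred, truth, positive = "pos"))
    ora <- metrics_oracle(pred, truth, "pos")
    expect_equal(unlist(m[, names(ora)]), ora, tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})
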
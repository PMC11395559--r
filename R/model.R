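#' Reference model specification
#'
#' Architecture of the small trainable transformer encoder used as a
#' desk-scale probed model: a BERT-family stack (multi-head self-attention,
#' feed-forward blocks, layer normalisation) shrunk to sizes that train on
#' one CPU in minutes.
#'
#' @param k Token length the model is built for.
#' @param dim Embedding / hidden width.
#' @param n_layers Number of transformer blocks.
#' @param n_heads Attention heads (`dim` must be divisible).
#' @param ff_dim Feed-forward width (default `4 * dim`).
#' @param context_len Maximum input length in tokens.
#' @param seed Seed for weight initialisation.
#' @return A `ref_model_spec` list.
#' @export
reference_model_spec <- function(k = 4L, dim = 64L, n_layers = 2L,
                                 n_heads = 2L, ff_dim = NULL,
                                 context_len = 64L, seed = 1L) {
  k <- assert_scalar_int(k, "k", min = 1, max = 12)
  dim <- assert_scalar_int(dim, "dim", min = 2)
  n_heads <- assert_scalar_int(n_heads, "n_heads", min = 1)
  if (dim %% n_heads != 0) {
    abort("`dim` must be divisible by `n_heads`.", class = "dnalm_parameter_error")
  }
  structure(list(k = k, dim = dim,
                 n_layers = assert_scalar_int(n_layers, "n_layers", min = 1),
                 n_heads = n_heads,
                 ff_dim = ff_dim %||% 4L * dim,
                 context_len = assert_scalar_int(context_len, "context_len", min = 4),
                 seed = seed),
            class = "ref_model_spec")
}

#' Training configuration
#'
#' Optimisation settings for fine-tuning, defaulting to the published
#' protocol for probing a pretrained DNA language model: Adam with learning
#' rate `1e-6`, epsilon `1e-8` and beta `0.99` (applied as the
#' second-moment decay `beta2`, with `beta1` at the conventional 0.9 — both
#' are exposed), batch size 64, 150 iterations for next-k-mer, 10 epochs
#' for Prom300, and classifier dropout 0.5. When training the small
#' reference model from scratch, pass a larger learning rate (around 1e-3
#' to 1e-2); the defaults are calibrated for nudging an already-pretrained
#' network.
#'
#' @param learning_rate Adam learning rate.
#' @param adam_epsilon Adam epsilon.
#' @param adam_beta1,adam_beta2 Adam moment decays.
#' @param batch_size Minibatch size.
#' @param steps Optimisation steps (iteration-based training).
#' @param epochs Epochs (epoch-based training, Prom300).
#' @param classifier_dropout Dropout on the pooled representation.
#' @param max_input_tokens Cap on input length; `NULL` adapts to the data.
#' @return A `training_config` list.
#' @export
training_config <- function(learning_rate = 1e-6, adam_epsilon = 1e-8,
                            adam_beta1 = 0.9, adam_beta2 = 0.99,
                            batch_size = 64L, steps = 150L, epochs = 10L,
                            classifier_dropout = 0.5,
                            max_input_tokens = NULL) {
  stopifnot(learning_rate > 0, adam_epsilon > 0,
            adam_beta1 > 0, adam_beta1 < 1, adam_beta2 > 0, adam_beta2 < 1,
            classifier_dropout >= 0, classifier_dropout < 1)
  structure(list(learning_rate = learning_rate, adam_epsilon = adam_epsilon,
                 adam_beta1 = adam_beta1, adam_beta2 = adam_beta2,
                 batch_size = assert_scalar_int(batch_size, "batch_size", min = 1),
                 steps = assert_scalar_int(steps, "steps", min = 1),
                 epochs = assert_scalar_int(epochs, "epochs", min = 1),
                 classifier_dropout = classifier_dropout,
                 max_input_tokens = max_input_tokens),
            class = "training_config")
}

# ---- model contract -----------------------------------------------------

#' Predict probabilities of masked tokens
#'
#' Part of the masked-language-model contract: given one masked sample, the
#' model returns a probability distribution over the full vocabulary at
#' every masked position (rows sum to 1).
#'
#' @param model A model satisfying the contract ([train_reference_mlm()]
#'   result or [uniform_stub_model()]).
#' @param sample One row of a `masked_dataset` (a list with `ids` and
#'   `masked_idx`), or the tibble row itself.
#' @param ... Unused.
#' @return A `(number of masked positions) x (vocabulary size)` matrix.
#' @export
predict_masked <- function(model, sample, ...) UseMethod("predict_masked")

#' Token embedding matrix of a model
#'
#' Contract accessor: one row per vocabulary entry (k-mers first, then the
#' five special tokens), mirroring the `word_embeddings` layer of a
#' BERT-style model.
#'
#' @param model A contract-satisfying model.
#' @param ... Unused.
#' @return A `(4^k + 5) x dim` numeric matrix with token rownames.
#' @export
token_embeddings <- function(model, ...) UseMethod("token_embeddings")

# normalize a sample argument to list(ids=, masked_idx=)
as_masked_sample <- function(sample) {
  if (is.data.frame(sample)) {
    stopifnot(nrow(sample) == 1L)
    return(list(ids = sample$ids[[1]], masked_idx = sample$masked_idx[[1]]))
  }
  stopifnot(is.list(sample), !is.null(sample$ids), !is.null(sample$masked_idx))
  sample
}

#' Uniform stub model
#'
#' A contract-satisfying test double that assigns every token probability
#' `1 / vocab_size` at every masked position and exposes an identity token
#' embedding. Useful for exercising evaluation code at the known chance
#' level.
#'
#' @param vocab A [build_vocabulary()] vocabulary.
#' @return A `uniform_mlm` model object.
#' @export
uniform_stub_model <- function(vocab) {
  stopifnot(inherits(vocab, "kmer_vocab"))
  structure(list(vocab = vocab), class = c("uniform_mlm", "dnalm_model"))
}

#' @export
predict_masked.uniform_mlm <- function(model, sample, ...) {
  sample <- as_masked_sample(sample)
  V <- model$vocab$size
  matrix(1 / V, length(sample$masked_idx), V)
}

#' @export
token_embeddings.uniform_mlm <- function(model, ...) {
  V <- model$vocab$size
  E <- diag(V)
  rownames(E) <- c(model$vocab$kmers, names(model$vocab$special_ids))
  E
}

# ---- reference model ----------------------------------------------------

#' Train the reference masked language model
#'
#' Pretrains the small transformer encoder with the masked-token objective:
#' every training sample has one token chosen at random and the per-k mask
#' pattern applied around it, and the model is optimised with cross-entropy
#' on the masked token identities. Mask choices are redrawn every step from
#' the seeded stream, and losses are recorded per step, so fixed seeds give
#' reproducible loss trajectories.
#'
#' @param corpus Character vector of nucleotide sub-sequences (or a tibble
#'   with a `seq` column). Sub-sequences longer than the model context are
#'   truncated with a log message.
#' @param spec A [reference_model_spec()].
#' @param config A [training_config()]; `steps` controls training length.
#' @param seed Seed controlling batching and mask draws.
#' @return A `ref_mlm` model object satisfying the model contract, with the
#'   per-step `loss_log` attached.
#' @export
train_reference_mlm <- function(corpus, spec = reference_model_spec(),
                                config = training_config(learning_rate = 3e-3,
                                                         steps = 200L),
                                seed = 1L) {
  stopifnot(inherits(spec, "ref_model_spec"), inherits(config, "training_config"))
  if (is.data.frame(corpus)) corpus <- corpus$seq
  if (!length(corpus)) abort("Empty training corpus.", class = "dnalm_data_error")
  vocab <- build_vocabulary(spec$k)
  pattern <- make_mask_pattern(spec$k)
  maxlen <- spec$context_len
  tok_list <- purrr::map(corpus, function(s) tokenize(s, vocab)$ids)
  too_long <- sum(lengths(tok_list) > maxlen)
  if (too_long > 0) {
    inform(sprintf("Truncated %d sub-sequence(s) to the %d-token context.",
                   too_long, maxlen))
    tok_list <- purrr::map(tok_list, function(x) x[seq_len(min(length(x), maxlen))])
  }
  # keep only sequences the pattern fits in (one unmasked flank each side)
  need <- (max(pattern$offsets) - min(pattern$offsets) + 1L) + 2L
  fits <- lengths(tok_list) >= need
  if (!any(fits)) {
    abort("No corpus sequence is long enough for the mask pattern.",
          class = "dnalm_data_error")
  }
  if (any(!fits)) {
    inform(sprintf("Skipped %d sub-sequence(s) too short for the mask pattern.",
                   sum(!fits)))
  }
  tok_list <- tok_list[fits]
  V <- vocab$size
  params <- init_transformer_params(V, spec$dim, spec$n_layers, spec$n_heads,
                                    spec$ff_dim, maxlen, seed = spec$seed)
  state <- adam_init(params)
  mid <- mask_id(vocab)
  pad <- unname(vocab$special_ids[["PAD"]])
  lo <- min(pattern$offsets); hi <- max(pattern$offsets)
  loss_log <- numeric(config$steps)
  with_seed(seed, {
    for (step in seq_len(config$steps)) {
      take <- sample.int(length(tok_list), min(config$batch_size, length(tok_list)),
                         replace = length(tok_list) < config$batch_size)
      batch <- tok_list[take]
      masked <- purrr::map(batch, function(ids) {
        n <- length(ids)
        t <- sample.int(n - 1L - hi - (2L - lo) + 1L, 1L) + (2L - lo) - 1L
        midx <- t + pattern$offsets
        truth <- ids[midx]
        ids[midx] <- mid
        list(ids = ids, midx = midx, truth = truth)
      })
      pm <- pad_id_matrix(purrr::map(masked, "ids"), pad)
      B <- nrow(pm$ids); S <- ncol(pm$ids)
      mask_rows <- unlist(purrr::imap(masked, function(m, b) {
        (b - 1L) * S + m$midx
      }))
      targets <- unlist(purrr::map(masked, "truth"))
      fw <- transformer_forward(params, pm$ids, pm$lens,
                                spec$n_layers, spec$n_heads)
      ls <- mlm_loss_grad(params, fw$H, mask_rows, targets)
      loss_log[step] <- ls$loss
      grads <- transformer_backward(params, fw$caches, ls$dH,
                                    spec$n_layers, spec$n_heads)
      grads$mlm_W <- ls$g_mlm_W
      grads$mlm_b <- ls$g_mlm_b
      upd <- adam_step(params, grads, state, config$learning_rate,
                       config$adam_beta1, config$adam_beta2,
                       config$adam_epsilon)
      params <- upd$params; state <- upd$state
    }
  })
  structure(list(spec = spec, vocab = vocab, params = params,
                 pattern = pattern, loss_log = loss_log,
                 config = config),
            class = c("ref_mlm", "dnalm_model"))
}

#' @exportS3Method base::print
print.ref_mlm <- function(x, ...) {
  cat(sprintf(
    "<ref_mlm> k = %d, dim = %d, %d layer(s), %d head(s), context %d tokens\n",
    x$spec$k, x$spec$dim, x$spec$n_layers, x$spec$n_heads, x$spec$context_len))
  cat(sprintf("  trained %d step(s); final loss %.4f\n",
              length(x$loss_log), utils::tail(x$loss_log, 1)))
  invisible(x)
}

#' @export
predict_masked.ref_mlm <- function(model, sample, ...) {
  sample <- as_masked_sample(sample)
  n <- length(sample$ids)
  if (n > nrow(model$params$pos_emb)) {
    abort(sprintf("Sample has %d tokens but the model context is %d.",
                  n, nrow(model$params$pos_emb)),
          class = "dnalm_length_error")
  }
  ids <- matrix(sample$ids, nrow = 1)
  fw <- transformer_forward(model$params, ids, n,
                            model$spec$n_layers, model$spec$n_heads,
                            keep_cache = FALSE)
  mlm_probs(model$params, fw$H, sample$masked_idx)
}

#' @export
token_embeddings.ref_mlm <- function(model, ...) {
  E <- model$params$tok_emb
  rownames(E) <- c(model$vocab$kmers, names(model$vocab$special_ids))
  E
}

#' Predict masked-token probabilities for a whole dataset
#'
#' @param model A contract-satisfying model.
#' @param dataset A `masked_dataset`.
#' @return A list of per-sample probability matrices, aligned with rows of
#'   `dataset`.
#' @export
predict_masked_all <- function(model, dataset) {
  purrr::map2(dataset$ids, dataset$masked_idx, function(ids, midx) {
    predict_masked(model, list(ids = ids, masked_idx = midx))
  })
}

# ---- fine-tuning --------------------------------------------------------

# Shared encoder + classification-head training loop.
# xs: list of token-id vectors; y: integer class ids (1..C) or 0/1 for
# binary; C = 1 means a single sigmoid neuron.
train_classifier <- function(model, xs, y, C, config, seed,
                             freeze_encoder = FALSE, n_steps = NULL) {
  spec <- model$spec
  vocab <- model$vocab
  pad <- unname(vocab$special_ids[["PAD"]])
  params <- model$params
  maxlen_needed <- max(lengths(xs))
  if (maxlen_needed > nrow(params$pos_emb)) {
    inform(sprintf(
      "Extending max input length from %d to %d tokens to fit the data.",
      nrow(params$pos_emb), maxlen_needed))
    extra <- with_seed(spec$seed + 1L,
                       init_matrix(maxlen_needed - nrow(params$pos_emb),
                                   ncol(params$pos_emb)))
    params$pos_emb <- rbind(params$pos_emb, extra)
  }
  d <- spec$dim
  head <- with_seed(seed, list(Wc = init_matrix(d, C), bc = rep(0, C)))
  opt_params <- c(params[!names(params) %in% c("mlm_W", "mlm_b")], head)
  if (freeze_encoder) opt_params <- head
  state <- adam_init(opt_params)
  drop_p <- config$classifier_dropout
  n <- length(xs)
  loss_log <- numeric(0)
  with_seed(seed + 1L, {
    step_counter <- 0L
    run_batch <- function(take) {
      pm <- pad_id_matrix(xs[take], pad)
      B <- nrow(pm$ids); S <- ncol(pm$ids)
      fw <- transformer_forward(params, pm$ids, pm$lens,
                                spec$n_layers, spec$n_heads)
      pooled <- pool_mean(fw$H, B, S, pm$lens)
      if (drop_p > 0) {
        dm <- matrix((runif(B * d) >= drop_p) / (1 - drop_p), B, d)
        pooled_d <- pooled * dm
      } else {
        dm <- NULL
        pooled_d <- pooled
      }
      logits <- add_bias(pooled_d %*% head$Wc, head$bc)
      yb <- y[take]
      if (C == 1L) {
        p <- 1 / (1 + exp(-logits[, 1]))
        loss <- -mean(yb * log(pmax(p, 1e-12)) +
                        (1 - yb) * log(pmax(1 - p, 1e-12)))
        dlogits <- matrix((p - yb) / B, B, 1)
      } else {
        P <- softmax_rows(logits)
        loss <- -mean(log(pmax(P[cbind(seq_len(B), yb)], 1e-12)))
        dlogits <- P
        dlogits[cbind(seq_len(B), yb)] <- dlogits[cbind(seq_len(B), yb)] - 1
        dlogits <- dlogits / B
      }
      gWc <- t(pooled_d) %*% dlogits
      gbc <- colSums(dlogits)
      dpooled <- dlogits %*% t(head$Wc)
      if (!is.null(dm)) dpooled <- dpooled * dm
      grads <- list(Wc = gWc, bc = gbc)
      if (!freeze_encoder) {
        dH <- pool_mean_bwd(dpooled, B, S, pm$lens)
        genc <- transformer_backward(params, fw$caches, dH,
                                     spec$n_layers, spec$n_heads)
        genc$mlm_W <- NULL; genc$mlm_b <- NULL
        grads <- c(genc, grads)
      }
      opt_params <- c(if (!freeze_encoder)
        params[!names(params) %in% c("mlm_W", "mlm_b")], head)
      upd <- adam_step(opt_params, grads, state, config$learning_rate,
                       config$adam_beta1, config$adam_beta2,
                       config$adam_epsilon)
      state <<- upd$state
      if (!freeze_encoder) {
        for (nm in setdiff(names(upd$params), c("Wc", "bc"))) {
          params[[nm]] <<- upd$params[[nm]]
        }
      }
      head$Wc <<- upd$params$Wc
      head$bc <<- upd$params$bc
      loss
    }
    if (!is.null(n_steps)) {
      for (step in seq_len(n_steps)) {
        take <- sample.int(n, min(config$batch_size, n), replace = n < config$batch_size)
        loss_log[length(loss_log) + 1L] <- run_batch(take)
      }
    } else {
      for (ep in seq_len(config$epochs)) {
        ord <- sample.int(n)
        starts <- seq(1L, n, by = config$batch_size)
        for (st in starts) {
          take <- ord[st:min(st + config$batch_size - 1L, n)]
          loss_log[length(loss_log) + 1L] <- run_batch(take)
        }
      }
    }
  })
  list(params = params, head = head, loss_log = loss_log)
}

# encode + head probabilities for a list of id vectors (eval mode)
classifier_probs <- function(obj, xs) {
  pad <- unname(obj$vocab$special_ids[["PAD"]])
  spec <- obj$spec
  C <- ncol(obj$head$Wc)
  n <- length(xs)
  bs <- 64L
  out <- matrix(NA_real_, n, C)
  for (st in seq(1L, n, by = bs)) {
    take <- st:min(st + bs - 1L, n)
    pm <- pad_id_matrix(xs[take], pad)
    fw <- transformer_forward(obj$params, pm$ids, pm$lens,
                              spec$n_layers, spec$n_heads, keep_cache = FALSE)
    pooled <- pool_mean(fw$H, nrow(pm$ids), ncol(pm$ids), pm$lens)
    logits <- add_bias(pooled %*% obj$head$Wc, obj$head$bc)
    out[take, ] <- if (C == 1L) 1 / (1 + exp(-logits)) else softmax_rows(logits)
  }
  out
}

#' Fine-tune a model for next-k-mer prediction
#'
#' Adds a `4^k`-way classification head on the mean-pooled encoder output
#' and trains with cross-entropy on the training split, following the
#' iteration-based protocol (default 150 steps of batch 64).
#'
#' @param model A `ref_mlm` reference model.
#' @param dataset A [build_next_kmer_dataset()] result.
#' @param config A [training_config()]. For the from-scratch reference
#'   model use a learning rate around 1e-2.
#' @param freeze_encoder Train only the head (ablation).
#' @param seed RNG seed for head init, batching and dropout.
#' @return A `next_kmer_classifier` object.
#' @export
finetune_next_kmer <- function(model, dataset, config = training_config(),
                               freeze_encoder = FALSE, seed = 1L) {
  stopifnot(inherits(model, "ref_mlm"), inherits(dataset, "next_kmer_dataset"))
  k <- attr(dataset, "k")
  C <- 4L^k
  train <- dataset[dataset$split == "train", ]
  if (!nrow(train)) abort("Empty training split.", class = "dnalm_data_error")
  xs <- purrr::map(train$context, function(s) tokenize(s, model$vocab)$ids)
  fit <- train_classifier(model, xs, train$label_id, C, config, seed,
                          freeze_encoder = freeze_encoder,
                          n_steps = config$steps)
  structure(list(spec = model$spec, vocab = model$vocab, k_label = k,
                 params = fit$params, head = fit$head,
                 loss_log = fit$loss_log, config = config),
            class = "next_kmer_classifier")
}

#' @exportS3Method base::print
print.next_kmer_classifier <- function(x, ...) {
  cat(sprintf("<next_kmer_classifier> %d classes (k = %d), encoder k = %d\n",
              4L^x$k_label, x$k_label, x$spec$k))
  invisible(x)
}

#' Predict next-k-mer class probabilities
#'
#' @param object A `next_kmer_classifier`.
#' @param contexts Character vector of 50-nt contexts (or a
#'   `next_kmer_dataset`, in which case the test split is used).
#' @param ... Unused.
#' @return A matrix of class probabilities, one row per context.
#' @export
predict.next_kmer_classifier <- function(object, contexts, ...) {
  if (inherits(contexts, "next_kmer_dataset")) {
    contexts <- contexts$context[contexts$split == "test"]
  }
  xs <- purrr::map(contexts, function(s) tokenize(s, object$vocab)$ids)
  classifier_probs(object, xs)
}

#' Fine-tune a model for Prom300 promoter classification
#'
#' Adds a classification layer with one neuron (sigmoid output) on the
#' mean-pooled encoder and trains with cross-entropy for `config$epochs`
#' epochs. The positive class is `real`; the decision threshold is 0.5.
#' When promoters tokenize to more tokens than the model context, the
#' position table is extended to fit (and the extension logged) rather than
#' silently truncating the promoter.
#'
#' @param model A `ref_mlm` reference model.
#' @param dataset A [build_prom300_dataset()] result containing both labels.
#' @param config A [training_config()].
#' @param freeze_encoder Train only the head.
#' @param seed RNG seed.
#' @return A `prom300_classifier` object.
#' @export
finetune_prom300 <- function(model, dataset, config = training_config(),
                             freeze_encoder = FALSE, seed = 1L) {
  stopifnot(inherits(model, "ref_mlm"), inherits(dataset, "prom300_dataset"))
  if (length(unique(dataset$label)) < 2L) {
    abort("Prom300 dataset must contain both labels.", class = "dnalm_data_error")
  }
  xs <- purrr::map(dataset$seq, function(s) tokenize(s, model$vocab)$ids)
  y <- as.integer(dataset$label == "real")
  fit <- train_classifier(model, xs, y, 1L, config, seed,
                          freeze_encoder = freeze_encoder, n_steps = NULL)
  structure(list(spec = model$spec, vocab = model$vocab,
                 params = fit$params, head = fit$head,
                 loss_log = fit$loss_log, config = config,
                 threshold = 0.5),
            class = "prom300_classifier")
}

#' @exportS3Method base::print
print.prom300_classifier <- function(x, ...) {
  cat(sprintf("<prom300_classifier> one-neuron head, threshold %.2f\n",
              x$threshold))
  invisible(x)
}

#' Predict promoter probabilities
#'
#' @param object A `prom300_classifier`.
#' @param sequences Character vector of promoter-length sequences (or a
#'   `prom300_dataset`).
#' @param type `"prob"` for P(real) or `"label"` for thresholded labels.
#' @param ... Unused.
#' @export
predict.prom300_classifier <- function(object, sequences,
                                       type = c("prob", "label"), ...) {
  type <- match.arg(type)
  if (inherits(sequences, "prom300_dataset")) sequences <- sequences$seq
  xs <- purrr::map(sequences, function(s) tokenize(s, object$vocab)$ids)
  p <- classifier_probs(object, xs)[, 1]
  if (type == "prob") return(p)
  factor(ifelse(p >= object$threshold, "real", "shuffled"),
         levels = c("real", "shuffled"))
}

#' Save / load a reference model checkpoint
#'
#' A checkpoint is a directory holding `weights.rds` (the parameter list)
#' and `spec.json` (architecture, token length, and a hash of the
#' vocabulary so mismatched checkpoints are caught on load).
#'
#' @param model A `ref_mlm`.
#' @param dir Checkpoint directory (created if needed).
#' @return `dir` (invisibly); `load_reference_model()` returns the model.
#' @export
save_reference_model <- function(model, dir) {
  stopifnot(inherits(model, "ref_mlm"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  spec <- model$spec
  meta <- list(k = spec$k, dim = spec$dim, n_layers = spec$n_layers,
               n_heads = spec$n_heads, ff_dim = spec$ff_dim,
               context_len = spec$context_len, seed = spec$seed,
               vocab_hash = vocab_hash(model$vocab))
  jsonlite::write_json(meta, file.path(dir, "spec.json"), auto_unbox = TRUE)
  saveRDS(list(params = model$params, loss_log = model$loss_log,
               config = model$config),
          file.path(dir, "weights.rds"))
  invisible(dir)
}

#' @rdname save_reference_model
#' @export
load_reference_model <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "spec.json"),
                              simplifyVector = TRUE)
  spec <- reference_model_spec(k = meta$k, dim = meta$dim,
                               n_layers = meta$n_layers,
                               n_heads = meta$n_heads, ff_dim = meta$ff_dim,
                               context_len = meta$context_len,
                               seed = meta$seed)
  vocab <- build_vocabulary(meta$k)
  if (!identical(vocab_hash(vocab), meta$vocab_hash)) {
    abort("Checkpoint vocabulary hash does not match this toolkit's vocabulary.",
          class = "dnalm_contract_error")
  }
  w <- readRDS(file.path(dir, "weights.rds"))
  structure(list(spec = spec, vocab = vocab, params = w$params,
                 pattern = make_mask_pattern(meta$k), loss_log = w$loss_log,
                 config = w$config),
            class = c("ref_mlm", "dnalm_model"))
}

vocab_hash <- function(vocab) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(c(vocab$kmers, names(vocab$special_ids)), tmp)
  unname(tools::md5sum(tmp))
}
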
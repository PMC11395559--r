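# Shared fixtures. Expensive artifacts (trained models, fine-tunes) are
# memoized so each is computed once per test run regardless of which test
# file touches it first.

.fixtures <- new.env(parent = emptyenv())

fx <- function(name, expr) {
  if (is.null(.fixtures[[name]])) assign(name, force(expr), envir = .fixtures)
  .fixtures[[name]]
}

# Desk-scale study conditions for the behavioural controls: a small
# transformer (dim 32, 2 layers, 2 heads, 64-token context) pretrained for
# 200 steps at lr 5e-3 on 800 sub-sequences of up to 40 tokens.
desk_spec <- function() reference_model_spec(k = 4L, dim = 32L, n_layers = 2L,
                                             n_heads = 2L, context_len = 64L,
                                             seed = 1L)
desk_mlm_config <- function() training_config(learning_rate = 5e-3,
                                              steps = 200L, batch_size = 32L,
                                              classifier_dropout = 0)
desk_scheme <- function() subsequence_scheme(full_len = 40L, min_len = 20L)

periodic_genome <- function() {
  fx("gen_periodic", generate_genome(200000, "periodic", unit = "ACGTAGT"))
}

iid_genome <- function() {
  fx("gen_iid", generate_genome(200000, "iid", seed = 42))
}

pretrained_model <- function(which = c("periodic", "iid")) {
  which <- match.arg(which)
  fx(paste0("model_", which), {
    gen <- if (which == "periodic") periodic_genome() else iid_genome()
    subs <- sample_subsequences(gen, 4, desk_scheme(), n = 800, seed = 2)
    suppressMessages(
      train_reference_mlm(subs, desk_spec(), desk_mlm_config(), seed = 3))
  })
}

next_kmer_control <- function(which = c("periodic", "iid")) {
  which <- match.arg(which)
  fx(paste0("nk_", which), {
    gen <- if (which == "periodic") periodic_genome() else iid_genome()
    ds <- build_next_kmer_dataset(gen, 4, max_samples = 3000, seed = 11)
    clf <- suppressMessages(finetune_next_kmer(
      pretrained_model(which), ds,
      training_config(learning_rate = 5e-3, steps = 150L, batch_size = 64L,
                      classifier_dropout = 0.5),
      seed = 7))
    list(dataset = ds, classifier = clf,
         accuracy = next_kmer_accuracy(clf, ds))
  })
}

prom300_control <- function() {
  fx("prom300", {
    train_prom <- generate_promoters(100, seed = 21)
    train_ds <- build_prom300_dataset(train_prom, seed = 22)
    clf <- suppressMessages(finetune_prom300(
      pretrained_model("iid"), train_ds,
      training_config(learning_rate = 3e-3, epochs = 4L, batch_size = 16L,
                      classifier_dropout = 0.5),
      seed = 9))
    test_prom <- generate_promoters(50, seed = 31)
    test_ds <- build_prom300_dataset(test_prom, seed = 32)
    list(classifier = clf, train = train_ds, test = test_ds,
         metrics = suppressMessages(prom300_metrics(clf, test_ds)))
  })
}

# tiny model for cheap contract/determinism tests
tiny_spec <- function() reference_model_spec(k = 4L, dim = 8L, n_layers = 1L,
                                             n_heads = 2L, ff_dim = 16L,
                                             context_len = 16L, seed = 5L)

tiny_corpus <- function() {
  fx("tiny_corpus", {
    set.seed(11)
    vapply(1:40, function(i) random_dna(15), character(1))
  })
}

tiny_model <- function() {
  fx("tiny_model", suppressMessages(train_reference_mlm(
    tiny_corpus(), tiny_spec(),
    training_config(learning_rate = 1e-3, steps = 10L, batch_size = 8L,
                    classifier_dropout = 0),
    seed = 13)))
}
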
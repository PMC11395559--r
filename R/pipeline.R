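#' Validate a pipeline configuration
#'
#' Checks the nested configuration list against the expected schema and
#' value ranges, collecting every failing key before erroring.
#'
#' @param config Nested configuration list (see [run_pipeline()]).
#' @return The config, with defaults filled in, invisibly on success.
#' @export
validate_config <- function(config) {
  problems <- character()
  need <- function(cond, msg) if (!isTRUE(cond)) problems <<- c(problems, msg)
  defaults <- list(
    seed = 1L, k = 4L, out_dir = "dnalm_run",
    genome = list(mode = "markov", length = 200000L, order = 1L,
                  persistence = 0.85, unit = "ACGTAGT"),
    subsequences = list(n = 2000L, p_full = 0.5, full_len = 60L,
                        min_len = 20L),
    model = list(dim = 64L, n_layers = 2L, n_heads = 2L, context_len = 64L,
                 steps = 200L, learning_rate = 3e-3, batch_size = 32L),
    next_kmer = list(k = 4L, max_samples = 500000L, steps = 150L,
                     learning_rate = 1e-2, batch_size = 64L),
    prom300 = list(enabled = FALSE, n_promoters = 150L, epochs = 10L,
                   learning_rate = 1e-2, batch_size = 16L,
                   n_parts = 20L, n_shuffle = 15L),
    word2vec = list(enabled = FALSE, dim = 768L, window = 5L,
                    min_count = 1L, epochs = 2L),
    umap = list(enabled = FALSE, n_neighbors = 15L, min_dist = 0.1)
  )
  config <- utils::modifyList(defaults, config %||% list())
  bad <- setdiff(names(config), names(defaults))
  if (length(bad)) problems <- c(problems,
                                 paste0("unknown key(s): ", paste(bad, collapse = ", ")))
  need(config$k >= 1 && config$k <= 12, "k: must be in 1..12")
  need(config$genome$mode %in% c("iid", "markov", "periodic"),
       "genome.mode: must be iid/markov/periodic")
  need(config$genome$length >= 1000, "genome.length: must be >= 1000")
  need(config$next_kmer$k >= 2 && config$next_kmer$k <= 6,
       "next_kmer.k: must be in 2..6")
  need(config$subsequences$min_len <= config$subsequences$full_len,
       "subsequences: min_len must be <= full_len")
  need(config$model$dim %% config$model$n_heads == 0,
       "model: dim must be divisible by n_heads")
  if (length(problems)) {
    abort(paste0("Invalid configuration:\n  - ",
                 paste(problems, collapse = "\n  - ")),
          class = "dnalm_config_error")
  }
  invisible(config)
}

#' Run the probing pipeline end to end
#'
#' Orchestrates the standard workflow on a synthetic genome: generate the
#' genome, pretrain the reference masked language model, build and run the
#' masked-token evaluation, fine-tune and evaluate next-k-mer prediction
#' against the random baseline, optionally run the Prom300 control and the
#' embedding analyses (Word2Vec baseline, MEV, UMAP), and write every
#' artifact plus a run manifest (config snapshot, seeds, file hashes,
#' timing) under `config$out_dir`. Every stochastic stage draws its seed
#' from a seed tree rooted at `config$seed`, so re-running an identical
#' config reproduces all outputs.
#'
#' @param config Nested configuration list, or a path to a JSON/YAML file;
#'   see [validate_config()] for keys and defaults.
#' @return The run manifest, invisibly.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- read_config(config)
  config <- validate_config(config)
  t0 <- Sys.time()
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- derive_seeds(config$seed, 10L)
  outputs <- character()
  emit <- function(path) outputs <<- c(outputs, path)
  k <- config$k

  inform(sprintf("[synth] generating %s genome of %s nt",
                 config$genome$mode, log10_pretty(config$genome$length)))
  genome <- generate_genome(
    config$genome$length, config$genome$mode,
    transition = if (config$genome$mode == "markov")
      markov_transition(config$genome$order, config$genome$persistence),
    order = config$genome$order, unit = config$genome$unit,
    seed = seeds[1])
  emit(write_genome_fasta(genome, file.path(out_dir, "genome.fasta")))

  inform("[build] sampling sub-sequences and masked dataset")
  scheme <- subsequence_scheme(config$subsequences$p_full,
                               config$subsequences$full_len,
                               config$subsequences$min_len)
  subs <- sample_subsequences(genome, k, scheme, n = config$subsequences$n,
                              seed = seeds[2])
  vocab <- build_vocabulary(k)
  emit(write_vocabulary(vocab, file.path(out_dir, "vocab.txt")))
  freqs <- genome_kmer_frequencies(genome, k)
  emit(write_frequencies_tsv(freqs, file.path(out_dir, "kmer_frequencies.tsv")))

  inform("[train-ref] pretraining the reference masked language model")
  spec <- reference_model_spec(k = k, dim = config$model$dim,
                               n_layers = config$model$n_layers,
                               n_heads = config$model$n_heads,
                               context_len = config$model$context_len,
                               seed = seeds[3])
  mlm_cfg <- training_config(learning_rate = config$model$learning_rate,
                             steps = config$model$steps,
                             batch_size = config$model$batch_size,
                             classifier_dropout = 0)
  model <- train_reference_mlm(subs, spec, mlm_cfg, seed = seeds[4])

  inform("[eval] masked-token accuracy by offset")
  masked <- build_masked_dataset(subs$seq[seq_len(min(200L, nrow(subs)))],
                                 vocab, seed = seeds[5])
  acc <- masked_accuracy_by_offset(predict_masked_all(model, masked), masked)

  inform("[finetune] next-k-mer prediction")
  nk <- build_next_kmer_dataset(genome, config$next_kmer$k,
                                max_samples = config$next_kmer$max_samples,
                                seed = seeds[6])
  emit(write_next_kmer_tsv(nk, file.path(out_dir, "next_kmer.tsv")))
  nk_cfg <- training_config(learning_rate = config$next_kmer$learning_rate,
                            steps = config$next_kmer$steps,
                            batch_size = config$next_kmer$batch_size,
                            classifier_dropout = 0.5)
  clf <- finetune_next_kmer(model, nk, nk_cfg, seed = seeds[7])
  nk_acc <- next_kmer_accuracy(clf, nk)

  report <- list(
    k = k,
    masked_accuracy = list(
      by_offset = as.data.frame(tidy(acc)),
      overall = attr(acc, "overall"),
      overall_by_sample = attr(acc, "overall_by_sample")),
    next_kmer = list(k = config$next_kmer$k,
                     accuracy = nk_acc,
                     random_baseline = random_baseline(config$next_kmer$k),
                     n_test = sum(nk$split == "test")))

  if (isTRUE(config$prom300$enabled)) {
    inform("[finetune] Prom300 promoter classification")
    proms <- generate_promoters(config$prom300$n_promoters, seed = seeds[8])
    p300 <- build_prom300_dataset(proms, config$prom300$n_parts,
                                  config$prom300$n_shuffle, seed = seeds[8])
    emit(write_prom300_tsv(p300, file.path(out_dir, "prom300.tsv")))
    p_cfg <- training_config(learning_rate = config$prom300$learning_rate,
                             epochs = config$prom300$epochs,
                             batch_size = config$prom300$batch_size)
    pclf <- finetune_prom300(model, p300, p_cfg, seed = seeds[8])
    pm <- prom300_metrics(pclf, p300)
    report$prom300 <- as.list(as.data.frame(pm[, c("accuracy", "precision",
                                                   "recall", "f1", "mcc")]))
  }

  if (isTRUE(config$word2vec$enabled)) {
    inform("[embed] model embeddings, Word2Vec baseline and MEV")
    Em <- extract_model_embeddings(model)
    emit(write_embedding_tsv(Em, file.path(out_dir, "embedding_model.tsv")))
    Ew <- train_word2vec_embeddings(subs, vocab,
                                    window = config$word2vec$window,
                                    dim = config$word2vec$dim,
                                    min_count = config$word2vec$min_count,
                                    epochs = config$word2vec$epochs,
                                    seed = seeds[9])
    emit(write_embedding_tsv(Ew, file.path(out_dir, "embedding_w2v.tsv")))
    mev <- compare_mev(Em, Ew)
    report$mev <- as.list(setNames(mev$mev, mev$source))
    if (isTRUE(config$umap$enabled)) {
      proj <- umap_project(Em, config$umap$n_neighbors, config$umap$min_dist,
                           seed = seeds[10])
      pp <- file.path(out_dir, "projection_model.tsv")
      utils::write.table(as.data.frame(proj), pp, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      emit(pp)
    }
  }

  report_path <- file.path(out_dir, "report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA)
  emit(report_path)
  emit(write_report_markdown(report, file.path(out_dir, "report.md")))
  ckpt <- save_reference_model(model, file.path(out_dir, "checkpoint"))
  emit(file.path(ckpt, "spec.json"))
  emit(file.path(ckpt, "weights.rds"))

  manifest <- list(
    toolkit_version = as.character(utils::packageVersion("dnalmprobe")),
    created = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    config = config,
    seeds = seeds,
    outputs = tibble(path = outputs,
                     md5 = unname(tools::md5sum(outputs))),
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(
    c(manifest[c("toolkit_version", "created", "config", "seeds")],
      list(outputs = as.data.frame(manifest$outputs),
           elapsed_sec = manifest$elapsed_sec)),
    manifest_path, auto_unbox = TRUE, digits = NA)
  inform(sprintf("[done] %d output file(s) in %s (%.1f s)",
                 length(outputs), out_dir, manifest$elapsed_sec))
  invisible(manifest)
}

# Read a JSON or YAML config file.
read_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Config file not found: %s", path), class = "dnalm_io_error")
  }
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      abort("YAML configs require the yaml package.", class = "dnalm_io_error")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

#' Write a pipeline report as Markdown
#'
#' Human-readable companion to the JSON report written by [run_pipeline()].
#'
#' @param report Report list (as serialized to `report.json`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_markdown <- function(report, path) {
  lines <- c("# DNA language model probing report", "")
  if (!is.null(report$masked_accuracy)) {
    lines <- c(lines, "## Masked-token prediction", "",
               sprintf("- overall accuracy (pooled): %.4f",
                       report$masked_accuracy$overall),
               sprintf("- overall accuracy (per-sample mean): %.4f",
                       report$masked_accuracy$overall_by_sample),
               "", "| offset | accuracy |", "|---|---|",
               sprintf("| %d | %.4f |",
                       report$masked_accuracy$by_offset$offset,
                       report$masked_accuracy$by_offset$accuracy), "")
  }
  if (!is.null(report$next_kmer)) {
    lines <- c(lines, "## Next-k-mer prediction", "",
               sprintf("- k = %d (%d classes)", report$next_kmer$k,
                       4^report$next_kmer$k),
               sprintf("- test accuracy: %.4f over %d samples",
                       report$next_kmer$accuracy, report$next_kmer$n_test),
               sprintf("- random baseline: %.6f",
                       report$next_kmer$random_baseline), "")
  }
  if (!is.null(report$prom300)) {
    lines <- c(lines, "## Prom300", "",
               sprintf("- F1 %.3f, precision %.3f, recall %.3f, MCC %.3f",
                       report$prom300$f1, report$prom300$precision,
                       report$prom300$recall, report$prom300$mcc), "")
  }
  if (!is.null(report$mev)) {
    lines <- c(lines, "## Maximum explainable variance", "",
               sprintf("- model: %.4f", report$mev$model),
               sprintf("- word2vec: %.4f", report$mev$word2vec), "")
  }
  writeLines(lines, path)
  invisible(path)
}
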
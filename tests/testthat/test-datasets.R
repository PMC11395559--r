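test_that("sub-sequence sampling honours the 50% full-length rule and bounds", {
  gen <- generate_genome(4.3e6, "iid", seed = 3)
  subs <- sample_subsequences(gen, 4, subsequence_scheme(), n = 10000, seed = 9)
  expect_equal(nrow(subs), 10000)
  expect_true(all(subs$n_tokens >= 20 & subs$n_tokens <= 510))
  expect_true(all(nchar(subs$seq) == subs$n_tokens + 3L))
  frac_full <- mean(subs$n_tokens == 510)
  expect_lt(abs(frac_full - 0.5), 0.015)  # 3 sigma at n = 10,000
  again <- sample_subsequences(gen, 4, subsequence_scheme(), n = 10000, seed = 9)
  expect_identical(subs, again)
  expect_error(sample_subsequences(tibble::tibble(name = "x", seq = "ACGT"),
                                   4, subsequence_scheme(), n = 5),
               class = "dnalm_data_error")
})

test_that("mask patterns match the canonical per-k offsets", {
  expect_identical(make_mask_pattern(4)$offsets, -1:2)
  expect_identical(make_mask_pattern(5)$offsets, -2:2)
  expect_identical(make_mask_pattern(6)$offsets, -2:3)
  expect_message(p3 <- make_mask_pattern(3), "no canonical")
  expect_identical(p3$offsets, -1:1)
  expect_error(make_mask_pattern(0), class = "dnalm_parameter_error")
})

test_that("mask geometry: exactly one fully-masked nucleotide, 2k-1 nt span", {
  for (k in 4:6) {
    pat <- make_mask_pattern(k)
    for (t in c(10L, 17L)) {
      ora <- coverage_oracle(n_tokens = 40L, k = k, masked_idx = t + pat$offsets)
      expect_length(ora$fully_masked, 1)
      expect_identical(ora$fully_masked, t + pat$central_nt_offset)
      expect_identical(ora$span_nt, pat$span)
      expect_identical(pat$span, 2L * k - 1L)
    }
  }
})

test_that("masked dataset applies the pattern around a chosen token and keeps truth", {
  v <- build_vocabulary(4)
  set.seed(2)
  subs <- vapply(1:50, function(i) random_dna(33), character(1))  # 30 tokens
  ds <- build_masked_dataset(subs, v, seed = 4)
  pat <- attr(ds, "pattern")
  mid <- v$special_ids[["MASK"]]
  for (i in seq_len(nrow(ds))) {
    t <- ds$chosen_index[i]
    expect_identical(ds$masked_idx[[i]], t + pat$offsets)
    expect_true(all(ds$ids[[i]][ds$masked_idx[[i]]] == mid))
    expect_false(any(ds$ids[[i]][-ds$masked_idx[[i]]] == mid))
    expect_length(ds$truth_ids[[i]], 4)
    ora <- coverage_oracle(ds$n_tokens[i], 4L, ds$masked_idx[[i]])
    expect_length(ora$fully_masked, 1)
  }
  # truth restores the original sequence
  ids <- ds$ids[[1]]
  ids[ds$masked_idx[[1]]] <- ds$truth_ids[[1]]
  expect_identical(detokenize(ids, v), subs[1])
})

test_that("masked dataset skips short sub-sequences and is seed-reproducible", {
  v <- build_vocabulary(4)
  set.seed(3)
  subs <- c(vapply(1:20, function(i) random_dna(40), character(1)), "ACGTACG")
  expect_message(ds <- build_masked_dataset(subs, v, seed = 8), "Skipped 1")
  expect_equal(nrow(ds), 20)
  ds2 <- suppressMessages(build_masked_dataset(subs, v, seed = 8))
  expect_identical(ds$chosen_index, ds2$chosen_index)
  expect_identical(ds$ids, ds2$ids)
})

test_that("masked samples serialize to JSON lines", {
  v <- build_vocabulary(4)
  ds <- build_masked_dataset(c("ACGTACGTACGTACGT"), v, seed = 1)
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_masked_jsonl(ds, path)
  rec <- jsonlite::fromJSON(readLines(path)[1])
  expect_identical(rec$ids, ds$ids[[1]])
  expect_identical(rec$truth_ids, ds$truth_ids[[1]])
})

test_that("next-k-mer datasets chunk at 510 nt with leakage-free labels", {
  set.seed(5)
  s <- random_dna(1530)
  ds <- build_next_kmer_dataset(c(chr = s), 4, seed = 1)
  expect_equal(nrow(ds), 3)
  chunks <- substring(s, c(1, 511, 1021), c(510, 1020, 1530))
  for (i in seq_len(3)) {
    src <- chunks[match(ds$context[i], substr(chunks, 1, 50))]
    expect_identical(ds$context[i], substr(src, 1, 50))
    expect_identical(ds$label[i], substr(src, 51, 54))  # positions 50..53 0-based
  }
  v <- build_vocabulary(4)
  expect_identical(unname(v$kmer_ids[ds$label]), ds$label_id)

  # trailing remainder below 510 nt is discarded
  ds2 <- build_next_kmer_dataset(c(chr = random_dna(1700)), 4, seed = 1)
  expect_equal(nrow(ds2), 3)
  expect_error(build_next_kmer_dataset(c(chr = s), 7),
               class = "dnalm_parameter_error")
  expect_error(build_next_kmer_dataset(c(chr = s), 1),
               class = "dnalm_parameter_error")
})

test_that("next-k-mer split is 80/20 and the cap applies after shuffling", {
  gen <- generate_genome(102000, "iid", seed = 8)   # 200 chunks
  ds <- build_next_kmer_dataset(gen, 2, seed = 3)
  expect_equal(sum(ds$split == "train"), 160)
  expect_equal(sum(ds$split == "test"), 40)
  expect_true(all(ds$label_id >= 1 & ds$label_id <= 16))
  capped <- build_next_kmer_dataset(gen, 2, max_samples = 50, seed = 3)
  expect_equal(nrow(capped), 50)
  expect_equal(sum(capped$split == "train"), 40)
  ds2 <- build_next_kmer_dataset(gen, 2, seed = 3)
  expect_identical(ds, ds2)
})

test_that("promoter windows cover -249..+50 with strand-aware orientation", {
  set.seed(6)
  contig <- random_dna(2000)
  genome <- tibble::tibble(name = "chr1", seq = contig)
  tss <- tibble::tibble(chrom = "chr1", pos = c(1000L, 1200L),
                        strand = c("+", "-"))
  win <- extract_promoter_windows(genome, tss)
  expect_true(all(nchar(win$seq) == 300))
  # + strand: 0-based [751, 1051) -> 1-based 752..1051
  expect_identical(win$seq[1], substr(contig, 752, 1051))
  # - strand: reverse complement of 0-based [pos-50, pos+250)
  fwd <- substr(contig, 1200 - 50 + 1, 1200 + 250)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(fwd)))
  expect_identical(win$seq[2], rc)

  near_edge <- tibble::tibble(chrom = "chr1", pos = 100L, strand = "+")
  expect_message(out <- extract_promoter_windows(
    tibble::tibble(name = "chr1", seq = random_dna(300)), near_edge),
    "Skipped 1")
  expect_equal(nrow(out), 0)
})

test_that("Prom300 negatives preserve per-part composition and flag 15 of 20 parts", {
  proms <- generate_promoters(60, seed = 14)
  ds <- build_prom300_dataset(proms, seed = 15)
  expect_equal(nrow(ds), 120)
  expect_equal(as.vector(table(ds$label)), c(60, 60))
  part_of <- function(s, p) substr(s, (p - 1) * 15 + 1, p * 15)
  for (i in seq_len(60)) {
    real <- ds$seq[2 * i - 1]; shuf <- ds$seq[2 * i]
    chosen <- ds$shuffled_parts[[2 * i]]
    expect_length(chosen, 15)
    for (p in 1:20) {
      a <- part_of(real, p); b <- part_of(shuf, p)
      expect_identical(sort(strsplit(a, "")[[1]]), sort(strsplit(b, "")[[1]]))
      if (!p %in% chosen) expect_identical(a, b)
    }
  }
  # degenerate composition: shuffling a homopolymer is the identity
  mono <- build_prom300_dataset(strrep("A", 300), seed = 1)
  expect_identical(mono$seq[1], mono$seq[2])
  expect_identical(as.character(mono$label[2]), "shuffled")

  expect_error(build_prom300_dataset(c(strrep("A", 300), strrep("A", 299))),
               class = "dnalm_parameter_error")
  expect_error(build_prom300_dataset(strrep("A", 300), n_parts = 7),
               class = "dnalm_parameter_error")
})

test_that("Prom300 block-shuffle mode permutes whole parts", {
  proms <- generate_promoters(10, seed = 44)
  ds <- build_prom300_dataset(proms, seed = 45, shuffle_mode = "parts")
  for (i in seq_len(10)) {
    real <- ds$seq[2 * i - 1]; shuf <- ds$seq[2 * i]
    parts_r <- substring(real, 15 * (0:19) + 1, 15 * (1:20))
    parts_s <- substring(shuf, 15 * (0:19) + 1, 15 * (1:20))
    expect_setequal(parts_s, parts_r)
  }
})

test_that("dataset TSV writers emit the documented layouts", {
  gen <- generate_genome(2040, "iid", seed = 2)
  nk <- build_next_kmer_dataset(gen, 3, seed = 1)
  p1 <- withr::local_tempfile(fileext = ".tsv")
  write_next_kmer_tsv(nk, p1)
  back <- utils::read.table(p1, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  expect_identical(names(back), c("context", "label", "split"))
  expect_identical(back$context, nk$context)

  ds <- build_prom300_dataset(generate_promoters(3, seed = 1), seed = 2)
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_prom300_tsv(ds, p2)
  back2 <- utils::read.table(p2, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
  expect_identical(names(back2), c("sequence", "label", "shuffled_parts"))
  expect_equal(nrow(back2), 6)
})
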
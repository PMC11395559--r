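#' Sub-sequence sampling scheme
#'
#' The sampling rule used to cut a genome into training sub-sequences: with
#' probability `p_full` a window is emitted at the full length (`full_len`
#' tokens); otherwise its token length is uniform on `[min_len, full_len]`.
#' Lengths are expressed in tokens; a window of `t` tokens spans
#' `t + k - 1` nucleotides.
#'
#' @param p_full Probability of a full-length window.
#' @param full_len Full window length in tokens.
#' @param min_len Minimum window length in tokens.
#' @return A `subseq_scheme` list.
#' @export
subsequence_scheme <- function(p_full = 0.5, full_len = 510L, min_len = 20L) {
  stopifnot(p_full >= 0, p_full <= 1)
  full_len <- assert_scalar_int(full_len, "full_len", min = 1)
  min_len <- assert_scalar_int(min_len, "min_len", min = 1, max = full_len)
  structure(list(p_full = p_full, full_len = full_len, min_len = min_len),
            class = "subseq_scheme")
}

#' Split a genome into sub-sequences and sample from them
#'
#' Each contig is cut left-to-right into consecutive windows whose token
#' lengths are drawn from `scheme`; the trailing remainder shorter than
#' `min_len` tokens is dropped. A count (`n >= 1`) or a fraction
#' (`0 < fraction <= 1`) of the resulting windows is then sampled uniformly
#' without replacement.
#'
#' @param seqs Genome tibble or character vector.
#' @param k Token length (converts token lengths to nucleotides).
#' @param scheme A [subsequence_scheme()].
#' @param n Number of windows to sample (mutually exclusive with `fraction`).
#' @param fraction Fraction of windows to sample.
#' @param seed RNG seed; fixed seed gives byte-identical output.
#' @return A tibble with `seq` and `n_tokens`.
#' @export
sample_subsequences <- function(seqs, k, scheme = subsequence_scheme(),
                                n = NULL, fraction = NULL, seed = NULL) {
  seqs <- as_genome_tbl(seqs)
  k <- assert_scalar_int(k, "k", min = 1, max = 12)
  stopifnot(inherits(scheme, "subseq_scheme"))
  if (nrow(seqs) == 0L) abort("Empty genome input.", class = "dnalm_data_error")
  min_nt <- scheme$min_len + k - 1L
  if (!any(nchar(seqs$seq) >= min_nt)) {
    abort(sprintf("No sequence reaches the minimum window of %d nt.", min_nt),
          class = "dnalm_data_error")
  }
  with_seed(seed, {
    pieces <- purrr::map(seqs$seq, function(s) {
      L <- nchar(s)
      starts <- integer(0); toks <- integer(0)
      pos <- 1L
      while (L - pos + 1L >= min_nt) {
        t_len <- if (runif(1) < scheme$p_full) scheme$full_len else
          sample(scheme$min_len:scheme$full_len, 1L)
        nt <- min(t_len + k - 1L, L - pos + 1L)
        t_len <- nt - k + 1L
        if (t_len < scheme$min_len) break
        starts <- c(starts, pos); toks <- c(toks, t_len)
        pos <- pos + nt
      }
      if (!length(starts)) return(tibble(seq = character(), n_tokens = integer()))
      tibble(seq = substring(s, starts, starts + toks + k - 2L),
             n_tokens = toks)
    })
    all <- dplyr::bind_rows(pieces)
    total <- nrow(all)
    if (!is.null(fraction)) {
      stopifnot(fraction > 0, fraction <= 1)
      n <- max(1L, round(fraction * total))
    }
    if (is.null(n)) return(all)
    if (n > total) {
      abort(sprintf(
        "Requested %d windows but only %d available; supply a longer genome.",
        n, total), class = "dnalm_data_error")
    }
    all[sample.int(total, n), ]
  })
}

#' Mask pattern for masked-token prediction
#'
#' For token length `k`, the pattern gives the offsets (relative to a chosen
#' token) of the `k` tokens that are masked together. The canonical patterns
#' are `4mer: -1,0,1,2`, `5mer: -2,-1,0,1,2`, `6mer: -2,-1,0,1,2,3`; other
#' `k` get the same symmetric-as-possible contiguous rule (extra offset on
#' the right). Because tokens overlap by `k - 1` nucleotides, the masked
#' tokens jointly cover `2k - 1` consecutive nucleotides of which exactly
#' one — the central nucleotide, at offset `max(offsets)` from the chosen
#' token's first base — is covered by no unmasked token.
#'
#' @param k Token length.
#' @return A `mask_pattern` list with `k`, `offsets`, `span` (`2k - 1` nt)
#'   and `central_nt_offset`.
#' @export
make_mask_pattern <- function(k) {
  k <- assert_scalar_int(k, "k", min = 1)
  offsets <- switch(as.character(k),
    "4" = -1:2, "5" = -2:2, "6" = -2:3,
    {
      inform(sprintf(
        "k = %d has no canonical mask pattern; using symmetric rule.", k))
      (-floor((k - 1) / 2)):(ceiling((k - 1) / 2))
    })
  structure(list(k = k, offsets = offsets, span = 2L * k - 1L,
                 central_nt_offset = max(offsets)),
            class = "mask_pattern")
}

#' Build masked-token prediction samples
#'
#' For each sub-sequence one token index is chosen uniformly among positions
#' where the mask pattern fits with at least one unmasked flanking token on
#' each side; the `k` pattern tokens are replaced by the MASK id and their
#' true ids retained. Sub-sequences too short for the pattern are skipped
#' with a logged count.
#'
#' @param subseqs Character vector of nucleotide strings, or a tibble with a
#'   `seq` column.
#' @param vocab A [build_vocabulary()] vocabulary.
#' @param seed RNG seed.
#' @param pattern A [make_mask_pattern()]; defaults to the canonical pattern
#'   for `vocab$k`.
#' @return A `masked_dataset` tibble: `sample_id`, `ids` (list of token-id
#'   vectors with MASK substituted), `n_tokens`, `chosen_index`,
#'   `masked_idx` (list), `truth_ids` (list). The pattern is attached as
#'   attribute `pattern`.
#' @export
build_masked_dataset <- function(subseqs, vocab, seed = NULL, pattern = NULL) {
  stopifnot(inherits(vocab, "kmer_vocab"))
  if (is.data.frame(subseqs)) subseqs <- subseqs$seq
  pattern <- pattern %||% make_mask_pattern(vocab$k)
  mid <- mask_id(vocab)
  lo <- min(pattern$offsets); hi <- max(pattern$offsets)
  with_seed(seed, {
    rows <- purrr::map(subseqs, function(s) {
      tok <- tokenize(s, vocab)
      n <- length(tok$ids)
      t_min <- 2L - lo          # >= 1 unmasked token on the left
      t_max <- n - 1L - hi      # >= 1 unmasked token on the right
      if (t_max < t_min) return(NULL)
      t <- if (t_max == t_min) t_min else sample(t_min:t_max, 1L)
      midx <- t + pattern$offsets
      ids <- tok$ids
      truth <- ids[midx]
      ids[midx] <- mid
      list(ids = ids, n_tokens = n, chosen_index = t,
           masked_idx = midx, truth_ids = truth)
    })
    skipped <- sum(vapply(rows, is.null, logical(1)))
    if (skipped > 0) {
      inform(sprintf("Skipped %d sub-sequence(s) too short for the mask pattern.",
                     skipped))
    }
    rows <- rows[!vapply(rows, is.null, logical(1))]
    out <- tibble(
      sample_id = seq_along(rows),
      ids = purrr::map(rows, "ids"),
      n_tokens = purrr::map_int(rows, "n_tokens"),
      chosen_index = purrr::map_int(rows, "chosen_index"),
      masked_idx = purrr::map(rows, "masked_idx"),
      truth_ids = purrr::map(rows, "truth_ids"))
    attr(out, "pattern") <- pattern
    attr(out, "k") <- vocab$k
    class(out) <- c("masked_dataset", class(out))
    out
  })
}

#' Serialize masked samples as JSON lines
#'
#' One JSON object per line with fields `ids`, `chosen_index`, `masked_idx`,
#' `truth_ids`.
#'
#' @param ds A `masked_dataset`.
#' @param path Output path.
#' @export
write_masked_jsonl <- function(ds, path) {
  lines <- purrr::pmap_chr(
    list(ds$ids, ds$chosen_index, ds$masked_idx, ds$truth_ids),
    function(ids, ci, mi, ti) {
      jsonlite::toJSON(list(ids = ids, chosen_index = ci,
                            masked_idx = mi, truth_ids = ti))
    })
  writeLines(lines, path)
  invisible(path)
}

#' Build the next-k-mer prediction dataset
#'
#' The genome is split into consecutive non-overlapping 510-nt chunks (the
#' trailing remainder is discarded); each chunk contributes one sample whose
#' context is its first 50 nucleotides and whose label is the `k`
#' nucleotides that immediately follow — so context and label share no
#' source positions. Samples are shuffled, capped at `max_samples`, and
#' split 80/20 into train/test.
#'
#' @param seqs Genome tibble or character vector.
#' @param k Label length, 2..6 (beyond 6 the `4^k` class head becomes
#'   impractical and classes are no longer well represented).
#' @param max_samples Cap on the number of samples (default 500000).
#' @param seed RNG seed for shuffling.
#' @param chunk_len Chunk length in nucleotides.
#' @param context_len Context length in nucleotides.
#' @param train_frac Training fraction of the split.
#' @return A `next_kmer_dataset` tibble: `context`, `label`, `label_id`
#'   (1-based class index in `1..4^k`), `split` (`"train"`/`"test"`), with
#'   attribute `k`.
#' @export
build_next_kmer_dataset <- function(seqs, k, max_samples = 500000L,
                                    seed = NULL, chunk_len = 510L,
                                    context_len = 50L, train_frac = 0.8) {
  k <- assert_scalar_int(k, "k", min = 2, max = 6)
  seqs <- as_genome_tbl(seqs)
  if (sum(nchar(seqs$seq) >= chunk_len) == 0L) {
    abort(sprintf("No sequence reaches the chunk length of %d nt.", chunk_len),
          class = "dnalm_data_error")
  }
  samples <- purrr::map(seqs$seq, function(s) {
    n_chunks <- nchar(s) %/% chunk_len
    if (n_chunks == 0L) return(NULL)
    starts <- (seq_len(n_chunks) - 1L) * chunk_len + 1L
    tibble(context = substring(s, starts, starts + context_len - 1L),
           label = substring(s, starts + context_len,
                             starts + context_len + k - 1L))
  })
  out <- dplyr::bind_rows(samples)
  with_seed(seed, {
    out <- out[sample.int(nrow(out)), ]
    if (nrow(out) > max_samples) out <- out[seq_len(max_samples), ]
    n_train <- round(train_frac * nrow(out))
    out$split <- rep(c("train", "test"),
                     c(n_train, nrow(out) - n_train))
    out$label_id <- vapply(out$label, function(l) {
      digits_to_kmer_ids(seq_to_digits(l, "label"), k)
    }, integer(1), USE.NAMES = FALSE)
    out <- out[, c("context", "label", "label_id", "split")]
    attr(out, "k") <- k
    class(out) <- c("next_kmer_dataset", class(out))
    out
  })
}

#' Write a next-k-mer dataset as TSV
#' @param ds A `next_kmer_dataset`.
#' @param path Output path.
#' @export
write_next_kmer_tsv <- function(ds, path) {
  utils::write.table(as.data.frame(ds[, c("context", "label", "split")]),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Extract promoter windows around transcription start sites
#'
#' Cuts the 300-bp window from −249 to +50 around each TSS (offset 0 is the
#' TSS itself; the closed range spans 300 positions). Minus-strand windows
#' take the mirrored genomic interval and are reverse-complemented so the
#' TSS-proximal end is consistent across strands. Sites too close to a
#' contig edge are skipped with a logged count.
#'
#' @param genome Genome tibble.
#' @param tss Tibble with `chrom`, `pos` (0-based TSS position), `strand`.
#' @param upstream,downstream Window extent (defaults 249 and 50).
#' @return A tibble `chrom`, `pos`, `strand`, `seq` with 300-nt windows.
#' @export
extract_promoter_windows <- function(genome, tss, upstream = 249L,
                                     downstream = 50L) {
  genome <- as_genome_tbl(genome)
  contig_len <- setNames(nchar(genome$seq), genome$name)
  contig_seq <- setNames(genome$seq, genome$name)
  width <- upstream + downstream + 1L
  res <- purrr::pmap(tss[, c("chrom", "pos", "strand")],
                     function(chrom, pos, strand) {
    if (!chrom %in% names(contig_seq)) return(NULL)
    L <- contig_len[[chrom]]
    if (strand == "-") {
      start0 <- pos - downstream; end0 <- pos + upstream + 1L
    } else {
      start0 <- pos - upstream; end0 <- pos + downstream + 1L
    }
    if (start0 < 0L || end0 > L) return(NULL)
    s <- substr(contig_seq[[chrom]], start0 + 1L, end0)
    if (strand == "-") {
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    }
    tibble(chrom = chrom, pos = pos, strand = strand, seq = s)
  })
  skipped <- sum(vapply(res, is.null, logical(1)))
  if (skipped > 0) {
    inform(sprintf("Skipped %d TSS record(s) too close to a contig edge.",
                   skipped))
  }
  out <- dplyr::bind_rows(res)
  if (!nrow(out)) {
    return(tibble(chrom = character(), pos = integer(), strand = character(),
                  seq = character()))
  }
  stopifnot(all(nchar(out$seq) == width))
  out
}

#' Build the Prom300 dataset: real vs part-shuffled promoters
#'
#' For every input promoter two records are produced: the intact sequence
#' (label `real`) and a negative (label `shuffled`) obtained by dividing the
#' sequence into `n_parts` contiguous equal parts and permuting the
#' nucleotides within `n_shuffle` randomly chosen parts. Shuffling operates
#' strictly within parts, so the global and per-part base composition of a
#' negative is identical to its source — composition carries no label
#' signal, only local order does.
#'
#' @param promoters Character vector of fixed-length sequences, or a tibble
#'   with a `seq` column.
#' @param n_parts Number of equal parts (must divide the sequence length).
#' @param n_shuffle Number of parts to shuffle.
#' @param seed RNG seed; part choice and permutations are fixed per record.
#' @param shuffle_mode `"nucleotides"` permutes bases within each chosen
#'   part (default); `"parts"` instead permutes the chosen parts as blocks.
#' @return A `prom300_dataset` tibble: `source_id`, `seq`, `label` (factor
#'   real/shuffled), `shuffled_parts` (list column, empty for real records).
#' @export
build_prom300_dataset <- function(promoters, n_parts = 20L, n_shuffle = 15L,
                                  seed = NULL,
                                  shuffle_mode = c("nucleotides", "parts")) {
  shuffle_mode <- match.arg(shuffle_mode)
  if (is.data.frame(promoters)) promoters <- promoters$seq
  if (!length(promoters)) abort("No promoters supplied.", class = "dnalm_data_error")
  len <- unique(nchar(promoters))
  if (length(len) != 1L) {
    abort("All promoter sequences must have the same length.",
          class = "dnalm_parameter_error")
  }
  n_parts <- assert_scalar_int(n_parts, "n_parts", min = 1, max = len)
  n_shuffle <- assert_scalar_int(n_shuffle, "n_shuffle", min = 1, max = n_parts)
  if (len %% n_parts != 0L) {
    abort(sprintf("Sequence length %d is not divisible into %d equal parts.",
                  len, n_parts), class = "dnalm_parameter_error")
  }
  part_len <- len %/% n_parts
  part_start <- (seq_len(n_parts) - 1L) * part_len + 1L
  with_seed(seed, {
    recs <- purrr::imap(promoters, function(s, i) {
      chosen <- sort(sample.int(n_parts, n_shuffle))
      parts <- substring(s, part_start, part_start + part_len - 1L)
      if (shuffle_mode == "nucleotides") {
        parts[chosen] <- vapply(parts[chosen], function(p) {
          paste(sample(strsplit(p, "")[[1]]), collapse = "")
        }, character(1), USE.NAMES = FALSE)
      } else {
        parts[chosen] <- parts[chosen][sample.int(n_shuffle)]
      }
      tibble(source_id = c(i, i),
             seq = c(s, paste(parts, collapse = "")),
             label = factor(c("real", "shuffled"),
                            levels = c("real", "shuffled")),
             shuffled_parts = list(integer(0), chosen))
    })
    out <- dplyr::bind_rows(recs)
    attr(out, "n_parts") <- n_parts
    attr(out, "n_shuffle") <- n_shuffle
    class(out) <- c("prom300_dataset", class(out))
    out
  })
}

#' Write a Prom300 dataset as TSV
#' @param ds A `prom300_dataset`.
#' @param path Output path.
#' @export
write_prom300_tsv <- function(ds, path) {
  df <- data.frame(
    sequence = ds$seq,
    label = as.character(ds$label),
    shuffled_parts = vapply(ds$shuffled_parts, paste, character(1),
                            collapse = ","))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
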
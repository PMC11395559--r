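#' Read a genome FASTA into a tibble
#'
#' Reads a (multi-record, wrapped or unwrapped) FASTA file, uppercases the
#' sequence, and applies the alphabet restriction used throughout the
#' toolkit: only sequences composed entirely of `A,C,G,T` are analysable.
#' By default records containing any other character (ambiguity codes,
#' `N` runs) are excluded with a logged count; with
#' `split_at_invalid = TRUE` each record is instead split into its maximal
#' valid runs, which is the practical choice for real assemblies where
#' whole-chromosome exclusion would discard everything.
#'
#' @param path Path to a FASTA file.
#' @param split_at_invalid Split records at non-ACGT runs instead of
#'   excluding them wholesale.
#' @param min_run Minimum length of a kept run when splitting.
#' @return A tibble with columns `name` and `seq`.
#' @export
read_genome_fasta <- function(path, split_at_invalid = FALSE, min_run = 1L) {
  if (!file.exists(path)) {
    abort(sprintf("FASTA file not found: %s", path), class = "dnalm_io_error")
  }
  if (file.size(path) == 0L) {
    warn("FASTA file is empty.")
    return(tibble(name = character(), seq = character()))
  }
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0L) {
    warn("FASTA file contains no records.")
    return(tibble(name = character(), seq = character()))
  }
  seqs <- toupper(as.character(set))
  names <- names(set) %||% paste0("seq", seq_along(seqs))
  valid <- !grepl("[^ACGT]", seqs)
  if (!split_at_invalid) {
    n_excl <- sum(!valid)
    if (n_excl > 0) {
      inform(sprintf("Excluded %d record(s) containing non-ACGT characters.", n_excl))
    }
    return(tibble(name = names[valid], seq = unname(seqs[valid])))
  }
  out <- purrr::map2(names, seqs, function(nm, s) {
    if (!grepl("[^ACGT]", s)) return(tibble(name = nm, seq = s))
    runs <- regmatches(s, gregexpr("[ACGT]+", s))[[1]]
    runs <- runs[nchar(runs) >= min_run]
    if (!length(runs)) return(tibble(name = character(), seq = character()))
    tibble(name = paste0(nm, "_run", seq_along(runs)), seq = runs)
  })
  res <- dplyr::bind_rows(out)
  inform(sprintf("Split %d record(s) into %d valid ACGT run(s).",
                 length(seqs), nrow(res)))
  res
}

#' Write sequences to FASTA
#'
#' @param seqs A tibble with `name` and `seq` columns (or a named character
#'   vector).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(seqs, path) {
  seqs <- as_genome_tbl(seqs)
  set <- Biostrings::DNAStringSet(setNames(seqs$seq, seqs$name))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

# Coerce character vectors / tibbles to the canonical genome tibble.
as_genome_tbl <- function(seqs) {
  if (is.character(seqs)) {
    nm <- names(seqs) %||% paste0("seq", seq_along(seqs))
    return(tibble(name = nm, seq = unname(seqs)))
  }
  if (is.data.frame(seqs)) {
    if (!all(c("name", "seq") %in% names(seqs))) {
      abort("Genome table must have `name` and `seq` columns.",
            class = "dnalm_parameter_error")
    }
    return(as_tibble(seqs[c("name", "seq")]))
  }
  abort("`seqs` must be a character vector or a tibble with name/seq.",
        class = "dnalm_parameter_error")
}

#' Genome-wide k-mer frequencies
#'
#' Counts every overlapping k-mer occurrence across the supplied sequences
#' and normalises to relative frequencies. All `4^k` k-mers get a row, with
#' zero counts where absent, so the table aligns with the vocabulary and
#' with per-position prediction profiles.
#'
#' @param seqs Genome tibble (`name`, `seq`) or character vector.
#' @param k K-mer length.
#' @return A tibble `kmer`, `count`, `frequency` in vocabulary (lexicographic)
#'   order; frequencies sum to 1.
#' @export
genome_kmer_frequencies <- function(seqs, k) {
  k <- assert_scalar_int(k, "k", min = 1, max = 12)
  seqs <- as_genome_tbl(seqs)
  keep <- nchar(seqs$seq) >= k
  if (!any(keep)) {
    abort(sprintf("No sequence of length >= k = %d supplied.", k),
          class = "dnalm_data_error")
  }
  set <- Biostrings::DNAStringSet(seqs$seq[keep])
  counts <- Biostrings::oligonucleotideFrequency(set, width = k)
  total <- colSums(counts)
  # oligonucleotideFrequency columns are already lexicographic over ACGT
  tibble(kmer = names(total),
         count = as.integer(unname(total)),
         frequency = unname(total) / sum(total))
}

#' Write a k-mer frequency table as TSV
#'
#' @param freqs Tibble from [genome_kmer_frequencies()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_frequencies_tsv <- function(freqs, path) {
  utils::write.table(freqs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
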
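#' Build an overlapping k-mer vocabulary
#'
#' Enumerates all `4^k` k-mers over the DNA alphabet in lexicographic order
#' (`A < C < G < T`) and appends the five special tokens `CLS`, `PAD`, `UNK`,
#' `SEP` and `MASK`, mirroring the vocabulary layout used by BERT-style DNA
#' language models trained on overlapping k-mers. Token ids are consecutive
#' integers: k-mers occupy `1..4^k`, specials `4^k + 1 .. 4^k + 5`.
#'
#' @param k Token length in nucleotides. Any `1 <= k <= 12` is accepted;
#'   4, 5 and 6 are the canonical sizes.
#' @return A `kmer_vocab` object: list with elements `k`, `kmers`
#'   (character vector of length `4^k`), `kmer_ids` (named integer vector),
#'   `special_ids` (named integer vector) and `size` (`4^k + 5`).
#' @examples
#' v <- build_vocabulary(4)
#' v$size          # 261
#' v$kmers[1:3]    # "AAAA" "AAAC" "AAAG"
#' @export
build_vocabulary <- function(k) {
  k <- assert_scalar_int(k, "k", min = 1, max = 12)
  n <- as.integer(4L^k)
  grid <- do.call(expand.grid, c(rep(list(DNA_BASES), k),
                                 list(stringsAsFactors = FALSE)))
  # expand.grid varies the first factor fastest; reverse columns so the
  # last nucleotide varies fastest, giving lexicographic order.
  kmers <- do.call(paste0, rev(grid))
  specials <- c(CLS = n + 1L, PAD = n + 2L, UNK = n + 3L, SEP = n + 4L,
                MASK = n + 5L)
  structure(
    list(k = k,
         kmers = kmers,
         kmer_ids = setNames(seq_len(n), kmers),
         special_ids = specials,
         size = n + 5L),
    class = "kmer_vocab")
}

#' @exportS3Method base::print
print.kmer_vocab <- function(x, ...) {
  cat(sprintf("<kmer_vocab> k = %d: %d k-mers + %d special tokens (%d ids)\n",
              x$k, length(x$kmers), length(x$special_ids), x$size))
  invisible(x)
}

# id of the MASK token
mask_id <- function(vocab) unname(vocab$special_ids[["MASK"]])

# Fast k-mer id computation: base-4 positional encoding of the digit vector.
# Returns 1-based ids aligned with the lexicographic vocabulary.
digits_to_kmer_ids <- function(dig, k) {
  n_tok <- length(dig) - k + 1L
  ids <- integer(n_tok)
  for (j in seq_len(k)) {
    ids <- ids + dig[j:(j + n_tok - 1L)] * as.integer(4L^(k - j))
  }
  ids + 1L
}

#' Tokenize a nucleotide sequence into overlapping k-mers
#'
#' Slides a window of width `k` along the sequence one nucleotide at a time,
#' so consecutive tokens overlap by `k - 1` bases and a sequence of length
#' `L >= k` yields exactly `L - k + 1` tokens.
#'
#' @param seq A single nucleotide string over `A,C,G,T` (uppercase).
#' @param vocab A [build_vocabulary()] object.
#' @return A `token_seq` object: list with `k`, `ids` (integer vocabulary
#'   ids), and `source_length`.
#' @examples
#' v <- build_vocabulary(4)
#' tokenize("ACGTAC", v)$ids  # ids of ACGT, CGTA, GTAC
#' @export
tokenize <- function(seq, vocab) {
  stopifnot(inherits(vocab, "kmer_vocab"))
  if (length(seq) != 1L || !is.character(seq)) {
    abort("`seq` must be a single character string.", class = "dnalm_parameter_error")
  }
  k <- vocab$k
  if (nchar(seq) < k) {
    abort(sprintf("Sequence length %d is shorter than k = %d.", nchar(seq), k),
          class = "dnalm_length_error")
  }
  dig <- seq_to_digits(seq)
  structure(
    list(k = k,
         ids = digits_to_kmer_ids(dig, k),
         source_length = nchar(seq)),
    class = "token_seq")
}

#' @exportS3Method base::print
print.token_seq <- function(x, ...) {
  cat(sprintf("<token_seq> %d tokens (k = %d, %d nt)\n",
              length(x$ids), x$k, x$source_length))
  invisible(x)
}

# Map token ids back to k-mer strings (errors on special/out-of-range ids).
ids_to_kmers <- function(ids, vocab) {
  if (any(ids < 1L | ids > length(vocab$kmers))) {
    bad <- which(ids < 1L | ids > length(vocab$kmers))[1]
    abort(sprintf("Token id %d at position %d is not a k-mer id.",
                  ids[bad], bad),
          class = "dnalm_data_error")
  }
  vocab$kmers[ids]
}

#' Reconstruct a nucleotide sequence from overlapping tokens
#'
#' Inverse of [tokenize()]: consecutive tokens must agree on their `k - 1`
#' overlapping nucleotides, which makes the reconstruction unique.
#'
#' @param tokens A `token_seq`, or an integer vector of k-mer token ids.
#' @param vocab The vocabulary the ids refer to.
#' @return A nucleotide string such that `detokenize(tokenize(s)) == s`.
#' @export
detokenize <- function(tokens, vocab) {
  ids <- if (inherits(tokens, "token_seq")) tokens$ids else as.integer(tokens)
  if (length(ids) == 0L) abort("Empty token sequence.", class = "dnalm_data_error")
  kmers <- ids_to_kmers(ids, vocab)
  k <- nchar(kmers[1])
  if (length(kmers) > 1L) {
    suffix <- substr(kmers[-length(kmers)], 2L, k)
    prefix <- substr(kmers[-1L], 1L, k - 1L)
    bad <- which(suffix != prefix)
    if (length(bad)) {
      abort(sprintf(
        "Inconsistent token overlap between positions %d and %d: '%s' vs '%s'.",
        bad[1], bad[1] + 1L, kmers[bad[1]], kmers[bad[1] + 1L]),
        class = "dnalm_data_error")
    }
  }
  paste0(kmers[1], paste(substr(kmers[-1L], k, k), collapse = ""))
}

#' Write / read a vocabulary as plain text
#'
#' One token per line; ids are implicit in line order (the layout used by
#' BERT-style `vocab.txt` files).
#'
#' @param vocab A `kmer_vocab`.
#' @param path Output file path.
#' @return `path`, invisibly; `read_vocabulary()` returns a `kmer_vocab`.
#' @export
write_vocabulary <- function(vocab, path) {
  writeLines(c(vocab$kmers, names(vocab$special_ids)), path)
  invisible(path)
}

#' @rdname write_vocabulary
#' @export
read_vocabulary <- function(path) {
  lines <- readLines(path)
  n_kmer <- length(lines) - 5L
  k <- round(log(n_kmer, 4))
  if (4L^k != n_kmer) {
    abort("Vocabulary file does not contain 4^k k-mer lines + 5 specials.",
          class = "dnalm_data_error")
  }
  v <- build_vocabulary(k)
  if (!identical(c(v$kmers, names(v$special_ids)), lines)) {
    abort("Vocabulary file tokens do not match the canonical layout.",
          class = "dnalm_data_error")
  }
  v
}
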
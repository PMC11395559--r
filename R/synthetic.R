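#' Generate a synthetic genome with known statistical structure
#'
#' Desk-scale stand-in for a reference assembly, with three modes chosen so
#' that context learning has a known ground truth:
#' \describe{
#'   \item{`iid`}{independent draws from `base_freqs` — no sequential
#'     dependence, so no model can beat the marginal base prior (negative
#'     control).}
#'   \item{`markov`}{an order-`order` Markov chain with the given transition
#'     matrix — learnable short-range context.}
#'   \item{`periodic`}{an exact tiling of `unit` truncated to `length` —
#'     fully deterministic context (positive control).}
#' }
#'
#' @param length Sequence length in nucleotides.
#' @param mode One of `"iid"`, `"markov"`, `"periodic"`.
#' @param base_freqs Length-4 base frequencies (A,C,G,T) for `iid`.
#' @param transition `4^order x 4` transition matrix for `markov`; rows sum
#'   to 1, row order is lexicographic over the length-`order` state. Default
#'   is [markov_transition()].
#' @param order Markov order (1..5).
#' @param unit Repeat unit for `periodic`.
#' @param name Contig name.
#' @param seed RNG seed; fixed seed gives a byte-identical sequence.
#' @return A one-row genome tibble (`name`, `seq`).
#' @examples
#' generate_genome(12, "periodic", unit = "ACGT")$seq  # "ACGTACGTACGT"
#' @export
generate_genome <- function(length, mode = c("iid", "markov", "periodic"),
                            base_freqs = rep(0.25, 4),
                            transition = NULL, order = 1L,
                            unit = "ACGT", name = NULL, seed = NULL) {
  mode <- match.arg(mode)
  length <- assert_scalar_int(length, "length", min = 1)
  seq <- switch(mode,
    iid = {
      if (base::length(base_freqs) != 4 || any(base_freqs < 0) ||
          abs(sum(base_freqs) - 1) > 1e-8) {
        abort("`base_freqs` must be 4 non-negative values summing to 1.",
              class = "dnalm_parameter_error")
      }
      with_seed(seed, paste(sample(DNA_BASES, length, replace = TRUE,
                                   prob = base_freqs), collapse = ""))
    },
    markov = {
      order <- assert_scalar_int(order, "order", min = 1, max = 5)
      if (is.null(transition)) transition <- markov_transition(order)
      n_states <- 4L^order
      if (!is.matrix(transition) || nrow(transition) != n_states ||
          ncol(transition) != 4 || any(transition < 0) ||
          any(abs(rowSums(transition) - 1) > 1e-8)) {
        abort(sprintf(
          "`transition` must be a %d x 4 matrix with rows summing to 1.",
          n_states), class = "dnalm_parameter_error")
      }
      with_seed(seed, markov_chain_seq(length, transition, order))
    },
    periodic = {
      if (!grepl("^[ACGT]+$", unit)) {
        abort("`unit` must be a non-empty ACGT string.",
              class = "dnalm_parameter_error")
      }
      substr(strrep(unit, ceiling(length / nchar(unit))), 1, length)
    })
  tibble(name = name %||% paste0("synthetic_", mode), seq = seq)
}

#' Default biased Markov transition matrix
#'
#' Each length-`order` state prefers a single successor base (the state's
#' last base shifted `A -> C -> G -> T -> A`) with probability `persistence`,
#' sharing the remainder equally. This plants strong, learnable sequential
#' structure while keeping the stationary base composition uniform.
#'
#' @param order Markov order.
#' @param persistence Probability of the preferred successor.
#' @return A `4^order x 4` stochastic matrix.
#' @export
markov_transition <- function(order = 1L, persistence = 0.85) {
  order <- assert_scalar_int(order, "order", min = 1, max = 5)
  stopifnot(persistence > 0, persistence < 1)
  n_states <- 4L^order
  M <- matrix((1 - persistence) / 3, n_states, 4)
  last_base <- (seq_len(n_states) - 1L) %% 4L        # 0..3 of the last base
  pref <- (last_base + 1L) %% 4L + 1L
  M[cbind(seq_len(n_states), pref)] <- persistence
  M
}

# Sample an order-m Markov chain; state = base-4 encoding of last m digits.
markov_chain_seq <- function(length, transition, order) {
  cum <- t(apply(transition, 1, cumsum))
  dig <- integer(length)
  # burn-in start: uniform initial state
  state_digits <- sample.int(4L, order, replace = TRUE) - 1L
  u <- runif(length)
  for (i in seq_len(length)) {
    state <- sum(state_digits * 4L^((order - 1L):0)) + 1L
    d <- findInterval(u[i], cum[state, ], left.open = TRUE)  # 0..3
    dig[i] <- d
    state_digits <- c(state_digits[-1L], d)[seq_len(order)]
    if (order == 1L) state_digits <- d
  }
  paste(DNA_BASES[dig + 1L], collapse = "")
}

#' Generate synthetic promoter sequences with planted positional structure
#'
#' Emits fixed-length sequences of iid uniform background with a
#' composition-balanced motif planted at fixed offsets. Because the motif's
#' base composition matches the background and the signal lives in the
#' *order* of nucleotides at fixed positions, within-part shuffling (the
#' Prom300 negative construction) destroys it while preserving composition —
#' exactly the property the Prom300 control requires.
#'
#' @param n Number of promoters.
#' @param length Sequence length (default 300).
#' @param motif Planted motif; the default `"ACGTTGCA"` contains each base
#'   exactly twice, so composition carries no signal.
#' @param motif_offsets 1-based start offsets of motif copies. The default
#'   plants one copy inside each 15-nt part of the 300-bp window.
#' @param seed RNG seed.
#' @return A tibble (`name`, `seq`) of `n` promoters.
#' @export
generate_promoters <- function(n, length = 300L, motif = "ACGTTGCA",
                               motif_offsets = seq(4L, 289L, by = 15L),
                               seed = NULL) {
  n <- assert_scalar_int(n, "n", min = 1)
  length <- assert_scalar_int(length, "length", min = 1)
  if (!grepl("^[ACGT]+$", motif)) {
    abort("`motif` must be an ACGT string.", class = "dnalm_parameter_error")
  }
  w <- nchar(motif)
  if (any(motif_offsets < 1) || any(motif_offsets + w - 1L > length)) {
    abort("`motif_offsets` place the motif outside the sequence.",
          class = "dnalm_parameter_error")
  }
  motif_chars <- strsplit(motif, "")[[1]]
  with_seed(seed, {
    seqs <- vapply(seq_len(n), function(i) {
      chars <- sample(DNA_BASES, length, replace = TRUE)
      for (off in motif_offsets) chars[off:(off + w - 1L)] <- motif_chars
      paste(chars, collapse = "")
    }, character(1))
    tibble(name = sprintf("promoter_%d", seq_len(n)), seq = seqs)
  })
}

#' Synthetic TSS annotations for a genome
#'
#' Draws `n` transcription start sites uniformly over positions that leave
#' room for a −249..+50 promoter window, with random strands, as a BED-like
#' tibble (`chrom`, `pos` 0-based, `strand`).
#'
#' @param genome Genome tibble.
#' @param n Number of sites.
#' @param seed RNG seed.
#' @export
generate_tss <- function(genome, n, seed = NULL) {
  genome <- as_genome_tbl(genome)
  n <- assert_scalar_int(n, "n", min = 1)
  lens <- nchar(genome$seq)
  ok <- lens >= 300L
  if (!any(ok)) abort("No contig long enough for a 300-bp window.",
                      class = "dnalm_data_error")
  with_seed(seed, {
    idx <- sample(which(ok), n, replace = TRUE,
                  prob = lens[ok] - 299)
    pos <- vapply(idx, function(i) {
      # valid TSS for either strand: 250 upstream-ish and 250 downstream-ish
      sample(250:(lens[i] - 251L), 1L)
    }, integer(1))
    tibble(chrom = genome$name[idx],
           pos = as.integer(pos),
           strand = sample(c("+", "-"), n, replace = TRUE))
  })
}

#' Write / read TSS annotations as BED
#'
#' Six-column BED with one-base intervals at the TSS (0-based start).
#' Reading uses `rtracklayer` when available.
#'
#' @param tss Tibble with `chrom`, `pos`, `strand`.
#' @param path File path.
#' @export
write_tss_bed <- function(tss, path) {
  df <- data.frame(chrom = tss$chrom, start = tss$pos, end = tss$pos + 1L,
                   name = sprintf("tss_%d", seq_len(nrow(tss))),
                   score = 0L, strand = tss$strand)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_tss_bed
#' @export
read_tss_bed <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("BED file not found: %s", path), class = "dnalm_io_error")
  }
  if (requireNamespace("rtracklayer", quietly = TRUE)) {
    gr <- rtracklayer::import(path, format = "BED")
    return(tibble(chrom = as.character(GenomicRanges::seqnames(gr)),
                  pos = GenomicRanges::start(gr) - 1L,
                  strand = as.character(GenomicRanges::strand(gr))))
  }
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  tibble(chrom = df[[1]], pos = as.integer(df[[2]]),
         strand = if (ncol(df) >= 6) df[[6]] else "+")
}
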
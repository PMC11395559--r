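#' @importFrom rlang abort warn inform %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom purrr map map_chr map_int map_dbl map2 pmap imap
#' @importFrom stats rnorm runif setNames
NULL

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG stream. A NULL seed leaves the global stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Derive `n` independent child seeds (< 2^31) from a parent seed.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

assert_scalar_int <- function(x, name, min = -Inf, max = Inf) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != as.integer(x)) {
    abort(sprintf("`%s` must be a single integer.", name), class = "dnalm_parameter_error")
  }
  if (x < min || x > max) {
    abort(sprintf("`%s` must be in [%s, %s], got %s.", name, min, max, x),
          class = "dnalm_parameter_error")
  }
  as.integer(x)
}

DNA_BASES <- c("A", "C", "G", "T")

# Map a nucleotide string to 0-based digits over A<C<G<T; reports the first
# offending position on failure.
seq_to_digits <- function(seq, what = "sequence") {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  dig <- match(chars, DNA_BASES)
  if (anyNA(dig)) {
    bad <- which(is.na(dig))[1]
    abort(sprintf("Non-ACGT character '%s' in %s at position %d.",
                  chars[bad], what, bad),
          class = "dnalm_data_error")
  }
  dig - 1L
}

log10_pretty <- function(x) format(x, digits = 4)
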
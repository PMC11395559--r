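#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an offset-accuracy profile
#'
#' @param x An `offset_accuracy` from [masked_accuracy_by_offset()].
#' @param ... Unused.
#' @return A plain tibble of per-offset accuracies.
#' @export
tidy.offset_accuracy <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- class(tibble())
  out
}

#' @rdname tidy.offset_accuracy
#' @export
glance.offset_accuracy <- function(x, ...) {
  tibble(overall = attr(x, "overall"),
         overall_by_sample = attr(x, "overall_by_sample"),
         n_ties = attr(x, "n_ties"),
         k = attr(x, "k"))
}

#' Tidy a MEV result
#'
#' `tidy()` returns the explained-variance spectrum per component;
#' `glance()` the one-row summary with the MEV itself.
#'
#' @param x A `mev_result` from [compute_mev()].
#' @param ... Unused.
#' @export
tidy.mev_result <- function(x, ...) {
  tibble(component = seq_along(x$eigenvalues),
         eigenvalue = x$eigenvalues,
         proportion = x$eigenvalues / sum(x$eigenvalues))
}

#' @rdname tidy.mev_result
#' @export
glance.mev_result <- function(x, ...) {
  tibble(mev = x$mev, n_tokens = x$n_tokens,
         n_components = length(x$eigenvalues))
}

#' Tidy a fitted reference masked language model
#'
#' `tidy()` returns the per-step training-loss trajectory; `glance()` a
#' one-row summary of the architecture and final loss.
#'
#' @param x A `ref_mlm`.
#' @param ... Unused.
#' @export
tidy.ref_mlm <- function(x, ...) {
  tibble(step = seq_along(x$loss_log), loss = x$loss_log)
}

#' @rdname tidy.ref_mlm
#' @export
glance.ref_mlm <- function(x, ...) {
  tibble(k = x$spec$k, dim = x$spec$dim, n_layers = x$spec$n_layers,
         n_heads = x$spec$n_heads, context_len = x$spec$context_len,
         n_steps = length(x$loss_log),
         final_loss = utils::tail(x$loss_log, 1))
}

#' @rdname tidy.ref_mlm
#' @export
tidy.next_kmer_classifier <- function(x, ...) {
  tibble(step = seq_along(x$loss_log), loss = x$loss_log)
}

#' @rdname tidy.ref_mlm
#' @export
tidy.prom300_classifier <- function(x, ...) {
  tibble(step = seq_along(x$loss_log), loss = x$loss_log)
}

#' @rdname tidy.ref_mlm
#' @export
glance.next_kmer_classifier <- function(x, ...) {
  tibble(k_label = x$k_label, n_classes = 4L^x$k_label,
         encoder_k = x$spec$k, n_steps = length(x$loss_log),
         final_loss = utils::tail(x$loss_log, 1))
}

#' @rdname tidy.ref_mlm
#' @export
glance.prom300_classifier <- function(x, ...) {
  tibble(threshold = x$threshold, n_steps = length(x$loss_log),
         final_loss = utils::tail(x$loss_log, 1))
}
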
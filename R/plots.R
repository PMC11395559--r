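#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_point geom_hline
#'   geom_line labs theme_minimal scale_color_brewer facet_wrap
#' @export
ggplot2::autoplot

#' Plot per-offset masked-token accuracy
#'
#' Bar chart of prediction accuracy at each mask offset relative to the
#' chosen token, with the overall accuracy as a dashed line.
#'
#' @param object An `offset_accuracy`.
#' @param ... Unused.
#' @export
autoplot.offset_accuracy <- function(object, ...) {
  df <- tidy(object)
  ggplot(df, aes(x = factor(.data$offset), y = .data$accuracy)) +
    geom_col(fill = "steelblue") +
    geom_hline(yintercept = attr(object, "overall"), linetype = "dashed") +
    labs(x = "mask offset (tokens, relative to chosen token)",
         y = "accuracy",
         title = sprintf("Masked-token accuracy by offset (k = %s)",
                         attr(object, "k"))) +
    theme_minimal()
}

#' Plot a 2-D token-embedding projection
#'
#' Scatter of the UMAP coordinates coloured by the purine/pyrimidine
#' pattern of each token's central n-mer.
#'
#' @param object A `token_projection` from [umap_project()].
#' @param colour `"ry_pattern"` (default) or `"central"`.
#' @param ... Unused.
#' @export
autoplot.token_projection <- function(object, colour = "ry_pattern", ...) {
  ggplot(as_tibble(object),
         aes(x = .data$x, y = .data$y, colour = .data[[colour]])) +
    geom_point(size = 0.8, alpha = 0.8) +
    labs(title = "Token-embedding projection (UMAP)",
         colour = colour) +
    theme_minimal()
}

#' Plot a rank/probability profile
#'
#' Per masked position, the predicted probabilities of the top-ranked
#' tokens; the ground-truth token is highlighted.
#'
#' @param object A `rank_profile`.
#' @param max_rank Show at most this many ranks per position.
#' @param ... Unused.
#' @export
autoplot.rank_profile <- function(object, max_rank = 8L, ...) {
  df <- dplyr::filter(as_tibble(object), .data$rank <= max_rank)
  ggplot(df, aes(x = .data$rank, y = .data$probability,
                 fill = .data$is_truth)) +
    geom_col() +
    facet_wrap(~position, nrow = 1) +
    labs(x = "prediction rank", y = "probability",
         fill = "ground truth",
         title = "Masked-token prediction profile") +
    theme_minimal()
}

#' Plot training-loss trajectories
#'
#' @param x A `ref_mlm`, `next_kmer_classifier` or `prom300_classifier`.
#' @return A ggplot of per-step loss.
#' @export
plot_training_loss <- function(x) {
  df <- tidy(x)
  ggplot(df, aes(x = .data$step, y = .data$loss)) +
    geom_line(colour = "steelblue") +
    labs(x = "step", y = "training loss") +
    theme_minimal()
}

#' @importFrom rlang .data
NULL
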
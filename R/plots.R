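# ggplot2 displays for association results and selection.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Manhattan-style plot of score associations
#'
#' One point per score at the position of its target (when available) or in
#' score order, height `-log10(p)`; the core-gene selection threshold is
#' drawn as a dashed line.
#'
#' @param object A `trans_assoc` tibble.
#' @param p_core Threshold line (default 1e-9).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot trans_assoc
#' @export
autoplot.trans_assoc <- function(object, p_core = 1e-9, ...) {
  d <- tibble::as_tibble(object) |>
    dplyr::mutate(idx = dplyr::row_number(),
                  neglogp = -log10(pmax(.data$pvalue, 1e-300)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$idx, y = .data$neglogp)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = -log10(p_core), linetype = "dashed") +
    ggplot2::labs(x = "score", y = expression(-log[10] * p),
                  title = "Score associations with disease") +
    ggplot2::theme_minimal()
}

#' Diversity-versus-association display of the selection rule
#'
#' Plots each genome-wide trans-score by its effective eQTL count and
#' `-log10(p)`, with the two selection thresholds drawn; points in the upper
#' right quadrant are the diversity-criterion core-gene calls.
#'
#' @param object A `trans_pipeline`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot trans_pipeline
#' @export
autoplot.trans_pipeline <- function(object, ...) {
  d <- tibble::as_tibble(object$trans_assoc) |>
    dplyr::mutate(neglogp = -log10(pmax(.data$pvalue, 1e-300)),
                  called = .data$score_id %in% object$core_calls$target_id)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$effective_n, y = .data$neglogp,
                                  colour = .data$called)) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$pconfig$diversity_min,
                        linetype = "dashed") +
    ggplot2::geom_hline(yintercept = -log10(object$pconfig$p_core),
                        linetype = "dashed") +
    ggplot2::labs(x = "effective number of eQTLs", y = expression(-log[10] * p),
                  colour = "core call",
                  title = "Core-gene selection: diversity vs association") +
    ggplot2::theme_minimal()
}

#' Heatmap of control-group score correlations
#'
#' @param pairs Output of [score_correlation_matrix()].
#' @return A ggplot.
#' @export
plot_score_correlations <- function(pairs) {
  R <- attr(pairs, "R")
  d <- tibble::as_tibble(as.table(R), .name_repair = "minimal")
  names(d) <- c("score_a", "score_b", "r")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$score_a, y = .data$score_b,
                                  fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Score correlations among controls") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
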
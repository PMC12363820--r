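#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot selection frequencies
#' @param object A `qa_selection`.
#' @param ... Unused.
#' @return A ggplot: per-question selection frequency with the threshold line.
#' @export
autoplot.qa_selection <- function(object, ...) {
  df <- tidy(object)
  df$qid <- factor(df$qid, levels = df$qid[order(-df$frequency)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$qid, y = .data$frequency,
                                   fill = .data$selected)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = 2) +
    ggplot2::labs(x = NULL, y = "selection frequency") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, hjust = 1, vjust = 0.5))
}

#' Plot held-out score distribution
#' @param object A `qa_scores`.
#' @param ... Unused.
#' @return A ggplot histogram of per-target correlations.
#' @export
autoplot.qa_scores <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$r)) +
    ggplot2::geom_histogram(bins = 40) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "held-out correlation", y = "targets") +
    ggplot2::theme_minimal()
}

#' Plot the lag profile of ECoG encoding performance
#' @param object A `qa_lagmodels`.
#' @param ... Unused.
#' @return A ggplot: mean held-out correlation against lag, with word onset
#'   marked.
#' @export
autoplot.qa_lagmodels <- function(object, ...) {
  df <- dplyr::summarise(dplyr::group_by(tidy(object), .data$lag),
                         r = mean(.data$r), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lag, y = .data$r)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "lag from word onset (ms)", y = "mean held-out correlation") +
    ggplot2::theme_minimal()
}
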
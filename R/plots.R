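#' Plot ERI scores by rank
#'
#' Rank-ordered scatter of per-feature ERI scores; for a selection result
#' the permutation cutoff is drawn and significant features highlighted.
#'
#' @param object An `eri_fit` or `eri_select`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.eri_fit <- function(object, ...) {
  ggplot2::ggplot(object$table,
                  ggplot2::aes(x = .data$rank, y = .data$eri)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "rank", y = "ERI",
                  title = "Early Response Index by rank") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.eri_fit
#' @export
autoplot.eri_select <- function(object, ...) {
  ggplot2::ggplot(object$table,
                  ggplot2::aes(x = .data$rank, y = .data$eri,
                               colour = .data$significant)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_hline(yintercept = object$threshold$cutoff,
                        linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#D55E00",
                                            `FALSE` = "grey40")) +
    ggplot2::labs(x = "rank", y = "ERI", colour = "significant",
                  title = sprintf("ERI selection (cutoff %.4g, %d permutation trials)",
                                  object$threshold$cutoff,
                                  object$threshold$n_trials)) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.eri_fit
#' @export
autoplot.eri_null <- function(object, ...) {
  df <- tibble::as_tibble(unclass(object))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$max_eri)) +
    ggplot2::geom_histogram(bins = max(5, nrow(df) %/% 2),
                            fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = max(df$max_eri), linetype = "dashed") +
    ggplot2::labs(x = "per-trial maximum ERI", y = "trials",
                  title = "Permutation null of the maximum ERI") +
    ggplot2::theme_minimal()
}
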
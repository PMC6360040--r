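#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Broom-style tidiers for plateletscore result objects
#'
#' `tidy()` returns one row per term/subject/variate; `glance()` a one-row
#' model summary.  Available for cumulative scores (`ps_cum_score`),
#' logistic fits (`ps_logistic`), discriminant rankings (`ps_lda_rank`),
#' canonical summaries (`ps_canonical`) and classifier panels
#' (`ps_panel`).
#'
#' @param x A plateletscore result object.
#' @param ... Unused.
#' @name tidy-plateletscore
NULL

#' Classifier-panel accuracy plot
#'
#' @param object A `ps_panel` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ps_panel
#' @export
autoplot.ps_panel <- function(object, ...) {
  ggplot2::ggplot(object$accuracy,
                  ggplot2::aes(x = stats::reorder(.data$method,
                                                  .data$percent_correct),
                               y = .data$percent_correct)) +
    ggplot2::geom_col(width = 0.6) +
    ggplot2::geom_hline(yintercept = 50, linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "% correct (vs true allocation)") +
    ggplot2::theme_minimal()
}
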
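#' Variable-importance bar chart
#'
#' Horizontal bars of relative influence for all predictors at or above
#' the display cutoff (0.5% by default), coloured by predictor group.
#'
#' @param object A fitted `brt`.
#' @param vi_cutoff Minimum VI score (percent) to display.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.brt <- function(object, vi_cutoff = 0.5, ...) {
  vi <- dplyr::filter(tidy(object), .data$vi >= vi_cutoff)
  ggplot2::ggplot(vi, ggplot2::aes(
    x = .data$vi,
    y = stats::reorder(.data$term, .data$vi),
    fill = .data$group
  )) +
    ggplot2::geom_col() +
    ggplot2::labs(
      x = "Variable importance (% of model deviance)", y = NULL,
      fill = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Partial-dependence panels
#'
#' One panel per predictor: fitted response against the predictor with all
#' other predictors held at their observed values (averaged).
#'
#' @param pd A partial-dependence tibble (`term`, `value`, `yhat`) as
#'   produced by [partial_dependence()], possibly row-bound over terms.
#' @return A ggplot object with one facet per term.
#' @export
plot_partial_dependence <- function(pd) {
  pd <- dplyr::mutate(pd, value_num = suppressWarnings(
    as.numeric(as.character(.data$value))
  ))
  if (anyNA(pd$value_num)) {
    ggplot2::ggplot(pd, ggplot2::aes(x = as.character(.data$value),
                                     y = .data$yhat)) +
      ggplot2::geom_point() +
      ggplot2::facet_wrap(~term, scales = "free_x") +
      ggplot2::labs(x = NULL, y = "Partial dependence") +
      ggplot2::theme_minimal() +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                         hjust = 1))
  } else {
    ggplot2::ggplot(pd, ggplot2::aes(x = .data$value_num, y = .data$yhat)) +
      ggplot2::geom_line() +
      ggplot2::facet_wrap(~term, scales = "free_x") +
      ggplot2::labs(x = NULL, y = "Partial dependence") +
      ggplot2::theme_minimal()
  }
}

#' @describeIn run_pipeline Plot method for the report: the
#'   variable-importance chart restricted to the configured cutoff.
#' @param object An `analysis_report`.
#' @param ... Unused.
#' @export
autoplot.analysis_report <- function(object, ...) {
  autoplot(object$model, vi_cutoff = object$config$vi_cutoff)
}
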
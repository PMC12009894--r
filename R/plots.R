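# ggplot2 displays for sweep results and validation output.

#' Plot a flanking-window sweep
#'
#' Accuracy (and the number of usable SNPs, as point size) against the
#' half-window width.
#'
#' @param object a `cn_window_sweep` tibble from [window_sweep()].
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot cn_window_sweep
#' @export
autoplot.cn_window_sweep <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$window_kb, y = .data$accuracy)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(size = .data$n_snps)) +
    ggplot2::scale_size_continuous(name = "SNPs in window") +
    ggplot2::labs(
      x = "flanking half-window (kb)", y = "internal validation accuracy",
      title = "Imputation accuracy by flanking window"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a call-threshold sweep
#'
#' Call rate and accuracy-among-called against the call threshold — the
#' trade-off used to choose an operating point (0.5 by default in
#' [predict.cnbag()]).
#'
#' @param object a `cn_ct_sweep` tibble from [ct_sweep()].
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot cn_ct_sweep
#' @export
autoplot.cn_ct_sweep <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object[, c("ct", "call_rate", "accuracy")],
    cols = c("call_rate", "accuracy"),
    names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$ct, y = .data$value, colour = .data$metric
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "call threshold", y = NULL, colour = NULL,
      title = "Call rate vs accuracy across call thresholds"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a validation confusion table
#'
#' Tile display of the total-CN confusion counts from
#' [internal_validation()].
#'
#' @param object a `cn_validation` object.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot cn_validation
#' @export
autoplot.cn_validation <- function(object, ...) {
  m <- unclass(object$confusion)
  df <- tibble::as_tibble(as.data.frame.table(m, responseName = "count"))
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$predicted, y = .data$truth, fill = .data$count
  )) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), colour = "white") +
    ggplot2::labs(
      x = "predicted total CN", y = "true total CN",
      title = paste0("Confusion (", object$mode, " validation)")
    ) +
    ggplot2::theme_minimal()
}
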
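#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the training history of a fit
#'
#' @param x an `ssp_fit`.
#' @param ... unused.
#' @return long tibble with columns `epoch`, `metric`, `value`.
#' @export
tidy.ssp_fit <- function(x, ...) {
  tidyr::pivot_longer(x$history, -"epoch", names_to = "metric",
                      values_to = "value")
}

#' One-row summary of a fit
#'
#' @param x an `ssp_fit`.
#' @param ... unused.
#' @return tibble with the final/best accuracies, parameter count and
#'   wall time.
#' @export
glance.ssp_fit <- function(x, ...) {
  h <- x$history
  tibble::tibble(
    epochs = nrow(h),
    best_epoch = x$best_epoch,
    train_loss = h$train_loss[nrow(h)],
    train_accuracy = h$train_accuracy[nrow(h)],
    val_accuracy = h$val_accuracy[nrow(h)],
    n_parameters = n_parameters(x$model),
    wall_time = x$wall_time
  )
}

#' Tidy a metrics report
#'
#' @param x a `metrics_report`.
#' @param ... unused.
#' @return the per-record tibble (without the label strings).
#' @export
tidy.metrics_report <- function(x, ...) {
  x$per_record[, c("id", "length", "accuracy", "sov99", "miauc")]
}

#' @rdname tidy.metrics_report
#' @param x a `metrics_report`.
#' @export
glance.metrics_report <- function(x, ...) x$summary

#' Training-curve plot
#'
#' @param object an `ssp_fit`.
#' @param ... unused.
#' @return a ggplot: loss and accuracy traces over epochs.
#' @export
autoplot.ssp_fit <- function(object, ...) {
  df <- tidy(object)
  df <- df[!is.na(df$value), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$metric), scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL) +
    ggplot2::theme_minimal()
}

#' Per-record metric plot
#'
#' @param object a `metrics_report`.
#' @param ... unused.
#' @return a ggplot: per-record accuracy and SOV99 against chain length.
#' @export
autoplot.metrics_report <- function(object, ...) {
  df <- tidyr::pivot_longer(tidy(object), c("accuracy", "sov99", "miauc"),
                            names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$length, y = .data$value)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::facet_wrap(ggplot2::vars(.data$metric), scales = "free_y") +
    ggplot2::labs(x = "chain length (residues)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Sweep surface plot
#'
#' @param sweep_tbl the tibble returned by [sweep_scales_alpha()].
#' @return a ggplot tile plot of accuracy over the (scales, alpha) grid.
#' @export
plot_sweep <- function(sweep_tbl) {
  ggplot2::ggplot(sweep_tbl,
                  ggplot2::aes(x = factor(.data$alpha),
                               y = factor(.data$scales,
                                          levels = unique(.data$scales)),
                               fill = .data$accuracy)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.1f", .data$accuracy)), color = "white") +
    ggplot2::labs(x = "alpha", y = "scales", fill = "ACC (%)") +
    ggplot2::theme_minimal()
}
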
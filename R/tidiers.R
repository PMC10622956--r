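#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted network
#'
#' One row per architecture layer with its traced output shape and
#' trainable parameter count.
#'
#' @param x A fitted `eca_deepnet`.
#' @param ... Unused.
#' @return A tibble with columns `layer`, `kind`, `output` and
#'   `parameters`.
#' @export
tidy.eca_deepnet <- function(x, ...) {
  tibble::tibble(layer = x$spec$layer, kind = x$spec$kind,
                 output = x$spec$output_label,
                 parameters = x$spec$parameters)
}

#' Glance at a fitted network
#'
#' @param x A fitted `eca_deepnet`.
#' @param ... Unused.
#' @return One-row tibble: channel/class counts, total parameters, epochs
#'   run, best epoch, final training loss/accuracy and the seed.
#' @export
glance.eca_deepnet <- function(x, ...) {
  h <- x$history
  tibble::tibble(
    channels = attr(x$spec, "channels"),
    classes = attr(x$spec, "classes"),
    n_parameters = count_parameters(x$spec),
    epochs = nrow(h),
    best_epoch = x$best_epoch,
    train_loss = h$train_loss[nrow(h)],
    train_acc = h$train_acc[nrow(h)],
    seed = x$seed
  )
}

#' @export
print.eca_deepnet <- function(x, ...) {
  cat("Fitted attention-augmented DeepNet (", attr(x$spec, "channels"),
      " channels, ", attr(x$spec, "classes"), " classes, ",
      count_parameters(x$spec), " parameters)\n", sep = "")
  h <- x$history
  cat("Trained ", nrow(h), " epoch(s); best epoch ", x$best_epoch,
      "; final train loss ", sprintf("%.4f", h$train_loss[nrow(h)]),
      ", accuracy ", sprintf("%.3f", h$train_acc[nrow(h)]), "\n", sep = "")
  invisible(x)
}

#' Plot a channel ranking
#'
#' Bar chart of mean attention weight per electrode, in ranking order.
#'
#' @param object A `channel_ranking`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.channel_ranking <- function(object, ...) {
  df <- as.data.frame(object)
  df$channel <- factor(df$channel, levels = df$channel)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$channel, y = .data$weight)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "mean attention weight",
                  title = "Channel importance ranking") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot a training history
#'
#' Loss and accuracy per epoch for the training and validation splits.
#'
#' @param object A fitted `eca_deepnet`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.eca_deepnet <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history, -"epoch",
                           names_to = c("split", "metric"), names_sep = "_",
                           values_to = "value")
  ggplot2::ggplot(stats::na.omit(h),
                  ggplot2::aes(x = .data$epoch, y = .data$value,
                               colour = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(y = NULL, title = "Training history") +
    ggplot2::theme_minimal()
}

#' Plot an accuracy/latency channel sweep
#'
#' Held-out accuracy against subset size.
#'
#' @param object A [channel_sweep()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.channel_sweep <- function(object, ...) {
  ggplot2::ggplot(as.data.frame(object[, c("n_c", "accuracy")]),
                  ggplot2::aes(x = .data$n_c, y = .data$accuracy)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "channels retained", y = "held-out accuracy",
                  title = "Accuracy across channel-subset sizes") +
    ggplot2::theme_minimal()
}
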
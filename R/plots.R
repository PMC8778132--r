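#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Training curves
#'
#' Loss and accuracy for the training and validation splits, one panel per
#' quantity, across epochs.
#'
#' @param object A `res_bilstm_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.res_bilstm_fit <- function(object, ...) {
  long <- tidy(object)
  long$split <- ifelse(grepl("^val_", long$metric), "validation", "training")
  long$quantity <- sub("^val_", "", long$metric)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value,
                                     colour = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$quantity), scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Confusion-matrix heatmap
#'
#' @param object A [confusion_matrix()].
#' @param ... Unused.
#' @return A ggplot with true classes on rows and predicted on columns.
#' @export
autoplot.confusion_matrix <- function(object, ...) {
  df <- as.data.frame(as.table(unclass(object)))
  names(df) <- c("truth", "predicted", "n")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$truth,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), size = 3) +
    ggplot2::scale_y_discrete(limits = rev(rownames(object))) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "predicted", y = "true", fill = "count") +
    ggplot2::theme_minimal()
}

#' Plot a stretch of raw recordings
#'
#' Faceted channel traces for a time span of one subject's stream, coloured
#' by activity — handy for eyeballing what the synthetic generator (or a
#' reader) produced.
#'
#' @param data A recordings tibble.
#' @param subject_id Subject to plot; default the first present.
#' @param max_seconds Truncate to this many seconds; default 30.
#' @return A ggplot.
#' @export
plot_recordings <- function(data, subject_id = NULL, max_seconds = 30) {
  channels <- resolve_channels(data, NULL)
  sr <- imu_sample_rate(data) %||% 50
  if (is.null(subject_id)) subject_id <- data$subject[1]
  df <- data[data$subject == subject_id, , drop = FALSE]
  df <- df[seq_len(min(nrow(df), max_seconds * sr)), , drop = FALSE]
  df$time <- (seq_len(nrow(df)) - 1) / sr
  long <- tidyr::pivot_longer(df, dplyr::all_of(channels),
                              names_to = "channel", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value,
                                     colour = .data$activity)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(ggplot2::vars(.data$channel), scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL, colour = "activity") +
    ggplot2::theme_minimal()
}
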
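#' Per-channel corpus statistics for standardization
#'
#' Computes, for every sensor channel, the mean and the population standard
#' deviation (divide by N, not N - 1) over the concatenation of all samples
#' in `data`. These are the statistics used by [standardize_channels()] to
#' z-score each channel before windowing.
#'
#' @param data A recordings tibble (see [imu_recordings()]).
#' @param channels Channel columns; defaults to the channels stored on `data`.
#'
#' @return A tibble with columns `channel`, `mean`, `sd`.
#' @examples
#' x <- imu_recordings(
#'   data.frame(subject = "s", recording = 1L, activity = "sitting",
#'              ax = c(2, 4, 6)),
#'   sample_rate = 50
#' )
#' channel_stats(x) # mean 4, population sd sqrt(8/3)
#' @export
channel_stats <- function(data, channels = NULL) {
  channels <- resolve_channels(data, channels)
  if (nrow(data) == 0) stop("no samples: cannot compute channel statistics", call. = FALSE)
  purrr::map_dfr(channels, function(ch) {
    v <- data[[ch]]
    if (anyNA(v)) stop("channel `", ch, "` contains missing values", call. = FALSE)
    m <- mean(v)
    tibble::tibble(channel = ch, mean = m, sd = sqrt(mean((v - m)^2)))
  })
}

#' Standardize sensor channels to zero mean and unit variance
#'
#' Replaces each channel value by `(x - mean) / sd` using per-channel
#' statistics, typically from [channel_stats()] over the whole corpus.
#' Labels, sample rate and bookkeeping columns are untouched. A channel with
#' zero standard deviation is degenerate (constant signal) and is rejected.
#'
#' @param data A recordings tibble.
#' @param stats A tibble with columns `channel`, `mean`, `sd`, covering every
#'   channel of `data`. Defaults to statistics of `data` itself.
#'
#' @return `data` with standardized channel values (dimensionless).
#' @export
standardize_channels <- function(data, stats = NULL) {
  channels <- resolve_channels(data, NULL)
  if (is.null(stats)) stats <- channel_stats(data, channels)
  stopifnot(all(c("channel", "mean", "sd") %in% names(stats)))
  absent <- setdiff(channels, stats$channel)
  if (length(absent) > 0) {
    stop("no statistics for channel(s): ", paste(absent, collapse = ", "), call. = FALSE)
  }
  zero_sd <- stats$channel[stats$sd <= 0 & stats$channel %in% channels]
  if (length(zero_sd) > 0) {
    stop("zero standard deviation in channel(s): ",
         paste(zero_sd, collapse = ", "),
         "; constant channels cannot be standardized", call. = FALSE)
  }
  for (ch in channels) {
    i <- match(ch, stats$channel)
    data[[ch]] <- (data[[ch]] - stats$mean[i]) / stats$sd[i]
  }
  data
}

#' Majority label for one window
#'
#' A window that crosses an activity boundary contains more than one label;
#' the window-level label is the majority label, with ties broken by the
#' label of the centre sample (index `floor(L/2) + 1` in 1-based terms).
#'
#' @param labels Per-sample labels of one window (length L >= 1).
#' @return A single label.
#' @export
assign_window_label <- function(labels) {
  if (length(labels) == 0) stop("cannot label an empty window", call. = FALSE)
  labels <- as.character(labels)
  counts <- table(labels)
  top <- names(counts)[counts == max(counts)]
  if (length(top) == 1) return(top)
  mid <- labels[[floor(length(labels) / 2) + 1L]]
  if (mid %in% top) mid else top[[1L]]
}

#' Segment recordings into fixed-length overlapping windows
#'
#' Slides a window of `window_length` samples along every recording with
#' start indices 0, s, 2s, ... where `s = round(window_length * (1 -
#' overlap))`; with the default 50% overlap and a 100-sample window the step
#' is 50 samples. Only fully contained windows are emitted, windows never
#' span two recordings, and each window is labelled by majority vote over
#' its per-sample labels ([assign_window_label()]). A recording shorter than
#' the window contributes no windows.
#'
#' @param data A recordings tibble, normally already standardized.
#' @param window_length Window length L in samples (>= 1).
#' @param overlap Overlap fraction in `[0, 1)`; default 0.5.
#' @param channels Channel columns; defaults to those stored on `data`.
#' @param class_levels Optional fixed ordering of activity classes; defaults
#'   to the sorted set of labels present.
#'
#' @return A `windowed_dataset`: a list with elements `windows` (an
#'   `n x L x C` array), `labels` (factor of length n), `window_length`,
#'   `channels`, `class_levels` and a `provenance` tibble (subject,
#'   recording, 1-based start index per window).
#' @export
segment_windows <- function(data, window_length, overlap = 0.5,
                            channels = NULL, class_levels = NULL) {
  channels <- resolve_channels(data, channels)
  stopifnot(length(window_length) == 1, window_length >= 1)
  if (!(overlap >= 0 && overlap < 1)) {
    stop("`overlap` must be in [0, 1)", call. = FALSE)
  }
  window_length <- as.integer(window_length)
  step <- max(1L, as.integer(round(window_length * (1 - overlap))))

  pieces <- dplyr::group_split(dplyr::group_by(data, .data$subject, .data$recording))
  win_list <- list()
  prov <- list()
  lab <- character(0)
  for (piece in pieces) {
    n <- nrow(piece)
    if (n < window_length) next
    starts <- seq.int(1L, n - window_length + 1L, by = step)
    mat <- as.matrix(piece[channels])
    for (s0 in starts) {
      idx <- s0:(s0 + window_length - 1L)
      w <- mat[idx, , drop = FALSE]
      if (!all(is.finite(w))) {
        stop("non-finite values in window starting at sample ", s0,
             " of recording ", piece$recording[1], call. = FALSE)
      }
      win_list[[length(win_list) + 1L]] <- w
      lab[[length(lab) + 1L]] <- assign_window_label(piece$activity[idx])
      prov[[length(prov) + 1L]] <- tibble::tibble(
        subject = piece$subject[1], recording = piece$recording[1], start = s0
      )
    }
  }

  if (is.null(class_levels)) class_levels <- sort(unique(data$activity))
  n_win <- length(win_list)
  windows <- array(0, dim = c(n_win, window_length, length(channels)))
  for (i in seq_len(n_win)) windows[i, , ] <- win_list[[i]]
  unknown <- setdiff(unique(lab), class_levels)
  if (length(unknown) > 0) {
    stop("window label(s) outside `class_levels`: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  structure(
    list(
      windows = windows,
      labels = factor(lab, levels = class_levels),
      window_length = window_length,
      channels = channels,
      class_levels = class_levels,
      provenance = if (n_win > 0) dplyr::bind_rows(prov) else
        tibble::tibble(subject = character(), recording = integer(), start = integer())
    ),
    class = "windowed_dataset"
  )
}

#' @export
print.windowed_dataset <- function(x, ...) {
  cat(sprintf(
    "# windowed dataset: %d windows of %d samples x %d channels, %d classes\n",
    dim(x$windows)[1], x$window_length, length(x$channels),
    length(x$class_levels)
  ))
  print(table(x$labels))
  invisible(x)
}

#' @export
as_tibble.windowed_dataset <- function(x, ...) {
  dplyr::mutate(x$provenance, label = x$labels)
}

# Number of windows for a stream of n samples (closed form used by tests).
expected_window_count <- function(n, window_length, step) {
  if (n < window_length) 0L else as.integer((n - window_length) %/% step + 1L)
}
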
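#' Labelled IMU recordings as a tidy tibble
#'
#' The package represents raw sensor streams as one long tibble with one row
#' per sample and one column per sensor channel, plus three bookkeeping
#' columns: `subject` (who wore the sensor), `recording` (a contiguous
#' recorded session; windows never cross recording boundaries) and
#' `activity` (the per-sample class label). The sampling rate and the set of
#' channel columns are carried as attributes so that downstream verbs do not
#' need them respelled at every call.
#'
#' @param data A data frame with columns `subject`, `recording`, `activity`
#'   and one numeric column per channel.
#' @param channels Character vector naming the channel columns, in order.
#'   Defaults to every numeric column that is not a bookkeeping column.
#' @param sample_rate Sampling rate in Hz (samples per second).
#'
#' @return A tibble of class `imu_tbl` with attributes `channels` and
#'   `sample_rate`.
#' @examples
#' x <- imu_recordings(
#'   data.frame(
#'     subject = "s1", recording = 1L, activity = "walking",
#'     ax = rnorm(10), ay = rnorm(10), az = rnorm(10)
#'   ),
#'   sample_rate = 50
#' )
#' imu_channels(x)
#' @export
imu_recordings <- function(data, channels = NULL, sample_rate) {
  stopifnot(is.data.frame(data))
  required <- c("subject", "recording", "activity")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(channels)) {
    candidates <- setdiff(names(data), required)
    channels <- candidates[vapply(data[candidates], is.numeric, logical(1))]
  }
  if (length(channels) < 1) stop("at least one channel column is required", call. = FALSE)
  absent <- setdiff(channels, names(data))
  if (length(absent) > 0) {
    stop("channel column(s) not found: ", paste(absent, collapse = ", "), call. = FALSE)
  }
  if (!is.numeric(sample_rate) || length(sample_rate) != 1 || sample_rate <= 0) {
    stop("`sample_rate` must be a single positive number", call. = FALSE)
  }
  out <- tibble::as_tibble(data)
  attr(out, "channels") <- channels
  attr(out, "sample_rate") <- as.numeric(sample_rate)
  class(out) <- c("imu_tbl", class(out))
  out
}

#' @rdname imu_recordings
#' @param x An `imu_tbl` (or any data frame; then `NULL` is returned for
#'   attributes that were never set).
#' @export
imu_channels <- function(x) attr(x, "channels")

#' @rdname imu_recordings
#' @export
imu_sample_rate <- function(x) attr(x, "sample_rate")

# Resolve channels/sample rate from explicit arguments or attributes.
resolve_channels <- function(data, channels) {
  if (is.null(channels)) channels <- imu_channels(data)
  if (is.null(channels)) {
    stop("`channels` not given and not stored on `data`; pass them explicitly",
         call. = FALSE)
  }
  absent <- setdiff(channels, names(data))
  if (length(absent) > 0) {
    stop("channel column(s) not found: ", paste(absent, collapse = ", "), call. = FALSE)
  }
  channels
}

#' @export
print.imu_tbl <- function(x, ...) {
  ch <- imu_channels(x)
  sr <- imu_sample_rate(x)
  cat(sprintf(
    "# IMU recordings: %d samples, %d recording(s), %d subject(s), %s Hz\n",
    nrow(x), dplyr::n_distinct(x$recording), dplyr::n_distinct(x$subject),
    format(sr)
  ))
  cat("# channels:", paste(ch, collapse = ", "), "\n")
  NextMethod()
}
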
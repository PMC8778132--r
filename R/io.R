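#' Manifest describing an on-disk labelled IMU dataset
#'
#' @param format One of `"wisdm"`, `"pamap2"`, `"csv"`.
#' @param sample_rate Hz.
#' @param channels Channel column names (for `"csv"`) or derived names.
#' @param subject_col,label_col Column names holding subject and label (for
#'   `"csv"`).
#' @param subjects Optional subject subset to read.
#' @return A `dataset_manifest` list.
#' @export
dataset_manifest <- function(format = c("csv", "wisdm", "pamap2"),
                             sample_rate = NULL, channels = NULL,
                             subject_col = "subject", label_col = "activity",
                             subjects = NULL) {
  format <- match.arg(format)
  if (is.null(sample_rate)) {
    sample_rate <- switch(format, wisdm = 20, pamap2 = 100, csv = 50)
  }
  structure(list(format = format, sample_rate = sample_rate,
                 channels = channels, subject_col = subject_col,
                 label_col = label_col, subjects = subjects),
            class = "dataset_manifest")
}

#' Read WISDM-style raw accelerometer text
#'
#' Parses lines of the form `user,activity,timestamp,x,y,z;` (20 Hz
#' smartphone accelerometer). Malformed lines — missing fields, non-numeric
#' values, missing `;` terminator, blank lines — are skipped and counted; if
#' more than half of the nonempty lines are malformed, reading fails.
#' Contiguous runs of one (user, activity) pair become one recording, so
#' windows never straddle an activity change in the source file.
#'
#' @param path Path to the raw text file.
#' @param sample_rate Hz; the format's standard rate is 20.
#' @return A recordings tibble with channels `ax`, `ay`, `az` and an
#'   attribute `skipped` giving the number of malformed lines.
#' @export
read_wisdm <- function(path, sample_rate = 20) {
  if (!file.exists(path)) stop("cannot read `", path, "`", call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  # one well-formed record, terminated by ';' (tolerating trailing ',;')
  rx <- "^([^,]+),([^,]+),([0-9]+),(-?[0-9.eE+-]+),(-?[0-9.eE+-]+),(-?[0-9.eE+-]+),?;$"
  ok <- grepl(rx, lines)
  skipped <- sum(!ok)
  if (length(lines) > 0 && skipped > length(lines) / 2) {
    stop("more than half of the lines in `", path, "` are malformed", call. = FALSE)
  }
  m <- regmatches(lines[ok], regexec(rx, lines[ok]))
  if (length(m) == 0) {
    out <- tibble::tibble(subject = character(), recording = integer(),
                          activity = character(), ax = numeric(),
                          ay = numeric(), az = numeric())
  } else {
    fields <- do.call(rbind, m)
    vals <- suppressWarnings(cbind(as.numeric(fields[, 5]),
                                   as.numeric(fields[, 6]),
                                   as.numeric(fields[, 7])))
    good <- stats::complete.cases(vals)
    skipped <- skipped + sum(!good)
    out <- tibble::tibble(
      subject = fields[good, 2],
      activity = fields[good, 3],
      ax = vals[good, 1], ay = vals[good, 2], az = vals[good, 3]
    )
    out <- dplyr::mutate(
      out,
      recording = cumsum(
        dplyr::row_number() == 1 |
          .data$subject != dplyr::lag(.data$subject, default = "") |
          .data$activity != dplyr::lag(.data$activity, default = "")
      )
    )
    out <- dplyr::relocate(out, "subject", "recording", "activity")
  }
  res <- imu_recordings(out, channels = c("ax", "ay", "az"),
                        sample_rate = sample_rate)
  attr(res, "skipped") <- skipped
  res
}

# PAMAP2 protocol activity ids (the 12 scripted activities)
pamap2_protocol_ids <- c(1, 2, 3, 4, 5, 6, 7, 12, 13, 16, 17, 24)

pamap2_activity_names <- c(
  "1" = "lying", "2" = "sitting", "3" = "standing", "4" = "walking",
  "5" = "running", "6" = "cycling", "7" = "nordic_walking",
  "12" = "ascending_stairs", "13" = "descending_stairs",
  "16" = "vacuum_cleaning", "17" = "ironing", "24" = "rope_jumping"
)

#' Read PAMAP2 protocol `.dat` files
#'
#' Space-separated files with 54 columns: timestamp, activity id, heart
#' rate, then three 17-column IMU blocks (hand, chest, ankle). From each IMU
#' the wide-range (±16 g) 3-axis accelerometer and the 3-axis gyroscope are
#' kept — 18 channels in total; the ±6 g accelerometer is skipped because it
#' saturates during running. Rows with activity id 0 (transient between
#' activities) or outside the 12 protocol activities are dropped, missing
#' values are linearly interpolated within each recording, and recordings
#' are split at every activity change.
#'
#' @param path A directory containing `subjectNNN.dat` files, or a character
#'   vector of file paths.
#' @param subjects Optional integer vector of subject numbers to read (e.g.
#'   `c(5, 6)` for a held-out validation pair).
#' @param sample_rate Hz; the format's standard rate is 100.
#' @return A recordings tibble with 18 channels
#'   (`hand_ax`, ..., `ankle_gz`).
#' @export
read_pamap2 <- function(path, subjects = NULL, sample_rate = 100) {
  files <- if (length(path) == 1 && dir.exists(path)) {
    list.files(path, pattern = "^subject[0-9]+\\.dat$", full.names = TRUE)
  } else {
    path
  }
  if (length(files) == 0) stop("no PAMAP2 .dat files found", call. = FALSE)
  subj_num <- as.integer(gsub("\\D", "", basename(files)))
  if (!is.null(subjects)) {
    keep <- subj_num %% 100 %in% subjects | subj_num %in% subjects
    files <- files[keep]; subj_num <- subj_num[keep]
    if (length(files) == 0) stop("no files match `subjects`", call. = FALSE)
  }
  imu_cols <- function(block_start) block_start + c(2:4, 8:10) # acc16g + gyro
  starts <- c(hand = 3, chest = 20, ankle = 37)               # col after which block starts
  chan_names <- as.vector(t(outer(names(starts), c("ax", "ay", "az", "gx", "gy", "gz"),
                                  paste, sep = "_")))
  pieces <- list()
  rec_id <- 0L
  for (i in seq_along(files)) {
    dat <- utils::read.table(files[i], header = FALSE, na.strings = "NaN")
    if (ncol(dat) < 54) {
      stop("`", files[i], "` has ", ncol(dat), " columns; 54 expected", call. = FALSE)
    }
    act <- dat[[2]]
    keep <- act %in% pamap2_protocol_ids
    dat <- dat[keep, , drop = FALSE]
    act <- act[keep]
    if (nrow(dat) == 0) next
    sel <- unlist(lapply(starts, imu_cols), use.names = FALSE)
    sig <- as.matrix(dat[, sel, drop = FALSE])
    colnames(sig) <- chan_names
    run <- cumsum(c(TRUE, act[-1] != act[-length(act)]))
    for (r in unique(run)) {
      idx <- which(run == r)
      block <- sig[idx, , drop = FALSE]
      # linear interpolation of missing values, extending at the ends
      block <- apply(block, 2, function(v) {
        if (anyNA(v) && !all(is.na(v))) {
          v <- zoo::na.approx(v, na.rm = FALSE, rule = 2)
        }
        v
      })
      block <- matrix(block, nrow = length(idx),
                      dimnames = list(NULL, chan_names))
      if (anyNA(block)) next  # a channel entirely missing in this run
      rec_id <- rec_id + 1L
      df <- tibble::as_tibble(as.data.frame(block))
      pieces[[length(pieces) + 1L]] <- dplyr::bind_cols(
        tibble::tibble(
          subject = sprintf("subject%d", subj_num[i] %% 100),
          recording = rec_id,
          activity = unname(pamap2_activity_names[as.character(act[idx[1]])])
        ),
        df
      )
    }
  }
  if (length(pieces) == 0) stop("no usable protocol-activity rows found", call. = FALSE)
  imu_recordings(dplyr::bind_rows(pieces), channels = chan_names,
                 sample_rate = sample_rate)
}

#' Read a generic labelled IMU CSV
#'
#' A CSV with a header row naming a subject column, a label column and one
#' column per channel — the dialect [write_imu_csv()] produces, so synthetic
#' and real corpora go through the same path. Recordings are split per
#' subject and contiguous label run (unless the file already carries a
#' `recording` column, which is respected).
#'
#' @param path CSV path.
#' @param manifest A [dataset_manifest()]; defaults to `format = "csv"`,
#'   50 Hz, channels = every numeric non-bookkeeping column.
#' @return A recordings tibble.
#' @export
read_imu_csv <- function(path, manifest = dataset_manifest("csv")) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c(manifest$subject_col, manifest$label_col, manifest$channels)
  absent <- setdiff(need, names(df))
  if (length(absent) > 0) {
    stop("column(s) declared in the manifest are missing: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  names(df)[match(manifest$subject_col, names(df))] <- "subject"
  names(df)[match(manifest$label_col, names(df))] <- "activity"
  df$subject <- as.character(df$subject)
  df$activity <- as.character(df$activity)
  if (!"recording" %in% names(df)) {
    if (nrow(df) == 0) {
      df$recording <- integer(0)
    } else {
      df$recording <- cumsum(
        seq_len(nrow(df)) == 1 |
          df$subject != dplyr::lag(df$subject, default = "") |
          df$activity != dplyr::lag(df$activity, default = "")
      )
    }
  }
  df <- dplyr::relocate(df, "subject", "recording", "activity")
  if (!is.null(manifest$subjects)) {
    df <- df[df$subject %in% manifest$subjects, , drop = FALSE]
  }
  imu_recordings(df, channels = manifest$channels,
                 sample_rate = manifest$sample_rate)
}

#' @rdname read_imu_csv
#' @param data A recordings tibble to write.
#' @export
write_imu_csv <- function(data, path) {
  readr::write_csv(data, path)
  invisible(path)
}

WINDOW_CONTAINER_VERSION <- 1L

#' Persist / restore a windowed dataset
#'
#' Lossless round-trip of the window tensor, labels, class vocabulary,
#' channel names and provenance through a single versioned file (R's native
#' serialization). Loading rejects a container whose version or internal
#' shapes are inconsistent.
#'
#' @param dataset A `windowed_dataset`.
#' @param path File path.
#' @return `save_windows` invisibly returns `path`; `load_windows` returns
#'   the `windowed_dataset`.
#' @export
save_windows <- function(dataset, path) {
  stopifnot(inherits(dataset, "windowed_dataset"))
  saveRDS(list(version = WINDOW_CONTAINER_VERSION, payload = unclass(dataset)),
          path)
  invisible(path)
}

#' @rdname save_windows
#' @export
load_windows <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$version, WINDOW_CONTAINER_VERSION)) {
    stop("window container version ", obj$version %||% "<missing>",
         " not supported (expected ", WINDOW_CONTAINER_VERSION, ")",
         call. = FALSE)
  }
  p <- obj$payload
  d <- dim(p$windows)
  if (length(d) != 3 || d[2] != p$window_length || d[3] != length(p$channels) ||
      d[1] != length(p$labels)) {
    stop("window container is internally inconsistent", call. = FALSE)
  }
  structure(p, class = "windowed_dataset")
}
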
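#' Generative model for one activity class
#'
#' Each channel of an activity is modelled as a constant gravity/orientation
#' offset plus a sum of sinusoidal harmonics (the gait cycle and its
#' overtones), Gaussian noise, and — for dynamic activities — occasional
#' short spikes at Poisson-distributed times, mimicking the irregular
#' transients that real shank-mounted IMUs record.
#'
#' @param offset Length-C baseline per channel (accelerometer channels in g,
#'   gyroscope channels in deg/s).
#' @param harmonics A data frame with columns `channel` (index), `amp`,
#'   `freq` (Hz), `phase` (radians); may be empty for static postures.
#' @param noise_sd Length-C (or scalar) Gaussian noise standard deviation.
#' @param spike_rate Expected spikes per second (0 disables spikes).
#' @param spike_amp Length-2 range of absolute spike amplitudes.
#' @return An `activity_model`.
#' @export
activity_model <- function(offset, harmonics = NULL, noise_sd = 0.01,
                           spike_rate = 0, spike_amp = c(2, 4)) {
  C <- length(offset)
  if (is.null(harmonics)) {
    harmonics <- tibble::tibble(channel = integer(), amp = numeric(),
                                freq = numeric(), phase = numeric())
  }
  harmonics <- tibble::as_tibble(harmonics)
  stopifnot(all(c("channel", "amp", "freq", "phase") %in% names(harmonics)),
            all(harmonics$channel >= 1), all(harmonics$channel <= C),
            all(harmonics$freq > 0), spike_rate >= 0, all(noise_sd >= 0))
  if (length(noise_sd) == 1) noise_sd <- rep(noise_sd, C)
  stopifnot(length(noise_sd) == C)
  structure(list(offset = offset, harmonics = harmonics, noise_sd = noise_sd,
                 spike_rate = spike_rate, spike_amp = spike_amp),
            class = "activity_model")
}

#' Default six-activity generative models
#'
#' Models for sitting, standing, walking, running, going upstairs and going
#' downstairs over six channels (ax, ay, az in g; gx, gy, gz in deg/s),
#' emulating a shank-mounted 50 Hz IMU. Static postures differ in
#' orientation offsets and have no harmonics; dynamic activities carry gait
#' harmonics at roughly 1 Hz (walking), 2.5 Hz (running) and 0.8 Hz
#' (stairs), with stairs-up and stairs-down sharing the fundamental but
#' differing in inter-channel phase and amplitude balance so they are
#' confusable yet separable. Running and the stair classes include rare
#' spikes.
#'
#' @return A named list of [activity_model()] objects.
#' @export
default_activity_models <- function() {
  harm <- function(...) {
    m <- matrix(c(...), ncol = 4, byrow = TRUE)
    tibble::tibble(channel = as.integer(m[, 1]), amp = m[, 2],
                   freq = m[, 3], phase = m[, 4])
  }
  list(
    sitting = activity_model(
      offset = c(0.62, 0.74, 0.18, 0, 0, 0),
      noise_sd = c(rep(0.015, 3), rep(0.6, 3))
    ),
    standing = activity_model(
      offset = c(0.03, 0.99, 0.05, 0, 0, 0),
      harmonics = harm(2, 0.012, 0.3, 0),
      noise_sd = c(rep(0.02, 3), rep(0.8, 3))
    ),
    walking = activity_model(
      offset = c(0.05, 0.95, 0.08, 0, 0, 0),
      harmonics = harm(
        1, 0.45, 1.0, 0,
        2, 0.60, 1.0, 1.2,
        3, 0.25, 2.0, 0.5,
        4, 60, 1.0, 0.3,
        5, 80, 1.0, 2.1,
        6, 35, 2.0, 1.0
      ),
      noise_sd = c(rep(0.06, 3), rep(4, 3)),
      spike_rate = 0.05, spike_amp = c(0.8, 1.5)
    ),
    running = activity_model(
      offset = c(0.10, 0.90, 0.10, 0, 0, 0),
      harmonics = harm(
        1, 1.5, 2.5, 0,
        2, 2.0, 2.5, 1.0,
        3, 0.8, 5.0, 0.4,
        4, 250, 2.5, 0.2,
        5, 320, 2.5, 1.8,
        6, 120, 5.0, 0.9
      ),
      noise_sd = c(rep(0.15, 3), rep(10, 3)),
      spike_rate = 0.2, spike_amp = c(2, 4)
    ),
    upstairs = activity_model(
      offset = c(0.20, 0.92, 0.05, 0, 0, 0),
      harmonics = harm(
        1, 0.55, 0.8, 0,
        2, 0.50, 0.8, 0.6,
        3, 0.35, 1.6, 0.2,
        4, 90, 0.8, 0.0,
        5, 70, 0.8, 0.9,
        6, 45, 1.6, 0.4
      ),
      noise_sd = c(rep(0.07, 3), rep(5, 3)),
      spike_rate = 0.1, spike_amp = c(1, 2)
    ),
    downstairs = activity_model(
      offset = c(-0.15, 0.90, 0.18, 0, 0, 0),
      harmonics = harm(
        1, 0.40, 0.8, 2.4,
        2, 0.75, 0.8, 3.0,
        3, 0.30, 1.6, 1.8,
        4, 60, 0.8, 2.6,
        5, 110, 0.8, 0.2,
        6, 50, 1.6, 2.0
      ),
      noise_sd = c(rep(0.09, 3), rep(6, 3)),
      spike_rate = 0.1, spike_amp = c(1.5, 3)
    )
  )
}

#' Generator configuration for synthetic IMU corpora
#'
#' The default class mix follows the composition of a five-subject
#' shank-mounted recording campaign: sitting 42.4%, standing 12.7%, walking
#' 14.4%, running 9.6%, going upstairs 10.9%, going downstairs 10.0%.
#'
#' @param sample_rate Hz; default 50.
#' @param class_mix Named fractions per activity, summing to 1.
#' @param models Named list of [activity_model()]s covering `class_mix`.
#' @param n_subjects Number of simulated subjects; default 5.
#' @param total_duration Total corpus duration in seconds; default 1800
#'   (30 minutes).
#' @param session_range Length-2 range (seconds) of individual session
#'   durations before the per-activity budget is exhausted.
#' @param amp_jitter,freq_jitter Per-subject multiplicative jitter ranges
#'   applied to harmonic amplitudes and frequencies.
#' @param seed Integer seed.
#' @return A `generator_config` list.
#' @export
generator_config <- function(sample_rate = 50,
                             class_mix = c(sitting = 0.424, standing = 0.127,
                                           walking = 0.144, running = 0.096,
                                           upstairs = 0.109, downstairs = 0.100),
                             models = default_activity_models(),
                             n_subjects = 5,
                             total_duration = 1800,
                             session_range = c(20, 60),
                             amp_jitter = c(0.7, 1.3),
                             freq_jitter = c(0.9, 1.1),
                             seed = 1) {
  if (abs(sum(class_mix) - 1) > 1e-9) {
    stop("`class_mix` fractions must sum to 1", call. = FALSE)
  }
  absent <- setdiff(names(class_mix), names(models))
  if (length(absent) > 0) {
    stop("no activity model for: ", paste(absent, collapse = ", "), call. = FALSE)
  }
  structure(list(sample_rate = sample_rate, class_mix = class_mix,
                 models = models, n_subjects = as.integer(n_subjects),
                 total_duration = total_duration, session_range = session_range,
                 amp_jitter = amp_jitter, freq_jitter = freq_jitter,
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Generate one labelled recording session
#'
#' @param activity Activity label for every sample of the session.
#' @param duration Session length in seconds (> 0).
#' @param model An [activity_model()].
#' @param sample_rate Hz.
#' @param subject Subject identifier.
#' @param recording Recording identifier.
#' @param amp_factor,freq_factor Subject-level multiplicative jitter applied
#'   to every harmonic's amplitude and frequency.
#' @param channel_names Channel column names.
#' @return A recordings tibble ([imu_recordings()]) with
#'   `duration * sample_rate` rows, all labelled `activity`.
#' @export
generate_session <- function(activity, duration, model, sample_rate = 50,
                             subject = "s1", recording = 1L,
                             amp_factor = 1, freq_factor = 1,
                             channel_names = c("ax", "ay", "az", "gx", "gy", "gz")) {
  stopifnot(inherits(model, "activity_model"), duration > 0)
  C <- length(model$offset)
  stopifnot(length(channel_names) == C)
  if (nrow(model$harmonics) > 0 &&
      any(model$harmonics$freq * freq_factor >= sample_rate / 2)) {
    stop("harmonic frequency at or above the Nyquist limit", call. = FALSE)
  }
  n <- as.integer(round(duration * sample_rate))
  t <- (seq_len(n) - 1) / sample_rate
  sig <- matrix(rep(model$offset, each = n), n, C)
  if (nrow(model$harmonics) > 0) {
    for (j in seq_len(nrow(model$harmonics))) {
      h <- model$harmonics[j, ]
      sig[, h$channel] <- sig[, h$channel] +
        amp_factor * h$amp * sin(2 * pi * h$freq * freq_factor * t + h$phase)
    }
  }
  sig <- sig + matrix(stats::rnorm(n * C, sd = rep(model$noise_sd, each = n)), n, C)
  if (model$spike_rate > 0) {
    n_spikes <- stats::rpois(1, model$spike_rate * duration)
    if (n_spikes > 0) {
      at <- sample.int(n, min(n_spikes, n))
      ch <- sample.int(C, length(at), replace = TRUE)
      amp <- stats::runif(length(at), model$spike_amp[1], model$spike_amp[2]) *
        sample(c(-1, 1), length(at), replace = TRUE)
      # spikes scale with the channel's own magnitude (gyro channels are in
      # deg/s, two orders larger than accelerometer channels in g)
      scale <- pmax(model$noise_sd[ch] * 10, abs(model$offset[ch]))
      sig[cbind(at, ch)] <- sig[cbind(at, ch)] + amp * scale
    }
  }
  df <- tibble::as_tibble(as.data.frame(sig))
  names(df) <- channel_names
  out <- dplyr::bind_cols(
    tibble::tibble(subject = subject, recording = recording,
                   activity = activity),
    df
  )
  imu_recordings(out, channels = channel_names, sample_rate = sample_rate)
}

#' Generate a full labelled synthetic IMU corpus
#'
#' Splits the total duration across subjects and activities according to the
#' configured class mix, chops each activity budget into sessions of random
#' length, and concatenates everything into one tidy recordings tibble.
#' Per-subject amplitude/frequency jitter makes subjects systematically
#' different, as real gait is. Fully reproducible from `config$seed`.
#'
#' @param config A [generator_config()].
#' @return A recordings tibble ([imu_recordings()]).
#' @examples
#' x <- generate_imu_dataset(generator_config(total_duration = 60, seed = 7))
#' table(x$activity)
#' @export
generate_imu_dataset <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  withr::local_seed(config$seed)
  per_subject <- config$total_duration / config$n_subjects
  rec_id <- 0L
  pieces <- list()
  for (s in seq_len(config$n_subjects)) {
    subject <- sprintf("subj%02d", s)
    amp_factor <- stats::runif(1, config$amp_jitter[1], config$amp_jitter[2])
    freq_factor <- stats::runif(1, config$freq_jitter[1], config$freq_jitter[2])
    for (act in names(config$class_mix)) {
      budget <- per_subject * config$class_mix[[act]]
      while (budget > 0.5) {
        dur <- min(budget, stats::runif(1, config$session_range[1],
                                        config$session_range[2]))
        rec_id <- rec_id + 1L
        pieces[[length(pieces) + 1L]] <- generate_session(
          activity = act, duration = dur, model = config$models[[act]],
          sample_rate = config$sample_rate, subject = subject,
          recording = rec_id, amp_factor = amp_factor,
          freq_factor = freq_factor
        )
        budget <- budget - dur
      }
    }
  }
  out <- dplyr::bind_rows(pieces)
  imu_recordings(out, channels = imu_channels(pieces[[1]]),
                 sample_rate = config$sample_rate)
}
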
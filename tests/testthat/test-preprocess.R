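test_that("channel statistics use the population standard deviation", {
  x <- make_recordings(matrix(c(2, 4, 6), ncol = 1))
  s <- channel_stats(x)
  expect_equal(s$mean, 4)
  expect_equal(s$sd, sqrt(8 / 3))

  const <- make_recordings(matrix(c(5, 5, 5), ncol = 1))
  s2 <- channel_stats(const)
  expect_equal(s2$sd, 0)
  expect_error(standardize_channels(const, s2), "ch1")
})

test_that("statistics over several recordings equal those of their concatenation", {
  a <- make_recordings(matrix(rnorm(30), ncol = 3), recording = 1L)
  b <- make_recordings(matrix(rnorm(45), ncol = 3), recording = 2L,
                       activity = "running")
  both <- imu_recordings(dplyr::bind_rows(a, b),
                         channels = imu_channels(a), sample_rate = 50)
  concat <- make_recordings(rbind(as.matrix(a[imu_channels(a)]),
                                  as.matrix(b[imu_channels(b)])))
  expect_equal(channel_stats(both)[c("mean", "sd")],
               channel_stats(concat)[c("mean", "sd")])
})

test_that("standardization centres, scales, and inverts exactly", {
  x <- make_recordings(matrix(c(2, 4, 6), ncol = 1))
  s <- channel_stats(x)
  z <- standardize_channels(x, s)
  expect_equal(z$ch1, c(-2, 0, 2) / sqrt(8 / 3), tolerance = 1e-12)
  expect_equal(z$ch1[2], 0)

  # corpus statistics of the standardized corpus are 0 / 1
  y <- make_recordings(matrix(rnorm(200, mean = 3, sd = 7), ncol = 2))
  zs <- channel_stats(standardize_channels(y))
  expect_true(all(abs(zs$mean) < 1e-9))
  expect_true(all(abs(zs$sd - 1) < 1e-9))

  # invertibility: x = z * sd + mean
  sy <- channel_stats(y)
  zy <- standardize_channels(y, sy)
  for (i in 1:2) {
    ch <- sy$channel[i]
    expect_equal(zy[[ch]] * sy$sd[i] + sy$mean[i], y[[ch]], tolerance = 1e-9)
  }

  # already standardized input is a fixed point under its own statistics
  z2 <- standardize_channels(zy, channel_stats(zy))
  expect_equal(z2[[sy$channel[1]]], zy[[sy$channel[1]]], tolerance = 1e-9)
})

test_that("window segmentation emits fully contained windows on a fixed step", {
  mk <- function(n) make_recordings(matrix(seq_len(n), ncol = 1))
  one <- segment_windows(mk(100), 100, 0.5)
  expect_equal(dim(one$windows)[1], 1)
  expect_equal(one$provenance$start, 1L)

  four <- segment_windows(mk(250), 100, 0.5)
  expect_equal(dim(four$windows)[1], 4)
  expect_equal(four$provenance$start, c(1L, 51L, 101L, 151L))
  # window content is the contiguous source slice
  expect_equal(four$windows[2, , 1], as.numeric(51:150))

  none <- segment_windows(mk(99), 100, 0.5)
  expect_equal(dim(none$windows)[1], 0)
})

test_that("window counts match brute-force start enumeration", {
  brute <- function(n, L, step) {
    if (n < L) return(0L)
    length(seq(0L, n - L, by = step))
  }
  for (L in c(10L, 40L, 100L)) {
    for (overlap in c(0, 0.25, 0.5, 0.75)) {
      step <- max(1L, as.integer(round(L * (1 - overlap))))
      counts <- vapply(1:500, function(n) {
        dim(segment_windows(make_recordings(matrix(rep(0, n), ncol = 1)),
                            L, overlap)$windows)[1]
      }, integer(1))
      expect_equal(counts, vapply(1:500, brute, integer(1), L = L, step = step),
                   info = sprintf("L=%d overlap=%.2f", L, overlap))
    }
  }
})

test_that("windows never span recording or subject boundaries", {
  a <- make_recordings(matrix(rnorm(60), ncol = 1), subject = "s1", recording = 1L)
  b <- make_recordings(matrix(rnorm(60), ncol = 1), subject = "s2", recording = 2L)
  both <- imu_recordings(dplyr::bind_rows(a, b), channels = "ch1",
                         sample_rate = 50)
  ds <- segment_windows(both, 50, 0.5)
  expect_equal(dim(ds$windows)[1], 2)
  expect_equal(sort(unique(ds$provenance$subject)), c("s1", "s2"))
  expect_true(all(ds$provenance$start + ds$window_length - 1 <= 60))
})

test_that("window labels follow majority vote with a midpoint tie-break", {
  expect_equal(assign_window_label(rep("walking", 10)), "walking")
  expect_equal(assign_window_label(c(rep("walking", 60), rep("running", 40))),
               "walking")
  # 50/50 tie: sample at 0-based index L/2 is the first "running"
  tied <- c(rep("walking", 50), rep("running", 50))
  expect_equal(assign_window_label(tied), "running")
  expect_error(assign_window_label(character(0)), "empty")
})
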
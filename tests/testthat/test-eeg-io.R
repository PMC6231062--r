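# Reading, writing, synchronization, epoching.

test_that("csv round-trip is lossless and rates/labels survive", {
  set.seed(1)
  m <- matrix(rnorm(3 * 1000), 3)
  eeg <- eeg_recording(m, rate = 1000,
                       channel_labels = c("C3", "CZ", "C4"))
  f <- withr::local_tempfile(fileext = ".csv")
  write_eeg_csv(eeg, f)
  back <- read_eeg(f, "csv", rate = 1000)
  expect_equal(back$samples, eeg$samples, ignore_attr = TRUE)
  expect_identical(back$channel_labels, c("C3", "CZ", "C4"))
  expect_identical(back$rate, 1000)
})

test_that("a 25-channel file at 1000 Hz reads as such", {
  set.seed(2)
  eeg <- eeg_recording(matrix(rnorm(25 * 500), 25), rate = 1000,
                       channel_labels = analysis_electrodes())
  f <- withr::local_tempfile(fileext = ".csv")
  write_eeg_csv(eeg, f)
  back <- read_eeg(f, "csv", rate = 1000)
  expect_equal(nrow(back$samples), 25)
  expect_equal(back$rate, 1000)
})

test_that("ragged csv rows raise a parse error naming the line", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("C3,C4,CZ", "1,2,3", "4,5", "6,7,8"), f)
  expect_error(read_eeg(f, "csv"), "line 3")
})

test_that("reference/EOG channels are flagged, unknown labels warned", {
  eeg <- eeg_recording(matrix(0, 3, 20), channel_labels =
                         c("C3", "A1", "HEOG"))
  expect_identical(eeg$aux, c(FALSE, TRUE, TRUE))
  expect_warning(eeg_recording(matrix(0, 1, 20),
                               channel_labels = "XX9"),
                 "unrecognized")
})

test_that("EDF round-trips at 16-bit quantization", {
  set.seed(3)
  m <- matrix(rnorm(4 * 2000, sd = 30), 4)
  eeg <- eeg_recording(m, rate = 1000,
                       channel_labels = c("C3", "CZ", "C4", "PZ"))
  f <- withr::local_tempfile(fileext = ".edf")
  write_edf(eeg, f)
  back <- read_edf(f)
  expect_identical(back$channel_labels, eeg$channel_labels)
  expect_equal(back$rate, 1000)
  q <- (max(m) - min(m)) / 65535        # one quantization step
  expect_lt(max(abs(back$samples - m)), 2 * q)
})

test_that("synchronize restricts to the overlap and interpolates exactly", {
  eeg <- eeg_recording(matrix(rnorm(2 * 3000), 2), rate = 1000,
                       channel_labels = c("C3", "C4"), start_time = 1)
  tt <- seq(0, 6, by = 1 / 120)
  traj <- trajectory_recording(tt, 2 + 3 * tt, -1 + 0.5 * tt, 7 + 0 * tt)
  tr <- synchronize(eeg, traj, mode = "UD", analysis_rate = 100)
  # output span equals the EEG span (subset of trajectory span)
  expect_gte(min(tr$times), 1)
  expect_lte(max(tr$times), 4)
  # a line interpolates exactly on any grid
  expect_equal(tr$trajectory[, "x"], 2 + 3 * tr$times, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(tr$trajectory[, "y"], -1 + 0.5 * tr$times,
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(unname(tr$trajectory[, "z"]), rep(7, length(tr$times)),
               tolerance = 1e-9)
})

test_that("synchronize errors without overlap", {
  eeg <- eeg_recording(matrix(0, 1, 1000), rate = 1000,
                       channel_labels = "C3", start_time = 100)
  traj <- trajectory_recording(0:5, 0:5, 0:5, 0:5)
  expect_error(synchronize(eeg, traj, "UD"), "overlap")
})

test_that("epoching follows the integer-division and remainder rules", {
  mk <- function(dur) {
    eeg <- eeg_recording(matrix(rnorm(round(dur * 1000)), 1), rate = 1000,
                         channel_labels = "C3")
    tt <- seq(0, dur - 1 / 120, by = 1 / 120)
    synchronize(eeg, trajectory_recording(tt, tt, tt, sin(tt)), "UD")
  }
  expect_equal(nrow(epoch_trial(mk(10), 2)$epochs), 5)
  expect_message(t119 <- epoch_trial(mk(11.9), 2), "dropped")
  expect_equal(nrow(t119$epochs), 5)
  expect_warning(t1 <- epoch_trial(mk(1), 2), "shorter")
  expect_equal(nrow(t1$epochs), 0)
})

test_that("epoching conserves samples", {
  eeg <- eeg_recording(matrix(rnorm(7300), 1), rate = 1000,
                       channel_labels = "C3")
  tt <- seq(0, 7.2, by = 1 / 120)
  tr <- synchronize(eeg, trajectory_recording(tt, tt, tt, tt), "UD")
  tr <- suppressMessages(epoch_trial(tr, 2))
  tot <- sum(vapply(seq_len(nrow(tr$epochs)), function(i)
    length(bfndecode:::epoch_index(tr, i)), integer(1)))
  expect_equal(tot, nrow(tr$epochs) * 2 * tr$analysis_rate)
  expect_lte(tot, length(tr$times))
})

test_that("trial bundles round-trip through disk", {
  cfg <- cfg_small(seed = 9)
  tr <- generate_mode_trial("LR", cfg)
  d <- withr::local_tempdir()
  write_trial_bundle(tr, d)
  back <- read_trial_bundle(d)
  expect_equal(back$mode, "LR")
  expect_equal(back$analysis, tr$analysis, tolerance = 1e-9)
  expect_equal(back$trajectory, tr$trajectory, tolerance = 1e-6)
  expect_equal(nrow(back$epochs), nrow(tr$epochs))
})
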
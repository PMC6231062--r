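# Reading, preprocessing, synchronizing, and epoching EEG + hand trajectories.

#' Construct an EEG recording
#'
#' @param samples Numeric matrix, channels x time, in microvolts.
#' @param rate Sampling rate in Hz (default 1000).
#' @param channel_labels Character vector of 10-20 labels, one per row.
#' @param start_time Absolute start time in seconds (default 0).
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(samples, rate = 1000, channel_labels = NULL,
                          start_time = 0) {
  samples <- as.matrix(samples)
  if (is.null(channel_labels))
    channel_labels <- paste0("CH", seq_len(nrow(samples)))
  channel_labels <- normalize_label(channel_labels)
  if (length(channel_labels) != nrow(samples))
    stop("channel count (", nrow(samples), ") != label count (",
         length(channel_labels), ")")
  if (rate <= 0) stop("rate must be positive")
  aux <- channel_labels %in% AUX_LABELS
  unknown <- !aux & !(channel_labels %in% KNOWN_1020) &
    !grepl("^CH[0-9]+$", channel_labels)
  if (any(unknown))
    warning("unrecognized channel label(s) passed through: ",
            paste(channel_labels[unknown], collapse = ", "))
  structure(
    list(samples = samples, rate = rate, channel_labels = channel_labels,
         start_time = start_time, aux = aux),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat("<eeg_recording> ", nrow(x$samples), " channels x ",
      ncol(x$samples), " samples @ ", x$rate, " Hz (",
      round(ncol(x$samples) / x$rate, 2), " s)\n", sep = "")
  invisible(x)
}

eeg_times <- function(eeg) {
  eeg$start_time + (seq_len(ncol(eeg$samples)) - 1) / eeg$rate
}

#' Construct a 3-D hand trajectory recording
#'
#' @param times Absolute timestamps in seconds, strictly increasing.
#' @param x,y,z Coordinates in mm.
#' @param rate Nominal sampling rate in Hz (default 120).
#' @return An object of class `trajectory_recording`.
#' @export
trajectory_recording <- function(times, x, y, z, rate = 120) {
  n <- length(times)
  if (length(x) != n || length(y) != n || length(z) != n)
    stop("times/x/y/z must have equal lengths")
  if (n > 1 && any(diff(times) <= 0))
    stop("times must be strictly increasing")
  structure(list(times = times, x = x, y = y, z = z, rate = rate),
            class = "trajectory_recording")
}

#' Read an EEG file
#'
#' Supports a delimited matrix with a one-line header of channel labels
#' (columns = channels, rows = samples) and 16-bit EDF.
#'
#' @param path File path.
#' @param format `"csv"` or `"edf"`.
#' @param rate Sampling rate in Hz for csv input (EDF stores its own).
#' @param start_time Absolute start time in seconds for csv input.
#' @return An [eeg_recording()].
#' @export
read_eeg <- function(path, format = c("csv", "edf"), rate = 1000,
                     start_time = 0) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file does not exist: ", path)
  if (format == "edf") return(read_edf(path))
  header <- strsplit(readLines(path, n = 1), ",", fixed = TRUE)[[1]]
  header <- gsub("\"", "", header, fixed = TRUE)
  widths <- utils::count.fields(path, sep = ",")
  bad <- which(widths != length(header))
  if (length(bad) > 0)
    stop("ragged csv: line ", bad[1], " has ", widths[bad[1]],
         " fields, expected ", length(header))
  m <- as.matrix(utils::read.csv(path, header = TRUE, check.names = FALSE))
  eeg_recording(t(m), rate = rate, channel_labels = header,
                start_time = start_time)
}

#' Write an EEG recording as a delimited matrix
#'
#' @param eeg An [eeg_recording()].
#' @param path Output path.
#' @export
write_eeg_csv <- function(eeg, path) {
  m <- t(eeg$samples)
  colnames(m) <- eeg$channel_labels
  utils::write.csv(m, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a trajectory file
#'
#' Delimited file with header `time,x,y,z`: seconds and mm.
#'
#' @param path File path.
#' @param rate Nominal rate in Hz.
#' @return A [trajectory_recording()].
#' @export
read_trajectory <- function(path, rate = 120) {
  d <- utils::read.csv(path)
  need <- c("time", "x", "y", "z")
  if (!all(need %in% names(d)))
    stop("trajectory file must have header time,x,y,z")
  trajectory_recording(d$time, d$x, d$y, d$z, rate = rate)
}

#' Write a trajectory recording
#' @param traj A [trajectory_recording()].
#' @param path Output path.
#' @export
write_trajectory_csv <- function(traj, path) {
  utils::write.csv(
    data.frame(time = traj$times, x = traj$x, y = traj$y, z = traj$z),
    path, row.names = FALSE)
  invisible(path)
}

#' Default preprocessing configuration
#'
#' @param notch_hz Line-noise notch frequency (default 50 Hz).
#' @param lowpass_hz Low-pass corner (default 55 Hz; the "0 Hz" corner of a
#'   0-55 Hz band-pass is realized as DC removal).
#' @param filter_order Butterworth order (default 4).
#' @param notch_bw_hz Notch bandwidth (default 2 Hz).
#' @param analysis_rate Decimation target rate in Hz (default 100).
#' @param exclude_channels Labels to drop before analysis (artifact hook).
#' @return List of class `preprocess_cfg`.
#' @export
preprocess_cfg <- function(notch_hz = 50, lowpass_hz = 55, filter_order = 4,
                           notch_bw_hz = 2, analysis_rate = 100,
                           exclude_channels = character(0)) {
  structure(list(notch_hz = notch_hz, lowpass_hz = lowpass_hz,
                 filter_order = filter_order, notch_bw_hz = notch_bw_hz,
                 analysis_rate = analysis_rate,
                 exclude_channels = normalize_label(exclude_channels)),
            class = "preprocess_cfg")
}

#' Preprocess an EEG recording
#'
#' Removes per-channel DC, applies a zero-phase line-noise notch and a
#' zero-phase Butterworth low-pass, and optionally drops excluded channels.
#' Ocular/myographic artifact rejection is out of scope; use
#' `exclude_channels` to remove contaminated channels.
#'
#' @param eeg An [eeg_recording()].
#' @param cfg A [preprocess_cfg()].
#' @return A preprocessed [eeg_recording()].
#' @export
preprocess <- function(eeg, cfg = preprocess_cfg()) {
  if (eeg$rate <= 2 * cfg$lowpass_hz)
    stop("sampling rate ", eeg$rate, " Hz too low for a ", cfg$lowpass_hz,
         " Hz low-pass")
  keep <- !(eeg$channel_labels %in% cfg$exclude_channels)
  s <- eeg$samples[keep, , drop = FALSE]
  s <- s - rowMeans(s)
  nt <- iir_notch(cfg$notch_hz, eeg$rate, cfg$notch_bw_hz)
  lp <- butter_lowpass(cfg$filter_order, cfg$lowpass_hz, eeg$rate)
  for (i in seq_len(nrow(s))) {
    v <- filtfilt_ba(nt$b, nt$a, s[i, ])
    s[i, ] <- filtfilt_ba(lp$b, lp$a, v)
  }
  s <- s - rowMeans(s)
  if (any(!is.finite(s))) stop("non-finite values after preprocessing")
  out <- eeg
  out$samples <- s
  out$channel_labels <- eeg$channel_labels[keep]
  out$aux <- eeg$aux[keep]
  out
}

#' Synchronize EEG and trajectory by absolute timestamps
#'
#' Restricts both signals to their overlapping time span, decimates the EEG
#' to the analysis rate (anti-alias filtered), and linearly interpolates the
#' trajectory onto the same analysis-rate grid. The raw-rate EEG over the
#' overlap is kept for band decomposition.
#'
#' @param eeg A preprocessed [eeg_recording()].
#' @param traj A [trajectory_recording()].
#' @param mode Motion mode label: UD, LR, BF, SPIRAL1 or SPIRAL2.
#' @param analysis_rate Analysis grid rate in Hz (default 100).
#' @return An object of class `synced_trial`.
#' @export
synchronize <- function(eeg, traj, mode = c("UD", "LR", "BF",
                                            "SPIRAL1", "SPIRAL2"),
                        analysis_rate = 100) {
  mode <- match.arg(mode)
  te <- eeg_times(eeg)
  t0 <- max(te[1], traj$times[1])
  t1 <- min(te[length(te)], traj$times[length(traj$times)])
  if (t1 <= t0) stop("EEG and trajectory time spans do not overlap")
  i0 <- which(te >= t0 - 1e-9)[1]
  i1 <- max(which(te <= t1 + 1e-9))
  raw <- eeg$samples[, i0:i1, drop = FALSE]
  raw_t0 <- te[i0]
  fac <- eeg$rate / analysis_rate
  if (abs(fac - round(fac)) > 1e-9)
    stop("EEG rate must be an integer multiple of analysis_rate")
  an <- t(apply(raw, 1, decimate_signal, rate = eeg$rate,
                new_rate = analysis_rate))
  if (nrow(raw) == 1) an <- matrix(an, nrow = 1)
  tg <- raw_t0 + (seq_len(ncol(an)) - 1) / analysis_rate
  tg <- tg[tg <= t1 + 1e-9]
  an <- an[, seq_along(tg), drop = FALSE]
  interp <- function(v) stats::approx(traj$times, v, xout = tg,
                                      rule = 2)$y
  structure(
    list(eeg = eeg_recording(raw, eeg$rate, eeg$channel_labels, raw_t0),
         analysis = an,
         analysis_rate = analysis_rate,
         times = tg,
         trajectory = cbind(x = interp(traj$x), y = interp(traj$y),
                            z = interp(traj$z)),
         mode = mode,
         epochs = NULL, unit_s = NULL, features = NULL),
    class = "synced_trial"
  )
}

#' @export
print.synced_trial <- function(x, ...) {
  cat("<synced_trial> mode=", x$mode, ", ",
      nrow(x$eeg$samples), " channels, ",
      length(x$times), " analysis samples @ ", x$analysis_rate, " Hz",
      if (!is.null(x$epochs)) paste0(", ", nrow(x$epochs), " epochs of ",
                                     x$unit_s, " s"),
      "\n", sep = "")
  invisible(x)
}

#' Split a synchronized trial into fixed-length epochs
#'
#' Non-overlapping contiguous windows of `unit_s` seconds; a trailing
#' remainder shorter than `unit_s` is discarded (and reported).
#'
#' @param trial A `synced_trial`.
#' @param unit_s Epoch length in seconds (default 2).
#' @return The trial with an `epochs` matrix (columns `start`, `end`,
#'   seconds, absolute) attached.
#' @export
epoch_trial <- function(trial, unit_s = 2) {
  if (unit_s <= 0) stop("unit_s must be positive")
  span <- trial$times[length(trial$times)] - trial$times[1] +
    1 / trial$analysis_rate
  n_ep <- floor(span / unit_s + 1e-9)
  if (n_ep < 1) {
    warning("trial span (", round(span, 3), " s) shorter than unit_s (",
            unit_s, " s): no epochs")
    trial$epochs <- matrix(numeric(0), ncol = 2,
                           dimnames = list(NULL, c("start", "end")))
    trial$unit_s <- unit_s
    return(trial)
  }
  dropped <- span - n_ep * unit_s
  if (dropped > 1e-9)
    message("epoching dropped trailing ", round(dropped, 3), " s")
  st <- trial$times[1] + (seq_len(n_ep) - 1) * unit_s
  trial$epochs <- cbind(start = st, end = st + unit_s)
  trial$unit_s <- unit_s
  trial
}

# analysis-grid indices covered by epoch i
epoch_index <- function(trial, i) {
  which(trial$times >= trial$epochs[i, "start"] - 1e-9 &
          trial$times < trial$epochs[i, "end"] - 1e-9)
}

# raw-rate sample indices covered by epoch i
epoch_index_raw <- function(trial, i) {
  tr <- eeg_times(trial$eeg)
  which(tr >= trial$epochs[i, "start"] - 1e-9 &
          tr < trial$epochs[i, "end"] - 1e-9)
}
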
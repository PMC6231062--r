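# Versioned plain-text trial bundles: a directory holding the raw-rate EEG
# (csv), the trajectory (csv), and a meta.json with rates, mode and epoch
# layout. Reading a bundle re-synchronizes and re-epochs deterministically.

BUNDLE_VERSION <- 1L

#' Write a trial bundle
#'
#' @param trial An (epoched) `synced_trial`.
#' @param dir Output directory (created).
#' @return The directory, invisibly.
#' @export
write_trial_bundle <- function(trial, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_eeg_csv(trial$eeg, file.path(dir, "eeg.csv"))
  tt <- trial$times
  df <- data.frame(time = tt,
                   x = trial$trajectory[, "x"],
                   y = trial$trajectory[, "y"],
                   z = trial$trajectory[, "z"])
  # pad the trajectory to the stored EEG's end so that re-reading
  # reconstructs exactly the same overlap (hence identical decimation)
  eeg_end <- trial$eeg$start_time +
    (ncol(trial$eeg$samples) - 1) / trial$eeg$rate
  if (eeg_end > tt[length(tt)] + 1e-12)
    df <- rbind(df, data.frame(time = eeg_end,
                               x = df$x[nrow(df)], y = df$y[nrow(df)],
                               z = df$z[nrow(df)]))
  utils::write.csv(df, file.path(dir, "traj.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(version = BUNDLE_VERSION, mode = trial$mode,
         eeg_rate = trial$eeg$rate, eeg_start = trial$eeg$start_time,
         analysis_rate = trial$analysis_rate,
         unit_s = trial$unit_s),
    file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a trial bundle
#'
#' @param dir Bundle directory written by [write_trial_bundle()].
#' @return An epoched `synced_trial`.
#' @export
read_trial_bundle <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"))
  if (is.null(meta$version) || meta$version > BUNDLE_VERSION)
    stop("unsupported bundle version")
  eeg <- read_eeg(file.path(dir, "eeg.csv"), "csv",
                  rate = meta$eeg_rate, start_time = meta$eeg_start)
  traj <- read_trajectory(file.path(dir, "traj.csv"),
                          rate = meta$analysis_rate)
  trial <- synchronize(eeg, traj, mode = meta$mode,
                       analysis_rate = meta$analysis_rate)
  if (!is.null(meta$unit_s))
    trial <- suppressMessages(epoch_trial(trial, meta$unit_s))
  trial
}
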
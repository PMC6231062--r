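# Trial-level feature extraction: epochs x bands -> BFN metrics.

#' Compute per-epoch, per-band network features for a trial
#'
#' For every epoch of the trial and every requested band: Morlet band
#' envelopes of the raw-rate EEG, Spearman correlation matrix,
#' cost-thresholded network, graph metrics.
#'
#' @param trial An epoched `synced_trial` (see [epoch_trial()]).
#' @param bands Band names (default all eight).
#' @param cost Network-cost threshold (default 0.18).
#' @param electrodes Electrode subset to use (default: all scalp channels
#'   present in the trial).
#' @param n_cycles,n_scales Morlet parameters, see [band_envelope()].
#' @return The trial with `$features` set: a list with `metrics`
#'   (data.frame epoch, mode, band, VDegree, VPLength, Cluster, Pbar) and
#'   `degrees` (data.frame epoch, mode, band, electrode, degree).
#' @export
compute_bfn_features <- function(trial, bands = band_names(), cost = 0.18,
                                 electrodes = NULL,
                                 n_cycles = 6, n_scales = 4) {
  if (is.null(trial$epochs) || nrow(trial$epochs) == 0)
    stop("trial has no epochs; call epoch_trial() first")
  labs <- trial$eeg$channel_labels
  if (is.null(electrodes)) electrodes <- labs[!trial$eeg$aux]
  sel <- match(electrodes, labs)
  if (anyNA(sel))
    stop("electrode(s) not in trial: ",
         paste(electrodes[is.na(sel)], collapse = ", "))
  met <- list(); degs <- list()
  for (i in seq_len(nrow(trial$epochs))) {
    idx <- epoch_index_raw(trial, i)
    seg <- trial$eeg$samples[sel, idx, drop = FALSE]
    rownames(seg) <- electrodes
    for (b in bands) {
      env <- band_envelope(seg, trial$eeg$rate, b, n_cycles, n_scales)
      cm <- correlation_matrix(env, labels = electrodes)
      nf <- suppressWarnings(network_features(build_bfn(cm, cost)))
      met[[length(met) + 1]] <- data.frame(
        epoch = i, mode = trial$mode, band = b,
        VDegree = nf$VDegree, VPLength = nf$VPLength,
        Cluster = nf$Cluster, Pbar = nf$Pbar,
        stringsAsFactors = FALSE)
      degs[[length(degs) + 1]] <- data.frame(
        epoch = i, mode = trial$mode, band = b,
        electrode = electrodes, degree = as.numeric(nf$DVector),
        stringsAsFactors = FALSE)
    }
  }
  trial$features <- list(metrics = do.call(rbind, met),
                         degrees = do.call(rbind, degs),
                         bands = bands, cost = cost,
                         electrodes = electrodes)
  trial
}

#' Stack features of several trials into tidy tables
#'
#' @param trials List of trials processed by [compute_bfn_features()].
#' @return List with combined `metrics` and `degrees` data.frames, each
#'   gaining a `trial` column.
#' @export
collect_features <- function(trials) {
  m <- lapply(seq_along(trials), function(i) {
    f <- trials[[i]]$features
    if (is.null(f)) stop("trial ", i, " has no computed features")
    cbind(trial = i, f$metrics)
  })
  d <- lapply(seq_along(trials), function(i)
    cbind(trial = i, trials[[i]]$features$degrees))
  list(metrics = do.call(rbind, m), degrees = do.call(rbind, d))
}
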
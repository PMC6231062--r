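# Seeded synthetic EEG + trajectory generator with known ground truth.
#
# Mode trials (UD/LR/BF): single-axis sinusoidal hand oscillation; EEG is
# per-electrode pink noise plus shared band-limited latent sources injected
# into planted electrode pairs with mode-dependent gain, creating
# mode-dependent envelope (Spearman) connectivity in the planted band.
#
# Spiral trials: parametric helix (circle + linear advance along Y or Z);
# EEG is a linear mixture of the (standardized) axis trajectories plus pink
# noise, so a linear decode exists by construction. An epoch-level hidden
# state can modulate both the forward gain (true slopes) and the planted
# band coupling, so the measured network covariates carry the information a
# hierarchical decoder needs to beat the flat baseline.

#' Synthetic dataset configuration
#'
#' Defaults emulate the experimental design: 25 scalp electrodes at
#' 1000 Hz, 2-s unit epochs, 20 trials per motion mode of ~10 s (5
#' oscillation units at 0.5 Hz), 40 repetitions per spiral of 5.91 s,
#' trajectory at 120 Hz in mm.
#'
#' @param seed Integer RNG seed.
#' @param rate EEG rate Hz. @param traj_rate Trajectory rate Hz.
#' @param analysis_rate Decimated analysis rate Hz.
#' @param electrodes Electrode labels.
#' @param unit_s Epoch length s. @param trial_s Mode-trial duration s.
#' @param n_trials Mode trials per mode. @param n_repetitions Spiral
#'   repetitions.
#' @param amplitude_mm,freq_hz Mode-trial oscillation amplitude/frequency.
#' @param jitter_frac Off-axis jitter as a fraction of amplitude.
#' @param planted_band Band carrying planted coupling.
#' @param planted_pairs List of electrode-label pairs sharing latents.
#' @param coupling_by_mode Named list mode -> coupling in \[0,1\] applied
#'   to all planted pairs.
#' @param coupling_gain Latent injection amplitude per unit coupling,
#'   relative to unit-variance background.
#' @param spiral_radius_mm,spiral_turns,spiral_advance_mm,spiral_s Spiral
#'   geometry and duration.
#' @param noise_sd Spiral-EEG noise SD relative to unit-variance signal.
#' @param slope_modulation Relative slope swing gamma: epoch gain is
#'   `1 + gamma * z` with hidden state z in {-1, +1}. 0 disables
#'   modulation.
#' @param coupling_states Planted-band coupling for z = -1 / z = +1 in
#'   spiral trials.
#' @return List of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1,
                             rate = 1000, traj_rate = 120,
                             analysis_rate = 100,
                             electrodes = analysis_electrodes(),
                             unit_s = 2, trial_s = 10,
                             n_trials = 20, n_repetitions = 40,
                             amplitude_mm = 100, freq_hz = 0.5,
                             jitter_frac = 0.02,
                             planted_band = "theta",
                             planted_pairs = list(c("C3", "CZ"),
                                                  c("CZ", "C4"),
                                                  c("C3", "C4")),
                             coupling_by_mode = list(UD = 0.8, LR = 0.2,
                                                     BF = 0.2),
                             coupling_gain = 2,
                             spiral_radius_mm = 80, spiral_turns = 3,
                             spiral_advance_mm = 300, spiral_s = 5.91,
                             noise_sd = 0.3,
                             slope_modulation = 0.5,
                             coupling_states = c(0.2, 0.8)) {
  stopifnot(all(unlist(coupling_by_mode) >= 0),
            all(unlist(coupling_by_mode) <= 1))
  cfg <- as.list(environment())
  structure(cfg, class = "synthetic_config")
}

# deterministic child seed; stays well below 2^31
child_seed <- function(seed, ...) {
  key <- paste(..., collapse = "/")
  h <- sum(utf8ToInt(key) * seq_along(utf8ToInt(key)))
  (as.integer(seed) * 1009L + as.integer(h %% 100003L)) %% 2000000011L
}

# 1/f amplitude-shaped Gaussian noise, unit variance
pink_noise <- function(n) {
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1)                 # symmetric frequency index
  W <- W / sqrt(f)
  x <- Re(stats::fft(W, inverse = TRUE) / n)
  (x - mean(x)) / stats::sd(x)
}

# brick-wall band-limited Gaussian noise, unit variance
band_noise <- function(n, rate, lo, hi) {
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  f <- (seq_len(n) - 1) / n * rate
  f <- pmin(f, rate - f)
  W[f < lo | f > hi] <- 0
  x <- Re(stats::fft(W, inverse = TRUE) / n)
  (x - mean(x)) / stats::sd(x)
}

# Inject band-limited latents into the planted electrode group: constant
# amplitude `coupling_gain`, of which a fraction sqrt(c) is a latent shared
# by the group and sqrt(1-c) is electrode-private. Pairwise envelope
# correlation inside the group therefore tracks c while in-band power stays
# mode-invariant.
inject_coupling <- function(x, cfg, coupling, idx = seq_len(ncol(x))) {
  group <- unique(unlist(cfg$planted_pairs))
  if (length(group) < 2 || cfg$coupling_gain <= 0) return(x)
  rng <- band_range(cfg$planted_band)
  n <- length(idx)
  shared <- band_noise(n, cfg$rate, rng["lo"], rng["hi"])
  for (e in group) {
    own <- band_noise(n, cfg$rate, rng["lo"], rng["hi"])
    x[e, idx] <- x[e, idx] + cfg$coupling_gain *
      (sqrt(coupling) * shared + sqrt(1 - coupling) * own)
  }
  x
}

# EEG background + planted group coupling; returns electrodes x n matrix
synth_eeg_background <- function(cfg, n, coupling) {
  ne <- length(cfg$electrodes)
  x <- t(vapply(seq_len(ne), function(i) pink_noise(n), numeric(n)))
  rownames(x) <- cfg$electrodes
  x <- inject_coupling(x, cfg, coupling)
  x * 10                                   # ~10 uV scale
}

finish_trial <- function(cfg, eeg_mat, traj_t, tx, ty, tz, mode) {
  eeg <- eeg_recording(eeg_mat, rate = cfg$rate,
                       channel_labels = cfg$electrodes)
  traj <- trajectory_recording(traj_t, tx, ty, tz, rate = cfg$traj_rate)
  trial <- synchronize(eeg, traj, mode = mode,
                       analysis_rate = cfg$analysis_rate)
  suppressMessages(epoch_trial(trial, cfg$unit_s))
}

#' Generate one single-axis motion-mode trial
#'
#' @param mode `"UD"` (Z axis), `"LR"` (X) or `"BF"` (Y).
#' @param cfg A [synthetic_config()].
#' @param index Trial index (varies the seed deterministically).
#' @return An epoched `synced_trial`.
#' @export
generate_mode_trial <- function(mode = c("UD", "LR", "BF"),
                                cfg = synthetic_config(), index = 1) {
  mode <- match.arg(mode)
  set.seed(child_seed(cfg$seed, "mode", mode, index))
  n <- round(cfg$trial_s * cfg$rate)
  cpl <- cfg$coupling_by_mode[[mode]]
  if (is.null(cpl)) stop("no coupling configured for mode ", mode)
  eeg_mat <- synth_eeg_background(cfg, n, cpl)
  tt <- seq(0, cfg$trial_s - 1 / cfg$traj_rate, by = 1 / cfg$traj_rate)
  on_axis <- cfg$amplitude_mm * sin(2 * pi * cfg$freq_hz * tt)
  jit <- function() cfg$jitter_frac * cfg$amplitude_mm *
    band_noise(length(tt), cfg$traj_rate, 0.05, 1)
  ax <- switch(mode,
               LR = list(x = on_axis, y = jit(), z = jit()),
               BF = list(x = jit(), y = on_axis, z = jit()),
               UD = list(x = jit(), y = jit(), z = on_axis))
  finish_trial(cfg, eeg_mat, tt, ax$x, ax$y, ax$z, mode)
}

spiral_axes <- function(which, cfg, tt) {
  frac <- tt / max(tt)
  ang <- 2 * pi * cfg$spiral_turns * frac
  adv <- cfg$spiral_advance_mm * (frac - 0.5)
  r <- cfg$spiral_radius_mm
  if (which == "SPIRAL1")       # advance along Y, circle in XZ
    list(x = r * cos(ang), y = adv, z = r * sin(ang))
  else                          # advance along Z, circle in XY
    list(x = r * cos(ang), y = r * sin(ang), z = adv)
}

#' Generate one spiral trial with linear EEG-kinematics coupling
#'
#' @param which `"SPIRAL1"` (advance along Y) or `"SPIRAL2"` (along Z).
#' @param cfg A [synthetic_config()].
#' @param index Repetition index.
#' @param truth Optional shared truth record from [decoder_truth()];
#'   created from `cfg` when NULL.
#' @return An epoched `synced_trial` with attribute `"truth"`.
#' @export
generate_spiral_trial <- function(which = c("SPIRAL1", "SPIRAL2"),
                                  cfg = synthetic_config(), index = 1,
                                  truth = NULL) {
  which <- match.arg(which)
  if (cfg$spiral_s <= cfg$unit_s) stop("spiral duration must exceed unit_s")
  if (is.null(truth)) truth <- decoder_truth(cfg)
  set.seed(child_seed(cfg$seed, "spiral", which, index))
  n <- round(cfg$spiral_s * cfg$rate)
  tr <- (seq_len(n) - 1) / cfg$rate
  axr <- spiral_axes(which, cfg, tr)
  A <- scale(cbind(axr$x, axr$y, axr$z))   # n x 3, standardized axes
  A[is.nan(A)] <- 0
  # hidden epoch state: gain + coupling modulation
  n_ep <- floor(cfg$spiral_s / cfg$unit_s)
  # balanced alternating state with a random phase, so both states occur
  # in every trial of more than one epoch
  z <- if (cfg$slope_modulation > 0)
    rep(c(-1, 1), length.out = n_ep + 1)[sample(1:2, 1) - 1 + seq_len(n_ep)]
  else rep(0, n_ep)
  ep_of <- pmin(floor(tr / cfg$unit_s) + 1, n_ep)
  gain <- 1 + cfg$slope_modulation * z[ep_of]
  ne <- length(cfg$electrodes)
  sig <- truth$mixing %*% t(A / gain)      # electrodes x n
  noise <- t(vapply(seq_len(ne), function(i) pink_noise(n), numeric(n)))
  eeg_mat <- sig + cfg$noise_sd * noise
  if (cfg$slope_modulation > 0 && length(cfg$planted_pairs) > 0) {
    # state-scaled pair synchrony: injected latent amplitude follows the
    # epoch's coupling state, so the band network flags the hidden state
    # (unlike mode trials, band power here may vary with the state)
    rng <- band_range(cfg$planted_band)
    rownames(eeg_mat) <- cfg$electrodes
    for (e_i in seq_len(n_ep)) {
      idx <- which(ep_of == e_i)
      cpl <- if (z[e_i] > 0) cfg$coupling_states[2] else
        cfg$coupling_states[1]
      for (p in cfg$planted_pairs) {
        lat <- band_noise(length(idx), cfg$rate, rng["lo"], rng["hi"])
        for (e in p)
          eeg_mat[e, idx] <- eeg_mat[e, idx] + cfg$coupling_gain * cpl * lat
      }
    }
  }
  eeg_mat <- eeg_mat * 10
  ttj <- seq(0, cfg$spiral_s - 1 / cfg$traj_rate, by = 1 / cfg$traj_rate)
  axj <- spiral_axes(which, cfg, ttj)
  trial <- finish_trial(cfg, eeg_mat, ttj, axj$x, axj$y, axj$z, which)
  attr(trial, "truth") <- c(truth, list(state = z))
  trial
}

#' Ground-truth record for the spiral forward model
#'
#' @param cfg A [synthetic_config()].
#' @return List: `mixing` (electrodes x 3), planted pairs/couplings,
#'   modulation, seed. Regenerating from the same cfg is bit-identical.
#' @export
decoder_truth <- function(cfg) {
  set.seed(child_seed(cfg$seed, "truth"))
  ne <- length(cfg$electrodes)
  M <- matrix(stats::rnorm(ne * 3), ne, 3,
              dimnames = list(cfg$electrodes, c("x", "y", "z")))
  list(mixing = M, planted_band = cfg$planted_band,
       planted_pairs = cfg$planted_pairs,
       coupling_by_mode = cfg$coupling_by_mode,
       coupling_states = cfg$coupling_states,
       slope_modulation = cfg$slope_modulation, seed = cfg$seed)
}

#' Generate a full synthetic dataset
#'
#' @param cfg A [synthetic_config()].
#' @param preset `"experiment1"` (mode trials), `"experiment2"` (spiral
#'   trials), `"null"` (mode trials, mode-invariant coupling) or
#'   `"planted"` (alias of experiment1).
#' @param out_dir Optional directory: trials are written as bundles plus a
#'   `truth.json`.
#' @return List: `trials`, `truth`, `preset`.
#' @export
generate_dataset <- function(cfg = synthetic_config(),
                             preset = c("experiment1", "experiment2",
                                        "null", "planted"),
                             out_dir = NULL) {
  preset <- match.arg(preset)
  if (preset == "null")
    cfg$coupling_by_mode <- list(UD = 0, LR = 0, BF = 0)
  trials <- list()
  if (preset == "experiment2") {
    truth <- decoder_truth(cfg)
    for (w in c("SPIRAL1", "SPIRAL2"))
      for (i in seq_len(cfg$n_repetitions))
        trials[[length(trials) + 1]] <-
          generate_spiral_trial(w, cfg, i, truth)
  } else {
    truth <- list(planted_band = cfg$planted_band,
                  planted_pairs = cfg$planted_pairs,
                  coupling_by_mode = cfg$coupling_by_mode,
                  seed = cfg$seed)
    for (m in c("UD", "LR", "BF"))
      for (i in seq_len(cfg$n_trials))
        trials[[length(trials) + 1]] <- generate_mode_trial(m, cfg, i)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_along(trials))
      write_trial_bundle(trials[[i]],
                         file.path(out_dir, sprintf("trial_%03d", i)))
    tr <- truth
    if (!is.null(tr$mixing)) tr$mixing <- as.data.frame(tr$mixing)
    jsonlite::write_json(c(list(version = 1L, preset = preset), tr),
                         file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(trials = trials, truth = truth, preset = preset)
}
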
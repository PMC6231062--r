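# Shared reduced-scale synthetic scenarios. Parameters are the suite's
# stated world, chosen once (see the methods vignette) and reused by the
# unit and acceptance tests.

ELS8 <- c("C3", "CZ", "C4", "F3", "F4", "P3", "PZ", "P4")
ELS6 <- c("C3", "CZ", "C4", "F3", "F4", "P3")
TRIANGLE <- list(c("C3", "CZ"), c("CZ", "C4"), c("C3", "C4"))

# small fast config for plumbing tests
cfg_small <- function(seed = 1, trial_s = 6, ...) {
  synthetic_config(seed = seed, rate = 200, analysis_rate = 50,
                   electrodes = ELS8, trial_s = trial_s, ...)
}

# planted mode-dependent coupling at full epoch count (100 epochs/mode
# via 10 trials x 10 epochs), reduced rate/electrode budget
cfg_planted <- function(seed = 1)
  synthetic_config(seed = seed, rate = 200, analysis_rate = 50,
                   electrodes = ELS8, trial_s = 20, unit_s = 2,
                   n_trials = 10, planted_pairs = TRIANGLE,
                   coupling_by_mode = list(UD = 0.8, LR = 0.2, BF = 0.2))

# null coupling for type-I calibration (1-s epochs, 10 epochs/mode)
cfg_null <- function(seed = 1)
  synthetic_config(seed = seed, rate = 200, analysis_rate = 50,
                   electrodes = ELS8, trial_s = 10, unit_s = 1,
                   coupling_by_mode = list(UD = 0, LR = 0, BF = 0))

# spiral scenario with network-state-modulated slopes (the planted
# HLM-over-MLR advantage)
cfg_spiral_mod <- function(seed = 1, slope_modulation = 0.95)
  synthetic_config(seed = seed, rate = 200, analysis_rate = 50,
                   electrodes = ELS6, planted_pairs = TRIANGLE,
                   spiral_s = 16, noise_sd = 0.3,
                   slope_modulation = slope_modulation,
                   coupling_states = c(0, 0.9), coupling_gain = 2)

make_mode_trials <- function(cfg, n_per_mode, bands = "theta",
                             cost = 0.18) {
  trials <- list()
  for (m in c("UD", "LR", "BF")) for (i in seq_len(n_per_mode))
    trials[[length(trials) + 1]] <- generate_mode_trial(m, cfg, i)
  lapply(trials, compute_bfn_features, bands = bands, cost = cost)
}

make_spiral_trials <- function(cfg, n, which = "SPIRAL1", bands = "theta",
                               cost = 0.18) {
  tru <- decoder_truth(cfg)
  trials <- lapply(seq_len(n), function(i)
    generate_spiral_trial(which, cfg, i, tru))
  lapply(trials, compute_bfn_features, bands = bands, cost = cost)
}

# held-out subject scores for both decoders on one planted replicate
hlm_vs_mlr_rep <- function(seed) {
  trials <- make_spiral_trials(cfg_spiral_mod(seed), 8)
  l1 <- l1_spec(electrodes = ELS6, lags = 5)
  l2 <- l2_spec(bands = "theta", history = 0)
  mh <- fit_hlm(trials[1:5], l1, l2)
  mm <- fit_mlr(trials[1:5], l1)
  score <- function(m) mean(vapply(6:8, function(i) {
    p <- smooth_decoded(predict_trajectory(m, trials[[i]]), rate = 50)
    subject_score(axis_pcc(trials[[i]]$trajectory, p$xyz))
  }, numeric(1)))
  c(hlm = score(mh), mlr = score(mm))
}
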
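# Composite design construction, ridge fitting, nesting, prediction.

test_that("design widths follow the coefficient-count formula", {
  cfg <- cfg_small(seed = 10, trial_s = 16)
  tr <- make_spiral_trials(cfg_spiral_mod(10), 1)[[1]]
  # N=6, L1=10, 1 band, L2=1 -> 1 + 2*2 + 6*11 + 66*2*1*2 = 335
  d <- build_design(tr, l1_spec(ELS6, lags = 10),
                    l2_spec("theta", history = 1))
  expect_equal(ncol(d$X), 1 + 4 + 66 + 264)
  # MLR design: 1 + N(L1+1)
  dm <- build_design(tr, l1_spec(ELS6, lags = 10), NULL)
  expect_equal(ncol(dm$X), 1 + 66)
  # L1=0, L2=0, 1 electrode, 1 band -> width 6
  d1 <- build_design(tr, l1_spec("C3", lags = 0),
                     l2_spec("theta", history = 0))
  expect_equal(ncol(d1$X), 6)
  # the full-size formula evaluated independently
  n <- 8; l1 <- 10; nb <- 3; l2 <- 3
  expect_equal(1 + 2 * (l2 + 1) + n * (l1 + 1) +
                 n * (l1 + 1) * 2 * nb * (l2 + 1), 2209)
})

test_that("too-short trials yield an empty design with a warning", {
  tr <- make_spiral_trials(cfg_spiral_mod(11), 1)[[1]]
  expect_warning(
    d <- build_design(tr, l1_spec(ELS6, lags = 5),
                      l2_spec("theta", history = 50)),
    "too short")
  expect_equal(nrow(d$X), 0)
})

test_that("constant targets are fit by the intercept alone", {
  tr <- make_spiral_trials(cfg_spiral_mod(12), 1)[[1]]
  tr$trajectory[, ] <- rep(c(5, -2, 11), each = nrow(tr$trajectory))
  m <- fit_mlr(list(tr), l1_spec(ELS6, lags = 2), lambda = 1e-8)
  p <- predict_trajectory(m, tr)
  ok <- p$t_index
  expect_lt(max(abs(p$xyz[ok, 1] - 5)), 1e-6)
  expect_lt(max(abs(p$xyz[ok, 3] - 11)), 1e-6)
  expect_lt(max(abs(m$coef)), 1e-6)
})

test_that("known composite coefficients are recovered on clean data", {
  # simulate directly from a composite design (width << samples)
  set.seed(13)
  trials <- make_spiral_trials(cfg_spiral_mod(13, slope_modulation = 0), 4)
  l1 <- l1_spec(ELS6, lags = 2); l2 <- l2_spec("theta", history = 0)
  cs <- bfndecode:::covariate_stats(trials, l2$bands)
  d <- lapply(trials, build_design, l1spec = l1, l2spec = l2,
              cov_stats = cs)
  X <- do.call(rbind, lapply(d, `[[`, "X"))
  st <- bfndecode:::standardize_design(X)
  p <- ncol(st$Z)
  beta <- matrix(rnorm(p * 3), p, 3) * st$keep
  Y <- st$Z %*% beta + matrix(rnorm(nrow(X) * 3, sd = 0.1), ncol = 3)
  off <- 0
  for (i in seq_along(trials)) {
    idx <- off + seq_len(nrow(d[[i]]$X))
    trials[[i]]$trajectory[d[[i]]$t_index, ] <- Y[idx, ]
    off <- off + nrow(d[[i]]$X)
  }
  m <- fit_hlm(trials, l1, l2, lambda = 1e-6)
  err <- sqrt(sum((m$coef - beta)^2)) / sqrt(sum(beta^2))
  expect_lt(err, 0.1)
})

test_that("HLM collapses onto MLR when level-2 covariates are constant", {
  trials <- make_spiral_trials(cfg_spiral_mod(14, slope_modulation = 0), 3)
  for (i in seq_along(trials)) {
    f <- trials[[i]]$features$metrics
    f$Cluster <- 0.42; f$VPLength <- 1.7
    trials[[i]]$features$metrics <- f
  }
  # history = 0 keeps the usable row set identical to the baseline's
  l1 <- l1_spec(ELS6, lags = 4)
  mh <- fit_hlm(trials[1:2], l1, l2_spec("theta", history = 0),
                lambda = 0.5)
  mm <- fit_mlr(trials[1:2], l1, lambda = 0.5)
  ph <- predict_trajectory(mh, trials[[3]])
  pm <- predict_trajectory(mm, trials[[3]])
  expect_lt(max(abs(ph$xyz - pm$xyz), na.rm = TRUE), 1e-8)
})

test_that("single-electrode noiseless line fit recovers slope and intercept", {
  tr <- make_spiral_trials(cfg_spiral_mod(15, slope_modulation = 0), 1)[[1]]
  l1 <- l1_spec("C3", lags = 0)
  d <- build_design(tr, l1, NULL)
  s <- d$X[, 2]
  tr$trajectory[d$t_index, ] <- cbind(2 * s + 3, 2 * s + 3, 2 * s + 3)
  m <- fit_mlr(list(tr), l1, lambda = 1e-10)
  p <- predict_trajectory(m, tr)
  expect_equal(p$xyz[d$t_index, 1], 2 * s + 3, tolerance = 1e-6,
               ignore_attr = TRUE)
  # slope in original units: standardized coef / scale
  expect_equal(unname(m$coef[1, 1] / m$scale[1]), 2, tolerance = 1e-6)
})

test_that("memorization on noiseless data reaches r > 0.999", {
  cfg <- cfg_spiral_mod(16, slope_modulation = 0)
  cfg$noise_sd <- 0
  tru <- decoder_truth(cfg)
  tr <- compute_bfn_features(generate_spiral_trial("SPIRAL1", cfg, 1, tru),
                             bands = "theta")
  m <- fit_mlr(list(tr), l1_spec(ELS6, lags = 5), lambda = 1e-8)
  p <- predict_trajectory(m, tr)
  r <- axis_pcc(tr$trajectory, p$xyz)
  expect_true(all(r > 0.999))
})

test_that("shuffled targets decode at chance", {
  set.seed(17)
  rs <- vapply(1:5, function(i) {
    trials <- make_spiral_trials(cfg_spiral_mod(100 + i), 3)
    for (j in 1:3) {
      n <- nrow(trials[[j]]$trajectory)
      trials[[j]]$trajectory <- trials[[j]]$trajectory[sample(n), ]
    }
    m <- fit_mlr(trials[1:2], l1_spec(ELS6, lags = 3), lambda = 10)
    p <- predict_trajectory(m, trials[[3]])
    subject_score(axis_pcc(trials[[3]]$trajectory, p$xyz))
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.1)
})

test_that("zero EEG input decodes to the intercept path", {
  trials <- make_spiral_trials(cfg_spiral_mod(18, slope_modulation = 0), 1)
  m <- fit_mlr(trials, l1_spec(ELS6, lags = 2), lambda = 1)
  tr <- trials[[1]]
  tr$analysis[, ] <- 0
  p <- predict_trajectory(m, tr)
  ok <- p$t_index
  # standardized zero-EEG rows are constant -> constant prediction
  expect_lt(max(apply(p$xyz[ok, ], 2, sd)), 1e-9)
})

test_that("electrode order in the trial does not change predictions", {
  trials <- make_spiral_trials(cfg_spiral_mod(19), 2)
  m <- fit_hlm(trials[1], l1_spec(ELS6, lags = 2),
               l2_spec("theta", history = 0), lambda = 1)
  tr <- trials[[2]]
  perm <- rev(seq_len(nrow(tr$eeg$samples)))
  tr$eeg$samples <- tr$eeg$samples[perm, ]
  tr$eeg$channel_labels <- tr$eeg$channel_labels[perm]
  tr$eeg$aux <- tr$eeg$aux[perm]
  tr$analysis <- tr$analysis[perm, ]
  p1 <- predict_trajectory(m, trials[[2]])
  p2 <- predict_trajectory(m, tr)
  expect_equal(p1$xyz, p2$xyz, tolerance = 1e-12)
})

test_that("predictions are equivariant to target rescaling", {
  trials <- make_spiral_trials(cfg_spiral_mod(20), 2)
  l1 <- l1_spec(ELS6, lags = 2)
  m1 <- fit_mlr(trials[1], l1, lambda = 1)
  scaled <- trials
  scaled[[1]]$trajectory <- scaled[[1]]$trajectory * 3
  m2 <- fit_mlr(scaled[1], l1, lambda = 1)
  p1 <- predict_trajectory(m1, trials[[2]])
  p2 <- predict_trajectory(m2, trials[[2]])
  expect_equal(3 * p1$xyz, p2$xyz, tolerance = 1e-8)
})

test_that("model JSON serialization round-trips predictions", {
  trials <- make_spiral_trials(cfg_spiral_mod(21), 2)
  m <- fit_hlm(trials[1], l1_spec(ELS6, lags = 2),
               l2_spec("theta", history = 0), lambda = 1)
  f <- withr::local_tempfile(fileext = ".json")
  bfndecode:::saveRDS_json(m, f)
  back <- bfndecode:::readRDS_json(f)
  p1 <- predict_trajectory(m, trials[[2]])
  p2 <- predict_trajectory(back, trials[[2]])
  expect_equal(p1$xyz, p2$xyz, tolerance = 1e-9)
})
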
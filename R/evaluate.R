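# Scoring decoded trajectories, cross-validation, and reference-range ROC.

#' Smooth a decoded trajectory
#'
#' Zero-phase fourth-order Butterworth low-pass (default 1 Hz cutoff)
#' applied per axis before correlation scoring. Missing (NA) stretches at
#' the start are preserved.
#'
#' @param decoded A `decoded_trajectory` (or plain matrix with columns
#'   x,y,z).
#' @param rate Analysis rate in Hz (taken from the object when present).
#' @param order Filter order (default 4).
#' @param cutoff_hz Cutoff frequency (default 1 Hz).
#' @return Object/matrix of the same shape, smoothed.
#' @export
smooth_decoded <- function(decoded, rate = NULL, order = 4,
                           cutoff_hz = 1) {
  is_obj <- inherits(decoded, "decoded_trajectory")
  xyz <- if (is_obj) decoded$xyz else as.matrix(decoded)
  if (is.null(rate)) {
    if (!is_obj || length(decoded$times) < 2)
      stop("rate must be supplied")
    rate <- 1 / diff(decoded$times[1:2])
  }
  if (rate <= 2 * cutoff_hz) stop("analysis rate too low for the cutoff")
  d <- butter_lowpass(order, cutoff_hz, rate)
  for (j in seq_len(ncol(xyz))) {
    ok <- !is.na(xyz[, j])
    if (sum(ok) < 3 * (order + 1)) {
      warning("axis ", j, " too short to smooth; skipped")
      next
    }
    xyz[ok, j] <- filtfilt_ba(d$b, d$a, xyz[ok, j])
  }
  if (is_obj) { decoded$xyz <- xyz; decoded } else xyz
}

#' Per-axis Pearson correlation of measured vs decoded trajectory
#'
#' @param measured Matrix/data.frame with columns x,y,z (mm).
#' @param decoded Matrix of the same shape (rows with NA are dropped
#'   pairwise).
#' @return Named numeric `c(R_x, R_y, R_z)`; an axis with zero variance in
#'   either series is NA with a warning.
#' @export
axis_pcc <- function(measured, decoded) {
  measured <- as.matrix(measured); decoded <- as.matrix(decoded)
  out <- c(R_x = NA_real_, R_y = NA_real_, R_z = NA_real_)
  for (j in 1:3) {
    ok <- !is.na(measured[, j]) & !is.na(decoded[, j])
    if (sum(ok) < 3) { warning("axis ", j, ": fewer than 3 points"); next }
    a <- measured[ok, j]; b <- decoded[ok, j]
    if (stats::sd(a) < 1e-12 || stats::sd(b) < 1e-12) {
      warning("axis ", j, ": zero variance, score undefined")
      next
    }
    out[j] <- stats::cor(a, b)
  }
  out
}

#' Subject score: mean of the three axis correlations
#'
#' @param axis_scores Numeric vector of three per-axis correlations.
#' @return Their arithmetic mean (NA if any axis is undefined).
#' @export
subject_score <- function(axis_scores) {
  if (length(axis_scores) != 3) stop("expected three axis scores")
  mean(axis_scores)
}

#' Mean score over subjects
#'
#' @param subject_scores Numeric vector of per-subject mean correlations.
#' @return Arithmetic mean.
#' @export
aggregate_scores <- function(subject_scores) {
  if (length(subject_scores) == 0) stop("empty score list")
  mean(subject_scores)
}

#' Cross-validation fold plan
#'
#' @param n_trials Number of trials to partition.
#' @param runs Shuffled repetitions (default 10).
#' @param folds Folds per run (default 10).
#' @param seed RNG seed; assignments are reproducible from it.
#' @return List of class `fold_plan` with `assignment[[run]]`: integer
#'   fold id per trial.
#' @export
fold_plan <- function(n_trials, runs = 10, folds = 10, seed = 1) {
  if (folds > n_trials) stop("folds (", folds, ") > trials (", n_trials, ")")
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  assignment <- lapply(seq_len(runs), function(r) {
    f <- rep(seq_len(folds), length.out = n_trials)
    sample(f)
  })
  structure(list(runs = runs, folds = folds, seed = seed,
                 assignment = assignment),
            class = "fold_plan")
}

#' Repeated k-fold cross-validation of a decoder
#'
#' Per run, trials are partitioned by the seeded fold plan; per fold the
#' decoder is trained on the remaining trials and each held-out trial is
#' decoded, smoothed, and scored (Pearson r per axis, mean over axes and
#' trials).
#'
#' @param trials List of epoched trials with features.
#' @param fitter `function(train_trials) -> function(trial) ->
#'   decoded xyz matrix`; see [hlm_fitter()] for the default decoders.
#' @param plan A [fold_plan()].
#' @param smooth Smooth predictions before scoring (default TRUE).
#' @return List: `scores` data.frame (run, fold, R_x, R_y, R_z, R),
#'   `mean_R`, `sd_R`, `plan`.
#' @export
cross_validate <- function(trials, fitter, plan, smooth = TRUE) {
  rate <- trials[[1]]$analysis_rate
  rows <- list()
  for (r in seq_len(plan$runs)) {
    fa <- plan$assignment[[r]]
    for (f in sort(unique(fa))) {
      test_i <- which(fa == f)
      dec <- fitter(trials[-test_i])
      sc <- vapply(test_i, function(i) {
        pred <- dec(trials[[i]])
        if (smooth) pred <- smooth_decoded(pred, rate = rate)
        if (inherits(pred, "decoded_trajectory")) pred <- pred$xyz
        axis_pcc(trials[[i]]$trajectory, pred)
      }, numeric(3))
      m <- rowMeans(sc, na.rm = TRUE)
      rows[[length(rows) + 1]] <- data.frame(
        run = r, fold = f, R_x = m[1], R_y = m[2], R_z = m[3],
        R = mean(m))
    }
  }
  scores <- do.call(rbind, rows)
  list(scores = scores, mean_R = mean(scores$R), sd_R = stats::sd(scores$R),
       plan = plan)
}

#' Default model-based decoder factories for cross-validation
#'
#' @param model `"hlm"` or `"mlr"`.
#' @param l1spec,l2spec Model specifications.
#' @param ... Passed to [fit_hlm()] / [fit_mlr()].
#' @return A fitter function for [cross_validate()].
#' @export
hlm_fitter <- function(model = c("hlm", "mlr"), l1spec = l1_spec(),
                       l2spec = l2_spec(), ...) {
  model <- match.arg(model)
  function(train_trials) {
    m <- if (model == "hlm")
      fit_hlm(train_trials, l1spec, l2spec, ...)
    else fit_mlr(train_trials, l1spec, ...)
    function(trial) predict_trajectory(m, trial)
  }
}

#' Reference-range ROC of decoded vs measured series
#'
#' Both series are binarized by the central `coverage` reference interval
#' of the *measured* series convention: values inside the interval are 0
#' (normal), outside are 1 (abnormal); each series uses its own empirical
#' interval. The AUC is the rank-sum probability that the decoded flag of
#' a measured-abnormal point exceeds that of a measured-normal point.
#'
#' @param measured,decoded Numeric vectors (equal length; NA pairs
#'   dropped).
#' @param coverage Central coverage of the reference interval (default
#'   0.95).
#' @return List of class `roc_result`: `auc`, `bounds_measured`,
#'   `bounds_decoded`, `labels`, `flags`.
#' @export
roc_reference_range <- function(measured, decoded, coverage = 0.95) {
  ok <- !is.na(measured) & !is.na(decoded)
  measured <- measured[ok]; decoded <- decoded[ok]
  if (stats::sd(measured) < 1e-12 || stats::sd(decoded) < 1e-12)
    stop("degenerate series")
  a <- (1 - coverage) / 2
  bm <- stats::quantile(measured, c(a, 1 - a), names = FALSE)
  bd <- stats::quantile(decoded, c(a, 1 - a), names = FALSE)
  labels <- as.integer(measured < bm[1] | measured > bm[2])
  flags <- as.integer(decoded < bd[1] | decoded > bd[2])
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    warning("all-one or all-zero labels: AUC undefined")
    return(structure(list(auc = NA_real_, bounds_measured = bm,
                          bounds_decoded = bd), class = "roc_result"))
  }
  rk <- rank(flags)
  auc <- (sum(rk[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  structure(list(auc = auc, bounds_measured = bm, bounds_decoded = bd,
                 labels = labels, flags = flags),
            class = "roc_result")
}
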
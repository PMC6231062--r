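# Two-level hierarchical linear trajectory decoder and MLR baseline.
#
# Level 1 regresses each hand coordinate on lagged EEG from the selected
# electrodes. Level 2 lets epoch-level network metrics (clustering, average
# path length per selected band, and their across-band means) modulate the
# Level-1 intercept and slopes. Substituting Level 2 into Level 1 yields a
# single linear model whose predictors are the lagged EEG samples, the
# network covariates, and their interactions; it is fitted by ridge
# regression on standardized predictors. Zero-variance predictors are
# zeroed by standardization, so with constant network covariates the model
# collapses exactly onto the MLR baseline.

#' Level-1 specification: electrodes and lag window
#'
#' @param electrodes Electrode labels used as EEG inputs (default the 8
#'   characteristic ones).
#' @param lags Number of lags L1 at the analysis rate (default 10, i.e.
#'   100 ms of history at 100 Hz); lag 0 is always included.
#' @return List of class `l1_spec`.
#' @export
l1_spec <- function(electrodes = characteristic_electrodes(), lags = 10) {
  if (lags < 0) stop("lags must be >= 0")
  if (length(electrodes) == 0) stop("need at least one electrode")
  structure(list(electrodes = normalize_label(electrodes), lags = lags),
            class = "l1_spec")
}

#' Level-2 specification: bands and epoch history
#'
#' @param bands Bands whose clustering / path-length covariates enter
#'   Level 2 (default the characteristic delta/theta/gamma1).
#' @param history Epoch-history length L2; covariates from epochs
#'   `tau - 0 ... tau - L2` enter the model (default 3).
#' @return List of class `l2_spec`.
#' @export
l2_spec <- function(bands = characteristic_bands(), history = 3) {
  if (history < 0) stop("history must be >= 0")
  structure(list(bands = bands, history = history), class = "l2_spec")
}

# epoch id for each analysis-grid time index; NA outside the epoched span
epoch_of_times <- function(trial) {
  if (is.null(trial$epochs) || nrow(trial$epochs) == 0)
    stop("trial has no epochs; call epoch_trial() first")
  e <- findInterval(trial$times + 1e-9, trial$epochs[, "start"])
  e[e < 1 | trial$times >= trial$epochs[nrow(trial$epochs), "end"] - 1e-9] <-
    NA
  e
}

# covariate lookup: matrix epochs x (band) for one metric
feature_matrix <- function(trial, bands, metric) {
  f <- trial$features$metrics
  if (is.null(f)) stop("trial has no computed BFN features")
  n_ep <- nrow(trial$epochs)
  out <- matrix(NA_real_, n_ep, length(bands),
                dimnames = list(NULL, bands))
  for (b in bands) {
    sub <- f[f$band == b, ]
    if (nrow(sub) == 0) stop("missing band features: ", b)
    miss <- setdiff(seq_len(n_ep), sub$epoch)
    if (length(miss) > 0)
      stop("missing features for (epoch ", miss[1], ", band ", b, ")")
    out[sub$epoch, b] <- sub[[metric]]
  }
  out
}

# training-set mean/sd of the epoch-level covariates, per (metric, band)
covariate_stats <- function(trials, bands) {
  st <- list()
  for (b in bands) {
    cl <- unlist(lapply(trials, function(tr) {
      f <- tr$features$metrics
      f$Cluster[f$band == b]
    }))
    pl <- unlist(lapply(trials, function(tr) {
      f <- tr$features$metrics
      f$VPLength[f$band == b]
    }))
    st[[paste0("C.", b)]] <- c(center = mean(cl), scale = stats::sd(cl))
    st[[paste0("L.", b)]] <- c(center = mean(pl), scale = stats::sd(pl))
  }
  st
}

std_cov <- function(v, stat) {
  s <- stat[["scale"]]
  if (!is.finite(s) || s < 1e-12) return(rep(0, length(v)))
  (v - stat[["center"]]) / s
}

#' Build the composite regression design for one trial
#'
#' Per usable time point the predictor row is
#' `[1; Cmean_{tau-k}, Lmean_{tau-k} (k=0..L2); S_n(t-s);
#'   S_n(t-s) * C^phi_{tau-k}, S_n(t-s) * L^phi_{tau-k}]`.
#' Network covariates are centred and scaled by training statistics before
#' entering interactions, so a covariate that is constant over the training
#' set contributes nothing (and the model then collapses exactly onto the
#' Level-1-only baseline). Time points with incomplete lag or epoch history
#' are dropped.
#'
#' @param trial Epoched trial with computed features (for HLM designs).
#' @param l1spec An [l1_spec()].
#' @param l2spec An [l2_spec()], or `NULL` for the MLR (Level-1 only)
#'   design.
#' @param cov_stats Covariate centring statistics (computed from the
#'   training trials by the fitters; computed from this trial if NULL).
#' @return List: `X` (raw design incl. intercept column), `Y` (targets in
#'   mm), `t_index` (analysis-grid indices of the rows), `colnames`.
#' @export
build_design <- function(trial, l1spec, l2spec = NULL, cov_stats = NULL) {
  labs <- trial$eeg$channel_labels
  sel <- match(l1spec$electrodes, labs)
  if (anyNA(sel))
    stop("electrode(s) not in trial: ",
         paste(l1spec$electrodes[is.na(sel)], collapse = ", "))
  S <- trial$analysis[sel, , drop = FALSE]
  L1 <- l1spec$lags
  ep <- epoch_of_times(trial)
  L2 <- if (is.null(l2spec)) 0L else l2spec$history
  usable <- which(!is.na(ep) & seq_along(ep) > L1 &
                    (is.null(l2spec) | ep > L2))
  empty <- function() {
    warning("trial too short for the requested lag/epoch history")
    list(X = matrix(numeric(0), 0, 0), Y = matrix(numeric(0), 0, 3),
         t_index = integer(0), colnames = character(0))
  }
  if (length(usable) == 0) return(empty())
  N <- length(sel)
  # lagged EEG block
  lag_names <- as.vector(outer(l1spec$electrodes, 0:L1,
                               function(e, s) paste0("S[", e, ",s", s, "]")))
  Slag <- matrix(0, length(usable), N * (L1 + 1))
  for (s in 0:L1)
    Slag[, s * N + seq_len(N)] <- t(S[, usable - s, drop = FALSE])
  # reorder so electrode varies fastest within lag blocks already true
  colnames(Slag) <- as.vector(vapply(0:L1, function(s)
    paste0("S[", l1spec$electrodes, ",s", s, "]"), character(N)))
  if (is.null(l2spec)) {
    X <- cbind(`(Intercept)` = 1, Slag)
    return(list(X = X, Y = trial$trajectory[usable, , drop = FALSE],
                t_index = usable, colnames = colnames(X)))
  }
  Cm <- feature_matrix(trial, l2spec$bands, "Cluster")
  Lm <- feature_matrix(trial, l2spec$bands, "VPLength")
  if (is.null(cov_stats)) cov_stats <- covariate_stats(list(trial),
                                                       l2spec$bands)
  for (b in l2spec$bands) {
    Cm[, b] <- std_cov(Cm[, b], cov_stats[[paste0("C.", b)]])
    Lm[, b] <- std_cov(Lm[, b], cov_stats[[paste0("L.", b)]])
  }
  cov_blocks <- list()
  for (k in 0:L2) {
    ek <- ep[usable] - k
    cb <- matrix(NA_real_, length(usable), 2,
                 dimnames = list(NULL, paste0(c("Cmean", "Lmean"),
                                              "[k", k, "]")))
    cb[, 1] <- rowMeans(Cm[ek, , drop = FALSE])
    cb[, 2] <- rowMeans(Lm[ek, , drop = FALSE])
    cov_blocks[[k + 1]] <- cb
  }
  V <- do.call(cbind, cov_blocks)
  inter <- list()
  for (b in l2spec$bands) for (k in 0:L2) {
    ek <- ep[usable] - k
    cC <- Cm[ek, b]; cL <- Lm[ek, b]
    blkC <- Slag * cC
    colnames(blkC) <- paste0(colnames(Slag), "xC[", b, ",k", k, "]")
    blkL <- Slag * cL
    colnames(blkL) <- paste0(colnames(Slag), "xL[", b, ",k", k, "]")
    inter[[length(inter) + 1]] <- blkC
    inter[[length(inter) + 1]] <- blkL
  }
  X <- cbind(`(Intercept)` = 1, V, Slag, do.call(cbind, inter))
  list(X = X, Y = trial$trajectory[usable, , drop = FALSE],
       t_index = usable, colnames = colnames(X))
}

# standardize all non-intercept columns; zero-variance columns become 0
standardize_design <- function(X, center = NULL, scale = NULL) {
  Xs <- X[, -1, drop = FALSE]
  if (is.null(center)) {
    center <- colMeans(Xs)
    scale <- apply(Xs, 2, stats::sd)
  }
  keep <- scale > 1e-12
  Z <- sweep(Xs, 2, center, "-")
  Z <- sweep(Z, 2, ifelse(keep, scale, 1), "/")
  Z[, !keep] <- 0
  list(Z = Z, center = center, scale = scale, keep = keep)
}

ridge_solve <- function(Z, Yc, lambda) {
  p <- ncol(Z)
  A <- crossprod(Z) + diag(lambda, p)
  solve(A, crossprod(Z, Yc))
}

fit_composite <- function(trials, l1spec, l2spec, lambda = NULL,
                          lambda_grid = 10^seq(-3, 3, length.out = 7),
                          inner_frac = 0.2) {
  cov_stats <- if (is.null(l2spec)) NULL else
    covariate_stats(trials, l2spec$bands)
  designs <- lapply(trials, build_design, l1spec = l1spec,
                    l2spec = l2spec, cov_stats = cov_stats)
  designs <- designs[vapply(designs, function(d) nrow(d$X) > 0, logical(1))]
  if (length(designs) == 0) stop("no usable design rows in any trial")
  X <- do.call(rbind, lapply(designs, `[[`, "X"))
  Y <- do.call(rbind, lapply(designs, `[[`, "Y"))
  if (is.null(lambda) && length(lambda_grid) > 1) {
    n <- nrow(X)
    n_val <- max(3, floor(inner_frac * n))
    tr <- seq_len(n - n_val); va <- (n - n_val + 1):n
    st <- standardize_design(X[tr, , drop = FALSE])
    my <- colMeans(Y[tr, , drop = FALSE])
    Yc <- sweep(Y[tr, , drop = FALSE], 2, my, "-")
    Zva <- standardize_design(X[va, , drop = FALSE], st$center, st$scale)$Z
    score <- vapply(lambda_grid, function(l) {
      B <- ridge_solve(st$Z, Yc, l)
      P <- sweep(Zva %*% B, 2, my, "+")
      mean(vapply(1:3, function(j) {
        if (stats::sd(P[, j]) < 1e-12) return(0)
        stats::cor(P[, j], Y[va, j])
      }, numeric(1)))
    }, numeric(1))
    lambda <- lambda_grid[which.max(score)]
  } else if (is.null(lambda)) {
    lambda <- lambda_grid[1]
  }
  st <- standardize_design(X)
  my <- colMeans(Y)
  B <- ridge_solve(st$Z, sweep(Y, 2, my, "-"), lambda)
  resid <- sweep(st$Z %*% B, 2, my, "+") - Y
  structure(list(l1spec = l1spec, l2spec = l2spec,
                 cov_stats = cov_stats,
                 coef = B, y_center = my,
                 center = st$center, scale = st$scale, keep = st$keep,
                 lambda = lambda, colnames = colnames(X),
                 residual_sd = apply(resid, 2, stats::sd)),
            class = if (is.null(l2spec)) c("mlr_model", "decoder_model")
                    else c("hlm_model", "decoder_model"))
}

#' Fit the hierarchical linear decoding model
#'
#' @param trials List of epoched trials with computed BFN features.
#' @param l1spec An [l1_spec()].
#' @param l2spec An [l2_spec()].
#' @param lambda Ridge penalty; if `NULL`, chosen from `lambda_grid` by
#'   held-out correlation on the last `inner_frac` of training rows.
#' @param lambda_grid Candidate penalties (log-spaced 1e-3..1e3).
#' @param inner_frac Fraction of rows reserved for penalty selection.
#' @return An `hlm_model`.
#' @export
fit_hlm <- function(trials, l1spec = l1_spec(), l2spec = l2_spec(),
                    lambda = NULL,
                    lambda_grid = 10^seq(-3, 3, length.out = 7),
                    inner_frac = 0.2) {
  if (inherits(trials, "synced_trial")) trials <- list(trials)
  fit_composite(trials, l1spec, l2spec, lambda, lambda_grid, inner_frac)
}

#' Fit the multiple-linear-regression baseline decoder
#'
#' Level-1-only lagged linear regression (no network covariates).
#'
#' @inheritParams fit_hlm
#' @return An `mlr_model`.
#' @export
fit_mlr <- function(trials, l1spec = l1_spec(), lambda = NULL,
                    lambda_grid = 10^seq(-3, 3, length.out = 7),
                    inner_frac = 0.2) {
  if (inherits(trials, "synced_trial")) trials <- list(trials)
  fit_composite(trials, l1spec, NULL, lambda, lambda_grid, inner_frac)
}

#' Decode a trial's hand trajectory
#'
#' @param model A fitted `hlm_model` or `mlr_model`.
#' @param trial An epoched trial (with BFN features for HLM models).
#' @return List of class `decoded_trajectory`: `times`, `xyz` (matrix with
#'   NA on time points lacking lag/epoch history), `t_index`.
#' @export
predict_trajectory <- function(model, trial) {
  d <- build_design(trial, model$l1spec, model$l2spec, model$cov_stats)
  if (!identical(d$colnames, model$colnames))
    stop("trial design structure does not match the fitted model")
  xyz <- matrix(NA_real_, length(trial$times), 3,
                dimnames = list(NULL, c("x", "y", "z")))
  if (nrow(d$X) > 0) {
    Z <- standardize_design(d$X, model$center, model$scale)$Z
    xyz[d$t_index, ] <- sweep(Z %*% model$coef, 2, model$y_center, "+")
  }
  structure(list(times = trial$times, xyz = xyz, t_index = d$t_index),
            class = "decoded_trajectory")
}

#' @export
print.decoder_model <- function(x, ...) {
  cat("<", class(x)[1], "> ", length(x$colnames), " predictors, lambda=",
      signif(x$lambda, 3), "\n", sep = "")
  invisible(x)
}
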
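# Cross-mode summaries of network features, Kruskal-Wallis tests on node
# degrees, and the band/electrode selection rules.

MODES3 <- c("BF", "LR", "UD")

#' Per-mode means of the scalar network metrics
#'
#' Arithmetic mean over epochs, grouped by (band, mode), for each of
#' VDegree, VPLength and Cluster, with the across-mode sample SD appended.
#'
#' @param metrics Tidy metrics data.frame (see [compute_bfn_features()])
#'   covering the three motion modes.
#' @return Named list of data.frames (one per metric) with columns `band`,
#'   one column per mode, and `SD`.
#' @export
per_mode_metric_means <- function(metrics) {
  missing_modes <- setdiff(MODES3, unique(metrics$mode))
  if (length(missing_modes) > 0)
    stop("missing motion mode(s): ", paste(missing_modes, collapse = ", "))
  bands <- intersect(band_names(), unique(metrics$band))
  out <- lapply(c("VDegree", "VPLength", "Cluster"), function(metric) {
    rows <- lapply(bands, function(b) {
      means <- vapply(MODES3, function(m)
        mean(metrics[metrics$band == b & metrics$mode == m, metric]),
        numeric(1))
      data.frame(band = b, t(means), SD = mode_spread(means),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  names(out) <- c("VDegree", "VPLength", "Cluster")
  out
}

#' Across-mode spread of three per-mode values
#'
#' Sample standard deviation (n-1 denominator) of exactly three per-mode
#' means; this is the "SD" column convention of the summary tables.
#'
#' @param values Numeric vector of length 3.
#' @return Numeric SD.
#' @export
mode_spread <- function(values) {
  if (length(values) != 3) stop("mode_spread expects exactly 3 values")
  stats::sd(values)
}

#' Node-degree spread across motion modes
#'
#' For each (band, electrode): mean degree per mode over epochs, then the
#' sample SD across the three mode means. The per-band column mean over
#' electrodes summarizes how sensitive that band's degrees are to the
#' motion mode.
#'
#' @param degrees Tidy degree data.frame with columns mode, band,
#'   electrode, degree (one row per epoch x band x electrode).
#' @return List with `table` (electrode x band SD matrix) and `band_means`
#'   (named numeric).
#' @export
degree_spread_table <- function(degrees) {
  missing_modes <- setdiff(MODES3, unique(degrees$mode))
  if (length(missing_modes) > 0)
    stop("missing motion mode(s): ", paste(missing_modes, collapse = ", "))
  bands <- intersect(band_names(), unique(degrees$band))
  electrodes <- unique(degrees$electrode)
  tab <- matrix(NA_real_, length(electrodes), length(bands),
                dimnames = list(electrodes, bands))
  for (b in bands) for (e in electrodes) {
    sub <- degrees[degrees$band == b & degrees$electrode == e, ]
    if (!all(MODES3 %in% sub$mode)) {
      warning("electrode ", e, " missing a mode in band ", b, "; excluded")
      next
    }
    means <- vapply(MODES3, function(m)
      mean(sub$degree[sub$mode == m]), numeric(1))
    tab[e, b] <- mode_spread(means)
  }
  list(table = tab, band_means = colMeans(tab, na.rm = TRUE))
}

#' Kruskal-Wallis tests of node degrees across motion modes
#'
#' One tie-corrected Kruskal-Wallis test per (band, electrode) comparing
#' the per-epoch degree distributions of the three modes. Electrodes whose
#' degree shows no variation at all (e.g. always 0) get a degenerate
#' marker instead of a p-value.
#'
#' @param degrees Tidy degree data.frame (mode, band, electrode, degree).
#' @return data.frame of class `kw_table` with columns band, electrode,
#'   p, degenerate.
#' @export
kruskal_wallis_table <- function(degrees) {
  modes <- intersect(MODES3, unique(degrees$mode))
  if (length(modes) < 2) stop("need >= 2 non-empty mode groups")
  for (m in modes) {
    ne <- length(unique(degrees$epoch[degrees$mode == m]))
    if (ne < 2) stop("mode ", m, " has fewer than 2 epochs")
  }
  bands <- intersect(band_names(), unique(degrees$band))
  electrodes <- unique(degrees$electrode)
  rows <- list()
  for (b in bands) for (e in electrodes) {
    sub <- degrees[degrees$band == b & degrees$electrode == e, ]
    groups <- lapply(modes, function(m) sub$degree[sub$mode == m])
    allv <- unlist(groups)
    if (max(allv) - min(allv) < 1e-12) {
      rows[[length(rows) + 1]] <- data.frame(
        band = b, electrode = e, p = NA_real_, degenerate = TRUE,
        stringsAsFactors = FALSE)
    } else {
      kt <- stats::kruskal.test(groups)
      rows[[length(rows) + 1]] <- data.frame(
        band = b, electrode = e, p = kt$p.value, degenerate = FALSE,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("kw_table", class(out))
  out
}

#' Select characteristic bands and electrodes
#'
#' A band is retained when at least `min_electrode_fraction` of the
#' electrodes show a significant (p < alpha) degree difference across
#' modes; degenerate entries never count as significant. An electrode is
#' retained when it is significant in every retained band in which it has
#' a valid p-value (degenerate cells are skipped, missing cells
#' disqualify), with at least one significant cell. Manual exclusions are
#' applied last.
#'
#' @param kwtable A [kruskal_wallis_table()] result (columns band,
#'   electrode, p, degenerate; p may be NA for unusable cells).
#' @param alpha Significance level (default 0.05).
#' @param min_electrode_fraction Band-retention fraction (default 0.5).
#' @param manual_exclusions Electrodes removed last, default FP1/FP2
#'   (ocular contamination).
#' @param bonferroni Apply Bonferroni correction over electrodes within a
#'   band (off by default).
#' @return List of class `feature_selection`: `bands`, `electrodes`,
#'   `band_counts`, `exclusion_log`.
#' @export
select_features <- function(kwtable, alpha = 0.05,
                            min_electrode_fraction = 0.5,
                            manual_exclusions = c("FP1", "FP2"),
                            bonferroni = FALSE) {
  electrodes <- unique(kwtable$electrode)
  bands <- intersect(band_names(), unique(kwtable$band))
  n_el <- length(electrodes)
  eff_alpha <- if (bonferroni) alpha / n_el else alpha
  sig <- function(b, e) {
    r <- kwtable[kwtable$band == b & kwtable$electrode == e, ]
    if (nrow(r) == 0 || r$degenerate[1] || is.na(r$p[1])) return(FALSE)
    r$p[1] < eff_alpha
  }
  counts <- vapply(bands, function(b)
    sum(vapply(electrodes, function(e) sig(b, e), logical(1))), numeric(1))
  keep_bands <- bands[counts >= min_electrode_fraction * n_el]
  log <- list()
  if (length(keep_bands) == 0) {
    warning("no band reaches the electrode-fraction criterion")
    return(structure(list(bands = character(0), electrodes = character(0),
                          band_counts = counts, exclusion_log = list()),
                     class = "feature_selection"))
  }
  keep_el <- character(0)
  for (e in electrodes) {
    ok <- TRUE; any_sig <- FALSE; reason <- NULL
    for (b in keep_bands) {
      r <- kwtable[kwtable$band == b & kwtable$electrode == e, ]
      if (nrow(r) == 0 || is.na(r$p[1]) && !r$degenerate[1]) {
        ok <- FALSE; reason <- paste0("missing p-value in band ", b)
        break
      }
      if (r$degenerate[1]) next        # no-variation marker: skip
      if (r$p[1] < eff_alpha) any_sig <- TRUE
      else { ok <- FALSE
             reason <- paste0("not significant in band ", b) ; break }
    }
    if (ok && !any_sig) { ok <- FALSE; reason <- "no valid significant cell" }
    if (ok) keep_el <- c(keep_el, e)
    else log[[e]] <- reason
  }
  manual_exclusions <- normalize_label(manual_exclusions)
  dropped <- intersect(keep_el, manual_exclusions)
  for (e in dropped) log[[e]] <- "ocular contamination (manual exclusion)"
  keep_el <- setdiff(keep_el, manual_exclusions)
  structure(list(bands = keep_bands, electrodes = keep_el,
                 band_counts = counts, exclusion_log = log,
                 alpha = alpha),
            class = "feature_selection")
}

#' @export
print.feature_selection <- function(x, ...) {
  cat("<feature_selection> bands: ", paste(x$bands, collapse = ", "),
      "\n  electrodes: ", paste(x$electrodes, collapse = ", "), "\n",
      sep = "")
  invisible(x)
}
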
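#' Canonical EEG frequency bands
#'
#' The eight characteristic bands used throughout the package, with their
#' fixed frequency ranges in Hz: delta (1-3), theta (4-7), alpha1 (8-9),
#' alpha2 (10-12), beta1 (13-17), beta2 (18-30), gamma1 (31-40),
#' gamma2 (41-50).
#'
#' @return A data.frame with columns `band`, `lo`, `hi` (Hz).
#' @export
#' @examples
#' eeg_bands()
eeg_bands <- function() {
  data.frame(
    band = c("delta", "theta", "alpha1", "alpha2",
             "beta1", "beta2", "gamma1", "gamma2"),
    lo = c(1, 4, 8, 10, 13, 18, 31, 41),
    hi = c(3, 7, 9, 12, 17, 30, 40, 50),
    stringsAsFactors = FALSE
  )
}

#' Band names
#' @return Character vector of the eight band names in canonical order.
#' @export
band_names <- function() eeg_bands()$band

band_range <- function(band) {
  tab <- eeg_bands()
  i <- match(band, tab$band)
  if (is.na(i)) stop("unknown band: ", band)
  c(lo = tab$lo[i], hi = tab$hi[i])
}

#' Default scalp analysis electrodes
#'
#' The 25 standard 10-20 electrode labels used for network construction.
#' Labels are upper-case.
#'
#' @return Character vector of 25 labels.
#' @export
analysis_electrodes <- function() {
  c("FP1", "FP2", "F3", "FZ", "F4", "F8", "FT7", "FC3",
    "C3", "CZ", "C4", "CP3", "CPZ", "CP4",
    "P3", "PZ", "P4", "T3", "T5", "T4", "TP8", "T6",
    "O1", "OZ", "O2")
}

#' Characteristic electrodes for trajectory decoding
#'
#' The eight electrodes retained by the default feature-selection rules.
#' @return Character vector of 8 labels.
#' @export
characteristic_electrodes <- function() {
  c("F4", "F8", "C3", "CZ", "C4", "CP4", "T3", "T4")
}

#' Characteristic bands for trajectory decoding
#' @return Character vector: delta, theta, gamma1.
#' @export
characteristic_bands <- function() c("delta", "theta", "gamma1")

# labels recognized as non-scalp auxiliary channels (reference, ocular)
AUX_LABELS <- c("A1", "A2", "M1", "M2", "HEOG", "VEOG", "EOG",
                "HEOGL", "HEOGR", "VEOGU", "VEOGD", "ECG", "EMG")

# full 10-20/10-10 label set we recognize as scalp EEG
KNOWN_1020 <- unique(c(
  analysis_electrodes(),
  c("FPZ", "F7", "AF3", "AF4", "FC4", "FCZ", "FT8", "TP7",
    "P7", "P8", "T7", "T8", "T5", "T6", "CB1", "CB2", "POZ", "PO3", "PO4")
))

normalize_label <- function(x) toupper(trimws(x))
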
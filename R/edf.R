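# Minimal EDF (European Data Format) support: 16-bit little-endian samples,
# fixed-width ASCII header. No pre-installed package in the target image
# reads EDF, so a small standards-compliant subset is implemented here:
# one data-record duration, identical sample counts per signal, no
# annotations. Values round-trip at the 16-bit quantization of the declared
# physical range.

pad_field <- function(x, width) {
  s <- substr(as.character(x), 1, width)
  paste0(s, strrep(" ", width - nchar(s)))
}

#' Write an EEG recording as EDF
#'
#' @param eeg An [eeg_recording()].
#' @param path Output path.
#' @param record_s Data-record duration in seconds (default 1).
#' @export
write_edf <- function(eeg, path, record_s = 1) {
  ns <- nrow(eeg$samples)
  spr <- as.integer(round(eeg$rate * record_s))
  n_rec <- floor(ncol(eeg$samples) / spr)
  if (n_rec < 1) stop("recording shorter than one data record")
  x <- eeg$samples[, seq_len(n_rec * spr), drop = FALSE]
  pmin_ <- apply(x, 1, min); pmax_ <- apply(x, 1, max)
  flat <- pmax_ - pmin_ < 1e-12
  pmin_[flat] <- pmin_[flat] - 1; pmax_[flat] <- pmax_[flat] + 1
  dmin <- -32768; dmax <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_field("0", 8), pad_field("X X X X", 80), pad_field("X X X", 80),
    pad_field(format(Sys.Date(), "%d.%m.%y"), 8), pad_field("00.00.00", 8),
    pad_field(256 * (ns + 1), 8), pad_field("", 44),
    pad_field(n_rec, 8), pad_field(format(record_s), 8), pad_field(ns, 8))
  writeChar(hdr, con, eos = NULL)
  wf <- function(vals, width)
    writeChar(paste0(vapply(vals, pad_field, "", width = width),
                     collapse = ""), con, eos = NULL)
  wf(eeg$channel_labels, 16)
  wf(rep("", ns), 80)
  wf(rep("uV", ns), 8)
  wf(format(pmin_, digits = 7), 8)
  wf(format(pmax_, digits = 7), 8)
  wf(rep(dmin, ns), 8)
  wf(rep(dmax, ns), 8)
  wf(rep("", ns), 80)
  wf(rep(spr, ns), 8)
  wf(rep("", ns), 32)
  scale <- (pmax_ - pmin_) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * spr + 1):(r * spr)
    for (i in seq_len(ns)) {
      dig <- round((x[i, idx] - pmin_[i]) / scale[i] + dmin)
      writeBin(as.integer(pmin(pmax(dig, dmin), dmax)), con,
               size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file
#'
#' @param path EDF file path.
#' @return An [eeg_recording()] in physical units (microvolts assumed).
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                                    # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  record_s <- as.numeric(rd(8))
  ns <- as.integer(rd(8))
  rdn <- function(w) vapply(seq_len(ns), function(i) rd(w), "")
  labels <- rdn(16)
  rdn(80); rdn(8)
  pmin_ <- as.numeric(rdn(8)); pmax_ <- as.numeric(rdn(8))
  dmin <- as.numeric(rdn(8)); dmax <- as.numeric(rdn(8))
  rdn(80)
  spr <- as.integer(rdn(8))
  rdn(32)
  if (length(unique(spr)) != 1)
    stop("EDF with per-signal sample rates is not supported")
  spr <- spr[1]
  out <- matrix(0, ns, n_rec * spr)
  scale <- (pmax_ - pmin_) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr, size = 2, endian = "little")
      out[i, ((r - 1) * spr + 1):(r * spr)] <-
        (dig - dmin[i]) * scale[i] + pmin_[i]
    }
  }
  eeg_recording(out, rate = spr / record_s, channel_labels = labels)
}
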
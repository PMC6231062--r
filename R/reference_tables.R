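# Published reference tables from the motor-decoding study this package's
# methods derive from, shipped as plain-text fixtures. They serve as worked
# examples for the summary/selection/scoring arithmetic; one garbled row of
# the printed p-value table (electrode O1, gamma bands) is stored as NA.

ref_path <- function(name) {
  system.file("extdata", "reference", name, package = "bfndecode",
              mustWork = TRUE)
}

#' Published reference tables (worked examples)
#'
#' @param which One of `"metric_means"` (per-mode means of the scalar
#'   network metrics, with across-mode SD), `"degree_spread"` (SD of node
#'   degrees across modes, electrodes x bands), `"kw_pvalues"`
#'   (Kruskal-Wallis p-values per band x electrode; 0/1 entries are
#'   degenerate always-zero-degree markers), `"decoding_pcc"` (per-subject
#'   decoding correlations for both spiral trajectories and both models).
#' @return A data.frame.
#' @export
reference_table <- function(which = c("metric_means", "degree_spread",
                                      "kw_pvalues", "decoding_pcc")) {
  which <- match.arg(which)
  f <- c(metric_means = "metric_means_by_mode.tsv",
         degree_spread = "degree_spread.tsv",
         kw_pvalues = "kw_pvalues.tsv",
         decoding_pcc = "decoding_pcc.tsv")[[which]]
  utils::read.delim(ref_path(f), check.names = FALSE)
}

#' Published p-value table as a kw_table
#'
#' Converts the printed p-value reference table into the
#' [kruskal_wallis_table()] layout: exact 0/1 entries become degenerate
#' markers (the always-zero-degree convention), NA entries stay missing.
#'
#' @return A `kw_table` data.frame (band, electrode, p, degenerate).
#' @export
reference_kw_table <- function() {
  tab <- reference_table("kw_pvalues")
  bands <- band_names()
  rows <- list()
  for (i in seq_len(nrow(tab))) for (b in bands) {
    p <- tab[i, b]
    degen <- !is.na(p) && (p == 0 || p == 1)
    rows[[length(rows) + 1]] <- data.frame(
      band = b, electrode = normalize_label(tab$electrode[i]),
      p = if (degen) NA_real_ else p, degenerate = degen,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("kw_table", class(out))
  out
}
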
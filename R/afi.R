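# Across-frequency interaction (AFI): change in noise-onset response between
# the narrowband and broadband maskers, on an exponentially transformed,
# per-cell max-normalised spike-count scale.

#' Mean onset spike count
#'
#' Mean per-trial spike count in the onset window (the first 75 ms of noise,
#' trial time 0.5--0.575 s; half-open), computed from noise-alone trials of
#' the given condition.
#'
#' @param spikes,trials spike and trial tables.
#' @param cell_id cell.
#' @param masker_kind masker condition (noise-alone trials, laser off).
#' @param window onset window (trial-aligned s).
#' @return mean spike count per trial.
#' @export
onset_count <- function(spikes, trials, cell_id, masker_kind,
                        window = cmr_timeline()$onset_window_s) {
  ids <- select_trials(trials, masker_kind = masker_kind, snr_db = NA,
                       laser = "off")
  if (!length(ids)) stop("no noise-alone trials for this condition")
  counts <- trial_window_rates(spikes, trials, cell_id, window,
                               trial_ids = ids, as_rate = FALSE)
  mean(counts)
}

#' Exponential-scale, max-normalised spike counts
#'
#' Converts counts to a linear scale with the exponential function and
#' normalises by the cell's maximum across all stimuli:
#' `a_s = exp(c_s) / max_s exp(c_s) = exp(c_s - max_s c_s)` (computed in the
#' shifted form so large counts cannot overflow).
#'
#' @param counts named numeric vector of onset counts, one per stimulus.
#' @param transform `"exp"` (default, the headline analysis), `"log"` or
#'   `"identity"` for sensitivity analyses.
#' @return normalised values in (0, 1] (the maximal stimulus maps to 1).
#' @export
normalize_counts <- function(counts, transform = c("exp", "log", "identity")) {
  if (!length(counts)) stop("need at least one stimulus")
  transform <- match.arg(transform)
  a <- switch(transform,
              exp = exp(counts - max(counts)),
              log = { v <- log1p(counts); v / max(v) },
              identity = counts / max(counts))
  a
}

#' AFI of one cell for a broadband condition
#'
#' `AFI = a[broadband] - a[NB]` on the normalised onset-count scale; positive
#' values are facilitation of the noise-onset response relative to the
#' narrowband masker, negative values suppression.
#'
#' @param norm_counts named normalised counts from [normalize_counts()]
#'   (must include `"NB"` and the broadband condition).
#' @param broadband `"IM"`, `"CM_long"` or `"CM_short"`.
#' @return AFI value in (-1, 1).
#' @export
afi <- function(norm_counts, broadband = "CM_long") {
  for (nm in c("NB", broadband))
    if (!nm %in% names(norm_counts))
      stop(sprintf("normalised counts missing condition '%s'", nm))
  unname(norm_counts[broadband] - norm_counts["NB"])
}

#' AFI of every cell in a dataset
#'
#' Computes onset counts per masker condition from noise-alone trials,
#' normalises per cell across all conditions present, and returns per-cell
#' AFI values for the broadband conditions.
#'
#' @param spikes,trials spike and trial tables.
#' @param cells cell ids (default: all in `spikes`).
#' @param transform passed to [normalize_counts()].
#' @return data.frame(cell_id, afi_cm, afi_im, onset counts per condition).
#' @export
afi_table <- function(spikes, trials, cells = NULL, transform = "exp") {
  cells <- cells %||% sort(unique(spikes$cell_id))
  kinds <- intersect(masker_kinds(),
                     unique(trials$masker_kind[!is.na(trials$masker_kind)]))
  rows <- lapply(cells, function(cell) {
    counts <- vapply(kinds, function(k)
      onset_count(spikes, trials, cell, k), numeric(1))
    a <- normalize_counts(counts, transform)
    data.frame(cell_id = cell,
               afi_cm = if ("CM_long" %in% kinds) afi(a, "CM_long") else NA,
               afi_im = if ("IM" %in% kinds) afi(a, "IM") else NA,
               t(counts))
  })
  do.call(rbind, rows)
}

#' Relationship between AFI and masking release
#'
#' Cells are split into `n_bins` equal-count AFI bins; per-bin mean masking
#' release supports the binwise comparison, and the across-cell Pearson
#' correlation quantifies the overall association.
#'
#' @param afi_values,mr_values per-cell AFI and masking release (dB); pairs
#'   with NA in either are dropped.
#' @param n_bins number of equal-count bins (6, matching a 5-df ANOVA).
#' @return list(bins [data.frame: bin, n, mean_afi, mean_mr], r, p, n). When
#'   the correlation is undefined (constant input) `r` and `p` are NA.
#' @export
afi_mr_relation <- function(afi_values, mr_values, n_bins = 6L) {
  keep <- is.finite(afi_values) & is.finite(mr_values)
  a <- afi_values[keep]; m <- mr_values[keep]
  if (length(a) < 2L) stop("need at least 2 cells with AFI and masking release")
  qs <- quantile(a, probs = seq(0, 1, length.out = n_bins + 1L), type = 7)
  qs[1] <- -Inf; qs[n_bins + 1L] <- Inf
  bin <- cut(a, breaks = unique(qs), labels = FALSE, right = TRUE)
  bins <- data.frame(
    bin = sort(unique(bin)),
    n = as.vector(table(bin)),
    mean_afi = tapply(a, bin, mean),
    mean_mr = tapply(m, bin, mean))
  if (sd(a) == 0 || sd(m) == 0) {
    r <- NA_real_; p <- NA_real_
  } else {
    ct <- cor.test(a, m, method = "pearson")
    r <- unname(ct$estimate); p <- ct$p.value
  }
  list(bins = bins, r = r, p = p, n = length(a))
}

#' Mean AFI per characteristic frequency
#'
#' @param afi_values per-cell AFI.
#' @param cf_hz per-cell CF (on the FRA grid); NA cells are dropped.
#' @return data.frame(cf_hz, n, mean_afi) — one row per CF actually
#'   represented (empty bins are absent, not zero).
#' @export
afi_by_cf <- function(afi_values, cf_hz) {
  keep <- is.finite(afi_values) & !is.na(cf_hz)
  if (!any(keep)) return(data.frame(cf_hz = numeric(), n = integer(),
                                    mean_afi = numeric()))
  a <- afi_values[keep]; f <- cf_hz[keep]
  agg <- aggregate(a, by = list(cf_hz = f), FUN = mean)
  cnt <- aggregate(a, by = list(cf_hz = f), FUN = length)
  data.frame(cf_hz = agg$cf_hz, n = cnt$x, mean_afi = agg$x)
}
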
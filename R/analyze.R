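# Population-scale analysis: the same PSTH / sigma / SR / vote arithmetic as
# the per-cell operations (compute_psth, cell_sigma, signal_response,
# sr_snr_function, cell_vote), vectorised with integer-coded tabulate()
# passes so tens of millions of spikes stay tractable. Unit tests assert
# equivalence of the two routes on small fixtures.

# Threshold of an SR/SNR value vector: linear upsampling + first crossing.
threshold_from_values <- function(snr_db, values, criterion = 0.5,
                                  step = 0.1) {
  if (anyNA(values)) return(NA_real_)
  up <- upsample_linear(snr_db, values, step)
  first_crossing(up$x, up$y, criterion)
}

# Integer lookup from trial_id to a group index (0 = not grouped).
trial_group_index <- function(trial_id, group_of_trial, all_trial_ids) {
  lut <- integer(max(all_trial_ids))
  lut[all_trial_ids] <- group_of_trial
  lut[trial_id]
}

#' Signal-response analysis of a whole dataset
#'
#' For every cell and masking condition this computes, from 5 ms PSTHs: the
#' pooled bin-rate SD (sigma), the first-pip-window rates per SNR and for
#' noise alone, the SR values in SD units, detection votes (+/-25% rule) and
#' per-cell 0.5 SD thresholds. Numerically identical to chaining
#' [compute_psth()], [cell_sigma()], [signal_response()],
#' [sr_snr_function()] and [cell_vote()] per cell.
#'
#' @param spikes,trials spike and trial tables (FRA trials are ignored).
#' @param bin_s PSTH bin width (5 ms).
#' @param window first-pip analysis window, trial-aligned seconds.
#' @param criterion per-cell SR threshold criterion (SD units).
#' @return list of data frames: `sr` (cell_id, condition, snr_db,
#'   window_rate, noise_rate, sr, vote), `sigma` (cell_id, sigma),
#'   `thresholds` (cell_id, condition, threshold_db).
#' @export
analyze_signal_responses <- function(spikes, trials, bin_s = 0.005,
                                     window = cmr_timeline()$pip1_window_s,
                                     criterion = 0.5) {
  mt <- trials[!is.na(trials$masker_kind), , drop = FALSE]
  if (!nrow(mt)) stop("no masking trials")
  cond <- condition_label(mt$masker_kind, mt$laser)
  snr_key <- ifelse(is.na(mt$snr_db), "noise", as.character(mt$snr_db))
  combo_key <- paste(cond, snr_key, sep = "\r")
  combos <- !duplicated(combo_key)
  klev <- combo_key[combos]
  K <- length(klev)
  kmap <- match(combo_key, klev)
  n_trials <- tabulate(kmap, K)
  k_cond <- cond[combos]; k_snr <- snr_key[combos]
  k_dur <- mt$duration_s[combos]
  nb_k <- as.integer(ceiling(k_dur / bin_s - 1e-9))
  nb <- max(nb_k)

  cells <- sort(unique(spikes$cell_id))
  C <- length(cells)

  ki <- trial_group_index(spikes$trial_id, kmap, mt$trial_id)
  keep <- ki > 0L
  ci <- match(spikes$cell_id[keep], cells)
  ki <- ki[keep]
  bin <- pmin(as.integer(spikes$spike_time_s[keep] %/% bin_s), nb - 1L)
  code <- (ci - 1L) * (K * nb) + (ki - 1L) * nb + bin
  counts <- array(tabulate(code + 1L, C * K * nb), dim = c(nb, K, C))

  # rates per 5 ms bin; sigma pools every bin of every PSTH (zeros included)
  scale_k <- 1 / (n_trials * bin_s)
  total_bins <- sum(nb_k)
  s1 <- s2 <- numeric(C)
  for (k in seq_len(K)) {
    rk <- counts[seq_len(nb_k[k]), k, ] * scale_k[k]
    s1 <- s1 + colSums(rk)
    s2 <- s2 + colSums(rk^2)
  }
  mu <- s1 / total_bins
  sigma <- sqrt(pmax(s2 / total_bins - mu^2, 0))
  sigma[sigma <= 0] <- NA_real_

  # first-pip-window rates per (cell, combo)
  b0 <- as.integer(floor(window[1] / bin_s + 1e-9))
  b1 <- as.integer(ceiling(window[2] / bin_s - 1e-9))
  wlen <- (b1 - b0) * bin_s
  wr <- apply(counts[(b0 + 1L):b1, , , drop = FALSE], c(2, 3), sum)
  wr <- wr / (n_trials * wlen)        # K x C

  noise_k <- match(paste(k_cond, "noise", sep = "\r"), klev)
  sig_idx <- which(k_snr != "noise")
  sr_list <- vector("list", length(sig_idx))
  for (j in seq_along(sig_idx)) {
    k <- sig_idx[j]
    nk <- noise_k[k]
    sr_list[[j]] <- data.frame(
      cell_id = cells,
      condition = k_cond[k],
      snr_db = as.numeric(k_snr[k]),
      window_rate = wr[k, ],
      noise_rate = wr[nk, ],
      sr = (wr[k, ] - wr[nk, ]) / sigma,
      vote = cell_vote(wr[k, ], wr[nk, ]))
  }
  sr <- do.call(rbind, sr_list)
  sr <- sr[order(sr$cell_id, sr$condition, sr$snr_db), , drop = FALSE]
  rownames(sr) <- NULL

  thr <- data.table::as.data.table(sr)[
    , .(threshold_db = threshold_from_values(snr_db, sr, criterion)),
    by = .(cell_id, condition)]

  list(sr = sr,
       sigma = data.frame(cell_id = cells, sigma = sigma),
       thresholds = as.data.frame(thr))
}

# Mean per-trial spike count per cell for noise-alone, laser-off trials of
# each masker kind, restricted to `windows` (list of half-open intervals).
noise_window_counts <- function(spikes, trials, windows) {
  mt <- trials[!is.na(trials$masker_kind) & is.na(trials$snr_db) &
                 trials$laser == "off", , drop = FALSE]
  if (!nrow(mt)) stop("no noise-alone trials")
  kinds <- unique(mt$masker_kind)
  kmap <- match(mt$masker_kind, kinds)
  n_trials <- tabulate(kmap, length(kinds))
  cells <- sort(unique(spikes$cell_id))
  ki <- trial_group_index(spikes$trial_id, kmap, mt$trial_id)
  keep <- ki > 0L
  st <- spikes$spike_time_s[keep]
  inw <- rep(FALSE, length(st))
  for (w in windows) inw <- inw | (st >= w[1] & st < w[2])
  ci <- match(spikes$cell_id[keep][inw], cells)
  code <- (ci - 1L) * length(kinds) + ki[keep][inw]
  counts <- matrix(tabulate(code, length(kinds) * length(cells)),
                   nrow = length(kinds))
  list(kinds = kinds, cells = cells, n_trials = n_trials,
       mean_count = counts / n_trials)  # kinds x cells
}

#' Mean onset spike counts per cell and masker condition
#'
#' Vectorised version of [onset_count()] over all cells and masker kinds
#' (noise-alone, laser-off trials; 0--75 ms of noise, half-open).
#'
#' @param spikes,trials spike and trial tables.
#' @param window onset window, trial-aligned seconds.
#' @return data.frame(cell_id, masker_kind, mean_count).
#' @export
onset_count_table <- function(spikes, trials,
                              window = cmr_timeline()$onset_window_s) {
  x <- noise_window_counts(spikes, trials, list(window))
  data.frame(cell_id = rep(x$cells, each = length(x$kinds)),
             masker_kind = rep(x$kinds, length(x$cells)),
             mean_count = as.vector(x$mean_count))
}

#' Mean noise-alone firing rate per cell in arbitrary windows
#'
#' Supports the ongoing-noise comparisons (e.g. trial windows 0.6--0.9 s and
#' 1.1--1.5 s, the sound portions away from onsets).
#'
#' @param spikes,trials spike and trial tables.
#' @param windows list of `c(t0, t1)` windows whose spike counts are pooled.
#' @return data.frame(cell_id, masker_kind, rate).
#' @export
noise_rate_table <- function(spikes, trials,
                             windows = list(c(0.6, 0.9), c(1.1, 1.5))) {
  x <- noise_window_counts(spikes, trials, windows)
  tot <- sum(vapply(windows, diff, numeric(1)))
  data.frame(cell_id = rep(x$cells, each = length(x$kinds)),
             masker_kind = rep(x$kinds, length(x$cells)),
             rate = as.vector(x$mean_count) / tot)
}
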
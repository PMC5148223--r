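# The signal-response (SR) statistic: per-bin difference between
# signal-plus-noise and noise-alone PSTHs in units of the cell's pooled
# bin-rate SD, with per-cell and population SR/SNR functions, threshold
# extraction, bootstrap responsiveness screening and the CF-subpopulation
# bootstrap.

#' Pooled bin-rate standard deviation of a cell
#'
#' The SD over the pooled multiset of all PSTH bin rates for the cell — every
#' bin of every masking-condition/SNR PSTH (FRA excluded). Uses the
#' population (divide-by-n) SD. A cell whose bins have zero variance has an
#' undefined sigma and is excluded from SR analyses (returns NA with a
#' warning).
#'
#' @param psths list of `psth` objects for one cell.
#' @return sigma in spikes/s, or NA.
#' @export
cell_sigma <- function(psths) {
  rates <- unlist(lapply(psths, `[[`, "rate"), use.names = FALSE)
  if (length(rates) < 2L) stop("need at least 2 bins to compute sigma")
  s2 <- mean(rates^2) - mean(rates)^2
  if (s2 <= 0) {
    warning("zero variance across PSTH bins; sigma undefined, cell excluded")
    return(NA_real_)
  }
  sqrt(s2)
}

#' Signal-response profile
#'
#' `SR(t) = (Sig(t) - N(t)) / sigma` per 5 ms bin, where `Sig` is the
#' signal-plus-noise PSTH and `N` the noise-alone PSTH of the same cell and
#' masker condition.
#'
#' @param sig,noise `psth` objects sharing bin edges.
#' @param sigma the cell's pooled SD from [cell_sigma()].
#' @return object of class `sr_profile`: list(breaks, sr, cell_id).
#' @export
signal_response <- function(sig, noise, sigma) {
  stopifnot(inherits(sig, "psth"), inherits(noise, "psth"))
  if (length(sig$rate) != length(noise$rate) ||
      !isTRUE(all.equal(sig$breaks, noise$breaks)))
    stop("Sig and N PSTHs must share bin edges")
  if (!is.finite(sigma) || sigma <= 0) stop("sigma must be finite and > 0")
  structure(list(breaks = sig$breaks, bin_s = sig$bin_s,
                 sr = (sig$rate - noise$rate) / sigma,
                 cell_id = sig$cell_id),
            class = "sr_profile")
}

# Mean of a binned series over bins fully inside [w1, w2).
window_mean_bins <- function(values, breaks, window) {
  lo <- breaks[-length(breaks)]; hi <- breaks[-1]
  inside <- lo >= window[1] - 1e-9 & hi <= window[2] + 1e-9
  if (!any(inside)) stop("no bins fully inside the window")
  mean(values[inside])
}

#' SR/SNR function and threshold for one cell and condition
#'
#' Each SR profile is averaged over the first-pip window (default
#' 1.175--1.275 s), giving one SR value (SD units) per measured SNR. The
#' function is upsampled by linear interpolation onto a 0.1 dB grid and the
#' threshold is the lowest grid SNR at which it reaches the criterion
#' (default 0.5 SD); NA if the criterion is never reached.
#'
#' @param profiles named list of `sr_profile`s, one per SNR (names = dB).
#' @param snr_db numeric vector of the measured SNRs (defaults to the profile
#'   names).
#' @param window averaging window, trial-aligned seconds.
#' @param criterion threshold criterion in SD units.
#' @param step upsampling step, dB.
#' @return object of class `sr_function`: list(snr_db, value, grid_snr,
#'   grid_value, threshold_db, criterion).
#' @export
sr_snr_function <- function(profiles, snr_db = as.numeric(names(profiles)),
                            window = cmr_timeline()$pip1_window_s,
                            criterion = 0.5, step = 0.1) {
  if (anyNA(snr_db)) stop("missing SNR labels for SR profiles")
  ord <- order(snr_db)
  vals <- unname(vapply(profiles, function(p)
    window_mean_bins(p$sr, p$breaks, window), numeric(1))[ord])
  sr_function_from_values(snr_db[ord], vals, criterion, step)
}

# Build an sr_function from precomputed window-averaged SR values.
sr_function_from_values <- function(snr_db, values, criterion = 0.5,
                                    step = 0.1) {
  up <- upsample_linear(snr_db, values, step)
  structure(list(snr_db = snr_db, value = values,
                 grid_snr = up$x, grid_value = up$y,
                 threshold_db = first_crossing(up$x, up$y, criterion),
                 criterion = criterion),
            class = "sr_function")
}

#' Bootstrap screen for a significant rate increase
#'
#' Pools the single-presentation window rates of conditions A and B and
#' bootstraps the pooled-null distribution of the mean-rate increase: per
#' replicate, a mean of size `|A|` and a mean of size `|B|` are drawn from
#' the pool with replacement and differenced. B shows a significant increase
#' when the observed `mean(B) - mean(A)` exceeds the 0.95 point of that
#' distribution (`p > 0.95`, one-sided). This form is calibrated: under a
#' true null the type-I rate is ~5%.
#'
#' @param rates_a,rates_b per-trial window rates under the two conditions.
#' @param n_boot number of bootstrap samples (500).
#' @param seed integer seed.
#' @param min_trials minimum trials per condition.
#' @return list(significant, p, observed): `p` is the fraction of bootstrap
#'   mean differences below the observed difference.
#' @export
bootstrap_significance <- function(rates_a, rates_b, n_boot = 500L,
                                   seed = 1L, min_trials = 5L) {
  if (length(rates_a) < min_trials || length(rates_b) < min_trials)
    stop(sprintf("need at least %d trials per condition", min_trials))
  pool <- c(rates_a, rates_b)
  na <- length(rates_a); nb <- length(rates_b)
  obs <- mean(rates_b) - mean(rates_a)
  boots <- with_seed(seed, {
    db <- rowMeans(matrix(sample(pool, n_boot * nb, replace = TRUE),
                          nrow = n_boot))
    da <- rowMeans(matrix(sample(pool, n_boot * na, replace = TRUE),
                          nrow = n_boot))
    db - da
  })
  p <- mean(boots < obs)
  list(significant = p > 0.95, p = p, observed = obs)
}

#' Screen cells for significant signal responses
#'
#' For every (cell, condition, SNR) combination, the per-trial first-pip
#' window rates of the signal trials are screened against the same
#' condition's noise-alone trials with [bootstrap_significance()]. The
#' overall responsive set contains cells significant for at least one
#' combination; per-condition sets are restricted to that condition.
#'
#' @param spikes,trials spike and trial tables.
#' @param cells cell ids to screen (default: all cells in `spikes`).
#' @param conditions condition labels to screen (default: all masking
#'   conditions present).
#' @param window screening window (first-pip window by default).
#' @param seed master seed; one substream per combination.
#' @param n_boot bootstrap samples per screen.
#' @return list(overall, by_condition, table): `table` has one row per
#'   combination with its p-value.
#' @export
select_responsive <- function(spikes, trials, cells = NULL, conditions = NULL,
                              window = cmr_timeline()$pip1_window_s,
                              seed = 1L, n_boot = 500L) {
  mt <- trials[!is.na(trials$masker_kind), , drop = FALSE]
  mt$condition <- condition_label(mt$masker_kind, mt$laser)
  conditions <- conditions %||% unique(mt$condition)
  cells <- cells %||% sort(unique(spikes$cell_id))
  rows <- list()
  k <- 0L
  for (cond in conditions) {
    ct <- mt[mt$condition == cond, , drop = FALSE]
    noise_ids <- ct$trial_id[is.na(ct$snr_db)]
    snrs <- sort(unique(ct$snr_db[!is.na(ct$snr_db)]))
    for (cell in cells) {
      ra <- trial_window_rates(spikes, trials, cell, window,
                               trial_ids = noise_ids)
      for (snr in snrs) {
        sig_ids <- ct$trial_id[!is.na(ct$snr_db) & ct$snr_db == snr]
        rb <- trial_window_rates(spikes, trials, cell, window,
                                 trial_ids = sig_ids)
        k <- k + 1L
        bs <- bootstrap_significance(ra, rb, n_boot = n_boot,
                                     seed = substream_seed(seed, k))
        rows[[k]] <- data.frame(cell_id = cell, condition = cond,
                                snr_db = snr, p = bs$p,
                                significant = bs$significant)
      }
    }
  }
  tab <- do.call(rbind, rows)
  sig <- tab[tab$significant, , drop = FALSE]
  by_cond <- lapply(split(sig$cell_id, sig$condition), unique)
  list(overall = sort(unique(sig$cell_id)),
       by_condition = by_cond[conditions[conditions %in% names(by_cond)]],
       table = tab)
}

#' Population mean signal response
#'
#' Unweighted mean of per-cell SR profiles (per bin), and the corresponding
#' population SR/SNR function via the first-pip window average.
#'
#' @param profiles_by_snr named list (by SNR) of lists of `sr_profile`s
#'   across cells.
#' @param window,criterion,step as in [sr_snr_function()].
#' @return list(profiles = mean `sr_profile` per SNR, fn = `sr_function`).
#' @export
population_mean_sr <- function(profiles_by_snr,
                               window = cmr_timeline()$pip1_window_s,
                               criterion = 0.5, step = 0.1) {
  if (!length(profiles_by_snr) || !length(profiles_by_snr[[1]]))
    stop("empty cell set")
  mean_profiles <- lapply(profiles_by_snr, function(pl) {
    m <- rowMeans(vapply(pl, `[[`, numeric(length(pl[[1]]$sr)), "sr"))
    structure(list(breaks = pl[[1]]$breaks, bin_s = pl[[1]]$bin_s,
                   sr = m, cell_id = NA), class = "sr_profile")
  })
  list(profiles = mean_profiles,
       fn = sr_snr_function(mean_profiles,
                            as.numeric(names(profiles_by_snr)),
                            window, criterion, step))
}

#' Bootstrap sensitivity of CF-defined subpopulations
#'
#' Per repeat, 50 cells are drawn with replacement from the subpopulation and
#' their SR/SNR functions averaged; the mean of the 500 repeat functions is
#' the subpopulation estimate, and its sensitivity is the lowest upsampled
#' SNR reaching the (deliberately low) 0.25 SD criterion.
#'
#' @param fn_matrix numeric matrix, cells x SNRs, of window-averaged SR
#'   values for the cells of one CF bin.
#' @param snr_db measured SNRs (columns).
#' @param n_sel,n_rep selections per repeat and number of repeats.
#' @param criterion sensitivity criterion, SD units.
#' @param seed integer seed.
#' @return list(fn = `sr_function` of the bootstrap-mean values,
#'   sensitivity_db = threshold or NA).
#' @export
subpopulation_sensitivity <- function(fn_matrix, snr_db,
                                      n_sel = 50L, n_rep = 500L,
                                      criterion = 0.25, seed = 1L) {
  if (!nrow(fn_matrix)) stop("empty CF bin")
  stopifnot(ncol(fn_matrix) == length(snr_db))
  boot_mean <- with_seed(seed, {
    acc <- matrix(0, n_rep, length(snr_db))
    for (r in seq_len(n_rep)) {
      pick <- sample.int(nrow(fn_matrix), n_sel, replace = TRUE)
      acc[r, ] <- colMeans(fn_matrix[pick, , drop = FALSE])
    }
    colMeans(acc)
  })
  fn <- sr_function_from_values(snr_db, boot_mean, criterion)
  list(fn = fn, sensitivity_db = fn$threshold_db)
}

#' Masking release between two conditions
#'
#' `MR = threshold(A) - threshold(B)` in dB; positive values mean condition B
#' is the more sensitive one. NA if either threshold is undefined.
#'
#' @param threshold_a,threshold_b thresholds in dB SNR (scalars or vectors).
#' @return dB of masking release.
#' @export
masking_release <- function(threshold_a, threshold_b) {
  threshold_a - threshold_b
}

#' Signal-tuned cell selection
#'
#' Cells whose characteristic frequency falls in the 15--23 kHz band around
#' the 20 kHz signal. On the 0.125-octave CF grid this selects
#' `20 * 2^(-3/8)` through `20 * 2^(1/8)` kHz (15.4--21.8 kHz).
#'
#' @param cf_hz vector of characteristic frequencies (Hz).
#' @param band numeric `c(lo, hi)` in Hz.
#' @return logical vector.
#' @export
is_signal_tuned <- function(cf_hz, band = c(15000, 23000)) {
  !is.na(cf_hz) & cf_hz >= band[1] & cf_hz <= band[2]
}
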
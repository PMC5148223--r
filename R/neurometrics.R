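# Neurometrics: per-cell detection votes from relative firing-rate changes,
# the population proportion-correct function, and binomial detection
# thresholds.

#' Detection vote of one cell at one SNR
#'
#' A relative increase in first-pip-window firing rate of at least 25%
#' (signal trials vs the condition's own noise-alone trials) is a "yes"
#' (1), a decrease of at least 25% a "no" (0), anything in between chance
#' (0.5). A zero noise rate with a positive signal rate counts as an
#' infinite relative increase (vote 1); two zero rates are chance.
#'
#' @param rate_signal,rate_noise mean window rates, spikes/s (vectorised).
#' @return votes in {0, 0.5, 1}.
#' @export
cell_vote <- function(rate_signal, rate_noise) {
  if (any(rate_noise < 0, na.rm = TRUE)) stop("rate_noise must be >= 0")
  v <- ifelse(rate_signal >= 1.25 * rate_noise, 1,
              ifelse(rate_signal <= 0.75 * rate_noise, 0, 0.5))
  # both criteria fire when rate_noise == 0: resolve the 0/0 tie to chance
  v[rate_noise == 0 & rate_signal == 0] <- 0.5
  v[rate_noise == 0 & rate_signal > 0] <- 1
  v
}

#' Population neurometric function
#'
#' Proportion correct per SNR is the mean vote across cells, upsampled by
#' linear interpolation onto a 0.1 dB grid.
#'
#' @param votes numeric matrix, cells x SNRs (values in {0, 0.5, 1}).
#' @param snr_db measured SNRs (columns of `votes`).
#' @param step upsampling step, dB.
#' @return object of class `neurometric_fn`: list(snr_db, proportion,
#'   grid_snr, grid_proportion, n_cells).
#' @export
population_proportion <- function(votes, snr_db = as.numeric(colnames(votes)),
                                  step = 0.1) {
  votes <- as.matrix(votes)
  if (!nrow(votes)) stop("empty population")
  stopifnot(ncol(votes) == length(snr_db), !anyNA(snr_db))
  prop <- colMeans(votes)
  up <- upsample_linear(snr_db, prop, step)
  structure(list(snr_db = snr_db, proportion = unname(prop),
                 grid_snr = up$x, grid_proportion = up$y,
                 n_cells = nrow(votes)),
            class = "neurometric_fn")
}

# One-sided exact binomial tail: P(X >= successes), X ~ Binomial(n, 0.5).
binomial_tail <- function(successes, n) {
  pbinom(successes - 1, n, 0.5, lower.tail = FALSE)
}

#' Neurometric detection threshold by binomial probability
#'
#' At every upsampled SNR the interpolated proportion correct is converted to
#' a success count (`round(p * n_cells)`) and tested one-sided against chance
#' 0.5 with the exact binomial tail. The threshold is the lowest grid SNR
#' whose p-value beats the Bonferroni-corrected level `alpha / m_tests`,
#' where `m_tests` is the number of measured SNRs (7), not the upsampled grid
#' size.
#'
#' @param fn a `neurometric_fn`.
#' @param alpha family-wise level (0.05).
#' @param m_tests Bonferroni correction count (defaults to the number of
#'   measured SNRs).
#' @return list(threshold_db [NA if never significant], alpha_corrected,
#'   p_values [per grid point]).
#' @export
neurometric_threshold <- function(fn, alpha = 0.05,
                                  m_tests = length(fn$snr_db)) {
  stopifnot(inherits(fn, "neurometric_fn"))
  if (fn$n_cells == 0) stop("n_cells is 0")
  succ <- round(fn$grid_proportion * fn$n_cells)
  pv <- binomial_tail(succ, fn$n_cells)
  crit <- alpha / m_tests
  hit <- which(pv < crit)
  list(threshold_db = if (length(hit)) fn$grid_snr[hit[1]] else NA_real_,
       alpha_corrected = crit,
       p_values = pv)
}
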
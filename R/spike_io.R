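# Interchange layer: trial-aligned spike tables on disk (plain CSV), trial
# selection by condition, PSTH construction and window rates.

SPIKE_COLS <- c("cell_id", "trial_id", "spike_time_s")
TRIAL_COLS <- c("trial_id", "onset_s", "duration_s", "masker_kind", "snr_db",
                "laser", "fra_freq_hz", "fra_level_db")

#' Read a trial-aligned spike dataset
#'
#' `spikes.csv` holds (cell_id, trial_id, spike_time_s in trial-aligned
#' seconds); `trials.csv` one row per trial with the flattened condition
#' descriptor. Referential integrity is enforced: a spike pointing at an
#' unknown trial is a hard error naming the offending trial id(s).
#'
#' @param spikes_path,trials_path CSV paths.
#' @return list with `spikes` and `trials` data frames.
#' @export
read_dataset <- function(spikes_path, trials_path) {
  spikes <- utils::read.csv(spikes_path, stringsAsFactors = FALSE)
  trials <- utils::read.csv(trials_path, stringsAsFactors = FALSE)
  stop_missing_cols(spikes, SPIKE_COLS, "spikes table")
  stop_missing_cols(trials, c("trial_id", "onset_s", "duration_s"), "trial table")
  if (anyDuplicated(trials$trial_id))
    stop("trial table has duplicated trial_id values")
  if (nrow(spikes) == 0L)  # empty file with valid header: fix column types
    spikes$spike_time_s <- as.numeric(spikes$spike_time_s)
  if (!is.numeric(spikes$spike_time_s))
    stop("spike_time_s must be numeric")
  orphans <- setdiff(unique(spikes$trial_id), trials$trial_id)
  if (length(orphans))
    stop(sprintf("spikes reference unknown trial_id(s): %s",
                 paste(utils::head(orphans, 10), collapse = ", ")))
  list(spikes = spikes, trials = trials)
}

#' Write a spike dataset to CSV
#'
#' @param dataset a `cmr_dataset` or list with `spikes` and `trials`.
#' @param dir output directory (created if absent).
#' @return invisibly, the two file paths.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sp <- file.path(dir, "spikes.csv"); tp <- file.path(dir, "trials.csv")
  utils::write.csv(dataset$spikes, sp, row.names = FALSE)
  utils::write.csv(dataset$trials, tp, row.names = FALSE)
  if (!is.null(dataset$truth))
    utils::write.csv(dataset$truth, file.path(dir, "truth.csv"),
                     row.names = FALSE)
  invisible(c(spikes = sp, trials = tp))
}

#' Select trial ids matching a condition key
#'
#' The key is a named list matched against columns of the trial table; NA in
#' the key matches NA in the table (e.g. `snr_db = NA` selects noise-alone
#' trials).
#'
#' @param trials trial table.
#' @param ... named condition fields, e.g. `masker_kind = "CM_long"`.
#' @return integer vector of trial ids.
#' @export
select_trials <- function(trials, ...) {
  key <- list(...)
  keep <- rep(TRUE, nrow(trials))
  for (nm in names(key)) {
    if (!nm %in% names(trials)) stop(sprintf("unknown trial column '%s'", nm))
    v <- trials[[nm]]
    m <- if (is.na(key[[nm]])) is.na(v) else !is.na(v) & v == key[[nm]]
    keep <- keep & m
  }
  trials$trial_id[keep]
}

#' Peristimulus time histogram
#'
#' Bins anchored at trial time 0, half-open `[t, t + bin)` (a spike exactly on
#' an edge belongs to the later bin). `rate[b] = count_b / (n_trials * bin_s)`
#' so that `sum(rate) * bin_s * n_trials` equals the raw spike count.
#'
#' @param spikes spike table.
#' @param trials trial table.
#' @param cell_id cell to histogram.
#' @param ... condition key passed to [select_trials()]; alternatively supply
#'   `trial_ids` directly.
#' @param trial_ids optional explicit trial ids (overrides the key).
#' @param bin_s bin width, default 5 ms.
#' @return object of class `psth`: list(cell_id, breaks, rate, n_trials).
#' @export
compute_psth <- function(spikes, trials, cell_id, ..., trial_ids = NULL,
                         bin_s = 0.005) {
  ids <- trial_ids %||% select_trials(trials, ...)
  if (!length(ids)) stop("no trials match the condition key")
  dur <- unique(trials$duration_s[match(ids, trials$trial_id)])
  if (length(dur) != 1L) stop("matched trials have differing durations")
  nb <- as.integer(ceiling(dur / bin_s - 1e-9))
  st <- spikes$spike_time_s[spikes$cell_id == cell_id &
                              spikes$trial_id %in% ids]
  bins <- pmin(floor(st / bin_s), nb - 1L)
  counts <- tabulate(bins + 1L, nbins = nb)
  structure(list(
    cell_id = cell_id,
    breaks = seq(0, nb * bin_s, by = bin_s),
    bin_s = bin_s,
    rate = counts / (length(ids) * bin_s),
    n_trials = length(ids)
  ), class = "psth")
}

#' Mean firing rate in a time window
#'
#' Total in-window spike count over matched trials divided by
#' `n_trials * (t1 - t0)`; the window is half-open `[t0, t1)`.
#'
#' @inheritParams compute_psth
#' @param window numeric `c(t0, t1)`, trial-aligned seconds.
#' @return mean rate in spikes/s.
#' @export
window_rate <- function(spikes, trials, cell_id, window, ...,
                        trial_ids = NULL) {
  stopifnot(length(window) == 2L, window[2] > window[1])
  ids <- trial_ids %||% select_trials(trials, ...)
  if (!length(ids)) stop("no trials match the condition key")
  st <- spikes$spike_time_s[spikes$cell_id == cell_id &
                              spikes$trial_id %in% ids]
  n <- sum(st >= window[1] & st < window[2])
  n / (length(ids) * diff(window))
}

#' Per-trial spike counts or rates in a window
#'
#' @inheritParams window_rate
#' @param as_rate divide counts by the window length.
#' @return numeric vector, one value per matched trial (in `trial_ids` order).
#' @export
trial_window_rates <- function(spikes, trials, cell_id, window, ...,
                               trial_ids = NULL, as_rate = TRUE) {
  stopifnot(length(window) == 2L, window[2] > window[1])
  ids <- trial_ids %||% select_trials(trials, ...)
  if (!length(ids)) stop("no trials match the condition key")
  sel <- spikes$cell_id == cell_id & spikes$trial_id %in% ids &
    spikes$spike_time_s >= window[1] & spikes$spike_time_s < window[2]
  counts <- tabulate(match(spikes$trial_id[sel], ids), nbins = length(ids))
  if (as_rate) counts / diff(window) else counts
}
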
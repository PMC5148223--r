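# Synthetic population: generative model neurons and inhomogeneous-Poisson
# spike trains with planted condition effects (masking release, priming,
# cortical-silencing and onset-interaction couplings) for parameter-recovery
# testing of the analysis pipeline.

#' Population simulation configuration
#'
#' Defaults state the simulated world: log-normally distributed spontaneous
#' rates (median 5 spikes/s, sdlog 0.5), strong masker-driven sustained
#' responses (see the methods vignette on why the detection-vote statistic
#' needs the driven regime), log-uniform CFs across the FRA span,
#' Gaussian-in-log-frequency
#' tuning, and planted population detection thresholds of 8 dB SNR (NB),
#' 6.5 dB (IM), 1 dB (long CM), with a +5.5 dB priming shift (short CM) and a
#' +5.5 dB shift when cortex is silenced during the precursor. Per-cell
#' thresholds jitter around these while always respecting the orderings
#' CM_long < IM <= NB, CM_short > CM_long, CM_long_laser > CM_long.
#'
#' @param ... overrides for any entry.
#' @return named list of class `population_config`.
#' @export
population_config <- function(...) {
  cfg <- list(
    n_cells = 500L,
    cf_range_hz = range(build_fra_grid()$freqs),
    tuned_only = FALSE,          # restrict CFs to the signal-tuned band
    baseline_meanlog = log(5),   # log-normal spontaneous rate, spikes/s
    baseline_sdlog = 0.5,
    tuning_bw_oct = 0.3,         # receptive-field SD, octaves
    tuning_bw_sdlog = 0.3,
    onset_gain_meanlog = log(20),  # peak onset transient, spikes/s
    onset_gain_sdlog = 0.4,
    onset_tau_s = 0.025,         # transient decay constant
    sustained_gain = 400,        # drive scale of the sustained response
    sustained_norm = 2,          # divisive normalization of the summed
                                 # band drive: rate uses W / (1 + norm * W),
                                 # so ongoing rates saturate with bandwidth
    sustained_rise_s = 0.3,      # build-up constant of the sustained response
    signal_rel_gain_meanlog = log(2),  # max signal-evoked relative increase
    signal_rel_gain_sdlog = 0.25,
    fra_gain_meanlog = log(20),  # max tone-evoked rate on FRA trials, spikes/s
    fra_gain_sdlog = 0.5,
    threshold_slope_db = 1,
    thr_nb_db = 8,               # planted population thresholds (dB SNR)
    d_im_db = 1.5,               # NB -> IM release
    d_cm_db = 7,                 # NB -> long-CM release
    d_priming_db = 5.5,          # long-CM -> short-CM shift
    d_laser_db = 5.5,            # long-CM -> silenced long-CM shift
    thr_jitter_sd_db = 1,        # common per-cell sensitivity jitter
    condition_jitter_sd_db = 1.8, # iid per-condition threshold jitter; equal
                                 # across conditions so every condition's
                                 # threshold distribution has the same
                                 # spread (per-cell masking-release SD is
                                 # sqrt(2) times this)
    afi_coupling = -1,           # onset-suppression ~ masking-release link
    im_onset_boost = 0.10,       # log-scale onset facilitation, IM flankers
    cm_onset_boost = 0.05,       # log-scale onset facilitation, CM flankers
    near_cf_suppression = 0.3,   # extra CM onset suppression near 20 kHz
    pv_pos_fraction = 0.1,
    laser_gain_pv_neg = 0.1,     # rate multiplier during light, PV- cells
    laser_gain_pv_pos = 4,       # rate multiplier during light, PV+ cells
    fra_threshold_db = 30,       # tone level at CF needed for FRA response
    fra_vslope_db_per_oct = 60,  # FRA threshold growth away from CF
    lock_envelope = FALSE,       # sustained response follows the envelope
    pips_responding = 1L,        # 1 = first pip only, 3 = whole train
    seed = 1L
  )
  dots <- list(...)
  cfg[names(dots)] <- dots
  structure(cfg, class = "population_config")
}

#' Sample a model neuron population
#'
#' Draws per-cell generative parameters from the distributions in
#' [population_config()]. Planted per-cell thresholds are the population
#' effect sizes plus jitter, constrained so every cell satisfies
#' `CM_long < IM <= NB`, `CM_short > CM_long` and `CM_long_laser > CM_long`
#' (a planted effect of exactly 0 yields exactly equal thresholds). The
#' comodulated onset gain is coupled to the cell's planted masking release
#' through `afi_coupling` (negative: cells with large release have suppressed
#' broadband onsets), plus an extra suppression for cells tuned near the
#' 20 kHz signal frequency.
#'
#' @param config a `population_config`.
#' @return `data.frame` of class `neuron_params`, one row per cell.
#' @export
sample_population <- function(config = population_config()) {
  stopifnot(config$n_cells >= 1)
  if (any(config$cf_range_hz <= 0)) stop("invalid cf_range_hz")
  cfg <- config
  with_seed(cfg$seed, {
    n <- cfg$n_cells
    cf_lo <- log2(cfg$cf_range_hz[1]); cf_hi <- log2(cfg$cf_range_hz[2])
    if (isTRUE(cfg$tuned_only)) {  # inside the 15-23 kHz signal-tuned band
      cf_lo <- log2(SIGNAL_FREQ_HZ) - 3 / 8; cf_hi <- log2(SIGNAL_FREQ_HZ) + 1 / 8
    }
    cf <- 2^runif(n, cf_lo, cf_hi)
    baseline <- rlnorm(n, cfg$baseline_meanlog, cfg$baseline_sdlog)
    bw <- cfg$tuning_bw_oct * rlnorm(n, 0, cfg$tuning_bw_sdlog)
    onset <- rlnorm(n, cfg$onset_gain_meanlog, cfg$onset_gain_sdlog)
    sgain <- if (is.infinite(cfg$signal_rel_gain_meanlog)) rep(0, n) else
      rlnorm(n, cfg$signal_rel_gain_meanlog, cfg$signal_rel_gain_sdlog)
    fgain <- rlnorm(n, cfg$fra_gain_meanlog, cfg$fra_gain_sdlog)

    # Per-cell thresholds: one common sensitivity jitter plus an iid
    # per-condition jitter of EQUAL spread in every condition. Equal
    # marginal spreads matter: the population neurometric crossing sits at
    # a fixed lower-tail quantile of the per-cell threshold distribution,
    # so unequal spreads would bias recovered condition differences.
    # Orderings are enforced with one-sided clamps that only touch the
    # tail that does not carry the population crossing. A planted effect of
    # exactly 0 copies the reference threshold (exact null).
    u <- rnorm(n, 0, cfg$thr_jitter_sd_db)
    v <- function() rnorm(n, 0, cfg$condition_jitter_sd_db)
    thr_nb <- cfg$thr_nb_db + u + v()
    thr_im <- if (cfg$d_im_db == 0) thr_nb else
      pmin(cfg$thr_nb_db - cfg$d_im_db + u + v(), thr_nb)
    thr_cm_long <- if (cfg$d_cm_db == 0) thr_nb else
      pmin(cfg$thr_nb_db - cfg$d_cm_db + u + v(), thr_im - 0.1)
    shifted <- function(d_shift) {
      if (d_shift == 0) return(thr_cm_long)
      pmax(cfg$thr_nb_db - cfg$d_cm_db + d_shift + u + v(),
           thr_cm_long + 0.1)
    }
    thr_cm_short <- shifted(cfg$d_priming_db)
    thr_cm_long_laser <- shifted(cfg$d_laser_db)
    thr_cm_short_laser <- thr_cm_short  # silencing before a short masker: no effect
    cm_release <- thr_nb - thr_cm_long

    w20 <- exp(-0.5 * (log2(cf / SIGNAL_FREQ_HZ) / bw)^2)
    # Coupling: standardised planted-release deviation drives CM onset gain.
    z <- if (cfg$d_cm_db == 0) rep(0, n) else
      (cm_release - cfg$d_cm_db) / (sqrt(2) * cfg$condition_jitter_sd_db)
    onset_im <- onset * exp(cfg$im_onset_boost)
    onset_cm <- onset * exp(cfg$cm_onset_boost + cfg$afi_coupling * z -
                              cfg$near_cf_suppression * w20)
    pv <- ifelse(runif(n) < cfg$pv_pos_fraction, "PV+", "PV-")
    structure(data.frame(
      cell_id = seq_len(n),
      cf = cf,
      tuning_bw = bw,
      baseline_rate = baseline,
      onset_gain_NB = onset,
      onset_gain_IM = onset_im,
      onset_gain_CM = onset_cm,
      sustained_gain = cfg$sustained_gain,
      signal_rel_gain = sgain,
      fra_gain = fgain,
      threshold_slope = cfg$threshold_slope_db,
      thr_NB = thr_nb, thr_IM = thr_im,
      thr_CM_long = thr_cm_long, thr_CM_short = thr_cm_short,
      thr_CM_long_laser = thr_cm_long_laser,
      thr_CM_short_laser = thr_cm_short_laser,
      afi_coupling = cfg$afi_coupling,
      pv_type = pv,
      laser_gain = ifelse(pv == "PV+", cfg$laser_gain_pv_pos,
                          cfg$laser_gain_pv_neg),
      fra_threshold_db = cfg$fra_threshold_db,
      fra_vslope = cfg$fra_vslope_db_per_oct,
      stringsAsFactors = FALSE
    ), class = c("neuron_params", "data.frame"),
       config = cfg)
  })
}

# Gaussian-in-log-frequency receptive-field weight.
tuning_weight <- function(freq_hz, cf, bw_oct) {
  exp(-0.5 * (log2(freq_hz / cf) / bw_oct)^2)
}

# Summed tuning weight over the masker bands of a kind.
band_weight_sum <- function(kind, cf, bw_oct) {
  f <- masker_band_freqs(kind)
  rowSums(outer(seq_along(cf), seq_along(f),
                function(i, j) tuning_weight(f[j], cf[i], bw_oct[i])))
}

onset_gain_for <- function(neuron, kind) {
  switch(substr(kind, 1, 2),
         NB = neuron$onset_gain_NB,
         IM = neuron$onset_gain_IM,
         CM = neuron$onset_gain_CM)
}

# Time profiles shared by all cells for one masking condition. Returned on a
# regular grid so per-cell rates assemble as baseline + A*onset + B*sustained
# + C*pip (+ laser mask); `config` supplies timing constants.
condition_shapes <- function(kind, t, config = population_config()) {
  tl <- cmr_timeline()
  noise_on <- if (kind == "CM_short") tl$masker_on_s else tl$precursor_on_s
  onset <- ifelse(t >= noise_on & t < noise_on + 0.075,
                  exp(-(t - noise_on) / config$onset_tau_s), 0)
  # sustained drive builds up from each segment onset (the slow adaptation
  # to the masker statistics that the priming manipulations probe)
  ramp <- function(t0) 1 - exp(-(t - t0) / config$sustained_rise_s)
  sust <- numeric(length(t))
  if (kind != "CM_short") {
    pre <- t >= tl$precursor_on_s & t < tl$precursor_on_s + tl$precursor_s
    sust[pre] <- 0.5 * ramp(tl$precursor_on_s)[pre]
  }
  mask <- t >= tl$masker_on_s & t < tl$masker_on_s + tl$masker_s
  sust[mask] <- 0.5 * ramp(tl$masker_on_s)[mask]
  if (isTRUE(config$lock_envelope)) {
    mk <- build_masker(kind, seed = 1L)
    env <- rowMeans(sapply(seq_len(nrow(mk$bands)),
                           function(b) envelope_value(mk, b, t)))
    sust <- ifelse(sust > 0, 2 * sust * env, 0)
  }
  npips <- min(config$pips_responding, 3L)
  pip <- numeric(length(t))
  for (on in tl$pip_onsets_s[seq_len(npips)])
    pip[t >= on & t < on + tl$pip_s] <- 1
  laser <- t >= tl$laser_window_s[1] & t < tl$laser_window_s[2]
  list(onset = onset, sustained = sust, pip = pip, laser = laser)
}

#' Instantaneous firing rate of a model neuron
#'
#' The noise-driven part of the rate is additive: baseline, plus a
#' tuning-weighted sum over masker bands of an exponentially decaying onset
#' transient (0--75 ms after noise onset) and a sustained component that
#' builds up from each segment onset with time constant `sustained_rise_s`
#' (slow adaptation to the masker). The signal acts as a *multiplicative
#' gain* on that ongoing rate during the pip window(s):
#' `rate * (1 + signal_rel_gain * w20 * plogis((snr - thr[cond]) / slope))`,
#' with `w20` the tuning weight at 20 kHz. A gain (rather than additive)
#' signal makes the relative-rate detection analyses recover planted
#' thresholds with a condition-independent offset even though broadband
#' maskers drive more background activity than the narrowband one. During
#' the 150 ms silencing window the whole rate is multiplied by `laser_gain`
#' (PV-: < 1, PV+: > 1). FRA trials use a V-shaped tone response with
#' absolute gain `fra_gain`. The result is floored at 0.
#'
#' @param neuron one row of a `neuron_params` table.
#' @param condition list or single trial row with fields `masker_kind`,
#'   `snr_db`, `laser`, `fra_freq_hz`, `fra_level_db`.
#' @param t numeric vector of trial-aligned times (s).
#' @param config a `population_config` (timing/locking options).
#' @return numeric vector of rates (spikes/s).
#' @export
rate_function <- function(neuron, condition, t,
                          config = population_config(), shapes = NULL) {
  neuron <- as.list(neuron)
  tl <- cmr_timeline()
  rate <- rep(neuron$baseline_rate, length(t))
  if (!is.null(condition$masker_kind) && !is.na(condition$masker_kind)) {
    kind <- condition$masker_kind
    sh <- shapes %||% condition_shapes(kind, t, config)
    W <- band_weight_sum(kind, neuron$cf, neuron$tuning_bw)
    rate <- rate + onset_gain_for(neuron, kind) * W * sh$onset +
      neuron$sustained_gain * W / (1 + config$sustained_norm * W) *
        sh$sustained
    snr <- condition$snr_db
    if (!is.null(snr) && !is.na(snr)) {
      lab <- condition_label(kind, condition$laser %||% "off")
      # masker kinds without a planted laser effect fall back to their
      # baseline threshold (silencing before an unprimed masker is inert)
      thr <- neuron[[paste0("thr_", lab)]] %||% neuron[[paste0("thr_", kind)]]
      w20 <- tuning_weight(SIGNAL_FREQ_HZ, neuron$cf, neuron$tuning_bw)
      gain <- neuron$signal_rel_gain * w20 *
        plogis((snr - thr) / neuron$threshold_slope)
      rate <- rate * (1 + gain * sh$pip)
    }
    if (identical(condition$laser %||% "off", "precursor_150ms"))
      rate[sh$laser] <- rate[sh$laser] * neuron$laser_gain
  } else if (!is.null(condition$fra_freq_hz) && !is.na(condition$fra_freq_hz)) {
    tone <- t >= tl$fra_tone_on_s & t < tl$fra_tone_on_s + tl$fra_tone_s
    thr <- neuron$fra_threshold_db +
      neuron$fra_vslope * abs(log2(condition$fra_freq_hz / neuron$cf))
    rate[tone] <- rate[tone] + neuron$fra_gain *
      plogis((condition$fra_level_db - thr) / 3)
  }
  pmax(rate, 0)
}

# Rates of every cell for one condition on a common time grid
# (cells x bins). Row i equals rate_function(population[i, ], ...); the
# equivalence is asserted by a unit test.
rate_matrix <- function(population, condition, t,
                        config = population_config()) {
  tl <- cmr_timeline()
  n <- nrow(population)
  R <- matrix(population$baseline_rate, n, length(t))
  if (!is.null(condition$masker_kind) && !is.na(condition$masker_kind)) {
    kind <- condition$masker_kind
    sh <- condition_shapes(kind, t, config)
    freqs <- masker_band_freqs(kind)
    W <- rowSums(matrix(vapply(freqs, function(f)
      tuning_weight(f, population$cf, population$tuning_bw), numeric(n)),
      nrow = n))
    og <- switch(substr(kind, 1, 2), NB = population$onset_gain_NB,
                 IM = population$onset_gain_IM, CM = population$onset_gain_CM)
    R <- R + (og * W) %o% sh$onset +
      (population$sustained_gain * W / (1 + config$sustained_norm * W)) %o%
        sh$sustained
    snr <- condition$snr_db
    if (!is.null(snr) && !is.na(snr)) {
      lab <- condition_label(kind, condition$laser %||% "off")
      thr <- population[[paste0("thr_", lab)]] %||%
        population[[paste0("thr_", kind)]]
      w20 <- tuning_weight(SIGNAL_FREQ_HZ, population$cf,
                           population$tuning_bw)
      gain <- population$signal_rel_gain * w20 *
        plogis((snr - thr) / population$threshold_slope)
      R <- R * (1 + gain %o% sh$pip)
    }
    if (identical(condition$laser %||% "off", "precursor_150ms"))
      R[, sh$laser] <- R[, sh$laser] * population$laser_gain
  } else if (!is.null(condition$fra_freq_hz) &&
             !is.na(condition$fra_freq_hz)) {
    tone <- as.numeric(t >= tl$fra_tone_on_s &
                         t < tl$fra_tone_on_s + tl$fra_tone_s)
    thr <- population$fra_threshold_db + population$fra_vslope *
      abs(log2(condition$fra_freq_hz / population$cf))
    R <- R + (population$fra_gain *
                plogis((condition$fra_level_db - thr) / 3)) %o% tone
  }
  pmax(R, 0)
}

#' Generate trial-by-trial spike trains
#'
#' Spikes are drawn from an inhomogeneous Poisson process whose intensity is
#' [rate_function()] held piecewise-constant over bins of width `resolution`
#' (default 1 ms): within each bin the spike count is Poisson and spike times
#' are uniform. Trials sharing a stimulus condition are simulated jointly
#' (the superposition of independent Poisson trials is Poisson), which is
#' exact and fast. All draws flow from `seed`.
#'
#' @param population `neuron_params` table from [sample_population()].
#' @param schedule trial table from [build_schedule()].
#' @param seed integer seed.
#' @param resolution bin width for the piecewise-constant intensity (s).
#' @param config the `population_config` used to build `population`.
#' @return object of class `cmr_dataset`: list with `trials` (the schedule),
#'   `spikes` (`data.frame`: cell_id, trial_id, spike_time_s; trial-aligned
#'   seconds), and `truth` (the generative parameters).
#' @export
generate_trials <- function(population, schedule, seed = 1L,
                            resolution = 0.001,
                            config = attr(population, "config") %||%
                              population_config()) {
  stopifnot(nrow(schedule) > 0)
  key <- paste(schedule$masker_kind, schedule$snr_db, schedule$laser,
               signif(schedule$fra_freq_hz, 10), schedule$fra_level_db,
               schedule$duration_s, sep = "|")
  groups <- split(seq_len(nrow(schedule)), key)
  out <- vector("list", length(groups))
  k <- 0L
  n_cells <- nrow(population)
  with_seed(seed, {
    for (g in groups) {
      cond <- as.list(schedule[g[1L], c("masker_kind", "snr_db", "laser",
                                        "fra_freq_hz", "fra_level_db")])
      dur <- schedule$duration_s[g[1L]]
      nb <- as.integer(round(dur / resolution))
      tmid <- (seq_len(nb) - 0.5) * resolution
      ids <- schedule$trial_id[g]
      # superposed trials: independent Poisson counts per (cell, fine bin)
      lam <- rate_matrix(population, cond, tmid, config) *
        (resolution * length(ids))
      counts <- rpois(length(lam), lam)
      nz <- which(counts > 0L)
      if (!length(nz)) next
      cnt <- counts[nz]
      N <- sum(cnt)
      cell <- rep.int(population$cell_id[(nz - 1L) %% n_cells + 1L], cnt)
      bins <- rep.int((nz - 1L) %/% n_cells + 1L, cnt)
      k <- k + 1L
      out[[k]] <- list(
        cell_id = cell,
        trial_id = ids[sample.int(length(ids), N, replace = TRUE)],
        spike_time_s = (bins - 1L + runif(N)) * resolution)
    }
  })
  # rows in deterministic generation order (not sorted: sorting tens of
  # millions of spikes costs more than any consumer gains)
  spikes <- if (k) {
    dt <- data.table::rbindlist(out[seq_len(k)])
    data.table::setDF(dt)
    dt
  } else data.frame(cell_id = integer(), trial_id = integer(),
                    spike_time_s = numeric())
  structure(list(trials = schedule, spikes = spikes, truth = population),
            class = "cmr_dataset")
}
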
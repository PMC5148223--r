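# Stimulus model: SAM-tone maskers (narrowband / incoherent / comodulated),
# signal pips in masker troughs, pure-tone frequency-response-area grid, and
# the block-interleaved presentation schedule.

SIGNAL_FREQ_HZ <- 20000
MOD_RATE_HZ    <- 10
MASKER_LEVEL_DB <- 65

#' Trial timeline constants
#'
#' All analyses use a trial-aligned clock with a 0.5 s silent baseline, so the
#' masker portion always occupies 1.0--1.5 s regardless of whether a precursor
#' is present. Long maskers have precursor 0.5--0.9 s and a 0.1 s gap; the
#' short comodulated masker omits both (silence until 1.0 s). The first signal
#' pip occupies 1.175--1.225 s and its analysis window is 1.175--1.275 s.
#' The optogenetic silencing window covers the first 150 ms of stimulus time,
#' i.e. trial time 0.5--0.65 s.
#'
#' @return named list of durations and landmark times (seconds).
#' @export
cmr_timeline <- function() {
  list(
    baseline_s     = 0.5,
    precursor_on_s = 0.5,
    precursor_s    = 0.4,
    gap_s          = 0.1,
    masker_on_s    = 1.0,
    masker_s       = 0.5,
    trial_s        = 2.0,
    pip_onsets_s   = 1.0 + c(0.175, 0.275, 0.375),
    pip_s          = 0.05,
    pip1_window_s  = c(1.175, 1.275),
    onset_window_s = c(0.5, 0.575),
    laser_window_s = c(0.5, 0.65),
    fra_tone_on_s  = 0.5,
    fra_tone_s     = 0.5,
    fra_trial_s    = 1.5
  )
}

#' Masker kinds and SNR grid
#'
#' @return character vector of masker kinds / numeric dB SNR grid.
#' @export
masker_kinds <- function() c("NB", "IM", "CM_long", "CM_short")

#' @rdname masker_kinds
#' @export
snr_grid <- function() seq(-10, 20, by = 5)

# Carrier frequencies of the 7 masker components, on the 0.125-octave grid
# around 20 kHz. Flanking triplets are centred +/- 0.625 octaves away
# (12.9 and 30.8 kHz).
masker_band_freqs <- function(kind) {
  if (kind == "NB") return(SIGNAL_FREQ_HZ)
  SIGNAL_FREQ_HZ * 2^(c(-6, -5, -4, 0, 4, 5, 6) / 8)
}

#' Build a masker specification
#'
#' Constructs the band table (carrier frequency, 10 Hz modulator phase, role)
#' and segment durations for one masker condition. `NB` is a single SAM tone
#' at 20 kHz; `IM` and `CM` add two three-component flanking bands centred at
#' 12.9 and 30.8 kHz. Comodulated (`CM_*`) bands share the on-frequency
#' envelope phase; incoherent (`IM`) flanker phases are fresh uniform draws on
#' [0, 180) degrees at every call. `CM_short` drops the 400 ms precursor and
#' the 100 ms gap but keeps the 500 ms masker portion.
#'
#' @param kind one of `masker_kinds()`.
#' @param seed optional integer; fixes the IM phase draws.
#' @return object of class `masker_spec`.
#' @export
build_masker <- function(kind, seed = NULL) {
  kind <- match.arg(kind, masker_kinds())
  freqs <- masker_band_freqs(kind)
  n <- length(freqs)
  role <- if (n == 1L) "on_frequency" else
    c(rep("low_flanker", 3), "on_frequency", rep("high_flanker", 3))
  phase <- numeric(n)
  if (kind == "IM") {
    off <- role != "on_frequency"
    phase[off] <- with_seed(seed, runif(sum(off), 0, 180))
  }
  structure(list(
    kind = kind,
    bands = data.frame(center_freq = freqs, modulator_rate = MOD_RATE_HZ,
                       modulator_phase = phase, level_role = role,
                       stringsAsFactors = FALSE),
    precursor_s = if (kind == "CM_short") 0 else 0.4,
    gap_s       = if (kind == "CM_short") 0 else 0.1,
    masker_s    = 0.5,
    level_dbspl = MASKER_LEVEL_DB
  ), class = "masker_spec")
}

#' Masker envelope value
#'
#' Raised-cosine SAM envelope `0.5 * (1 - cos(2*pi*10*t' + phi))`, where `t'`
#' runs from the onset of the containing segment (precursor or masker
#' portion), so every segment starts at an envelope minimum. Returns 0 inside
#' the gap and outside the stimulus. Times are trial-aligned seconds (see
#' [cmr_timeline()]).
#'
#' @param masker a `masker_spec`.
#' @param band_index band row index.
#' @param t numeric vector of trial-aligned times (s).
#' @return envelope amplitude in [0, 1], same length as `t`.
#' @export
envelope_value <- function(masker, band_index, t) {
  stopifnot(inherits(masker, "masker_spec"))
  if (band_index < 1L || band_index > nrow(masker$bands))
    stop("band_index out of range")
  tl <- cmr_timeline()
  phi <- masker$bands$modulator_phase[band_index] * pi / 180
  env <- numeric(length(t))
  if (masker$precursor_s > 0) {
    on <- tl$precursor_on_s
    in_pre <- t >= on & t < on + masker$precursor_s
    env[in_pre] <- 0.5 * (1 - cos(2 * pi * MOD_RATE_HZ * (t[in_pre] - on) + phi))
  }
  on <- tl$masker_on_s
  in_mask <- t >= on & t < on + masker$masker_s
  env[in_mask] <- 0.5 * (1 - cos(2 * pi * MOD_RATE_HZ * (t[in_mask] - on) + phi))
  env
}

#' Build a signal specification
#'
#' Three 50 ms pips of a 20 kHz carrier, one in each of the 3rd, 4th and 5th
#' troughs of the masker portion. With the onset-minimum envelope convention
#' the troughs of the masker portion fall at multiples of 100 ms after masker
#' onset (the onset minimum is trough 1), so the pips are centred at masker
#' onset + 0.2/0.3/0.4 s and start 25 ms earlier. `snr_db = NA` (noise alone)
#' yields `NULL`: no signal.
#'
#' @param snr_db signal-to-noise ratio in dB re the 65 dB SPL masker; one of
#'   `snr_grid()` or NA.
#' @param masker a `masker_spec` (must have a masker portion).
#' @return object of class `signal_spec`, or NULL for noise alone.
#' @export
build_signal <- function(snr_db, masker) {
  stopifnot(inherits(masker, "masker_spec"), masker$masker_s > 0)
  if (length(snr_db) != 1L) stop("snr_db must be a scalar")
  if (is.na(snr_db)) return(NULL)
  if (!snr_db %in% snr_grid())
    stop(sprintf("snr_db = %g is not on the configured grid (%s)",
                 snr_db, paste(snr_grid(), collapse = ", ")))
  tl <- cmr_timeline()
  structure(list(
    carrier_freq = SIGNAL_FREQ_HZ,
    n_pips = 3L,
    pip_s = tl$pip_s,
    pip_onsets = tl$pip_onsets_s,
    snr_db = snr_db
  ), class = "signal_spec")
}

#' Pure-tone frequency response area grid
#'
#' 25 frequencies at 0.125-octave spacing centred on 20 kHz (spanning
#' 7.07--56.6 kHz, and containing 20 and 21.8 kHz exactly) crossed with 8
#' levels from 10 to 80 dB SPL in 10 dB steps.
#'
#' @return object of class `fra_grid` with `freqs` and `levels`.
#' @export
build_fra_grid <- function() {
  structure(list(
    freqs = SIGNAL_FREQ_HZ * 2^((-12:12) / 8),
    levels = seq(10, 80, by = 10)
  ), class = "fra_grid")
}

#' Default experiment configuration
#'
#' Masking conditions (four masker kinds, optogenetic-silencing variants of
#' the comodulated maskers), the 7-step SNR grid plus noise alone, the FRA
#' grid, and the block structure: each cycle holds five masking blocks (one
#' repeat of every masker/signal combination each, 2 s ISI) followed by one
#' FRA block (one repeat of every frequency/level combination, 1 s ISI).
#' Six cycles give 30 repeats per masking combination and 6 per FRA point.
#'
#' @param ... overrides for any config entry.
#' @return named list.
#' @export
cmr_config <- function(...) {
  cfg <- list(
    masker_kinds = masker_kinds(),
    laser_kinds  = c("CM_long", "CM_short"),
    snr_db       = snr_grid(),
    n_cycles     = 6L,
    masking_blocks_per_cycle = 5L,
    isi_masking_s = 2,
    isi_fra_s     = 1,
    include_fra   = TRUE
  )
  dots <- list(...)
  cfg[names(dots)] <- dots
  cfg
}

#' Build the block-interleaved trial schedule
#'
#' One row per presentation. Masking trials carry `masker_kind`, `snr_db`
#' (NA = noise alone) and `laser`; FRA trials carry `fra_freq_hz` and
#' `fra_level_db`. Within-block order is a seeded permutation; all
#' randomisation flows from `seed`.
#'
#' @param config list from [cmr_config()].
#' @param seed integer seed.
#' @return `data.frame` (the trial table) with attribute `"seed"`; columns
#'   trial_id, onset_s, duration_s, cycle, block, block_type, masker_kind,
#'   snr_db, laser, fra_freq_hz, fra_level_db.
#' @export
build_schedule <- function(config = cmr_config(), seed = 1L) {
  if (!length(config$masker_kinds)) stop("empty condition set")
  tl <- cmr_timeline()
  combos <- expand.grid(masker_kind = config$masker_kinds,
                        laser = "off",
                        snr_db = c(NA, config$snr_db),
                        stringsAsFactors = FALSE)
  if (length(config$laser_kinds)) {
    las <- expand.grid(masker_kind = intersect(config$laser_kinds,
                                               config$masker_kinds),
                       laser = "precursor_150ms",
                       snr_db = c(NA, config$snr_db),
                       stringsAsFactors = FALSE)
    combos <- rbind(combos, las)
  }
  grid <- build_fra_grid()
  fra <- expand.grid(fra_freq_hz = grid$freqs, fra_level_db = grid$levels)

  blocks <- list()
  with_seed(seed, {
    for (cyc in seq_len(config$n_cycles)) {
      for (b in seq_len(config$masking_blocks_per_cycle)) {
        ord <- sample.int(nrow(combos))
        blk <- combos[ord, , drop = FALSE]
        blk$cycle <- cyc; blk$block_type <- "masking"
        blk$duration_s <- tl$trial_s; blk$isi_s <- config$isi_masking_s
        blk$fra_freq_hz <- NA_real_; blk$fra_level_db <- NA_real_
        blocks[[length(blocks) + 1L]] <- blk
      }
      if (isTRUE(config$include_fra)) {
        ord <- sample.int(nrow(fra))
        blk <- fra[ord, , drop = FALSE]
        blk$masker_kind <- NA_character_; blk$laser <- "off"
        blk$snr_db <- NA_real_
        blk$cycle <- cyc; blk$block_type <- "fra"
        blk$duration_s <- tl$fra_trial_s; blk$isi_s <- config$isi_fra_s
        blocks[[length(blocks) + 1L]] <- blk
      }
    }
  })
  nblk <- seq_along(blocks)
  trials <- do.call(rbind, lapply(nblk, function(i) {
    b <- blocks[[i]]; b$block <- i; b
  }))
  cols <- c("cycle", "block", "block_type", "masker_kind", "snr_db", "laser",
            "fra_freq_hz", "fra_level_db", "duration_s", "isi_s")
  trials <- trials[, cols]
  trials$trial_id <- seq_len(nrow(trials))
  trials$onset_s <- cumsum(c(0, (trials$duration_s + trials$isi_s)[-nrow(trials)]))
  trials$isi_s <- NULL
  rownames(trials) <- NULL
  trials <- trials[, c("trial_id", "onset_s", "duration_s", "cycle", "block",
                       "block_type", "masker_kind", "snr_db", "laser",
                       "fra_freq_hz", "fra_level_db")]
  attr(trials, "seed") <- seed
  trials
}

#' Condition label combining masker kind and laser state
#'
#' @param masker_kind character vector of kinds.
#' @param laser character vector, `"off"` or `"precursor_150ms"`.
#' @return character vector, e.g. `"CM_long"`, `"CM_long_laser"`.
#' @export
condition_label <- function(masker_kind, laser = "off") {
  ifelse(is.na(masker_kind), NA_character_,
         paste0(masker_kind, ifelse(laser == "precursor_150ms", "_laser", "")))
}

#' Render a stimulus waveform
#'
#' Sums the SAM tone components of a masker (and, optionally, the half-sine
#' signal pips) over the 2 s trial timeline. Sound levels are treated as
#' relative amplitudes with the 65 dB SPL masker band level as reference
#' amplitude 1; the signal amplitude is `10^(snr_db/20)`.
#'
#' @param masker a `masker_spec`.
#' @param signal a `signal_spec` or NULL (noise alone).
#' @param sample_rate sampling rate (Hz); must be at least 4x the highest
#'   component frequency.
#' @return numeric vector of samples spanning the trial.
#' @export
render_waveform <- function(masker, signal = NULL, sample_rate = 250000) {
  fmax <- max(masker$bands$center_freq,
              if (!is.null(signal)) signal$carrier_freq else 0)
  if (sample_rate < 4 * fmax)
    stop(sprintf("sample_rate %g Hz would alias components up to %g Hz (need >= %g)",
                 sample_rate, fmax, 4 * fmax))
  tl <- cmr_timeline()
  t <- seq(0, tl$trial_s, by = 1 / sample_rate)
  wav <- numeric(length(t))
  for (b in seq_len(nrow(masker$bands))) {
    env <- envelope_value(masker, b, t)
    wav <- wav + env * sin(2 * pi * masker$bands$center_freq[b] * t)
  }
  if (!is.null(signal)) {
    amp <- 10^(signal$snr_db / 20)
    for (on in signal$pip_onsets) {
      idx <- t >= on & t < on + signal$pip_s
      penv <- sin(pi * (t[idx] - on) / signal$pip_s)  # half-sine fills the trough
      wav[idx] <- wav[idx] +
        amp * penv * sin(2 * pi * signal$carrier_freq * t[idx])
    }
  }
  wav
}
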
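# Stimulus model: masker construction, envelopes, signal pips, FRA grid,
# schedule invariants, waveform rendering.

test_that("build_masker assembles the band sets of each condition", {
  nb <- build_masker("NB")
  expect_equal(nrow(nb$bands), 1L)
  expect_equal(nb$bands$center_freq, 20000)
  expect_equal(nb$bands$modulator_rate, 10)

  cm <- build_masker("CM_long")
  expect_equal(nrow(cm$bands), 7L)
  low <- cm$bands$center_freq[cm$bands$level_role == "low_flanker"]
  high <- cm$bands$center_freq[cm$bands$level_role == "high_flanker"]
  # flanking triplets centred at 12.9 / 30.8 kHz on the 0.125-octave grid
  expect_equal(low, 20000 * 2^(c(-6, -5, -4) / 8), tolerance = 1e-12)
  expect_equal(round(low), c(11892, 12968, 14142))
  expect_equal(round(high), c(28284, 30844, 33636))
  expect_equal(low[2], 12900, tolerance = 0.01)   # printed "12.9 kHz" centre
  expect_equal(high[2], 30800, tolerance = 0.01)  # printed "30.8 kHz" centre
  expect_equal(round(sort(c(low, high, 20000))[4]), 20000)
  # all CM band envelopes share the on-frequency phase
  expect_true(all(cm$bands$modulator_phase == cm$bands$modulator_phase[4]))

  short <- build_masker("CM_short")
  expect_equal(short$precursor_s, 0)
  expect_equal(short$gap_s, 0)
  expect_equal(short$masker_s, 0.5)

  expect_error(build_masker("XX"))
})

test_that("IM flanker phases are fresh uniform draws on [0, 180)", {
  m1 <- build_masker("IM", seed = 1)
  m2 <- build_masker("IM", seed = 1)
  m3 <- build_masker("IM", seed = 2)
  off <- m1$bands$level_role != "on_frequency"
  expect_identical(m1$bands$modulator_phase, m2$bands$modulator_phase)
  expect_false(identical(m1$bands$modulator_phase[off],
                         m3$bands$modulator_phase[off]))
  expect_true(all(m1$bands$modulator_phase[off] >= 0 &
                    m1$bands$modulator_phase[off] < 180))
  expect_equal(m1$bands$modulator_phase[!off], 0)
  # repeated draws span the range (property over seeds)
  ph <- unlist(lapply(1:40, function(s)
    build_masker("IM", seed = s)$bands$modulator_phase[off]))
  expect_gt(max(ph), 150); expect_lt(min(ph), 30)
})

test_that("envelope follows the onset-minimum raised-cosine convention", {
  cm <- build_masker("CM_long")
  tl <- cmr_timeline()
  on <- tl$masker_on_s
  expect_equal(envelope_value(cm, 1, on), 0)
  expect_equal(envelope_value(cm, 1, on + 0.05), 1)
  expect_equal(envelope_value(cm, 1, on + 0.025), 0.5)
  # zero in the gap and before stimulus onset
  expect_equal(envelope_value(cm, 1, 0.95), 0)
  expect_equal(envelope_value(cm, 1, 0.2), 0)
  # precursor runs its own envelope from its own onset
  expect_equal(envelope_value(cm, 1, tl$precursor_on_s), 0)
  expect_equal(envelope_value(cm, 1, tl$precursor_on_s + 0.05), 1)
  # all 7 CM bands identical at every time
  t <- seq(0, 2, by = 0.001)
  e1 <- envelope_value(cm, 1, t)
  for (b in 2:7) expect_equal(envelope_value(cm, b, t), e1)
  expect_error(envelope_value(cm, 8, 1))
})

test_that("IM bands have distinct envelope phases with probability 1", {
  im <- build_masker("IM", seed = 3)
  t <- seq(1.0, 1.5, by = 0.001)
  e_on <- envelope_value(im, 4, t)
  cors <- vapply(c(1:3, 5:7), function(b)
    cor(envelope_value(im, b, t), e_on), numeric(1))
  expect_true(all(cors < 0.999))
})

test_that("signal pips fill the 3rd-5th masker troughs", {
  cm <- build_masker("CM_long")
  sig <- build_signal(5, cm)
  expect_equal(sig$n_pips, 3L)
  expect_equal(sig$pip_onsets, c(1.175, 1.275, 1.375))
  expect_equal(cmr_timeline()$pip1_window_s, c(1.175, 1.275))
  # pip centres sit on envelope minima (troughs) of the masker portion
  centres <- sig$pip_onsets + sig$pip_s / 2
  expect_equal(envelope_value(cm, 1, centres), rep(0, 3), tolerance = 1e-9)
  # pips all inside the masker portion
  expect_true(all(sig$pip_onsets >= 1.0 & sig$pip_onsets + sig$pip_s <= 1.5))
  expect_null(build_signal(NA, cm))
  expect_error(build_signal(7, cm), "grid")
})

test_that("FRA grid is 25 x 8 on the 0.125-octave / 10 dB lattice", {
  g <- build_fra_grid()
  expect_length(g$freqs, 25L)
  expect_length(g$levels, 8L)
  expect_equal(g$levels, seq(10, 80, 10))
  expect_true(20000 %in% g$freqs)
  expect_true(any(abs(g$freqs - 20000 * 2^(1 / 8)) < 1e-6))  # 21.8 kHz
  expect_equal(diff(log2(g$freqs)), rep(0.125, 24))
  expect_equal(range(g$freqs), 20000 * 2^c(-1.5, 1.5), tolerance = 1e-12)
})

test_that("schedule meets the block-count invariants for any config", {
  for (cfg in list(cmr_config(),
                   cmr_config(n_cycles = 3L, masking_blocks_per_cycle = 2L,
                              laser_kinds = character()))) {
    sched <- build_schedule(cfg, seed = 11)
    mk <- sched[sched$block_type == "masking", ]
    counts <- table(paste(mk$masker_kind, mk$snr_db, mk$laser))
    expect_true(all(counts == cfg$n_cycles * cfg$masking_blocks_per_cycle))
    fr <- sched[sched$block_type == "fra", ]
    fc <- table(paste(round(fr$fra_freq_hz), fr$fra_level_db))
    expect_length(fc, 200L)
    expect_true(all(fc == cfg$n_cycles))
    # every trial is exactly one of masking / FRA
    expect_true(all(xor(!is.na(sched$masker_kind), !is.na(sched$fra_freq_hz))))
    # onsets strictly increasing with at least the stated ISI
    expect_true(all(diff(sched$onset_s) >=
                      sched$duration_s[-nrow(sched)] + 1 - 1e-9))
  }
  # default config: 30 masking repeats, 6 FRA repeats
  sched <- build_schedule(cmr_config(), seed = 1)
  mk <- sched[sched$block_type == "masking", ]
  expect_true(all(table(paste(mk$masker_kind, mk$snr_db, mk$laser)) == 30L))
  expect_error(build_schedule(cmr_config(masker_kinds = character())))
})

test_that("schedule order is a seeded permutation (deterministic)", {
  a <- build_schedule(cmr_config(), seed = 9)
  b <- build_schedule(cmr_config(), seed = 9)
  c <- build_schedule(cmr_config(), seed = 10)
  expect_identical(a, b)
  expect_false(identical(a$masker_kind, c$masker_kind))
})

test_that("rendered waveforms respect gaps, SNR scaling and CM coherence", {
  cm <- build_masker("CM_long")
  fs <- 250000
  wav <- render_waveform(cm, signal = NULL, sample_rate = fs)
  t <- seq(0, 2, by = 1 / fs)
  expect_true(all(wav[t >= 0.91 & t < 0.99] == 0))   # gap
  expect_true(all(wav[t < 0.5] == 0))                # pre-stimulus silence
  expect_error(render_waveform(cm, sample_rate = 40000), "alias")

  # coarse rectified envelopes of two single-band renderings correlate ~1
  one_band <- function(b) {
    m <- cm; m$bands <- cm$bands[b, , drop = FALSE]
    render_waveform(m, sample_rate = fs)
  }
  sm <- function(x) as.numeric(stats::filter(abs(x), rep(1 / 2501, 2501),
                                             sides = 2))
  keep <- t >= 1.05 & t <= 1.45
  e1 <- sm(one_band(1))[keep]; e2 <- sm(one_band(7))[keep]
  expect_gt(cor(e1, e2, use = "complete.obs"), 0.9)

  # signal pips appear only in their windows, amplitude follows snr
  sig <- build_signal(20, cm)
  wav_s <- render_waveform(cm, sig, sample_rate = fs)
  d <- wav_s - wav
  expect_true(all(d[t < 1.175] == 0))
  expect_gt(max(abs(d[t >= 1.175 & t < 1.225])), 5)  # 10^(20/20) = 10x pip
})
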
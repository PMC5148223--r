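# SR statistic: sigma, SR profiles, SR/SNR functions, bootstrap screen,
# responsive-set selection, population SR, subpopulation bootstrap.

mk_psth <- function(rate, cell_id = 1, bin_s = 0.005, n_trials = 30) {
  structure(list(cell_id = cell_id,
                 breaks = seq(0, by = bin_s, length.out = length(rate) + 1),
                 bin_s = bin_s, rate = rate, n_trials = n_trials),
            class = "psth")
}

test_that("cell_sigma is the pooled population SD of all bins", {
  p1 <- mk_psth(c(0, 10)); p2 <- mk_psth(c(10, 0))
  expect_equal(cell_sigma(list(p1, p2)), 5)          # {0,10} equally -> 5
  expect_equal(cell_sigma(list(p2, p1)), 5)          # order invariant
  expect_warning(s <- cell_sigma(list(mk_psth(c(3, 3, 3)))), "zero variance")
  expect_true(is.na(s))
  expect_error(cell_sigma(list(mk_psth(5))), "2 bins")
})

test_that("signal_response is binwise (Sig - N) / sigma", {
  sig <- mk_psth(c(40, 10)); noi <- mk_psth(c(30, 10))
  sr <- signal_response(sig, noi, 5)
  expect_equal(sr$sr, c(2, 0))
  expect_equal(signal_response(noi, noi, 5)$sr, c(0, 0))  # Sig = N -> 0
  expect_error(signal_response(sig, mk_psth(c(1, 2, 3)), 5), "bin edges")
  expect_error(signal_response(sig, noi, 0), "sigma")
})

test_that("SR linearity: adding c*sigma per bin raises SR by c exactly", {
  set.seed(1)
  base <- runif(50, 0, 20)
  noi <- mk_psth(base)
  for (c0 in c(0.5, 2, -1)) {
    sig <- mk_psth(base + c0 * 4)
    expect_equal(signal_response(sig, noi, 4)$sr, rep(c0, 50))
  }
})

test_that("sr_snr_function interpolates thresholds on the 0.1 dB grid", {
  win <- cmr_timeline()$pip1_window_s
  nbin <- 400
  mk_prof <- function(v) {
    sr <- rep(0, nbin)
    sr[236:255] <- v  # bins covering 1.175-1.275 s
    structure(list(breaks = seq(0, 2, by = 0.005), bin_s = 0.005, sr = sr,
                   cell_id = 1), class = "sr_profile")
  }
  profs <- lapply(c(`0` = 0, `5` = 1), mk_prof)
  fn <- sr_snr_function(profs, window = win)
  expect_equal(fn$value, c(0, 1))
  expect_equal(fn$threshold_db, 2.5)               # linear crossing of 0.5

  # flat zero -> no threshold
  fn0 <- sr_snr_function(lapply(c(`-10` = 0, `20` = 0), mk_prof))
  expect_true(is.na(fn0$threshold_db))

  # exact criterion at a measured SNR -> that SNR
  fn1 <- sr_snr_function(lapply(c(`0` = 0.5, `5` = 1), mk_prof))
  expect_equal(fn1$threshold_db, 0)

  # first crossing retained for non-monotone functions
  fn2 <- sr_snr_function(lapply(c(`0` = 0, `5` = 1, `10` = 0.2,
                                  `15` = 1), mk_prof))
  expect_equal(fn2$threshold_db, 2.5)
  expect_error(sr_snr_function(list(mk_prof(1)), snr_db = NA), "SNR")
})

test_that("threshold is monotone under constant positive offsets", {
  set.seed(2)
  for (i in 1:20) {
    snr <- snr_grid()
    vals <- cumsum(runif(7, -0.1, 0.4))
    t1 <- cmrtools:::sr_function_from_values(snr, vals)$threshold_db
    t2 <- cmrtools:::sr_function_from_values(snr, vals + 0.2)$threshold_db
    if (!is.na(t1)) expect_true(!is.na(t2) && t2 <= t1)
  }
})

test_that("bootstrap screen flags clear increases and is seeded", {
  a <- rep(c(1, 2), 10); b <- rep(c(50, 60), 10)
  expect_true(bootstrap_significance(a, b, seed = 1)$significant)
  expect_false(bootstrap_significance(b, a, seed = 1)$significant)
  r1 <- bootstrap_significance(a, b, seed = 7)
  r2 <- bootstrap_significance(a, b, seed = 7)
  expect_identical(r1, r2)
  expect_error(bootstrap_significance(1:3, 1:10), "at least")
})

test_that("responsive-set selection finds planted responders", {
  # 4 cells: 1-2 respond at CM 20 dB only, 3-4 never
  trials <- data.frame(
    trial_id = 1:60, onset_s = 0, duration_s = 2,
    masker_kind = rep(c("NB", "CM_long"), each = 30),
    snr_db = rep(rep(c(NA, 20), each = 15), 2),
    laser = "off", fra_freq_hz = NA_real_, fra_level_db = NA_real_)
  win <- cmr_timeline()$pip1_window_s
  set.seed(4)
  mk_spikes <- function(cell, trial_ids, n_per_trial) {
    n <- length(trial_ids) * n_per_trial
    data.frame(cell_id = cell,
               trial_id = rep(trial_ids, each = n_per_trial),
               spike_time_s = runif(n, win[1], win[2]))
  }
  cm_sig <- trials$trial_id[trials$masker_kind == "CM_long" &
                              !is.na(trials$snr_db)]
  spikes <- rbind(
    mk_spikes(1, cm_sig, 8), mk_spikes(2, cm_sig, 8),
    mk_spikes(3, trials$trial_id, 1), mk_spikes(4, trials$trial_id, 1))
  res <- select_responsive(spikes, trials, cells = 1:4, seed = 3L)
  expect_setequal(res$overall, c(1L, 2L))
  expect_setequal(res$by_condition$CM_long, c(1L, 2L))
  expect_false("NB" %in% names(res$by_condition) &&
                 length(res$by_condition$NB) > 0)
})

test_that("population mean SR equals the oracle mean across cells", {
  nbin <- 400
  mk_prof <- function(v) structure(
    list(breaks = seq(0, 2, by = 0.005), bin_s = 0.005,
         sr = rep(v, nbin), cell_id = 1), class = "sr_profile")
  # identical cells: population equals any individual
  p <- population_mean_sr(list(`0` = list(mk_prof(0.3), mk_prof(0.3)),
                               `5` = list(mk_prof(1), mk_prof(1))))
  expect_equal(p$fn$value, c(0.3, 1))
  # cells with SR 0 and 2 -> population 1
  p2 <- population_mean_sr(list(`0` = list(mk_prof(0), mk_prof(2))))
  expect_equal(p2$fn$value, 1)
  # oracle: random profiles, mean recomputed independently
  set.seed(9)
  pl <- lapply(1:7, function(i) mk_prof(runif(1)))
  p3 <- population_mean_sr(list(`0` = pl))
  expect_equal(p3$profiles[["0"]]$sr,
               rowMeans(sapply(pl, `[[`, "sr")))
  expect_error(population_mean_sr(list()), "empty")
})

test_that("subpopulation bootstrap reproduces single cells and rankings", {
  snr <- snr_grid()
  # one-cell bin: bootstrap mean equals that cell's function
  one <- matrix(seq(0, 1.2, length.out = 7), nrow = 1)
  got <- subpopulation_sensitivity(one, snr, seed = 2)
  expect_equal(got$fn$value, as.numeric(one), tolerance = 1e-12)
  # tuned bin (strong SR) beats untuned bin (weak SR)
  set.seed(5)
  tuned <- t(replicate(20, plogis((snr - 0) / 2) * 2 + rnorm(7, 0, 0.05)))
  untuned <- t(replicate(20, plogis((snr - 12) / 2) * 2 + rnorm(7, 0, 0.05)))
  s_t <- subpopulation_sensitivity(tuned, snr, seed = 3)$sensitivity_db
  s_u <- subpopulation_sensitivity(untuned, snr, seed = 3)$sensitivity_db
  expect_lt(s_t, s_u)
  # deterministic given seed
  expect_identical(subpopulation_sensitivity(tuned, snr, seed = 4),
                   subpopulation_sensitivity(tuned, snr, seed = 4))
  expect_error(subpopulation_sensitivity(tuned[0, , drop = FALSE], snr),
               "empty")
})

test_that("masking release is a threshold difference", {
  expect_equal(masking_release(8, 2), 6)
  expect_equal(masking_release(3, 3), 0)
  expect_true(is.na(masking_release(NA, 2)))
})

test_that("signal-tuned band selects the 15.4-21.8 kHz CF grid points", {
  g <- build_fra_grid()$freqs
  expect_true(all(is_signal_tuned(c(20000, 21810.2, 15422))))
  expect_false(any(is_signal_tuned(c(7071, 56569, 12886, 23784, NA))))
  inside <- g[is_signal_tuned(g)]
  expect_equal(round(range(inside)), round(20000 * 2^(c(-3, 1) / 8)))
  expect_length(inside, 5L)
})
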
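# FRA mapping, pyramidal smoothing, dual-criterion regions, CF.

test_that("compute_fra averages tone-window rates per grid point", {
  grid <- build_fra_grid()
  combos <- expand.grid(f = grid$freqs, l = grid$levels)
  trials <- data.frame(
    trial_id = seq_len(nrow(combos) * 2),
    onset_s = 0, duration_s = 1.5,
    masker_kind = NA_character_, snr_db = NA_real_, laser = "off",
    fra_freq_hz = rep(combos$f, 2), fra_level_db = rep(combos$l, 2))
  # silent cell
  f0 <- compute_fra(data.frame(cell_id = integer(), trial_id = integer(),
                               spike_time_s = numeric()), trials, 1, grid)
  expect_true(all(f0$rates == 0))
  expect_equal(f0$baseline_rate, 0)

  # cell firing only at 20 kHz / 80 dB: 12 spikes over 2 trials x 0.5 s
  ids <- trials$trial_id[trials$fra_freq_hz == 20000 &
                           trials$fra_level_db == 80]
  spikes <- data.frame(cell_id = 1, trial_id = rep(ids, each = 6),
                       spike_time_s = 0.7)
  f1 <- compute_fra(spikes, trials, 1, grid)
  expect_equal(sum(f1$rates > 0), 1L)
  expect_equal(f1$rates[which(abs(grid$freqs - 20000) < 1), "80"],
               12 / (2 * 0.5), ignore_attr = TRUE)
  # pre-tone spikes feed the baseline only
  spikes2 <- rbind(spikes, data.frame(cell_id = 1, trial_id = trials$trial_id,
                                      spike_time_s = 0.25))
  f2 <- compute_fra(spikes2, trials, 1, grid)
  expect_equal(f2$baseline_rate, nrow(trials) / (nrow(trials) * 0.5))

  # missing grid point (both repeats of the first combo dropped) errors
  drop <- which(trials$fra_freq_hz == combos$f[1] &
                  trials$fra_level_db == combos$l[1])
  expect_error(compute_fra(spikes, trials[-drop, ], 1, grid), "missing FRA")
})

test_that("pyramidal smoothing matches kernel arithmetic and edge rules", {
  m <- matrix(0, 5, 5); m[3, 3] <- 16
  s <- smooth_pyramidal(m)
  expect_equal(s[3, 3], 4)
  expect_equal(s[2, 3], 2); expect_equal(s[3, 2], 2)
  expect_equal(s[2, 2], 1); expect_equal(s[4, 4], 1)
  expect_equal(sum(s), 16)  # kernel sums to one for interior impulses

  # corner impulse: kernel renormalised over the in-bounds 2x2 block
  m <- matrix(0, 4, 4); m[1, 1] <- 16
  s <- smooth_pyramidal(m)
  expect_equal(s[1, 1], 16 * 4 / 9)    # 2x2 in-bounds block, weight sum 9
  expect_equal(s[1, 2], 16 * 2 / 12)   # edge cell: weight sum 12
  expect_equal(s[2, 2], 16 * 1 / 16)   # full kernel in bounds

  # constant matrix unchanged everywhere (including edges)
  m <- matrix(7, 6, 3)
  expect_equal(smooth_pyramidal(m), m)

  # fra method preserves the object
  f <- as_fra(matrix(1, 3, 3))
  expect_s3_class(smooth_pyramidal(f), "fra")
})

test_that("find_regions implements the 30/15% dual criterion", {
  # two strong blobs joined by a 20% bridge -> one merged region
  r <- matrix(1, 5, 3)
  r[1, 1] <- 1.4; r[2, 1] <- 1.4          # blob A (rows 1-2)
  r[3, 1] <- 1.2                          # bridge passes 15% only
  r[4, 1] <- 1.4; r[5, 1] <- 1.4          # blob B
  regs <- find_regions(as_fra(r, baseline = 1))
  exc <- Filter(function(x) x$polarity == "excitatory", regs)
  expect_length(exc, 1L)
  expect_equal(exc[[1]]$size, 4L)         # strong cells only are members

  # sub-15% gap -> two regions
  r[3, 1] <- 1.1
  regs <- find_regions(as_fra(r, baseline = 1))
  exc <- Filter(function(x) x$polarity == "excitatory", regs)
  expect_length(exc, 2L)

  # all-baseline matrix -> no regions
  expect_length(find_regions(as_fra(matrix(1, 4, 4), baseline = 1)), 0L)

  # inhibitory regions found separately with mirrored criteria
  r <- matrix(1, 4, 4); r[2, 2] <- 0.6
  regs <- find_regions(as_fra(r, baseline = 1))
  pol <- vapply(regs, `[[`, character(1), "polarity")
  expect_equal(pol, "inhibitory")

  # zero baseline falls back to the absolute floor
  r <- matrix(0, 4, 4); r[1, 2] <- 2
  regs <- find_regions(as_fra(r, baseline = 0))
  expect_length(regs, 1L)
  expect_equal(regs[[1]]$polarity, "excitatory")
})

test_that("region finder agrees with flood-fill oracle on all 4x4 binaries", {
  mismatches <- 0L
  for (code in 0:65535) {
    mask <- matrix(bitwAnd(bitwShiftR(code, 0:15), 1L) == 1L, 4, 4)
    f <- as_fra(matrix(ifelse(mask, 2, 1), 4, 4), baseline = 1)
    regs <- Filter(function(x) x$polarity == "excitatory", find_regions(f))
    oracle <- flood_fill_components(mask)
    n_oracle <- max(oracle)
    if (length(regs) != n_oracle) { mismatches <- mismatches + 1L; next }
    if (n_oracle > 0) {
      got <- lapply(regs, function(rg)
        sort(rg$cells[, 1] + (rg$cells[, 2] - 1L) * 4L))
      want <- lapply(seq_len(n_oracle), function(k) sort(which(oracle == k)))
      if (!setequal(lapply(got, paste, collapse = ","),
                    lapply(want, paste, collapse = ",")))
        mismatches <- mismatches + 1L
    }
  }
  expect_equal(mismatches, 0L)
})

test_that("characteristic frequency uses the largest region and tie-breaks", {
  # V-shaped region with unique tip
  r <- matrix(1, 25, 8)
  tip_f <- 13  # 20 kHz row in the standard grid
  for (l in 3:8) {
    w <- (l - 3)
    r[(tip_f - w):(tip_f + w), l] <- 2
  }
  g <- build_fra_grid()
  f <- structure(list(rates = r, freqs = g$freqs, levels = g$levels,
                      baseline_rate = 1, cell_id = 1), class = "fra")
  res <- characteristic_frequency(find_regions(f), f)
  expect_equal(res$cf, 20000)
  expect_equal(res$threshold_level, g$levels[3])

  # two regions: CF must come from the larger one
  r2 <- matrix(1, 25, 8)
  r2[1:3, 4:7] <- 2            # 12 cells
  r2[20:21, 2:3] <- 2          # 4 cells (lower level, smaller region)
  f2 <- structure(list(rates = r2, freqs = g$freqs, levels = g$levels,
                       baseline_rate = 1, cell_id = 1), class = "fra")
  res2 <- characteristic_frequency(find_regions(f2), f2)
  expect_equal(res2$region$size, 12L)
  expect_equal(res2$threshold_level, g$levels[4])
  expect_true(res2$cf %in% g$freqs[1:3])

  # tie at the lowest level broken by the higher smoothed rate
  r3 <- matrix(1, 25, 8)
  r3[10, 3] <- 5; r3[11, 3] <- 8; r3[10:11, 4:6] <- 5
  f3 <- structure(list(rates = r3, freqs = g$freqs, levels = g$levels,
                       baseline_rate = 1, cell_id = 1), class = "fra")
  res3 <- characteristic_frequency(find_regions(f3), f3)
  expect_equal(res3$cf, g$freqs[11])

  # no excitatory region -> NULL (cell excluded)
  f4 <- as_fra(matrix(1, 4, 4), baseline = 1)
  expect_null(characteristic_frequency(find_regions(f4), f4))
})

test_that("CF recovery on simulated cells is within 0.125 octave", {
  # well-driven cells (high tuning-curve SNR) with CFs away from the grid
  # edges, where the V-tip is not truncated
  cfg <- population_config(n_cells = 8L, tuned_only = FALSE, seed = 31L,
                           cf_range_hz = c(9000, 45000),
                           baseline_meanlog = log(8), baseline_sdlog = 0.2,
                           fra_gain_meanlog = log(40), fra_gain_sdlog = 0.2)
  pop <- sample_population(cfg)
  sched <- build_schedule(cmr_config(masker_kinds = "NB", n_cycles = 6L,
                                     masking_blocks_per_cycle = 1L,
                                     laser_kinds = character(),
                                     snr_db = numeric()), seed = 8L)
  ds <- generate_trials(pop, sched, seed = 9L, config = cfg)
  err <- vapply(pop$cell_id, function(cell) {
    f <- smooth_pyramidal(compute_fra(ds$spikes, ds$trials, cell))
    res <- characteristic_frequency(find_regions(f), f)
    if (is.null(res)) return(NA_real_)
    abs(log2(res$cf / pop$cf[pop$cell_id == cell]))
  }, numeric(1))
  expect_true(all(is.na(err) | err <= 0.125 + 1e-9))
  expect_gt(sum(!is.na(err)), 5)
})
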
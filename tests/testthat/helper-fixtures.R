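# Shared fixtures and independent oracles used across test files.

# Hand-built tiny trial table: two masking conditions x (noise, one SNR),
# 3 trials each, plus two FRA points.
toy_trials <- function() {
  data.frame(
    trial_id = 1:14,
    onset_s = seq(0, by = 4, length.out = 14),
    duration_s = c(rep(2, 12), 1.5, 1.5),
    masker_kind = c(rep("NB", 6), rep("CM_long", 6), NA, NA),
    snr_db = c(rep(NA, 3), rep(5, 3), rep(NA, 3), rep(5, 3), NA, NA),
    laser = c(rep("off", 12), "off", "off"),
    fra_freq_hz = c(rep(NA, 12), 20000, 10000),
    fra_level_db = c(rep(NA, 12), 50, 50),
    stringsAsFactors = FALSE
  )
}

# Independent flood-fill oracle: 4-connected components of a logical matrix
# by breadth-first search over explicit neighbour lists.
flood_fill_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc); cur <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!mask[i, j] || lab[i, j] != 0L) next
    cur <- cur + 1L
    queue <- list(c(i, j))
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      if (lab[p[1], p[2]] != 0L) next
      lab[p[1], p[2]] <- cur
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        q <- p + d
        if (q[1] >= 1 && q[1] <= nr && q[2] >= 1 && q[2] <= nc &&
            mask[q[1], q[2]] && lab[q[1], q[2]] == 0L)
          queue <- c(queue, list(q))
      }
    }
  }
  lab
}

# Exact binomial upper-tail by summation of choose(n, k) / 2^n.
binom_tail_enum <- function(successes, n) {
  if (successes <= 0) return(1)
  if (successes > n) return(0)
  sum(choose(n, successes:n)) / 2^n
}

# Wrap a rate matrix as an `fra` object.
as_fra <- function(rates, baseline = 1) {
  structure(list(rates = rates,
                 freqs = 2^(seq_len(nrow(rates)) - 1) * 1000,
                 levels = seq_len(ncol(rates)) * 10,
                 baseline_rate = baseline, cell_id = 1L),
            class = "fra")
}

# Small simulated dataset shared by several test files (masking only).
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- population_config(n_cells = 8L, tuned_only = TRUE, seed = 42L)
      pop <- sample_population(cfg)
      sched <- build_schedule(
        cmr_config(n_cycles = 3L, masking_blocks_per_cycle = 5L,
                   include_fra = FALSE, laser_kinds = character()),
        seed = 5L)
      cache <<- generate_trials(pop, sched, seed = 6L, config = cfg)
    }
    cache
  }
})
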
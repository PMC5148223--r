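# Orchestration: simulate -> analyze -> report. Runs the condition-contrast
# experiments (narrowband vs incoherent vs comodulated maskers; long vs
# short maskers; precursor-window cortical silencing) end to end on
# simulated or supplied data and emits summary tables.

#' Experiment configuration
#'
#' Bundles the schedule and population configurations with analysis options.
#' `screen_responsive` applies the bootstrap responsiveness screen before
#' population analyses (the full screen is expensive; parameter-recovery
#' batteries may disable it — its calibration is validated separately).
#'
#' @param schedule list from [cmr_config()].
#' @param population list from [population_config()].
#' @param ... overrides: `screen_responsive`, `tuned_band_hz`,
#'   `cf_source` ("truth" or "fra"), `afi_transform`, `run_battery`.
#' @return named list of class `experiment_config`.
#' @export
experiment_config <- function(schedule = cmr_config(),
                              population = population_config(), ...) {
  cfg <- list(
    schedule = schedule,
    population = population,
    screen_responsive = TRUE,
    tuned_band_hz = c(15000, 23000),
    cf_source = "truth",
    afi_transform = "exp",
    run_battery = TRUE
  )
  dots <- list(...)
  cfg[names(dots)] <- dots
  structure(cfg, class = "experiment_config")
}

# Neurometric threshold for one condition over a cell set.
condition_neurometric <- function(sr, cells, condition) {
  sub <- sr[sr$cell_id %in% cells & sr$condition == condition, , drop = FALSE]
  if (!nrow(sub)) return(list(threshold_db = NA_real_, fn = NULL))
  votes <- data.table::dcast(data.table::as.data.table(sub),
                             cell_id ~ snr_db, value.var = "vote")
  m <- as.matrix(votes[, -1])
  fn <- population_proportion(m, as.numeric(colnames(m)))
  thr <- neurometric_threshold(fn)
  list(threshold_db = thr$threshold_db, fn = fn)
}

# Population mean SR/SNR values for one condition over a cell set.
condition_population_sr <- function(sr, cells, condition) {
  sub <- sr[sr$cell_id %in% cells & sr$condition == condition &
              is.finite(sr$sr), , drop = FALSE]
  if (!nrow(sub)) return(NULL)
  agg <- aggregate(sr ~ snr_db, data = sub, FUN = mean)
  sr_function_from_values(agg$snr_db, agg$sr, criterion = 0.5)
}

#' Run a full simulate-analyze-report experiment
#'
#' Simulates a population and schedule (or analyses a supplied dataset),
#' computes per-cell SR functions, thresholds and votes, the population
#' neurometric thresholds per condition, the masking-release contrasts, AFI
#' and its relation to masking release, and (optionally) the standard
#' statistical test battery. All randomness derives from `seed` via
#' per-stage substreams.
#'
#' @param config an `experiment_config`.
#' @param seed master integer seed.
#' @param dataset optional pre-built `cmr_dataset` (skips simulation).
#' @param out_dir optional directory; report tables are written there.
#' @return object of class `cmr_report`.
#' @export
run_experiment <- function(config = experiment_config(), seed = 1L,
                           dataset = NULL, out_dir = NULL) {
  if (is.null(dataset)) {
    pop_cfg <- config$population
    pop_cfg$seed <- substream_seed(seed, 1L)
    population <- sample_population(pop_cfg)
    schedule <- build_schedule(config$schedule, seed = substream_seed(seed, 2L))
    dataset <- generate_trials(population, schedule,
                               seed = substream_seed(seed, 3L),
                               config = pop_cfg)
  }
  spikes <- dataset$spikes; trials <- dataset$trials
  ana <- analyze_signal_responses(spikes, trials)

  # characteristic frequencies
  cells <- ana$sigma$cell_id
  if (identical(config$cf_source, "fra") && any(!is.na(trials$fra_freq_hz))) {
    cf <- vapply(cells, function(cell) {
      f <- smooth_pyramidal(compute_fra(spikes, trials, cell))
      res <- characteristic_frequency(find_regions(f), f)
      if (is.null(res)) NA_real_ else res$cf
    }, numeric(1))
  } else if (!is.null(dataset$truth)) {
    cf <- dataset$truth$cf[match(cells, dataset$truth$cell_id)]
  } else stop("no CF source: dataset has neither FRA trials nor truth")
  tuned <- cells[is_signal_tuned(cf, config$tuned_band_hz)]

  conditions <- sort(unique(ana$sr$condition))
  if (isTRUE(config$screen_responsive)) {
    resp <- select_responsive(spikes, trials, cells = cells,
                              seed = substream_seed(seed, 4L))
    set_main <- intersect(tuned, resp$overall)
    set_cm <- intersect(tuned, resp$by_condition[["CM_long"]] %||% integer())
  } else {
    resp <- NULL
    set_main <- tuned
    set_cm <- tuned
  }

  main_conds <- intersect(c("NB", "IM", "CM_long"), conditions)
  cm_conds <- intersect(c("CM_long", "CM_short", "CM_long_laser",
                          "CM_short_laser"), conditions)
  neuro <- list()
  for (cond in main_conds)
    neuro[[cond]] <- condition_neurometric(ana$sr, set_main, cond)
  for (cond in cm_conds)
    neuro[[paste0(cond, ".cmset")]] <-
      condition_neurometric(ana$sr, set_cm, cond)
  thr_of <- function(key) neuro[[key]]$threshold_db %||% NA_real_
  thresholds <- data.frame(
    condition = c(main_conds, cm_conds),
    cell_set = c(rep("tuned", length(main_conds)),
                 rep("tuned_cm", length(cm_conds))),
    n_cells = c(rep(length(set_main), length(main_conds)),
                rep(length(set_cm), length(cm_conds))),
    threshold_db = c(vapply(main_conds, thr_of, numeric(1)),
                     vapply(paste0(cm_conds, ".cmset"), thr_of, numeric(1))))

  pop_sr <- lapply(stats::setNames(conditions, conditions), function(cond)
    condition_population_sr(ana$sr, if (cond %in% main_conds) set_main
                            else set_cm, cond))

  thr_at <- function(cond, set) {
    i <- which(thresholds$condition == cond & thresholds$cell_set == set)
    if (length(i)) thresholds$threshold_db[i[1]] else NA_real_
  }
  contrasts <- data.frame(
    contrast = c("NB_vs_IM", "NB_vs_CM_long", "CM_long_vs_CM_short",
                 "CM_long_vs_CM_long_laser", "CM_short_vs_CM_short_laser"),
    masking_release_db = c(
      masking_release(thr_at("NB", "tuned"), thr_at("IM", "tuned")),
      masking_release(thr_at("NB", "tuned"), thr_at("CM_long", "tuned")),
      masking_release(thr_at("CM_short", "tuned_cm"),
                      thr_at("CM_long", "tuned_cm")),
      masking_release(thr_at("CM_long_laser", "tuned_cm"),
                      thr_at("CM_long", "tuned_cm")),
      masking_release(thr_at("CM_short_laser", "tuned_cm"),
                      thr_at("CM_short", "tuned_cm"))))

  # AFI and its relation to per-cell masking release (NB -> long CM)
  onsets <- onset_count_table(spikes, trials)
  odt <- data.table::dcast(data.table::as.data.table(onsets),
                           cell_id ~ masker_kind, value.var = "mean_count")
  kinds <- setdiff(names(odt), "cell_id")
  afi_df <- data.frame(cell_id = odt$cell_id)
  norm <- t(apply(as.matrix(odt[, ..kinds]), 1, normalize_counts,
                  transform = config$afi_transform))
  colnames(norm) <- kinds
  afi_df$afi_cm <- if (all(c("NB", "CM_long") %in% kinds))
    norm[, "CM_long"] - norm[, "NB"] else NA_real_
  afi_df$afi_im <- if (all(c("NB", "IM") %in% kinds))
    norm[, "IM"] - norm[, "NB"] else NA_real_

  thr_wide <- data.table::dcast(
    data.table::as.data.table(ana$thresholds),
    cell_id ~ condition, value.var = "threshold_db")
  mr_cell <- if (all(c("NB", "CM_long") %in% names(thr_wide)))
    data.frame(cell_id = thr_wide$cell_id,
               mr_cm = thr_wide$NB - thr_wide$CM_long) else NULL
  afi_mr <- NULL
  if (!is.null(mr_cell)) {
    j <- merge(afi_df, mr_cell, by = "cell_id")
    ok <- is.finite(j$afi_cm) & is.finite(j$mr_cm)
    if (sum(ok) >= 6) afi_mr <- afi_mr_relation(j$afi_cm[ok], j$mr_cm[ok])
  }

  report <- structure(list(
    seed = seed,
    config = config,
    n_cells = length(cells),
    cell_sets = list(tuned = tuned, tuned_cm = set_cm, main = set_main),
    cf = data.frame(cell_id = cells, cf_hz = cf),
    thresholds = thresholds,
    contrasts = contrasts,
    population_sr = pop_sr,
    neurometric = neuro,
    cell_thresholds = ana$thresholds,
    sr = ana$sr,
    sigma = ana$sigma,
    afi = afi_df,
    afi_mr = afi_mr,
    responsive = resp,
    battery = NULL
  ), class = "cmr_report")
  if (isTRUE(config$run_battery))
    report$battery <- run_test_battery(report, spikes, trials)
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Standard statistical test battery
#'
#' Applies the field's named off-the-shelf tests (via base R routines) to the
#' comparisons the analysis produces: a Friedman test of per-cell SR across
#' the three masker conditions, pairwise Wilcoxon signed-rank tests, a sign
#' test (exact binomial) on ongoing noise rates CM vs NB, a two-sample K-S
#' test on the AFI distributions, and the Pearson correlation between AFI
#' and masking release.
#'
#' @param report a `cmr_report` (or list with `sr`, `afi`, `cell_thresholds`,
#'   `cell_sets`).
#' @param spikes,trials the underlying tables (for ongoing noise rates).
#' @return data.frame(test, statistic, df, p).
#' @export
run_test_battery <- function(report, spikes = NULL, trials = NULL) {
  rows <- list()
  add <- function(test, statistic, df, p)
    rows[[length(rows) + 1L]] <<- data.frame(
      test = test, statistic = statistic, df = df, p = p)

  sr <- report$sr[report$sr$cell_id %in% report$cell_sets$main, , drop = FALSE]
  have <- intersect(c("NB", "IM", "CM_long"), unique(sr$condition))
  if (length(have) == 3L) {
    per_cell <- aggregate(sr ~ cell_id + condition,
                          data = sr[sr$condition %in% have, ], FUN = mean)
    wide <- data.table::dcast(data.table::as.data.table(per_cell),
                              cell_id ~ condition, value.var = "sr")
    m <- as.matrix(wide[, -1])
    m <- m[stats::complete.cases(m), , drop = FALSE]
    if (nrow(m) >= 3) {
      fr <- friedman.test(m)
      add("friedman_sr_conditions", unname(fr$statistic),
          unname(fr$parameter), fr$p.value)
      prs <- list(c("CM_long", "NB"), c("CM_long", "IM"), c("IM", "NB"))
      for (pr in prs) {
        wt <- suppressWarnings(wilcox.test(m[, pr[1]], m[, pr[2]],
                                           paired = TRUE))
        add(paste0("wilcoxon_", pr[1], "_vs_", pr[2]),
            unname(wt$statistic), NA, wt$p.value)
      }
    }
  }

  if (!is.null(spikes) && !is.null(trials)) {
    nr <- noise_rate_table(spikes, trials)
    w <- data.table::dcast(data.table::as.data.table(nr),
                           cell_id ~ masker_kind, value.var = "rate")
    if (all(c("NB", "CM_long") %in% names(w))) {
      d <- w$CM_long - w$NB
      d <- d[d != 0]
      if (length(d) >= 5) {
        st <- binom.test(sum(d > 0), length(d))
        add("sign_noise_rate_CM_vs_NB", sum(d > 0), length(d), st$p.value)
      }
    }
  }

  a <- report$afi
  if (!is.null(a) && sum(is.finite(a$afi_cm) & is.finite(a$afi_im)) >= 5) {
    ok <- is.finite(a$afi_cm) & is.finite(a$afi_im)
    kt <- suppressWarnings(ks.test(a$afi_cm[ok], a$afi_im[ok]))
    add("ks_afi_CM_vs_IM", unname(kt$statistic), NA, kt$p.value)
  }
  if (!is.null(report$afi_mr)) {
    add("pearson_afi_mr_CM", report$afi_mr$r, report$afi_mr$n - 2,
        report$afi_mr$p)
  }
  do.call(rbind, rows)
}

#' Write a report's tables to disk
#'
#' Delimited-text tables plus one JSON summary; no binary artifacts.
#'
#' @param report a `cmr_report`.
#' @param dir output directory.
#' @return invisibly, the directory.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$thresholds, file.path(dir, "thresholds.csv"),
                   row.names = FALSE)
  utils::write.csv(report$contrasts, file.path(dir, "contrasts.csv"),
                   row.names = FALSE)
  utils::write.csv(report$cell_thresholds,
                   file.path(dir, "cell_thresholds.csv"), row.names = FALSE)
  utils::write.csv(report$sr, file.path(dir, "sr_values.csv"),
                   row.names = FALSE)
  utils::write.csv(report$afi, file.path(dir, "afi.csv"), row.names = FALSE)
  utils::write.csv(report$cf, file.path(dir, "cf.csv"), row.names = FALSE)
  if (!is.null(report$battery))
    utils::write.csv(report$battery, file.path(dir, "battery.csv"),
                     row.names = FALSE)
  summary <- list(
    seed = report$seed,
    n_cells = report$n_cells,
    n_tuned = length(report$cell_sets$tuned),
    thresholds = stats::setNames(
      as.list(report$thresholds$threshold_db),
      paste(report$thresholds$condition, report$thresholds$cell_set,
            sep = ".")),
    contrasts = stats::setNames(as.list(report$contrasts$masking_release_db),
                                report$contrasts$contrast),
    afi_mr_r = report$afi_mr$r %||% NA,
    afi_mr_p = report$afi_mr$p %||% NA)
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(dir)
}

#' @export
print.cmr_report <- function(x, ...) {
  cat("CMR experiment report (seed", x$seed, ")\n")
  cat(sprintf("  cells: %d (%d signal-tuned)\n", x$n_cells,
              length(x$cell_sets$tuned)))
  cat("  neurometric thresholds (dB SNR):\n")
  for (i in seq_len(nrow(x$thresholds)))
    cat(sprintf("    %-16s [%s, n=%d] %6.1f\n",
                x$thresholds$condition[i], x$thresholds$cell_set[i],
                x$thresholds$n_cells[i], x$thresholds$threshold_db[i]))
  cat("  masking-release contrasts (dB):\n")
  for (i in seq_len(nrow(x$contrasts)))
    cat(sprintf("    %-26s %6.1f\n", x$contrasts$contrast[i],
                x$contrasts$masking_release_db[i]))
  if (!is.null(x$afi_mr))
    cat(sprintf("  AFI ~ masking release: r = %.3f (p = %.3g, n = %d)\n",
                x$afi_mr$r, x$afi_mr$p, x$afi_mr$n))
  invisible(x)
}
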
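# Frequency response areas: tone-evoked rate matrix, 3x3 pyramidal
# smoothing, dual-criterion (30% / 15%) region extraction and
# characteristic-frequency assignment.

#' Compute a frequency response area matrix
#'
#' Mean evoked rate in the tone window (0--0.5 s of tone time) for every
#' (frequency, level) grid point, plus the cell's baseline rate from the
#' pre-tone window pooled over all FRA trials.
#'
#' @param spikes,trials spike and trial tables.
#' @param cell_id cell to map.
#' @param grid an `fra_grid` (defaults to [build_fra_grid()]).
#' @return object of class `fra`: list(rates [freq x level matrix], freqs,
#'   levels, baseline_rate, cell_id).
#' @export
compute_fra <- function(spikes, trials, cell_id, grid = build_fra_grid()) {
  tl <- cmr_timeline()
  tone_win <- c(tl$fra_tone_on_s, tl$fra_tone_on_s + tl$fra_tone_s)
  fra_trials <- trials[!is.na(trials$fra_freq_hz), , drop = FALSE]
  if (!nrow(fra_trials)) stop("no FRA trials in the trial table")
  # map each trial onto the grid (tolerant float matching)
  fi <- vapply(fra_trials$fra_freq_hz, function(f)
    which.min(abs(log2(grid$freqs / f))), integer(1))
  li <- match(fra_trials$fra_level_db, grid$levels)
  if (anyNA(li)) stop("FRA trials with levels off the grid")
  have <- unique(cbind(fi, li))
  need <- expand.grid(f = seq_along(grid$freqs), l = seq_along(grid$levels))
  missing <- !paste(need$f, need$l) %in% paste(have[, 1], have[, 2])
  if (any(missing))
    stop(sprintf("missing FRA grid point(s): %s",
                 paste(utils::head(sprintf("%.0f Hz/%g dB",
                                           grid$freqs[need$f[missing]],
                                           grid$levels[need$l[missing]]), 5),
                       collapse = "; ")))
  st <- spikes[spikes$cell_id == cell_id &
                 spikes$trial_id %in% fra_trials$trial_id, , drop = FALSE]
  ti <- match(st$trial_id, fra_trials$trial_id)
  in_tone <- st$spike_time_s >= tone_win[1] & st$spike_time_s < tone_win[2]
  rates <- matrix(0, length(grid$freqs), length(grid$levels),
                  dimnames = list(signif(grid$freqs, 6), grid$levels))
  ntr <- matrix(0L, length(grid$freqs), length(grid$levels))
  for (k in seq_len(nrow(fra_trials)))
    ntr[fi[k], li[k]] <- ntr[fi[k], li[k]] + 1L
  if (any(in_tone)) {
    idx <- cbind(fi[ti[in_tone]], li[ti[in_tone]])
    for (r in seq_len(nrow(idx)))
      rates[idx[r, 1], idx[r, 2]] <- rates[idx[r, 1], idx[r, 2]] + 1
  }
  rates <- rates / (ntr * diff(tone_win))
  pre <- st$spike_time_s < tl$fra_tone_on_s
  baseline <- sum(pre) / (nrow(fra_trials) * tl$fra_tone_on_s)
  structure(list(rates = rates, freqs = grid$freqs, levels = grid$levels,
                 baseline_rate = baseline, cell_id = cell_id),
            class = "fra")
}

#' Smooth an FRA with a 3x3 pyramidal window
#'
#' Convolution with the kernel `[1 2 1; 2 4 2; 1 2 1] / 16`; at matrix edges
#' the kernel is renormalised over in-bounds cells so a constant matrix is
#' unchanged everywhere.
#'
#' @param m an `fra` object or plain numeric matrix.
#' @return same type as the input, smoothed.
#' @export
smooth_pyramidal <- function(m) {
  x <- if (inherits(m, "fra")) m$rates else m
  kern <- matrix(c(1, 2, 1, 2, 4, 2, 1, 2, 1), 3, 3)
  nr <- nrow(x); nc <- ncol(x)
  out <- matrix(0, nr, nc, dimnames = dimnames(x))
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    ii <- max(1, i - 1):min(nr, i + 1)
    jj <- max(1, j - 1):min(nc, j + 1)
    w <- kern[ii - i + 2, jj - j + 2, drop = FALSE]
    out[i, j] <- sum(x[ii, jj, drop = FALSE] * w) / sum(w)
  }
  if (inherits(m, "fra")) { m$rates <- out; m } else out
}

# 4-connected component labelling of a logical matrix; 0 = background.
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  idx <- which(mask)
  for (s in idx) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    stack <- s
    while (length(stack)) {
      p <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (lab[p] != 0L) next
      lab[p] <- cur
      i <- (p - 1L) %% nr + 1L; j <- (p - 1L) %/% nr + 1L
      for (q in c(if (i > 1L) p - 1L, if (i < nr) p + 1L,
                  if (j > 1L) p - nr, if (j < nc) p + nr))
        if (mask[q] && lab[q] == 0L) stack <- c(stack, q)
    }
  }
  lab
}

#' Extract response regions from a smoothed FRA
#'
#' Excitatory cells pass the strong criterion at `rate >= baseline * 1.30`
#' and the weak one at `baseline * 1.15`; inhibitory regions use
#' `baseline * 0.70` / `0.85` and are processed separately. Strong-criterion
#' cells form 4-connected components; components whose members are connected
#' through same-polarity weak-criterion cells are merged into a single region
#' (region membership remains the strong-criterion cells — weak cells only
#' bridge). When `baseline_rate` is 0, relative criteria are meaningless and
#' an absolute floor (default 1 spike/s strong, half that weak) is used for
#' excitatory regions; inhibitory regions are then undefined.
#'
#' @param m a smoothed `fra` object.
#' @param floor_rate absolute strong criterion (spikes/s) used when the
#'   baseline is zero.
#' @return list of regions; each is a list(polarity, cells [matrix of
#'   (freq_index, level_index) rows], size).
#' @export
find_regions <- function(m, floor_rate = 1) {
  stopifnot(inherits(m, "fra"))
  x <- m$rates; b <- m$baseline_rate
  regions <- list()
  grab <- function(strong, weak, polarity) {
    lab <- label_components(weak)
    out <- list()
    for (cc in setdiff(unique(as.vector(lab)), 0L)) {
      members <- which(lab == cc & strong, arr.ind = TRUE)
      if (!nrow(members)) next  # weak-only blob: not a defined region
      out[[length(out) + 1L]] <- list(
        polarity = polarity,
        cells = unname(members),
        size = nrow(members))
    }
    out
  }
  if (b > 0) {
    regions <- c(regions, grab(x >= b * 1.30, x >= b * 1.15, "excitatory"))
    regions <- c(regions, grab(x <= b * 0.70, x <= b * 0.85, "inhibitory"))
  } else {
    regions <- c(regions, grab(x >= floor_rate, x >= floor_rate / 2,
                               "excitatory"))
  }
  regions
}

#' Characteristic frequency from FRA regions
#'
#' The largest excitatory region (by member count) is always used. CF is the
#' frequency of the region member at the lowest sound level; ties at the
#' lowest level are broken by the member with the highest smoothed rate.
#'
#' @param regions output of [find_regions()].
#' @param m the smoothed `fra` the regions came from.
#' @return list(cf, threshold_level, region), or NULL when the cell has no
#'   excitatory region (CF undefined; cell excluded from CF-based analyses).
#' @export
characteristic_frequency <- function(regions, m) {
  stopifnot(inherits(m, "fra"))
  exc <- Filter(function(r) r$polarity == "excitatory", regions)
  if (!length(exc)) return(NULL)
  sizes <- vapply(exc, `[[`, numeric(1), "size")
  reg <- exc[[which.max(sizes)]]
  lev <- reg$cells[, 2]
  lo <- min(lev)
  tips <- reg$cells[lev == lo, , drop = FALSE]
  if (nrow(tips) > 1L) {
    rates <- m$rates[tips]
    tips <- tips[which.max(rates), , drop = FALSE]
  }
  list(cf = m$freqs[tips[1, 1]],
       threshold_level = m$levels[lo],
       region = reg)
}
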
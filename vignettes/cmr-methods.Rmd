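---
title: "Methods: models, statistics and design decisions in cmrtools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, statistics and design decisions in cmrtools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Scope

`cmrtools` reimplements, as a tested pipeline, the analysis of across-channel
comodulation masking release (CMR) in primary auditory cortex: stimulus
modelling, synthetic spike-train generation with planted condition effects,
and the bespoke statistics of the analysis chain (pooled-SD signal-response
statistic, vote-based neurometric thresholds, dual-criterion frequency
response areas, onset-interaction metrics, bootstrap screening). The original
recordings behind this analysis style are not public; the synthetic
population exists so that every statistic can be validated by *parameter
recovery* — plant an effect, run the full pipeline, and check that the
effect comes back out.

# Stimulus model

## Timeline

All analyses use a trial-aligned clock with a 0.5 s silent baseline. The
published analysis windows (e.g. the first-pip average over 1.175–1.275 s)
exceed a 1.0 s stimulus counted from sound onset; anchoring stimulus time 0
at trial time 0.5 s reconciles them exactly: precursor 0.5–0.9 s, gap
0.9–1.0 s, masker portion 1.0–1.5 s, so the first 50 ms pip occupies
1.175–1.225 s inside its 1.175–1.275 s analysis window. The short-CM masker
omits precursor and gap but its masker portion is aligned to the same
1.0–1.5 s interval so that every analysis window is condition-invariant.

## Envelopes and troughs

SAM envelopes are raised cosines `0.5 * (1 - cos(2*pi*10*t' + phi))` with
`t'` measured from the onset of the containing segment, i.e. every segment
starts at an envelope minimum. Counting that onset minimum as trough 1, the
3rd–5th troughs of the masker portion fall at +200/300/400 ms, which places
the three pips at 1.175/1.275/1.375 s — consistent with the published
first-pip window. Pips are positive half-cycles of the 10 Hz modulator
(half-sine over 50 ms), "filling" their trough. Comodulated flankers share
the on-frequency phase exactly; incoherent flanker phases are fresh uniform
draws on [0°, 180°) at masker construction (the alternative — freezing
phases once per stimulus file — is not distinguishable from the published
description; per-construction draws are the more conservative choice for
the analyses, which never assume IM phase).

## Frequencies

The printed band layout (25 tone frequencies spanning 7–57 kHz, flanker
triplets at 12.9 and 30.8 kHz) is inconsistent with the printed 0.25-octave
spacing; a 0.125-octave grid centred on 20 kHz reproduces every printed
number (7.07–56.6 kHz span; 20 and 21.8 kHz grid points; flanker centres
20·2^(−5/8) ≈ 12.9 kHz and 20·2^(5/8) ≈ 30.8 kHz), so that grid is used
for both the FRA battery and the flanking bands (components at ±1 grid step
around each flanker centre). The signal-tuned band "15–23 kHz" is applied
literally in Hz; on the CF grid it selects 15.4–21.8 kHz.

# The generative model

The model is the simplest rate model we found that reproduces, through the
*fixed* analysis chain, every planted analysis-level phenomenon: SR growth
with SNR, condition-ordered thresholds, priming and silencing shifts, onset
facilitation/suppression, and the onset–masking-release coupling. Per cell:

* **Spontaneous rate**: log-normal across cells (median 5 spikes/s,
  sdlog 0.5).
* **Tuning**: Gaussian in log-frequency, SD `tuning_bw` (0.3 octave
  median). `W` denotes the summed tuning weight over the masker bands and
  `w20` the weight at the 20 kHz signal.
* **Onset transient**: exponential decay (τ = 25 ms) over the first 75 ms
  of noise, amplitude `onset_gain × W` (median 20 spikes/s), with
  per-condition onset gains carrying the AFI structure (below).
* **Sustained noise response**: builds up from each segment onset with a
  300 ms time constant (the slow adaptation to masker statistics that the
  priming manipulations probe) and saturates with bandwidth through
  divisive normalization, `sustained_gain × W / (1 + 2 W)`. Envelope
  locking of the sustained response is available (`lock_envelope`) but off
  by default — locking is characteristic of within-channel, not
  across-channel, configurations.
* **Signal**: a multiplicative gain on the ongoing rate during the pip
  window, `rate × (1 + signal_rel_gain × w20 × logistic((SNR − thr)/slope))`
  with per-condition planted thresholds `thr` and slope 1 dB. By default
  only the first pip is driven (most cortical cells respond to the first
  pip only); `pips_responding = 3` drives the whole train.
* **Silencing**: during 0.5–0.65 s (the first 150 ms of the precursor) the
  whole rate is multiplied by `laser_gain` — 0.1 for the 90 % of cells
  labelled PV− (suppressed principal cells), 4 for PV+ cells (the directly
  driven interneurons). The suppression depth is a free parameter; no
  quantitative depth is published.
* **Spikes**: inhomogeneous Poisson. The intensity is held
  piecewise-constant on a 1 ms grid; trials sharing a stimulus are drawn
  jointly (Poisson superposition), which is exact and fast.

## Planted thresholds: equal spreads

Per-cell thresholds are `population mean + u + v_cond`, with `u` a common
sensitivity jitter (SD 1 dB) and `v_cond` an iid per-condition jitter of
**equal SD (1.8 dB) in every condition**; orderings
(`CM_long < IM ≤ NB`, `CM_short > CM_long`, `CM_long_laser > CM_long`) are
enforced by one-sided clamps, and a planted effect of exactly 0 copies the
reference threshold. Equal marginal spreads are load-bearing: the
population neurometric crossing sits at a fixed lower-tail quantile of the
per-cell threshold distribution, so conditions with unequal spreads would
have their recovered thresholds biased by different amounts and pairwise
differences would not recover. The per-cell masking release
(`thr_NB − thr_CM_long`) then has SD `1.8·√2 ≈ 2.5` dB — the substrate of
the AFI–masking-release association.

## Onset gains and the AFI coupling

Broadband onset gains are
`onset_gain × exp(boost + afi_coupling · z − near_cf_suppression · w20)`,
where `z` is the cell's standardized planted CM release and the boosts are
+0.10 (IM) and +0.05 (CM) on the log scale. With the default
`afi_coupling = −1`, cells with above-average planted release have
suppressed comodulated onsets (negative AFI), yielding a negative
AFI–masking-release correlation through the full measurement chain; the
near-CF term reproduces the negative AFI dip around the signal frequency.
With `afi_coupling = 0` the recovered correlation is small; a residual
positive channel (+0.05–0.08) remains because spectral-integration breadth
mildly affects both onset counts and measured thresholds — divisive
normalization of the sustained drive keeps it below significance.

# Why the signal is a gain, not an increment

The specification sketch suggested an additive signal term. The detection
vote, however, is *relative* (±25 % of the condition's own noise-alone
rate), and broadband maskers drive more background than NB; an additive
increment of fixed size therefore crosses the ±25 % criterion at
condition-dependent SNRs, which provably biases recovered condition
differences (we observed IM recovering *above* NB with planted IM < NB). A
response gain proportional to the ongoing rate — i.e. cortical
multiplicative gain modulation — makes the relative-rate analyses recover
planted thresholds with a condition-independent offset. This is the one
deliberate deviation from the specification's model sketch, which itself
designates the generative model as an open design choice.

# Calibration of the simulated world

The ±25 % vote is statistically delicate: with 30 trials and a 100 ms
window, Poisson count noise makes null votes both yes-biased (a 25 %
increase is a smaller log step than a 25 % decrease) and high-variance
whenever expected window counts sit between roughly 3 and 70 spikes. In
that regime the population proportion-correct hovers near the exact
binomial significance boundary at n = 500 cells (0.5548) and produces
spurious low-SNR threshold crossings. Two stable regimes exist: nearly
silent windows (≤ 1 expected spike) and strongly driven windows (≥ 120
expected spikes, where the ±25 % dead zone swallows the count noise). The
recovery battery uses the driven regime — masker-driven rates of ~40–80
spikes/s in the analysis window, which is also the regime in which the
published analyses operate (their maskers visibly drive the recorded
cells). This choice was made by analysing the null calibration of the vote
statistic, not by tuning toward any particular recovered number; the
sparse regime recovers orderings too but with occasional spurious
crossings that violate the 95 %-of-replicates requirement.

# Numerical and statistical choices

* **σ** uses the population (divide-by-n) SD over the pooled multiset of
  all 5 ms PSTH bins of the cell (all masking conditions and SNRs, FRA
  excluded). Zero-variance cells have undefined σ and are excluded, not
  imputed.
* **Upsampling** of SR/SNR and neurometric functions is linear onto a
  0.1 dB grid; thresholds are the *first* (lowest-SNR) criterion crossing,
  retained even if the function later re-crosses.
* **Bootstrap screen**: pooled-null difference of bootstrap means (a mean
  of size |A| and of size |B| drawn from the pooled trials, differenced;
  500 resamples; significant when the observed increase exceeds the 0.95
  point). The naive alternative — comparing the observed mean of B to
  bootstrap means of the pool — is intrinsically conservative (~1 %
  type-I) because the observed mean deviates from the pool mean by only
  half the group difference; the difference form calibrates at 4–6 %.
* **Votes**: ties at exactly ±25 % count as detection/rejection
  respectively (inclusive inequalities); a zero noise rate with a positive
  signal rate is an infinite relative increase (vote 1); two zeros are
  chance. Fractional votes enter the binomial test through rounding of
  `proportion × n_cells` to the nearest success count.
* **Bonferroni m = 7** (the measured SNRs), not the upsampled grid size:
  corrections over interpolated points would be degenerate.
* **FRA regions**: 4-connectivity; relative criteria `baseline × 1.30` /
  `× 1.15` (excitatory) and `× 0.70` / `× 0.85` (inhibitory, stored but
  unused downstream); weak-criterion cells only *bridge* strong-criterion
  regions, they are not members. A zero baseline falls back to an absolute
  floor (1 spike/s, half for bridging). Smoothing renormalises the 3 × 3
  pyramidal kernel over in-bounds cells at matrix edges.
* **CF ties** at the lowest responsive level break toward the higher
  smoothed rate.
* **AFI** uses the literal exponential transform, computed in the shifted
  form `exp(c − max c)`; `afi_transform = "log"` / `"identity"` are
  provided for sensitivity analysis only. The normalization maximum is
  taken over the masker conditions' onset counts for that cell. AFI–MR
  binning uses 6 equal-count bins (a 5-df one-way ANOVA).
* **Determinism**: one master seed fans out to per-stage substreams
  (population, schedule, spiking, bootstraps); every randomized helper
  restores the caller's RNG state.

# What a green recovery test does and does not establish

The generator emulates: log-normal rate distributions, frequency tuning,
SNR-dependent signal responses with condition-ordered thresholds, priming
and silencing effects, onset facilitation/suppression coupled to masking
release, and Poisson spiking. It does **not** emulate: non-Poisson
variability (bursting, refractoriness), correlated noise across cells or
trials, envelope locking (off by default), spike-sorting artefacts, or
electrode sampling biases. A green parameter-recovery criterion therefore
establishes that the analysis chain is a faithful estimator *within this
world*, not that the published biological effect sizes are correct.

# Known limitations

* Absolute neurometric thresholds carry a systematic negative offset (the
  exact-binomial criterion fires at the foot of the proportion-correct
  rise, and the vote criterion fires below the planted logistic midpoint);
  only threshold *differences* between conditions are bias-free and only
  they are asserted in the acceptance battery.
* Per-cell 0.5 SD thresholds are noisy at 30 trials (SD of a few dB);
  analyses built on them (per-cell masking release, AFI relations) are
  attenuated accordingly, which the planted coupling strength accounts
  for.
* The CF extractor is reliable for well-driven cells with CFs away from
  the edges of the 25-frequency grid; edge CFs are truncated-V cases and
  may land one or two grid steps inward.
* The zero-coupling null of the AFI–masking-release test is asserted over
  three seeded replicates (mean |r| < 0.1, ≥ 2/3 nonsignificant) because a
  single Pearson test is nonsignificant only with probability 1 − α under
  its own null.
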
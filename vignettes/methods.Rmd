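---
title: "Methods: spike-timing reliability, adaptation, and time warping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spike-timing reliability, adaptation, and time warping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spikereliability)
```

This vignette documents the models and estimators the package implements,
the assumptions behind the synthetic generator, and the numerical and design
choices that were genuinely open, with the reasoning for each.

## Experimental structure assumed

All analyses operate on *spike-train sets*: one unit, one stimulus series of
(canonically) 60 renditions of a 4-syllable ABAB sequence presented at one
per second, with per-rendition syllable boundaries. Time is in seconds,
sequence-relative, `t = 0` at sequence onset; the 200 ms epoch `[-0.2, 0)`
before each sequence is the spontaneous baseline. Renditions group into 6
blocks of 10 consecutive trials. Two regimes are distinguished: `Same`
(identical renditions) and `Var` (naturally varying renditions; in the
generator, per-rendition syllable-duration jitter and within-syllable
timing jitter).

## Response strength and adaptation

Per trial, `RS = (E_FR - B_FR) / (E_FR + B_FR)`, where `E_FR` is the rate
over that rendition's own sequence span (onset of syllable 1 to offset of
syllable 4 — renditions of a Var series have different spans) and `B_FR`
the baseline rate. All spike counting uses half-open windows `[t0, t1)` so
a spike on a shared boundary is counted once.

Two choices were open:

* **Degenerate trials.** When `E_FR = B_FR = 0`, RS is 0/0. We flag the
  trial undefined (`NA`) and exclude it from means rather than imputing 0,
  mirroring the practice of excluding a unit that never fires rather than
  letting silence masquerade as "no response preference". A block is flagged
  invalid when more than half its trials are undefined.
* **Block RS.** Whether a block's RS is the mean of its trial RS values or
  the RS of pooled counts is not fixed by the definitions. The default is
  the mean of defined trial values (flag-friendly, one value per trial
  feeds the flagging rule); `block_rs(..., method = "pooled")` provides the
  pooled-count alternative, which is less noisy for sparse units because
  the baseline count over a single 200 ms epoch is tiny (at 5 Hz, 1 spike
  on average, so trial-level RS is extremely coarse).

The **adaptation rate** is the OLS slope of `E_FR` against trial index over
renditions 1–10 (`stats::lm`; the tests verify it against the closed-form
normal equations at 1e-12). A fit is flagged invalid when the unit fired no
spike during trial 1, and invalid fits are excluded from population
summaries.

## CorrCoef: spike-timing reliability

Each train is convolved with a unit-area Gaussian kernel centred at each
spike and sampled on a uniform 1 ms grid over the evoked window (baseline
excluded); kernels are truncated at window edges without renormalization,
so a trace's trapezoidal integral approximates its spike count up to edge
losses. CorrCoef is the mean Pearson correlation over all unordered pairs
of traces.

Open points and how they were settled:

* **"Width" of the Gaussian.** Interpreted as the standard deviation
  $\sigma$ (the common convention for Gaussian spike-density kernels);
  `width_type = "fwhm"` is exposed because the alternative reading exists.
  All defaults use $\sigma$ = 10 ms.
* **Normalization.** A printed normalization of `1/(N(N-1))` over the
  `i<j` double sum would make ten identical trains score 0.5. We use the
  mean over unordered pairs, `2/(N(N-1)) * sum_{i<j} r_ij`, so perfect
  reliability scores 1 — this is what "mean of the Pearson correlation
  coefficients" describes, and what makes values comparable across N.
* **Zero-variance traces.** An empty train gives a constant trace whose
  Pearson correlation is undefined. Such pairs are excluded rather than
  scored 0 (scoring 0 would bias sparse units toward 0 reliability); a set
  whose pairs are all excluded is flagged undefined.
* **Common grid for Var series.** Renditions differ in span, so pairwise
  comparison needs one window; we use `[0, max offset over renditions)`.
  The tail beyond a short rendition's own offset contains baseline-driven
  activity only.

The **block-pair matrix** summarizes reliability across the session:
diagonal entries average the 45 within-block pairs, off-diagonal entries
the 100 cross-block pairs; the matrix is symmetric by construction and the
tests verify it against an independent brute-force double loop.

The **permutation null** redraws each train's spike times uniformly over
the evoked window, preserving counts, and recomputes CorrCoef per draw.
Whether the original procedure preserved inter-spike intervals is not
determinable from its description ("random permutation of the time" of
spikes); uniform redraw is the default and an ISI-shuffling variant
(`method = "isi_shuffle"`) is provided.

The **kernel-width sweep** recomputes per-unit CorrCoef at widths from 1 to
200 ms for both regimes plus the permuted reference, and tests the paired
Same−Var difference at each width with a sign-flip permutation test across
units (the unit is the experimental replicate). A linear mixed model per
width is the classical alternative; the sign-flip test was chosen because
it is exact under the symmetric-null assumption, assumption-light, and
keeps the package free of model-fitting machinery that belongs to the
downstream analysis. The `crossover_width_ms` is the smallest tested width
at which the difference is no longer significant at `alpha` (default 0.05).

## Linear time warping

Per rendition, each syllable interval is mapped affinely onto its label's
reference duration and each inter-syllable gap onto that gap position's
reference duration; segments are contiguous and strictly increasing, so
the map is invertible (round-trip identity is tested at 1e-9 s). Spikes
outside the covered span are mapped by the nearest segment's affine
extension. Gap handling is a package choice: warping only syllables would
leave the map discontinuous in the gaps, so gaps get their own linear
segments.

The reference duration is the per-label **maximum** across renditions and
positions by default (`ref_stat = "max"`), with `"mean"` as an option.
Two subtleties found while validating the estimator are worth recording:

* Warping to the maximum duration stretches every rendition, lowering the
  peak rate relative to the fixed 10 ms kernel and thus the
  signal-to-Poisson-noise ratio of the traces. In simulations with
  duration-only variability this depresses the post-warp CorrCoef by a
  fifth to a quarter relative to a zero-variability control *even though
  alignment is perfect* — a timescale artifact of the reference choice,
  not residual misalignment. Recovery comparisons against a
  zero-variability ceiling therefore use `ref_stat = "mean"`, which
  preserves the average timescale; the max reference remains the default
  for descriptive use because it never compresses a syllable.
* For the warp to be able to recover reliability at all, response timing
  must follow the stimulus timescale. The generator therefore time-rescales
  each syllable's rate profile with the realized syllable duration
  (integral preserved). If responses were instead locked to absolute time
  after syllable onset, warping would distort rather than align them; that
  regime can be explored by setting duration jitter to zero and supplying
  external boundaries.

`warped_reliability()` reports the between-block pooled CorrCoef (mean of
off-diagonal block-pair entries) before and after warping.

## AB-pair context analysis

Pair 1 is `[onset A1, offset B1)`, pair 2 `[onset A2, offset B2)`. RS per
pair uses the shared per-sequence baseline. For across-trial CorrCoef per
pair and the within-trial pair-1 vs pair-2 correlation, windows are
re-referenced to their own onsets and compared on the overlap of the two
lengths (truncating to the shorter; Var windows differ in length). The
alignment convention is a package choice — nothing in the source
definitions fixes it — and truncation was preferred to zero-padding
because padding manufactures a shared silent segment that inflates r.

`feature_regression()` fits one OLS per acoustic covariate (similarity,
entropy difference, pitch difference, duration difference) against a
reliability measure, reporting slope, r², and the slope t-test p-value;
zero-variance covariates are flagged, not fit. The synthetic covariates
from `synthesize_features()` are drawn independently of the spike trains
(similarity centred at 96.3% with SD 3.6, capped at 100) — *except*
duration difference, which is taken from the actual renditions and is
therefore genuinely coupled to pairwise reliability in the generator;
null-calibration checks use the independent covariates only.

## The synthetic generator

`simulate_series()` draws spikes from an inhomogeneous Poisson process by
Lewis–Shedler thinning. The rate on trial *k* is

`baseline + gain(k) * sum over syllables of profile(t - onset)`,

with `gain(k) = g_inf + (1 - g_inf) exp(-(k - 1)/tau)` (first trial gain 1,
e-folding `tau` trials, asymptote `g_inf`) emulating repetition adaptation.
Syllable profiles are onset bumps (silent until `latency`, exponential
decay from `amplitude`), truncated at the syllable offset and time-rescaled
with the realized duration.

Defaults and why:

| parameter | default | rationale |
|---|---|---|
| syllable durations A/B | 120 / 160 ms | inside the 57–235 ms range of zebra-finch song syllables; ABAB span ≈ 0.68 s |
| inter-syllable gap | 40 ms | middle of the 30–50 ms silent intervals typical of motifs |
| renditions / rate | 60 at 1 per s | the series structure of the emulated playback design |
| duration jitter (Var) | lognormal, CV 0.1 | lognormal guarantees positivity; CV ~10% is a plausible within-type natural variation |
| timing jitter (Var) | Gaussian, SD 10 ms, per syllable | places the Var/Same reliability difference at the 10 ms analysis scale, as observed in the emulated system |
| profile amplitude | 60 Hz peak | a moderately responsive unit; onset peaks well above the 5 Hz baseline |
| baseline rate | 5 Hz | typical spontaneous rate for secondary auditory neurons |

Each set runs on one RNG stream derived from the configured seed and a
stream label, so any unit/series regenerates independently and the full
pipeline is byte-reproducible.

What the generator does **not** emulate: non-Poisson spiking statistics
(bursting, refractoriness beyond the optional dead time), spectrotemporal
tuning (syllables drive a fixed profile, not an acoustic filter),
correlated variability across units, and any true acoustic feature →
response mapping (covariates are synthesized). Passing tests therefore
demonstrate correctness of the estimators and the qualitative phenomena
(jitter sensitivity, width dependence, warp recovery, adaptation), not
quantitative agreement with any particular recording.

## Numerical choices

* Grid step 1 ms everywhere (configurable); Pearson at zero lag on the
  gridded traces.
* Kernel widths are validated to `[1, 200]` ms.
* Boundary detection (`detect_boundaries()`): sliding RMS window 5 ms,
  threshold as a fraction of peak RMS (default 0.5), minimum syllable
  duration 20 ms — all configurable, since the original thresholds are
  unreported.
* Duration-jitter draws that produce non-positive durations are resampled
  with bounded retries (10), then error.
* Spike tables are written at 1e-6 s resolution; round trips are lossless
  at that precision.
* Seeds derived for substreams stay below 2^31.

## Simulation sizes used by the test suite

The property and acceptance tests use problem sizes chosen to keep the
Monte-Carlo error comfortably below the asserted effects: 20 seeds per
condition for seed-averaged monotonicity checks, 30 units for the paired
regime comparison, 50 seeds for adaptation recovery, 200 permutation draws
for null centering, and 500 simulations for the type-I calibration of the
feature regression (binomial 99% CI around 5%). The adaptation-recovery
simulation uses a strongly responsive onset unit (peak 250 Hz, decay
50 ms, baseline 2 Hz): an a-priori power calculation shows that with
weaker responses the OLS slope over 10 Poisson trials has a standard error
comparable to the slope itself, so per-seed sign recovery would be
dominated by noise rather than by the estimator under test.

## Known limitations

* CorrCoef values depend on the analysis window through the shared-silence
  effect: windows containing long common silent stretches inflate r. The
  package crops to the evoked window to limit this, but cross-study
  comparisons still require identical windows and widths.
* The sign-flip test assumes symmetric unit-level differences under the
  null; for strongly skewed populations a mixed-model analysis on the
  exported tidy tables is the better instrument.
* The `Same` regime's CorrCoef-vs-width curve need not be monotone in
  simulations (smoothing removes signal structure faster than Poisson
  noise at intermediate widths); monotonicity assertions apply to the
  jittered regime.
* Warping assumes boundaries are correct; boundary-detection error
  propagates directly into the maps and is not modelled.
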
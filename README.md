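# spikereliability

Trial-to-trial spike-timing reliability analysis for trial-structured
auditory responses.

## The problem

High-order auditory neurons — the motivating case is the songbird
caudomedial nidopallium (NCM) responding to played-back song — are probed
with series of 60 renditions of a short syllable sequence (ABAB, ~0.7 s,
one rendition per second). Two regimes matter: **Same** series repeat one
identical sequence 60 times, while **Var** series present 60 naturally
varying exemplars of the sequence, so syllable durations and fine acoustic
structure differ from rendition to rendition. The scientific questions are
(i) whether such natural variation changes the *strength* of responses,
(ii) whether it changes the *temporal reliability* of spike trains across
trials, (iii) at what timescale any reliability difference lives, and
(iv) how much of it is explained by syllable-duration variability alone.

This package implements the full analysis chain for these questions, plus a
synthetic generator of trial-structured spike trains (the original
recordings are not publicly released), so every method is testable against
data whose ground truth is known.

## The statistics

**Response strength.** With evoked rate $E_{FR}$ over the sequence and
baseline rate $B_{FR}$ over the 200 ms pre-stimulus epoch,

$$RS = \frac{E_{FR} - B_{FR}}{E_{FR} + B_{FR}} \in [-1, 1],$$

computed per trial and per block of 10 consecutive trials (6 blocks per
series). The **adaptation rate** is the OLS slope of $E_{FR}$ over the first
10 renditions; a negative slope is stimulus-specific adaptation.

**Spike-timing reliability (CorrCoef).** Each trial's spike train is
convolved with a unit-area Gaussian kernel (width $\sigma$, default 10 ms;
sweepable from 1 to 200 ms) and sampled on a 1 ms grid. For $N$ trials the
reliability is the mean Pearson correlation over all unordered pairs of
convolved traces,

$$\mathrm{CorrCoef} = \frac{2}{N(N-1)} \sum_{i<j} r(x_i, x_j),$$

so identical trains score 1 and the index is insensitive to overall
firing-rate changes. Block-pair matrices (within-block: 45 pairs;
between-block: 100 cross pairs), a spike-count-preserving permutation null
(spike times redrawn uniformly over the evoked window), a kernel-width
sweep with a paired sign-flip permutation test across units, **linear time
warping** of each syllable onto a per-label reference duration, and the
within-sequence **AB-pair context analysis** complete the chain.

## Worked example

```r
library(spikereliability)

spec <- series_spec("Var", seed = 42)            # 60 varying renditions, 1/s
set  <- simulate_series(spec, adapt = adaptation_model(g_inf = 0.6, tau = 4,
                                                       baseline_rate = 5))
set
#> <spike_train_set> unit unit1, series Var: 60 trials, 606 spikes
#>   evoked window [0, 0.735) s; 4 annotated syllables/trial

block_rs(set)
#> # A tibble: 6 x 6
#>   unit_id series block n_defined    rs valid
#> 1 unit1   Var        1        10 0.644 TRUE
#> 2 unit1   Var        2        10 0.514 TRUE
#> 3 unit1   Var        3        10 0.518 TRUE
#> ...

set_corrcoef(set, width_ms = 10)                  # 0.067
mean(permuted_null(set, 10, n_draws = 100, seed = 1))   # 0.0017

warped_reliability(set, 10)
#> # A tibble: 1 x 5
#>   unit_id series width_ms corrcoef_before corrcoef_after
#> 1 unit1   Var          10          0.0691         0.0622
```

The block RS falls from 0.64 (block 1) to ~0.51 afterwards: the simulated
repetition adaptation (`g_inf = 0.6, tau = 4`) reduces the evoked rate over
the first renditions. The CorrCoef of 0.067 at the 10 ms kernel is well
above its permutation null (0.002): even under natural variation the spike
trains keep genuine temporal organization. Warping barely moves the
between-block CorrCoef here because this Var series carries 10 ms
within-syllable timing jitter in addition to duration jitter — duration
variability alone is only a small part of the unreliability.

A full study (many units, both regimes, width sweep, warping, AB pairs,
CSV outputs) runs from one YAML-configurable call:

```r
cfg <- read_run_config(NULL)   # defaults: 20 units, 60 trials, both regimes
run_pipeline(cfg, "outputs/")  # deterministic given cfg$seed
```

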
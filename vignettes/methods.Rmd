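---
title: "Models and methods behind pctouch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pctouch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

pctouch analyses trial-structured spike data recorded while touch is
applied to (or imagined at) different body parts. This vignette explains
the statistical models the package implements, the parameters that matter,
what the synthetic-data generator does and does not emulate, and the
numerical and design choices that were genuinely open.

## The data model

A session holds units (with waveform SNR and isolation metadata), trials
(condition = body part × side × format, with cue, go and optionally
probe-contact event times), and spike events in trial-relative seconds.
All analysis windows are half-open `[start, end)` relative to a named
event, so bin membership is never ambiguous. Unit selection retains units
with session-wide mean rate strictly above 0.5 Hz and SNR strictly above
0.5; "strictly" matters only for units sitting exactly on a threshold and
is tested explicitly.

## Per-unit tuning model

Firing rate in the stimulation window (0.5–2.5 s after go; the 0.5 s
offset absorbs variable experimenter delay) is modelled as

\[ FR = \beta_0 + \sum_c \beta_c X_c \]

with one indicator per condition and all pooled baseline samples
(1.5 s before the cue) carrying zeros. With this design the OLS
coefficients are simply condition means minus the baseline mean, which is
what the closed-form oracle tests assert. A unit is *responsive* to a
condition if the t statistic of its β is significant, and *tuned* if the
overall F test is. Degenerate fits (zero residual variance with zero
effect) return p = 1 rather than NaN; perfect separation returns p = 0.

Two choices were open:

- **FDR family.** All unit × condition t tests of one analysis are pooled
  into a single Benjamini–Hochberg family. This is the most conservative
  reading of "FDR corrected for multiple comparisons" and is applied
  uniformly.
- **χ²(1) construction.** The responsive-fraction test is a
  goodness-of-fit of the observed count of responsive units against the
  α·N expected by chance over the {responsive, not responsive} cells.
  The quantity is reported as an interpretation; other constructions pool
  over conditions and give larger values.

## Decoding

The decoder is linear discriminant analysis under two assumptions: all
conditions share one covariance, and that covariance is diagonal (units
independent). Training therefore reduces to per-condition means plus one
pooled within-condition variance per unit. Zero-variance units receive a
variance floor of 1e-6 Hz² (otherwise the discriminant is degenerate), and
argmax ties break deterministically toward the alphabetically first
condition. Leave-one-out cross-validation iterates trials in stored order,
so results are bit-reproducible; all sorted units are used, never only the
significantly modulated ones (no peeking).

A caution that the calibration tests encode: leave-one-out accuracy on
label-free data is *biased below* chance, because removing a trial leaves
its class under-represented in training. Chance-level checks therefore use
structureless features, where the bias is mild, and test band membership
on the mean.

## Cross-validated population similarity

Each condition's trials are split 50–50 (odd counts send the extra trial
to half A); condition-mean population vectors from independent halves are
correlated for every condition pair, including a condition with itself —
the *noise ceiling* that bounds any between-condition similarity. Splits
are regenerated 250 times (the split mean stabilises well below 100
splits) and the i→j and j→i comparisons are averaged into a symmetric
mean matrix; the per-split samples are kept unsymmetrised.

**Baseline correction matters.** The population vectors must be
baseline-relative: raw rates share each unit's baseline offset across all
conditions, which by itself drives even null-condition self-correlations
to ~0.9. When the baseline matrix covers the same trials, each trial's own
pre-cue rate is subtracted (so the correction is cross-validated along
with the splits); the test suite asserts that null-condition correlations
then scatter about zero.

**Mirror symmetry.** Whether left↔right correlations reach the
within-condition ceiling is tested with a trial-level side-relabelling
permutation: under mirror-symmetric coding the side labels of a body
part's trials are exchangeable, so the permutation is exact. The
alternative — permuting the 250 split-correlation samples — is
pseudo-replicated (the samples are re-splits of the same trials): near a
0.99 ceiling it flags negligible data-level fluctuations and rejects ~86%
of truly symmetric pairs. The split-sample permutation
(`correlation_contrast_test`) remains available and appropriate for
contrasting two genuinely different correlation distributions, as in the
actual-vs-imagined matching-body-part contrasts, and for that use the
pseudo-replication caveat is documented here once: its p-values measure
stability across re-splits, not sampling variability of the data.

## Population response latency

Spike counts are binned at 2 ms (no smoothing) from −150 to +252 ms
around probe contact — 201 bins; the stated −150…250 ms range with 201
bins implies an inclusive endpoint, and the half-open `[−150, 252)`
grid is the documented equivalent. The population time course is the
first principal component of the units × (time·condition·repetition)
matrix (SVD on row-centred counts), with PC1 scores averaged over
conditions and repetitions and the sign oriented so the post-contact mean
exceeds the pre-contact mean. A continuous three-segment piecewise-linear
function (baseline, rise, plateau; slopes unconstrained) is fitted by
exhaustive breakpoint search on a grid of bin positions — full resolution
up to 64 bins, coarsened to ≤ 60 candidates beyond — followed by
Nelder–Mead refinement, so the result is never worse than the best grid
solution. Latency is the earliest time from the baseline start where the
fit exceeds the 95th percentile of the raw baseline values (a scale-aware
1e-8 guard keeps an exactly-flat fit from "crossing" its own threshold).
Population gains around 25 Hz put PC1 firmly above the 2 ms Poisson noise
floor; at a few Hz of gain the first singular vector locks onto noise and
no latency is recoverable at this resolution.

Bootstrap uncertainty resamples the single-trial PC1 traces with
replacement (loadings fixed), re-averages, re-fits and re-estimates;
quartiles of the resulting distribution are reported. Two properties of
this construction should be understood:

- A well-calibrated 25–75% interval covers the true value ~50% of the
  time *by construction* (P(|Z| < 0.674) = 0.50); demanding high IQR
  coverage of a truth is a misreading of what quartile bounds mean. The
  validation suite measures coverage of injected latencies at 25–40%
  (fixed loadings) and ~60% when the PCA is recomputed per resample
  (which adds loading uncertainty); median recovery error is well under
  2 ms for 30–80 ms latencies at 100 units × 8 trials.
- The side-difference permutation test operates on bootstrap samples,
  which are pseudo-replicates; it is therefore over-powered for small
  latency differences and its p-values should be read as descriptive.

## Receptive fields

Field counts tally FDR-significant lateralized sites (back of head,
cheek, neck, shoulder) per side into a 5 × 5 matrix. Peak structure along
four collinear sites walks outward from the preferred site and tests each
adjacent pair one-tailed (pooled-variance t) for a *reversal* — the
farther site significantly exceeding the nearer one, BH-corrected over
the ≤ 3 pair tests. Treating mere non-significance of the expected
decrease as evidence for a second peak would label most units multi-peak
at small n; that stricter reading is available via
`criterion = "nonsignificant_decrease"`. Field size comes from a
three-parameter Gaussian with the centre fixed at the preferred site
(2 cm spacing), fitted by Levenberg–Marquardt with multiple σ starts; σ
enters the model squared, so its absolute value is reported, and
`FWHM = 2√(2 ln 2)·σ`. Flat profiles are flagged, not fitted.

## Temporal dynamics

Sliding 500 ms windows stepped at 100 ms are classified with the same
diagonal LDA, training on each window and testing on all windows under
one leave-one-out partition reused everywhere, so every matrix entry uses
the same amount of training and test data. Per-unit matrices feed a
mean-centred PCA with units as observations.

The crossnobis statistic measures separation from a reference window
(0.25–0.75 s post-cue) as the inner product of two *independent-fold*
mean-difference vectors under a diagonal covariance pooled from
reference-window residuals. Because `E[1/s²] ≠ 1/σ²`, the pooled
variances carry a df/(df−2) inverse-variance correction before the
decoder's variance floor; with that correction the estimator's
expectation is exactly 0 for identical distributions and Σδ² for a known
mean shift δ under unit variances, which the validation suite asserts to
within 3 SE over 100 replicates.

Cross-format correlation stacks, per time window, each unit's
trial-averaged rates for the two body sites into a (2N) × 2 matrix
(columns = actual, imagery) for a train and a test half. Each unit's mean
over its two site entries is subtracted within each column before
correlating, so the correlations reflect *site-preference patterns*; a
scalar global-mean subtraction alone would leave per-unit rate offsets
shared across formats, and those offsets — not pattern similarity — would
then dominate every entry. The two cross-format directions are averaged
into a single actual↔imagery matrix.

## The synthetic generator

Units are inhomogeneous Poisson processes,
`λ(t) = b + G · r(t − onset − L)`, with `r` a linear 0→1 ramp of duration
`ramp_rise` sustained through the stimulation epoch; spikes are drawn by
thinning. `G` is the actual-touch gain of the touched site (zero for the
insensate hands and the null condition), the imagery gain after the go
beep of imagery trials, or the cue-epoch gain during their cue-delay; on
probe tasks the onset anchors to the recorded contact time (go +
uniform 0–0.3 s experimenter delay).

Key defaults, chosen once as a realistic operating regime:

| parameter | default | meaning |
|---|---|---|
| `n_units` | 100 | units per session (matches ~100/session recordings) |
| `tuned_fraction` | 0.66 | fraction of units with touch gains (~2/3 responsive) |
| `baseline_mean` | 5 Hz | gamma-distributed baseline rates |
| `gain_mean` | 25 Hz | gamma-distributed evoked gains (robust tens-of-Hz responses) |
| `field_prob` | 0.6 | per-body-part receptive-field probability |
| `mirror_sigma` | 0 Hz | SD of the left−right gain difference |
| `imagery_share` κ | 0.7 | shared fraction of touch gains in imagery gains |
| `cue_share` α | 0.5 | shared fraction of imagery gains in cue-epoch gains |
| `latency_mean` / jitter | 50 / 5 ms | onset latency distribution across units |
| `ramp_rise` | 10 ms | rise time of the onset ramp |

Task presets reproduce the four paradigms: touch mapping (13 conditions ×
10 trials), probe-contact latency (6 × 8, contact events), receptive-field
gradient (9 collinear sites 2 cm apart + null, × 10), and tactile imagery
(actual bilateral cheek/shoulder/hand + imagined right cheek/shoulder/hand
+ null, × 8; 0.5 s auditory cue and 2 s delay, following the epoch
timings of the dynamics analyses — the actual-touch tasks use a 1.5 s cue
and 1 s delay). Imagery hand gains are nonzero even though actual hand
gains are zero, mirroring the dissociation between imagined and actual
touch to an insensate limb; with κ = 1 the imagery gains equal the latent
touch gains exactly (the hand compares against its latent, pre-zeroing
value). Mirror asymmetry noise is truncated at zero gain, so very small
`mirror_sigma` values are realised slightly shrunken.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: refractory periods and spike-history dependence,
correlated noise across units (a major driver of real population
statistics), non-stationary baselines and electrode drift, waveform-level
artefacts, and any deviation from Poisson count statistics. Recovery
results here certify the estimators, not the biology.

## Validation problem sizes

The acceptance-style test suite runs, per criterion: latency recovery at
30/50/80 ms × 20 replicate sessions (100 units, 8 trials/condition) with
100 bootstrap draws each; decoder chance/separability on single 60-unit
sessions; FDR control on 20 replicates of 1000 null units; mirror
recovery on 20 + 20 touch-map sessions (60 units, 300 relabellings);
crossnobis null and shift at 100 replicates; generalization-structure
recovery at α ∈ {0, 0.5, 1} × 20 imagery sessions; cross-format recovery
at κ ∈ {1, 0} × 10 sessions; plus exact small-instance oracles. The
`scripts/acceptance.R` entry point runs one 100-unit session per paradigm
end to end.

## Known limitations

- The bootstrap IQR understates point-estimate uncertainty (loading noise
  is outside the resampling) and quartile bounds are not a coverage
  interval; see above.
- Permutation tests built on re-split or bootstrap samples
  (`correlation_contrast_test`, `latency_side_test`) are descriptive near
  their null; the calibrated alternative implemented for mirror symmetry
  relabels trials instead.
- The χ² construction and the FDR family are documented interpretations
  of under-specified procedures.
- Euclidean similarity is reported as a distance (smaller = more
  similar); it is unbounded and not directly comparable to the
  correlation ceiling.
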
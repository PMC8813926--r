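---
title: "Methods: synchronization-index PAC analysis on parcel time series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synchronization-index PAC analysis on parcel time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(megpac)
```

## Scope and model

megpac implements a resting-state phase-amplitude-coupling (PAC) analysis
for parcel-level neural time series (e.g. source-reconstructed MEG cortical
currents averaged into cortical areas), aimed at case-control studies of
Parkinson's disease where exaggerated beta-gamma coupling in sensorimotor
cortex is a candidate disease marker. The pipeline is: zero-phase
preprocessing, amplitude-based artifact-segment rejection, band-power
Z maps, synchronization-index (SI) comodulograms with rotation-surrogate
nulls, permutation-based group inference, and permutation-tested Pearson
correlation of sensorimotor PAC with an akinesia score.

The coupling statistic is the synchronization index

$$\mathrm{SI} = \left| \frac{1}{N} \sum_{t=1}^{N}
  e^{\,i\,(\theta_{\mathrm{phs}}(t) - \theta_{\mathrm{amp}}(t))} \right|,$$

where $\theta_{\mathrm{phs}}$ is the Hilbert phase of the low-band-filtered
signal and $\theta_{\mathrm{amp}}$ is the Hilbert phase of the low-band
filtered *amplitude envelope* of the high-band-filtered signal. SI is the
resultant length of the phase difference: 0 for unrelated phases, 1 for
perfect locking. It is symmetric in its arguments and invariant to a common
phase offset — a property with a practical consequence for surrogate design
discussed below.

## Signal processing choices

**Filters.** All filtering is zero-phase Butterworth (`signal::filtfilt`):
order 4 per pass for band-pass; order 2 per pass for the 0.5 Hz high-pass
and the 60 Hz notch (total stop width 1.5 Hz), because at those extreme
normalized cutoffs higher orders are numerically fragile while order 2
already exceeds every attenuation contract (the notch measures ~149 dB at
60 Hz; 50/70/80 Hz tones pass within 1 dB). Forward-backward application
doubles the effective order and cancels group delay, verified by
zero-lag cross-correlation in the passband.

**Edge trim.** After filtering, 1 s is trimmed from each end of every
contiguous clean segment before phases are extracted, covering the ringing
of the narrowest (4 Hz wide) band-pass. Segments shorter than twice the
trim are dropped; phases from surviving segments are pooled into one
vector per parcel (segments are *not* concatenated before the Hilbert
transform, which would manufacture phase discontinuities at the joins).

**Analytic signal.** The Hilbert transform uses the standard FFT
half-spectrum construction (positive frequencies doubled, negative zeroed).

**Artifact rejection.** The recording is tiled into non-overlapping 1 s
windows; a window is flagged when its peak |amplitude| in any parcel
exceeds 5 SDs of that parcel's currently clean samples, the SD is
re-estimated excluding flagged windows, and the rule iterates to a fixed
point, so large artifacts cannot inflate their own threshold. Flags are
unioned across parcels. On clean Gaussian noise the expected flag rate of
this rule is ~0.03% (tested ≤ 2%); a recording whose every window is
flagged raises an unusable-recording error.

**Band power.** Welch-style: overlapping 1 s Hamming windows shifted by
200 ms, windows wholly inside one clean segment, one-sided periodogram
bins with frequency in `(low, high]` summed and averaged over windows.
The normalization is fixed so a rectangular-window periodogram totals the
mean square (Parseval, tested to 1e-10); absolute units are internal
because the Z step — subtract the across-parcel mean and divide by the
across-parcel sample SD, per participant and band — removes scale.
Half-open bin assignment makes contiguous canonical bands partition the
frequency axis (alpha gets 4 bins of a 1 Hz-resolution window, beta 12,
matching the 4/12 white-noise power ratio).

**Resampling.** Polyphase (`signal::resample`), downsampling only; output
length `floor(n * target / fs)`; clean segments rescale by the same ratio.

## Comodulogram grids

The full grid pairs nine 4 Hz-wide phase bands (4-8 ... 20-24 Hz) with
eight 50 Hz-wide amplitude bands (30-80 ... 100-150 Hz). The canonical
whole-brain analysis uses alpha (8-12 Hz) or beta (13-25 Hz) phase against
gamma (50-100 Hz) amplitude. The 60 Hz notch sits inside every amplitude
band up to 60-110 Hz; it is applied as stated and its bite out of the
gamma envelope is accepted as part of the contract (a 1.5 Hz notch removes
3% of the 50-100 Hz bandwidth).

## Surrogate testing

The null preserves everything about each series except the alignment
between them: the low-frequency phase vector is cut at one uniformly
random point and the two blocks are swapped (a circular rotation), while
the envelope phase stays fixed. The empirical p-value uses the add-one
rule, $p = (1 + \#\{\mathrm{SI}_{\mathrm{surr}} \ge
\mathrm{SI}_{\mathrm{obs}}\})/(1 + n_{\mathrm{surr}})$, so it is bounded
below by $1/(n_{\mathrm{surr}}+1)$ and never zero. Default 1000 surrogates
per SI value; per-surrogate cut points derive deterministically from one
master seed.

Because SI ignores a constant phase offset, rotation surrogates are blind
to coupling whose phase series is a pure linear ramp (a sinusoidal
rhythm): rotating a ramp only adds a constant. Surrogate testing therefore
has power exactly because physiological (and simulated) rhythms have
stochastic, drifting phase — this drove the choice of band-limited noise
rhythms in the generator.

## Synthetic cohort generator

Each parcel receives unit-SD 1/f background (spectral exponent 1 by
default, synthesized by FFT shaping of white noise) plus three unit-RMS
band-limited Gaussian rhythms — alpha 8-12 Hz, a phase-band rhythm
(default beta 13-25 Hz), and an amplitude-band carrier (default gamma
50-100 Hz) — with default RMS amplitudes 1, 1 and 0.5 relative to the
background, jittered per parcel by a log-normal factor (SD 0.2) to emulate
anatomic variation (and to keep across-parcel Z scores non-degenerate).
In coupled parcels the carrier $c(t)$ becomes
$c(t)\,[1 + k\cos\theta_{\mathrm{low}}(t)]$ with $\theta_{\mathrm{low}}$
the Hilbert phase of the generated phase-band rhythm; $k = 0$ reduces
exactly to the uncoupled construction. Defaults: 240 s at 500 Hz
(mirroring a typical resting-state recording length after cleaning),
8 parcels with the first two "sensorimotor" parcels coupled. Generation is
bit-reproducible from the seed and leaves the caller's RNG untouched.

Cohorts draw per-patient depths $k_i$ from a normal distribution truncated
to $[0,1]$ (mean 0.5, SD 0.2); controls get $k = 0$. The akinesia score is
$a + b\,k_i + \varepsilon_i$ rounded to a non-negative integer, defaults
$a = 10$, $b = 20$, with the noise SD derived from a target population
correlation (default $\rho = 0.6$) via
$\sigma_\varepsilon = b\,\mathrm{sd}(k)\sqrt{1-\rho^2}/\rho$. Other
covariates (sex, age, side, medication state, LEDD, duration) are sampled
to resemble a typical Parkinson's cohort and carry no signal. Artifact
bursts are a Hann-tapered multiplicative gain (default 10x over 1 s) with
ground-truth intervals returned for testing the detector; gain 1 is an
exact no-op used as a negative control.

What the generator does *not* emulate: non-sinusoidal waveform shape
(sharp beta troughs can masquerade as PAC in real data), volume
conduction / parcel leakage, non-stationarity of coupling, and realistic
cortical geometry. Passing tests demonstrate correctness of the estimators
and calibration of the inference under this generative model, not that the
pipeline is immune to those real-data confounds.

## Group inference

Within a group, per-parcel paired t statistics compare each participant's
SI with their mean surrogate SI (a "paired Welch t test" would be a
contradiction in terms — Welch's correction applies to unpaired
comparisons — so an ordinary paired t on differences is used). Correction: sign-flip
permutations of the difference vectors build a null t distribution, pooled
across parcels and permutations by default (a per-parcel option exists);
per-parcel p-values are the pooled-null exceedance fractions
(add-one-corrected), then Benjamini-Hochberg across parcels/bands.

Between groups, per-parcel one-way F statistics (two groups) are
thresholded at parametric p < 0.05, supra-threshold parcels are joined
into connected components on a user-supplied parcel adjacency graph,
cluster mass is the sum of F, and the max-cluster-mass permutation null
(group labels shuffled) yields cluster p-values. The same code path serves
SI, power Z and phase-value maps. A lattice parcellation generator
provides synthetic adjacency (18 x 20 for a 360-area scheme).

## Clinical correlation

The patient metric is area-averaged SI over the parcels flagged by the
within-group test (falling back to the designated coupled set when nothing
is flagged), correlated with the akinesia score (sum of the five
MDS-UPDRS-III items 3.4-3.8). Significance is assessed by permuting
participants' metric rows with scores fixed (2000 permutations by
default): per area, the two-sided permutation p; at family level, the
observed count of parametrically significant areas against the
permutation null distribution of that count. The count statistic is
intrinsically weak when only one of several areas carries signal — with
six areas the null probability of at least one significant count is
already ~0.26, so a single true area can never make the family test
significant; in that regime the per-area permutation p is the informative
output, and both are always reported.

The a-priori sample-size utility uses the Fisher-z approximation
$n_0 = \lceil ((z_{1-\alpha/2} + z_{\beta})/\operatorname{atanh}\rho)^2 +
3\rceil$, giving $n_0 = 20$ at $\rho = 0.6$, $\alpha = 0.05$ two-sided,
power 0.8, and 29 after 30% dropout inflation; exact-power software
rounds the same inputs to 30, a one-subject discrepancy inherent to the
approximation, which Monte-Carlo checks confirm delivers ≥ 0.75 power at
$n_0$.

## Validation design and problem sizes

The test suite validates calibration and recovery at sizes chosen to keep
the whole suite in a few CPU-minutes: surrogate calibration on 100
uncoupled 60 s recordings with 200 surrogates each (rejection rate at
$\alpha=0.05$ within [0.01, 0.10]); comodulogram localization over 20
seeds at $k = 0.5$; SI monotonicity over depths {0, 0.25, 0.5, 0.75, 1}
with 10 seeds each; permutation FDR on 23 x 60 matrices (sensitivity with
a 1 SD shift in 10 parcels; zero false flags under the global null);
cluster recovery of a 6-parcel blob at 1.5 SD, 23 + 23 subjects; clinical
recovery on 50 cohorts of 23 patients (3 parcels, 60 s) with the score
slope set for population $\rho = 0.6$ (median recovered r in [0.4,
0.75]), plus zero-slope and power-Z negative controls.

One documented shortfall: the *two-axis* comodulogram argmax (phase band
*and* amplitude band simultaneously within one grid cell of the injected
pair) reaches only ~60-70% at $k = 0.5$. The amplitude bands overlap by
40 Hz, every band overlapping the 50-100 Hz carrier captures nearly all
of the injected modulation, and a 1/f background contributes almost no
competing envelope noise above 100 Hz, so the expected SI is nearly flat
across the 40-90 ... 80-130 Hz cells and the amplitude-axis argmax is
close to exchangeable among them — at 240 s as much as at 60 s. The
phase-axis argmax, which carries the scientific content (beta- versus
alpha-phase coupling), localizes in 100% of seeds. Both rates are
reported by the validation script.

## Known limitations

- SI quantifies coupling to the *low-band-filtered envelope fluctuation*,
  not preferred-phase concentration; alternative estimators (modulation
  index, mean-vector length, GLM-PAC) are out of scope.
- No correction for waveform non-sinusoidality; sharp rhythms can inflate
  apparent PAC in real recordings.
- Vertex-level inference, source imaging, ICA denoising and sensor-space
  processing are out of scope; inputs are parcel-level series.
- Whole-brain Z normalization is per participant; cross-participant
  normalization is not implemented.
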
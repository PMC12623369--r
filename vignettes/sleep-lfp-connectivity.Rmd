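---
title: "Sleep-state LFP connectivity: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sleep-state LFP connectivity: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sleeplfp)
```

## The problem this package addresses

Chronic multichannel local field potential (LFP) recordings from two
cortical regions (primary somatosensory cortex, S1, and the rostral
forelimb/premotor area, RFA) are used to ask how functional coupling between
spared sensorimotor areas changes across recording sessions — for example
before and after a focal ischemic lesion elsewhere in the loop. All coupling
metrics are computed inside slow-wave sleep (SWS), the state in which
slow-oscillation-driven plasticity is most active, so the pipeline must
first stage the sleep–wake cycle, then select clean SWS analysis windows,
and only then quantify spectra, phase coupling, cross-frequency coupling,
and their relation to sleep amount.

The package implements the full chain: preprocessing (bipolar referencing,
anti-alias decimation to 1 kHz, harmonic line-noise removal, bad-channel
screening), spectral-ratio sleep staging, Welch power spectral density,
Morlet-wavelet phase-locking value (PLV), surrogate-normalized
phase–amplitude coupling (PAC), eigenvector-centrality (EVC) network
summaries with mixed-model slope analysis against sleep duration, a
per-frequency group-comparison battery, and a ground-truthed synthetic
session generator that makes every stage testable without animal data.

## Preprocessing

**Bipolar referencing.** Nearby channels are subtracted pairwise to
suppress common-mode and volume-conducted activity. The pairing scheme is
not dictated by the data format, so the default montage pairs spatially
adjacent channels within each array (1–2, 3–4, ...); any montage can be
supplied as a data frame. Pairs never cross regions.

**Decimation.** Wideband input is low-pass filtered (zero-phase,
linear-phase FIR; −6 dB at ~350 Hz, ≥53 dB beyond ~400 Hz for the default
300 Hz band edge) and downsampled by an integer factor to 1 kHz. For white
input the 0–300 Hz power is preserved within 5%.

**Line-noise removal.** The mains filter is a cascade of linear-phase FIR
band-stops (Hamming-windowed sinc design) with 1 Hz nominal stop widths
(−6 dB edges at ±0.5 Hz) centered at 50 Hz and every harmonic below
Nyquist. The per-stage transition width is 0.25 Hz, which puts the
attenuation at each stop-band center far below −53 dB and keeps the whole
central ±0.35 Hz at or below −53 dB; passband ripple stays under 1 dB.
Zero phase is obtained by compensating the exact group delay of the
odd-length linear-phase kernel in a single FFT-convolution pass. This is
numerically identical in phase to forward–backward filtering but leaves the
designed magnitude response untouched (forward–backward would square it),
so the attenuation that is reported is the attenuation that is applied.

**Bad channels.** Clipped channels are detected by rail dwell: the fraction
of samples lying in runs of at least 5 consecutive samples within 0.1% of
the channel's observed min/max exceeding 2%. The run requirement matters: a
clean sinusoid touches its extremes instantaneously (2–3 samples at 1 kHz)
while genuine clipping dwells at the rail, and a literal "fraction of
samples near the rail" rule would flag a pure sine. Drifting channels are
those whose sub-0.5 Hz periodogram power exceeds half the total. All
thresholds are arguments.

## Sleep staging

Per channel, 2-s Hann-tapered periodogram windows advanced by 1 s yield two
band-power ratios: ratio 1 = (0.5–20 Hz)/(0.5–55 Hz) and ratio 2 =
(0.5–4.5 Hz)/(0.5–9 Hz). Ratio 2 tracks delta dominance (high in SWS);
ratio 1 separates theta-rich sleep from desynchronized wakefulness. For
each ratio the first principal component across channels is extracted over
epochs; its sign is fixed by requiring positive correlation with the
cross-channel mean, since a principal axis is defined only up to sign. The
two PCs are smoothed with a unit-sum 20-s Hann kernel and plotted as a 2-D
state map (x = ratio-2 PC, y = ratio-1 PC). Smoothing is applied
circularly, which keeps the kernel mass constant everywhere and therefore
preserves the series mean exactly; the wrap-around couples the first and
last ~10 s of a session, which is negligible at realistic session lengths.

States are assigned by k-means (k = 3, 20 restarts, fixed seed) on the map,
with a positional rule: the cluster with the highest mean x is SWS
(delta-dominant); of the remaining two, the one with higher mean y is REM
(theta-rich) and the last is WK. The literature describes cluster-to-state
assignment "by position" without a formula, so this operationalization is
validated by parameter recovery on synthetic sessions (≥0.90 epoch
accuracy in the acceptance suite) rather than asserted as the original
rule. Real structure is required before labels are issued: if the minimum
inter-center distance is below twice the mean within-cluster spread —
as for a single undifferentiated blob — every epoch is returned UNSCORED.

SWS analysis segments are non-overlapping 120-s windows tiled into maximal
runs of consecutive SWS epochs. A window is dropped if any good channel
deviates from its median by more than 8 robust standard deviations
(1.4826 × MAD), an operationalization of "artifact-free after visual
inspection"; the threshold is an argument. Normalized SWS duration is the
fraction of scored epochs labeled SWS — a scale-free quantity comparable
across sessions of different lengths.

## Spectral estimation

Welch's method with 4096-sample Hann windows at 1 kHz (frequency resolution
1000/4096 ≈ 0.24 Hz), 50% overlap, constant detrending per block, density
scaling. Region spectra are arithmetic means over good channels, then over
segments. Group figures use a percentile bootstrap over animals (resampling
animals with replacement, 1000 draws, 97% interval, fixed seed), matching
the convention that the shaded band describes inter-subject spread.

## Phase-locking value

LFPs are band-pass filtered with 43 complex Morlet wavelets, log-spaced
from 1.2 to 200 Hz. The width parameter m = 7.5 is interpreted as the
cycle count of the Gaussian envelope, sigma_t = m/(2*pi*f); conventions
differ between toolboxes, so this is stated explicitly. Log spacing is
chosen because the companion PAC low-frequency list (1.2, 2.4, 3.7, ...)
is itself near-geometric; linear spacing is available. Kernels are unit
energy, and samples within half a kernel support of either segment edge are
excluded so boundary bias never enters any estimate.

The complex PLV between two coefficient series is the mean unit phasor of
their phase difference; its modulus is the PLV in [0, 1]. Channel-pair
matrices are averaged over unordered pairs within S1, within RFA, and
across the regions, per 120-s segment, then over segments. A surrogate
reference spectrum — the same statistic after independently
circular-rotating every channel — is computed alongside, because the null
level of PLV depends strongly on the number of effectively independent
phase samples at each frequency (at 1.2 Hz a 120-s window carries only a
few dozen independent phase estimates, so "chance" PLV is far above zero).

EVC is the leading eigenvector of the band-averaged PLV matrix (diagonal
zeroed), non-negative and unit-norm, computed by power iteration with a
positive diagonal shift. The shift leaves eigenvectors unchanged while
making the leading eigenvalue strictly dominant; without it, bipartite-like
connectivity patterns make plain power iteration oscillate. Canonical bands
are delta 0.5–4, theta 4–8, alpha 8–12, beta 12–30, gamma 30–100 Hz, with
the lower edge inclusive.

## Phase–amplitude coupling

PAC is evaluated on a fixed grid: ten low frequencies (1.2–68.1 Hz) crossed
with 22 ratios; the high frequency is hf = lf × ratio and any cell with
hf > 200 Hz is discarded (111 valid cells). For a directed pair, the phase
channel contributes the phase of its lf-band Morlet coefficients; the
amplitude channel contributes the magnitude envelope of its hf-band
coefficients, which is then itself filtered at lf and enters through the
phase of that filtered envelope. Raw PAC is the modulus of the mean unit
phasor of the difference between those two phase series. The defining
expression names the second term an "amplitude envelope" while using it
inside a phase difference; filtering the envelope at the low frequency and
taking its phase is the only reading that makes the expression well
defined, and it is the one implemented (a band-pass + analytic-signal
variant of envelope extraction would behave equivalently; the wavelet route
reuses existing machinery). PAC kernels are centered at the exact lf and hf
values of the grid, not snapped to the 43-point PLV bank, since the grid
defines its own frequencies.

Raw PAC is normalized by surrogates: nPAC = observed / mean(surrogate
raws), about 1 under the null. Surrogates circular-rotate the lf phase
series at a uniformly drawn split point (50 draws by default, seeded), with
a minimum rotation distance of one kernel support so a surrogate is never a
near-identity copy. Because a rotation by k turns the mean phasor product
into a lag-k circular cross-correlation, the entire rotation family is
obtained from three FFTs and the seeded ensemble simply indexes into it —
exact, and far cheaper than re-evaluating each rotation.

Directionality: intra-areal PAC uses ordered pairs of distinct channels
within a region; inter-areal PAC takes the phase channel in one region and
the amplitude channel in the other, so S1→RFA and RFA→S1 are distinct.
For display and HF-resolved statistics the (lf, ratio) grid is projected to
(lf, hf) space and averaged across lf per logarithmic HF bin (24 bins,
2–200 Hz); the binning is a convention of this package, since only the
projection itself is prescribed.

Two estimator properties matter for interpretation and are exposed by the
synthetic experiments below. First, the metric is phase-consistency of the
envelope, not modulation amplitude: with little intrinsic envelope noise,
even a weak but steady modulation yields near-perfect envelope-phase
consistency, so raw PAC saturates and different (nonzero) modulation depths
converge. Second, nPAC grows with segment length for any true coupling,
because the surrogate mean shrinks with the effective sample count while
the observed value plateaus; nPAC values are therefore comparable only at a
fixed segment length, which is why all segments are 120 s.

## Surrogate construction

The circular split x_surr = [x(k+1..n), x(1..k)] preserves each channel's
sample multiset and magnitude spectrum exactly (a rotation only multiplies
the spectrum by a phase ramp) while scrambling cross-channel alignment.
The split is applied to the narrow-band coefficient series, the objects the
metrics actually consume. The alternative construction sometimes described
in prose — recombining mismatched halves of the two channels — is not
implemented: the formula variant (single-channel rotation) is unambiguous
and strictly coupling-destroying, and is what both PLV references and PAC
normalization use.

## Group statistics

For two independent groups, per frequency: two-sided Mann–Whitney U on
central tendency, Fligner–Killeen on spread, per-group coefficient of
variation across animals, log variance ratio, and Cohen's d with pooled SD.
For the within-animal comparison of two sessions: paired t on central
tendency and a permutation test on T = ln var(a) − ln var(b), with the null
built by independently swapping each animal's condition pair — all 2^n
assignments when n ≤ 12 (then the p-value lies on a k/2^n grid), otherwise
10,000 seeded draws with add-one smoothing. All two-sided; sidedness is a
package convention. Shapiro–Wilk normality is reported per frequency but
never switches the test battery. p-values are Benjamini–Hochberg adjusted
across frequencies at alpha = 0.05, separately for the central-tendency and
variability families. Mixed models for sleep–centrality slopes use a random
intercept per animal — random slopes are not identifiable with the 4–5
animals typical of this design — with per-condition trends and pairwise
slope contrasts extracted by `emmeans::emtrends`, and BH adjustment across
bands and conditions within region. The square-root transform of EVC is
applied before fitting; no quadratic term is added.

## The synthetic generator

`generate_session()` builds each channel as 1/f background (FFT spectral
shaping, exponent 1 by default) plus state-gated oscillators plus injected
couplings plus 50 Hz line noise plus optional clipping bursts. The
sleep–wake cycle is semi-Markov: gamma-distributed dwells (shape 2) around
mean durations WK 180 s / SWS 300 s / REM 90 s with a transition matrix in
which SWS follows WK, REM follows SWS, and REM returns to WK — so
hypnogram segmentation is non-trivial rather than block-structured. SWS
carries a strong 2 Hz delta oscillator, REM a theta oscillator, WK a weak
broadband profile: exactly the structure the staging ratios separate.
Oscillators are phase-diffusing (Lorentzian linewidth), not pure tones;
this matters because circular-rotation surrogates are only informative when
phases decorrelate over time.

**PLV injection.** A shared phase-diffusing oscillator is added to every
channel of the target region(s), each with independent slowly varying phase
jitter. For slow wrapped-Gaussian jitter of SD sigma per channel the
expected pair PLV is exp(−sigma²), so the generator sets
sigma = sqrt(−ln c) to realize a requested coupling c analytically; the
acceptance suite verifies the realized PLV to within ±0.05 for
c in {0.2, 0.5, 0.8}. The jitter is smoothed to a ~0.5 s correlation time
so that the wavelet does not average it away.

**PAC injection.** Amplitude-region channels receive a carrier at
hf = lf × ratio whose envelope is (1 + m·cos phi_lf)/(1 + m), phase-locked
to the lf oscillator delivered to the phase-region channels; the
normalization keeps peak amplitude constant across depths m so PAC tests
are not confounded by power. The default carrier amplitude (0.8 relative
to unit background) is calibrated so that the modulation competes with the
intrinsic envelope fluctuations of the background: with a much stronger
carrier the envelope-phase metric saturates (see above) and all nonzero
depths become indistinguishable, whereas at this amplitude recovered nPAC
is graded and strictly monotone over depths 0/0.3/0.6/0.9.

**Artifacts** are Poisson-placed clipping bursts that saturate all channels
at a configurable multiple of the robust SD; they are exactly the events
the segment screen is meant to drop, giving a precision test for the
artifact logic. `make_study()` assembles a control group (one session each)
and a lesion group (two sessions each, D7/D14) with per-animal log-normal
random effects on PAC depth and SWS dwell, and per-condition overrides to
create positive-control studies.

What the generator does **not** emulate: volume-conduction mixing between
channels, non-stationary oscillator amplitudes within a state, movement
artifacts with realistic spectra, electrode drift, or biophysical coupling
mechanisms. Passing the synthetic suites therefore demonstrates estimator
correctness and calibration under the stated statistical structure, not
robustness to every pathology of real recordings.

## Problem sizes in the test suite

The validation suites run on one CPU in tens of minutes, so they use
deliberately scaled designs, chosen once: null-calibration and
depth-monotonicity experiments use single channel pairs and 120-s segments
(20 and 6 seeds respectively); PLV-strength recovery uses 120-s windows and
20 seeds per strength (shorter windows would bias weak couplings upward,
because the PLV chance floor at 3 Hz is non-negligible below ~100 s); staging recovery uses ten 600-s three-state sessions
with shortened dwells (90/150/45 s) so every state appears repeatedly; and
the study-level positive control uses 4 lesion animals with three 120-s
segments and the 2×2 directed channel pairs per session — an order of
magnitude less data per animal than a real session would provide, which
bounds the attainable power of the paired battery. The mixed-model recovery
uses 4 animals × 20 observations with intercept SD 0.1 and noise SD 0.05
around a true slope of 0.3.

## Known limitations

- PAC comparisons across different segment lengths are not meaningful
  (nPAC scales with the effective sample count); the pipeline fixes 120 s.
- The rotation surrogate is weak for nearly deterministic narrow-band
  signals (a rotation of a pure phase ramp is a phase offset); the
  generator's phase-diffusing oscillators avoid this regime, and real LFPs
  are comfortably stochastic, but the caveat applies to any synthetic test
  one might add with pure tones.
- With four animals per group, the paired battery after multiple-testing
  correction has limited power unless per-animal estimates aggregate many
  segments and channel pairs; desk-scale runs sit near that limit.
- EDF input is not parsed; recordings enter either as in-memory matrices or
  through the package's flat binary + JSON sidecar container.
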
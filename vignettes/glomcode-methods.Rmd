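---
title: "Models and methods behind glomcode"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind glomcode}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glomcode)
```

This vignette is the package's own account of its models, parameter
choices, numerical decisions, and limitations. The package studies how a
population code for local visual features behaves under self-motion: an
ideal-observer detection task, a generative model of glomerulus
population responses with a shared gain, behavior and saccade analytics,
and a test for whether visual and motor gain modulation combine
multiplicatively.

## The ideal-observer detection task

A 15° dark spot moves at 100 °/s through a circular receptive field
(default 30°, a hard disc, sized like a small-object-detecting visual
projection neuron's field and comfortably larger than the spot) composited
over a panoramic background that rotates azimuthally at a fixed speed.
Geometry is equirectangular — an azimuth × elevation pixel grid with
cylindrical wrap and no perspective correction — because the analysis
operates on image pixels, not rendered screens. Two scalar channels are
recorded per frame over the receptive-field mask:

- local **luminance**: the mean pixel intensity;
- local **spatial contrast**: the variance of pixel intensities divided
  by their mean. The variance uses the population (1/N) convention
  throughout the package, so short windows remain well defined.

Discriminability between spot-present and spot-absent traces is

$$ d' = \frac{\bar{x}_\text{present} - \bar{x}_\text{absent}}
             {\sqrt{(\sigma^2_\text{present} + \sigma^2_\text{absent})/2}} $$

computed from the samples in the window during which the spot's center is
inside the receptive-field disc. For luminance the sign is inverted, since
a dark spot lowers luminance; a detectable spot then gives positive d' in
both channels. If the pooled variance vanishes with a nonzero mean
difference, discrimination is perfect and the value is reported as
infinite with a `capped` flag. Summaries over image collections retain
capped values only for static backgrounds, where perfect discrimination is
the expected outcome.

With a static background, d' is maximal; with increasing rotation speed
the background-driven fluctuations grow and d' falls monotonically. The
`speed_sweep()` driver averages multiple seeded background phases per
image (so each panorama is sampled at several receptive-field contents)
and reports mean ± SEM across images.

## Surrogate natural images

Natural scenes are dominated by low spatial frequencies, with power
spectra close to $p \propto 1/f^2$. The package synthesizes surrogate
panoramas spectrally: a white-noise field is reweighted in the frequency
domain by $f^{\text{slope}/2}$ (random phases retained, DC removed),
rescaled to mean 0.5 with pixel standard deviation 0.2 — an RMS contrast
of 0.4 relative to the mean, typical of natural scenes — and clipped to
[0, 1]. Surrogates replace downloaded photographic databases because only
the second-order statistics (long-range correlations, low-frequency
dominance) matter for the analyses here; higher-order structure of real
scenes is deliberately out of scope, and conclusions about phase-dependent
features of real images cannot be drawn from these tests.

Spectra are estimated by Welch's method: four Hann-windowed, 50 %-
overlapping azimuthal segments whose periodograms are averaged before a
least-squares log–log slope fit over a low-frequency band (default
0.01–0.2 cycles/degree). Two numerical points matter:

- the slope is fitted on the averaged periodogram *ordinates*, not on
  radial-bin means: the log of a bin mean is biased low in sparse
  low-frequency bins, which tilts the fit by several tenths;
- segment averaging reduces each ordinate's log-variance roughly
  fourfold, which is what makes a single-image slope estimate usable
  (per-image spread ~0.08 around the target at the default size).

Filtering uses radially symmetric Gaussian transfer functions with the
cutoff at the half-power frequency (default 0.1 cycles/degree). The
high-pass filter is the amplitude complement of the low-pass filter, so a
matched pair reconstructs the input exactly before rescaling. High- and
low-pass outputs are rescaled to the input's mean and standard deviation;
whitening divides each Fourier component by its own amplitude (epsilon
floor 1e-8, DC preserved) and scales the result to the input's peak pixel
intensity.

## Parametric stimuli

**Random-dot coherence fields.** A fraction `coherence` of dots (rounded
half away from zero) moves along the signal direction; the rest draw
uniform random directions, which may coincide with the signal direction by
chance, matching the fraction semantics. All dots share one speed, and
positions are drawn before directions, so for a fixed seed the initial
configuration is identical at every coherence. Rendering snaps dot centers
to the pixel grid and composites dots additively in darkness
("transparent" dark discs): a pixel covered by k dots is darkened k
steps. This is a deliberate departure from opaque (darker-value)
compositing — with opaque dots the overlapped area, and hence the frame
mean, depends on the dot directions, whereas the additive rule makes each
frame's total darkness exactly `n_dots × stamp area`, so the matched-
intensity guarantee across coherence levels holds bit-for-bit, not just
approximately. At the default density (40 dots of 15° on a 360° × 120°
torus) overlaps are rare, so the visual difference is negligible.

**Saccade playback.** The background displacement is 0 before onset, a
linear ramp to 70° over 200 ms, and constant afterwards — a constant
velocity of 350 °/s, consistent with a ballistic turn. The ramp shape is
a design choice; only total amplitude and duration are constrained.

**Grating + probe.** A sinusoidal grating drifts behind a dark probe
disc; the temporal frequency is `speed / period` and generation refuses
frame intervals that undersample it.

**Trial interleaving** is a seeded permutation of the stimulus multiset;
epoch structure defaults to 3 s of stimulus flanked by 1.5 s pre and tail
time.

## The synthetic population generator

The generator is the study's ground truth. Single-trial peak amplitudes
follow

$$ A_{g,t} = g_t \cdot T_{g,s(t)} \cdot e^{\beta_g b_t} + \varepsilon_{g,t} $$

- $g_t$: a single per-trial gain shared by all glomeruli, log-normal with
  mean 1 (log-sd default 0.4). Log-normality enforces positivity; the
  data constrain neither the distribution family nor the coupling form.
- $T$: a group-structured tuning matrix (default 13 glomeruli, 4
  functional groups). Each group has a template with strong responses
  (~1 dF/F) on its own block of stimuli and weak baseline responses
  (~0.1) elsewhere; glomeruli scale their template log-normally and add
  small jitter. Complete-linkage clustering of the rows recovers the
  groups (adjusted Rand index > 0.9 in tests).
- $b_t$: the standardized walking amplitude of trial t. Couplings
  $\beta_g$ are negative only for a designated "small-object" subset;
  the exponential-multiplicative form keeps gains positive.
- $\varepsilon$: independent Gaussian amplitude noise (default 0.05
  dF/F, about 15 % of the mean response).

Each trial is rendered as a difference-of-exponentials time course (rise
0.1 s, decay 0.5 s — a monophasic calcium response spanning several
hundred milliseconds) peaking at $A_{g,t}$, sampled at the 7.22 Hz
imaging volume rate within a 1.5 / 3 / 1.5 s pre/stimulus/tail epoch.

**Walking generator.** Saccade onsets follow a renewal process with a
hard 0.5 s refractory period: intervals are `refractory + Gamma(shape 2)`
with the scale set by the target rate (default 0.8 Hz), which puts the
inter-turn-interval mode near 0.9 s with a long tail. Each saccade is a
200 ms half-sine angular-velocity pulse with random sign; free-walking
peak speeds default to 200–500 °/s (well above the conventional 160 °/s
classification threshold), while ball-measured fictive sessions should
use attenuated peaks (the tests use 60–120 °/s) — ball inertia and the
tracking pipeline low-pass real saccades, and a Li threshold on a trace
containing free-walking-scale pulses separates the pulse tail rather than
quiet-versus-walking. Forward velocity alternates between stationary
periods and walking bouts (~1.5–2.5 cm/s) on a ~1 s timescale,
independent of saccade timing; the x/y ball axes carry components
proportional to forward speed, so forward and rotational movement are
correlated as in fictive walking. Heading integrates angular velocity and
the planar trajectory integrates forward velocity along the heading.

## Population analytics

**Peak amplitude** (max dF/F in the stimulus window) is the canonical
single-trial response statistic throughout.

**Noise correlations** are Pearson correlations of peak amplitudes across
trials *within* each stimulus, averaged across stimuli; zero-variance
glomeruli yield undefined entries that are excluded from the average with
a warning, never silently zeroed.

**Shared gain** is the first principal component of the trials ×
glomeruli amplitude matrix after removing each glomerulus's per-stimulus
mean, with the loading vector oriented to positive mean (so larger score
= globally stronger trial). Mean removal is per stimulus so the component
reflects trial-to-trial, not tuning, variance. A single global PC1 is
exact for rank-one data and essentially exact on probe sessions (one
repeated stimulus; recovery r > 0.99 at the default noise). Across
heterogeneous multi-stimulus blocks the per-stimulus response directions
differ, so one global component mixes them and recovery degrades to
r ≈ 0.9 — an intrinsic property of the estimator, which is why the
package's recovery benchmarks use the probe-session design that gain
characterization experiments use anyway.

**Gain–behavior statistics.** Per fly, Spearman's rho between single-
trial amplitudes and walking amplitude; across flies, a one-sample,
one-sided t-test per glomerulus (H1: mean rho < 0) with Holm (step-down
Bonferroni) correction at alpha = 0.05: sort ascending, compare
$p_{(i)} \le \alpha/(m-i+1)$, stop at the first failure.

**Decoding.** Multinomial logistic regression on the trials × glomeruli
peak matrix, ridge-penalized with a fixed small L2 strength (default
0.001; the penalty mainly stabilizes the fit). Each of 100 iterations
draws a stratified 90/10 split per class, z-scores each glomerulus with
training-fold statistics only (avoiding test-set leakage), fits, and
scores held-out trials; accuracies and the row-normalized confusion
matrix are averaged. One numerical point: the coordinate-descent solver
must be warm-started along a decreasing penalty path and queried at the
target penalty — a cold start at a single small penalty can terminate far
from the optimum and silently decode at chance.

**Trial shuffling** permutes amplitudes across same-stimulus trials
independently per glomerulus: per-stimulus means and variances are
preserved exactly (it is a permutation), while cross-glomerulus
correlations are destroyed in expectation. On generator data with a
shared gain, intact decoding beats shuffled decoding — the directional
signature of correlation-aided coding.

## Behavior analytics

**Li threshold.** The behaving/non-behaving threshold minimizes Li's
cross-entropy criterion $-(S_0\log\mu_0 + S_1\log\mu_1)$ (sums and means
of the values below/above the candidate). Rather than the common
histogram + fixed-point iteration, the criterion is evaluated exactly at
every midpoint between consecutive sorted unique values and the global
minimizer returned; this is exact, trivially scale-equivariant, and
matches the iterative reference implementation (agreement with
scikit-image's `threshold_li` to 0.1 % on generated sessions). A trial is
"behaving" when its walking amplitude exceeds the session threshold for
at least 25 % of time points (boundary inclusive).

**Saccade detection** marks contiguous excursions of angular speed at or
above 160 °/s, merges excursions separated by less than 0.1 s, and then
backtracks each onset (at most 0.1 s) to where the speed last fell below
20 % of the threshold. The backtracking step matters: for a 200 ms pulse
that barely clears threshold, the first supra-threshold sample lags the
turn start by up to ~100 ms, which would make a detector that reports raw
crossings appear to miss onsets it in fact found. With refinement, the
detector recovers 100 % of generated onsets within 50 ms at zero false
detections over 300 s sessions.

**Saccade-cycle statistics** partition samples into peri-saccade (within
±200 ms of an onset) and intersaccade phases. Comparisons of forward-
velocity distributions between phases must respect the strong sample
autocorrelation of walking bouts: the tests subsample one value per
saccade (and one per intersaccade midpoint) before a KS test, which is
then calibrated under the independent-generator null.

## Gain analyses and the independence test

"Gain" is operationalized as a ratio of condition means of peak
amplitudes (preferred over a mean of ratios, which is unstable when
single-trial amplitudes are near zero). Surround speed tuning normalizes
by the static-background mean; saccade-timing curves normalize by trials
with |saccade offset| ≥ 2 s, where suppression has recovered; the gain-
versus-walking curve normalizes each trial by its per-stimulus mean and
bins by walking amplitude, dropping bins with fewer than 5 trials with a
message.

The independence test asks whether visual-saccade suppression and
walking suppression combine multiplicatively. Per glomerulus, with the
four {visual} × {walking} condition cells,

- marginal gains: $g_V = m_{10}/m_{00}$, $g_B = m_{01}/m_{00}$;
- prediction under independence: $g_V \cdot g_B$;
- observation: $g_{VB} = m_{11}/m_{00}$;
- deviation: $g_{VB} - g_V g_B$, with a percentile bootstrap confidence
  interval from 1000 seeded resamples of trials within cells.

Under an exactly multiplicative generator the deviation CIs cover zero at
roughly their nominal rate (percentile bootstrap undercovers slightly at
50 trials/cell); with a multiplicative interaction of 0.3 injected into
the joint cell, the CIs exclude zero with power above 0.8 at 50
trials/cell. Deviations shrink toward zero as trials grow, checked at
n = 20/100/500.

## Orchestration and reproducibility

`run_experiment()` drives five end-to-end chains (discriminability sweep,
decoding with shuffle control, behavior-gain statistics, saccade
statistics, independence test). A single global seed expands into
per-stage child seeds through a fixed derivation (seed the RNG, draw the
stage seeds, restore the RNG state), so any stage can be rerun in
isolation; every output table gets a provenance sidecar JSON carrying the
experiment name, seed, full parameter echo, and an MD5 hash of the
serialized configuration. Dataset serialization uses a versioned JSON
layout with 17-significant-digit numbers, which round-trips doubles
exactly; a layout-version mismatch is an explicit error. Warnings for
dropped bins and undefined correlations are mandatory, not silent.

Problem sizes used by the test suite and the reproduction script — 20
surrogate images at 64 × 256 pixels, 13 glomeruli × 10 stimuli × 30
trials, 100 decoder iterations, 300 s walking sessions, 1000 bootstrap
replicates — were chosen so the complete suite runs in a few minutes on a
single core while keeping every statistical check well powered.

## What passing tests do and do not show

The generator reproduces the statistical structure the analyses assume —
shared multiplicative gain, group-structured tuning, saccadic walking
with refractory inter-turn intervals, multiplicative two-factor gain
control — but not the physiology behind it: no calcium-indicator
dynamics or nonlinearity, no motion artifacts, no spiking, no
photoreceptor optics, and surrogate images carry only second-order
natural-scene statistics. Recovery results therefore validate the
estimators and pipelines, not claims about biological effect sizes; on
real recordings, effect magnitudes (decoding decrements, correlation
strengths) will differ from the synthetic ones. The fictive-walking model
also cannot disambiguate forward- from rotation-driven modulation — the
two are correlated by construction, with the correlation exposed as a
parameter rather than a mechanism.
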
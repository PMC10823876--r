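---
title: "Virtual-dimension increase for sEMG gesture recognition: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual-dimension increase for sEMG gesture recognition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vdiemg)
```

This vignette is the package's account of its own methods: the
channel-augmentation transform, the SFV separability statistic, the
feature and classifier stages, the synthetic signal model that stands
in for human recordings, and the choices made where the design was
genuinely open.

## The augmentation transform

A window is an $m \times n$ matrix $S$ of raw sEMG samples ($m$ time
points, $n$ electrode channels; the canonical window is 200 ms at
1 kHz, $m = 200$). Squaring entries pointwise turns amplitude into
instantaneous intensity of muscle activity. For a channel pair
$(i, j)$ the virtual channel is

$$S_k = \left| S_i^2 - S_j^2 \right|,$$

and `augment()` appends one such column per unordered pair, in
lexicographic $(i, j)$ order, named `v_i_j`. An $n$-channel window
becomes $n + \binom{n}{2}$ columns. Three properties make this a
transform worth testing rather than a reshuffle of existing
information:

* it is nonlinear (squaring), so downstream linear or mildly nonlinear
  learners see genuinely new coordinates;
* additive interference common to both electrodes contributes equal
  power to $S_i^2$ and $S_j^2$ and is attenuated by the subtraction,
  so the virtual channel carries a cleaner between-muscle contrast;
* it needs no extra hardware, which is the point.

Virtual columns are in units of amplitude squared. No rescaling is
applied at this stage: the min–max normalization of the feature stage
absorbs scale differences between physical and virtual columns, and
rescaling earlier would change nothing downstream while complicating
the provenance of the columns.

## Features and normalization

Each column of a (possibly augmented) window contributes three
features, in a fixed layout `(abs_std, rms, mpf)`:

* **abs_std** — population standard deviation of the rectified signal
  $|s|$. No closed formula is standard under this name, so the package
  defines it explicitly as
  $\sqrt{\tfrac1m \sum_t (|s_t| - \overline{|s|})^2}$ and also offers
  the mean absolute value (`method = "mav"`) behind the same
  operation, since both are conventional sEMG amplitude features.
* **rms** — $\sqrt{\tfrac1m \sum_t s_t^2}$.
* **mpf** — mean power frequency, $\sum_b f_b P_b / \sum_b P_b$ over
  the positive-frequency bins of the single-taper periodogram of the
  mean-removed signal. No zero padding, bins $f_s/m$ apart (5 Hz at
  the default geometry), DC excluded. This is the simplest defensible
  estimator; anything fancier (Welch averaging, multitaper) would
  trade bias for variance invisibly to the rest of the pipeline. A
  constant column has no power after mean removal and MPF is an error
  rather than a silent 0: a zero-power channel is an acquisition bug
  the user should see.

Features are normalized per feature to $[0, 1]$ by the linear map
$y = (x - x_{\min}) / (x_{\max} - x_{\min})$. The extrema are fitted
**on the training split only** and applied to all rows, with values
outside the training range clipped to the endpoints; fitting on all
data would leak test information into the classifier's input scaling.
Degenerate features ($x_{\min} = x_{\max}$) map to 0. Population
($1/m$, $1/J$) denominators are used in every standard deviation in
the package, so the feature stage and the SFV stage agree on
conventions; the sample form ($J - 1$) is available in `class_stds()`
for sensitivity analysis.

## The SFV statistic

For a labeled, normalized feature set with $K$ classes and $I$
features, let $\bar{x}^k$ be the class-mean vectors and $s_i^k$ the
per-class, per-feature population standard deviations. Then

$$D = \frac{2}{K(K-1)} \sum_{p < q} \lVert \bar{x}^p - \bar{x}^q
\rVert_2, \qquad
c = \frac{1}{IK} \sum_{i,k} s_i^k, \qquad
\mathrm{SFV} = D / c.$$

$D$ measures how far apart class clusters sit; $c$ how diffuse they
are. SFV is invariant to global positive scaling and translation of
the feature set, to relabelling classes, and to permuting features —
all properties the test suite checks against an independent
brute-force implementation. Unequal class sizes are allowed (all
formulas use per-class $J_k$).

Degenerate inputs are handled explicitly rather than by crashing:
collapsed clusters with distinct means ($c = 0$, $D > 0$) are the
perfectly-separable limit and return `Inf` with a `degenerate` flag;
a dataset collapsed to a single point ($D = c = 0$) is an error. SFV
is defined on normalized features, so inputs outside $[0, 1]$ draw a
warning, not an error — the statistic is still well defined and the
scale invariance makes it meaningful.

By default SFV is computed on **all** samples of a run (training and
test), since it is a property of the feature set rather than of the
classifier; `sfv_score()` accepts any feature set, so restricting to a
split is a one-line change for users who prefer it.

## The classifier

The gesture classifier is a single-hidden-layer feed-forward network
(back-propagation family) with $2I + 1$ logistic hidden units for $I$
input features, a softmax output over the $K$ gestures, weight decay
$10^{-3}$ and at most 150 optimizer iterations, fitted by `nnet`.
These hyperparameters are deliberately ordinary: every claim the
package evaluates is *relative* (the same learner with and without
virtual channels, on byte-identical raw windows), so the learner only
needs to be reasonable and held fixed across arms. The configuration
is seeded — identical data and seed give identical weights — and
echoed in every evaluation report. Score ties break toward the lowest
class id. Raising the iteration cap does not sharpen the comparisons:
in our replicates it increased the variance of the paired
accuracy differences (overfitting noise) without moving their mean.

The train/test split is stratified per gesture:
$\operatorname{round}(J_k \cdot 2/3)$ rows to training after a seeded
shuffle, the rest to test — the conventional 2:1 ratio at 150 windows
per gesture gives 100/50 per class.

## The synthetic signal model

The generator replaces human recordings, so its assumptions deserve
the most scrutiny.

**Carrier.** Surface EMG at interference-pattern contraction levels is
well approximated by amplitude-modulated bandlimited Gaussian noise.
Each channel of a window is
$a_{g,c} \cdot j_{w,c} \cdot \epsilon(t) + \text{noise}(t)$, where
$\epsilon$ is white Gaussian noise passed through a zero-phase
4th-order Butterworth bandpass (20–450 Hz at $f_s = 1$ kHz — the
conventional sEMG energy band), $a_{g,c}$ is the activation of muscle
$c$ under gesture $g$, and $j_{w,c}$ is a log-normal amplitude jitter
(sdlog 0.1) drawn per window and channel to create within-class
spread. Zero-phase filtering needs $3 \times$ the effective filter
order of samples; windows shorter than 25 samples are rejected with
the minimum named.

**Noise.** Two parts, both scaled by `baseline_sd` (default 0.1):
a private white floor per channel, and a **common-mode interference**
term — one bandlimited series added identically to every channel,
with amplitude `common_gain` × `baseline_sd` (default gain 3) and a
log-normal level drift per window (sdlog 0.4). Physically this is
line interference, reference-electrode drift and crosstalk, which
nearby surface electrodes share; statistically it is a nuisance that
inflates every single-channel intensity feature while cancelling in
$S_i^2 - S_j^2$. It is the mechanism that makes virtual channels
informative in the simulation, exactly mirroring the motivation for
the transform on real electrodes. Setting `baseline_sd = 0` silences
both parts, which the simulator's exactness tests exploit.

**Activation profile.** The default 5-gesture × 4-muscle matrix
encodes the qualitative involvement of the forearm muscles: the thumb
extensor (extensor pollicis longus) raised for thumbs-up, fist and
open hand; the finger flexor/extensor group (flexor digitorum
superficialis, extensor carpi ulnaris) raised for everything except
thumbs-up; the little-finger extensor (extensor digiti minimi) raised
for OK, fist and open hand; overall levels following the strength
ranking ECU > EPL > FDS > EDM. All muscles keep a tonic co-activation
level (0.4) with gesture-specific increments of at most 0.3, because
real forearm muscles co-contract and single-channel contrasts between
gestures are moderate, not on/off. Together with the jitter and the
interference drift, these constants place the pipeline in the
operating regime typical of few-channel sEMG gesture studies —
recognition well above chance but well below ceiling, rising steeply
with channel count — which is the regime in which channel
augmentation is worth studying at all. At ceiling the before/after
comparison is vacuous. The numbers are modelling constants, not
physiological claims.

**Seeding.** Every window's seed is derived from (master seed,
gesture id, window index) by fixed modular mixing below $2^{31}$, so
datasets are bit-reproducible and independent of generation order;
stage seeds (split, network init, subsampling) derive from the arm
seed the same way. The experiment drivers reuse one 4-channel
simulation per seed and subset columns for the 2- and 3-channel
configurations — one recording, fewer electrodes — so arms and
channel counts are compared on paired data.

**What the generator does not emulate** — and therefore what passing
tests do and do not show. Windows within a seed are exchangeable:
there is no fatigue, electrode shift, posture drift or other
session-scale non-stationarity, and no cross-subject anatomical
variation (each master seed plays the role of one statistically
identical "subject"). Consequences observed in the package's own
studies: (1) across-seed accuracy variability at small sample sizes
collapses to near-binomial test noise, so accuracy looks *less*
volatile across replicates than it does across human subjects and, at
3–4 channels, less volatile than SFV itself — the small-sample
contrast between accuracy and SFV shows up clearly only at 2
channels, where accuracy is low; (2) the accuracy benefit of
augmentation grows with channel count (more virtual channels), rather
than being largest at 2 channels; at 2 channels the paired gain is
within a point or two and not reliably positive across 20 replicates.
Motor-unit-level simulation and amputee-specific degradation are out
of scope.

## Problem sizes

The packaged studies use 150 windows per gesture (750 per dataset),
20 replicate seeds for the channel sweep and the subsample study, and
per-gesture subsample sizes 60/90/120/150 — the sizes at which the
accuracy-versus-SFV stability question is interesting. The structural
test suite runs on much smaller geometries (windows of 20–40 samples,
datasets of 12–15 windows per gesture) since the laws it checks are
size-independent.

## Known limitations

* SFV compares feature *sets* of different dimensionality ($I$ enters
  only through $c$'s averaging); it is a heuristic index, not a
  calibrated probability of correct classification.
* The min–max normalization makes SFV dependent on training-split
  extrema, which are noisy order statistics; in our replicates this
  contributes little across-seed variance (refitting on all data
  moves the across-seed CV of SFV by under half a point), but extreme
  outliers in real recordings would matter.
* The MPF feature is nearly class-uninformative under this generator
  (all classes share one passband); it is retained because the
  three-feature set is part of the method under study, and a
  dimension that mostly adds noise is itself informative about the
  method's robustness.
* `nnet`'s BFGS optimization is deterministic given a seed on one
  platform, but bit-level reproducibility across BLAS builds is not
  guaranteed; all packaged comparisons are paired within a platform.
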
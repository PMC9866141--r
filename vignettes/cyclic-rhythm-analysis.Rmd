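---
title: "Cycle-aligned analysis of rhythmically connected multichannel signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cycle-aligned analysis of rhythmically connected multichannel signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cyclorhythm)
```

## The model

`cyclorhythm` analyses an $N$-channel EEG recording acquired while an
operator repeats the same mental-control task $M$ times. The recording is
modelled as a *vector of cyclic rhythmically connected random processes*
$\xi_i(\omega, t)$, $i = 1, \dots, N$: there exists a single rhythm function
$T(t, n)$, shared by all channels, such that the joint finite-dimensional
distributions of the vector are invariant under the shift
$t \mapsto t + T(t, n)$ for every integer $n$. A rhythm function satisfies

1. $T(t, n) > 0$ for $n > 0$, $T(t, 0) = 0$, $T(t, n) < 0$ for $n < 0$;
2. $t_1 + T(t_1, n) < t_2 + T(t_2, n)$ whenever $t_1 < t_2$ (the shifted
   time axis never folds);
3. $T$ is smallest in modulus among all functions satisfying 1--2.

Each cycle (one trial) splits into two zones: a *passivity* zone (zone 1,
no mental action) and an *activity* zone (zone 2, the operator performs the
control action). The special case $T(t, n) = nT$ recovers the classical
cyclostationary (periodically correlated) model; real trials have variable
durations, so the rhythm is irregular and $T(t, 1)$ is not constant.

Because repeated trials are the *ensemble*, probabilistic characteristics
are estimated by averaging the recording across cycles at single-phase
points $t + T(t, n)$, not across time. This is what distinguishes the
approach from plain epoch averaging: epochs of different lengths are mapped
onto one another by the fitted rhythm function instead of being truncated
or resampled ad hoc.

## Rhythm-function estimation

Cycle and zone boundaries $\tilde t_{m,k}$ are assumed known from the
experimental protocol (`cycle_annotation`). At each boundary the one-step
rhythm function is known exactly:
$T(\tilde t_{m,k}, 1) = \tilde t_{m+1,k} - \tilde t_{m,k}$
(`discrete_rhythm()`). Between boundaries `rhythm_interpolant()` uses
piecewise-linear interpolation: on zone $(m, k)$,
$\hat T_{mk}(t) = g_{mk} t + b_{mk}$ with

$$g_{mk} = \frac{T(\tilde t_{m,k+1},1) - T(\tilde t_{m,k},1)}
                {\tilde t_{m,k+1} - \tilde t_{m,k}}, \qquad
  b_{mk} = T(\tilde t_{m,k+1},1) - g_{mk}\,\tilde t_{m,k+1}.$$

Strict monotonicity of the boundaries implies every $g_{mk} > -1$, hence
$t + \hat T(t, 1)$ is strictly increasing — the map from a zone onto the
same zone of the next cycle is an affine bijection. `validate_rhythm()`
checks positivity, the slope bound, continuity at the knots and exact knot
reproduction; minimality (property 3) holds by construction for the
interpolant of a valid discrete rhythm and is reported rather than
searched for.

Design choices that were genuinely open:

* **Multi-step values.** Only $\hat T(t, 1)$ is interpolated; $\hat T(t, n)$
  is defined by recursive composition
  $\hat T(t, n) = \hat T(t, 1) + \hat T(t + \hat T(t, 1), n - 1)$, and
  negative shifts by inverting the strictly increasing aligned-time map.
  This is the unique extension consistent with the knot values
  $\tilde t_{m+n,k} - \tilde t_{m,k}$ and it preserves monotonicity.
* **Domain.** $\hat T(\cdot, 1)$ is defined on
  $[\tilde t_{1,1}, \tilde t_{M,1}]$ — a one-step lookahead needs a
  successor cycle, so the last cycle's interior is excluded. Requests
  outside the domain are errors, not extrapolations: no extrapolation rule
  is implied by the interpolation construction.
* **Half-open zones.** Each zone is $[\text{start}, \text{end})$ and the
  final boundary closes the last cycle, which makes zone membership of
  every sample unambiguous for the indicator decomposition.
* **Discrete values from data.** The discrete rhythm readings are defined
  as successor-boundary differences; the boundaries themselves come from
  the protocol, not from the signal (automatic boundary detection is out of
  scope).

## Cycle-aligned estimators

Let $x(n, t) = \xi_i(t + \hat T(t, n))$ be the aligned sample of channel
$i$ at phase $t \in W_{c1}$ (the first cycle) in cycle $n + 1$
(`align_cycles()`). With $M$ cycles the package computes, per phase $t$:

* mean $\hat m(t) = \frac1M \sum_{n=0}^{M-1} x(n,t)$;
* dispersion $\hat d(t) = \frac1M \sum_n (x(n,t) - \hat m(t))^2$;
* initial moments $\hat m^{(k)}(t) = \frac1M \sum_n x^k(n,t)$;
* central moments
  $\hat d^{(k)}(t) = \frac1{M-1} \sum_n (x(n,t) - \hat m(t))^k$;
* mixed initial/central moments across channels and cycle lags with
  normalizations $1/(M - M_1 + 1)$ and $1/(M - M_1)$, where $M_1$ is the
  number of leading cycles spanned by the lagged arguments.

The mixed estimators take their lag times as *phase-preserving cycle
shifts* (`lag_cycles`): factor $j$ is evaluated at
$t + \hat T(t, n + \ell_j)$. Specifying lags this way keeps a configuration
meaningful for any irregular rhythm (an absolute offset in seconds would
point at different phases in different cycles); the same-phase
lag-one-cycle covariance, the quantity of interest for inter-trial
dependence, is `lag_cycles = c(0, 1)`.

Numerical conventions:

* **Normalizations are kept exactly as stated** ($1/M$ for the dispersion,
  $1/(M-1)$ for central moments), so the identity
  $\hat d = \frac{M-1}{M}\,\hat d^{(2)}$ holds to machine precision and is
  tested rather than "corrected".
* **Fractional sample times** are evaluated by linear interpolation between
  adjacent samples, matching the order of the piecewise-linear rhythm
  model. Interpolation weights within $10^{-6}$ of a sample snap to the
  exact sample, so integer-sample alignments (regular rhythm) are exact.
* **The mean at shifted arguments** $\hat m(t + \hat T(t,n))$ is taken as
  the cyclic extension $\hat m(t)$ — the estimate's own invariance under
  the fitted rhythm.
* **Last-cycle overflow**: an aligned time overrunning the recording by
  less than one sample period reuses the final sample (boundary rounding at
  the sampling rate); larger overruns are errors naming the failing cycle
  and phase.
* The default phase grid is the recording's own sample times inside the
  chosen zone of cycle 1, so a 2 s zone at 250 Hz yields a 500-point
  estimate.

## Preprocessing

The preprocessing chain mirrors standard EEG practice: a 3rd-order
Butterworth band-stop of $\pm 2$ Hz around the mains frequency (50 Hz, or
60 Hz via `f0`), then a 5th-order Butterworth band-pass, default 1--17 Hz.
Defaults apply the filters forward--backward (zero phase) so that no group
delay biases the cycle-phase alignment downstream; a causal mode exists for
streaming parity.

The filters are *designed* with `signal::butter()` but *applied* as a
cascade of second-order sections assembled from the design's zeros and
poles. The expanded 10th-order band-pass polynomial is numerically
ill-conditioned: direct-form filtering of it leaves relative errors around
$10^{-5}$, while the biquad cascade is linear to about $10^{-12}$. Each
section starts from its steady-state response to the signal's first sample
(step-response initialization), which removes most of the edge transient;
the remaining ring-down of the 1 Hz corner decays within roughly a second,
and is the caller's to discard. The notch bandwidth ($\pm 2$ Hz) and the
zero-phase default are package choices; both are documented parameters.

## Spectral features and sensitivity

`moment_spectrum()` takes the DFT of an estimate on its uniform phase grid
and reports one-sided magnitudes on the Fourier-coefficient scale
$|X_j|/P$, DC first. Energy is accounted with one-sided weights so the
total equals the mean-square energy of the grid signal (Parseval, checked
to $10^{-9}$ relative). `select_leading()` implements the
Bessel-inequality reduction: the smallest prefix $K$ of low-frequency
coefficients whose cumulative energy fraction reaches the threshold
(default 95%) — the discarded tail then carries at most 5% of the energy.
$K$ is minimal and monotone in the threshold. Magnitudes (not complex
pairs) form the feature vector, matching one-sided spectral displays and
yielding real-valued features; no windowing or detrending is applied
before the DFT.

`mean_absolute_distance()` scores the sensitivity of a characteristic to
the operator's action: the two zone estimates (or their spectra) are
compared by the mean absolute difference on a common normalized-phase grid
of $L$ points, $L$ defaulting to the shorter input so that zones of
unequal duration are compared without extrapolation; spectra are compared
on their first $L$ bins. Distances are computed on raw estimate values
(no normalization). `sensitivity_report()` assembles the
characteristic-by-channel table, ordered from the 4th-order initial moment
down to the mean — for a mean shift $\mu_1 \to \mu_2$ with $\mu > 1$ the
contrast $|\mu_2^p - \mu_1^p|$ grows with the order $p$, which is why
higher-order moments are the more sensitive detector inputs.

## The simulator

`simulate_recording()` generates data with exactly the structure the model
assumes, so every estimator can be validated against closed-form ground
truth (`true_moment()`):

* one rhythm shared by all channels; zone durations drawn uniformly from
  $d_k [1 - j, 1 + j]$ (default $d_k = 2$ s, jitter $j = 0.1$, a realistic
  trial-to-trial variability for voice-paced trials);
* per-zone mean profiles on normalized phase (sums of sinusoids plus
  offset; defaults: a 5 µV one-period wave in passivity, a 10 µV
  two-period wave in activity) and per-zone noise scales (defaults 2 and
  3 µV — activity noisier than rest);
* noise families with closed-form moments: Gaussian, or centred
  exponential for skew (third central moment $2s^3$, fourth $9s^4$ at
  scale $s$);
* inter-cycle dependence: AR(1) across the cycle index at fixed phase
  (default $\rho = 0.2$), restricted to the Gaussian family because an AR
  recursion does not preserve an exponential marginal;
* an optional Gaussian noise component shared across channels
  (`shared_sd`), giving a known cross-channel covariance.

Noise is realized on a per-zone canonical phase lattice of
$\mathrm{round}(d_k f_s)$ points with AR(1) recursion across cycles at
each lattice point; samples read the nearest lattice value, which
preserves the marginal law exactly. Random streams are split per channel
from the master seed, so adding channels does not reshuffle existing
draws. Within-cycle noise is independent across phases by default — this
keeps the analytic ground truth exact, and none of the estimators require
within-cycle dependence.

**What passing tests do and do not show.** The simulator emulates the
*cyclic structure* of multi-trial EEG — shared irregular rhythm, two-zone
cycles, zone-dependent moments, inter-trial dependence — not the
biophysics: there is no $1/f$ background, no alpha/beta band structure, no
ocular or muscular artifacts, and within-cycle samples are uncorrelated.
Parameter-recovery results therefore validate the estimators and the
alignment machinery, not the claim that real EEG follows the model.

One interpolation property matters when reading recovery numbers: if the
rhythm is jittered, aligned times fall between samples and linear
interpolation averages two *independent* noise draws, deflating pure-noise
second moments by up to one third (for real EEG, whose spectrum is
band-limited well below Nyquist, adjacent samples are strongly dependent
and the effect is far smaller). Recovery checks with two-sided tolerances
therefore use a lattice-aligned rhythm (jitter 0), where aligned values
are exact samples; irregular-rhythm behaviour is exercised by the rhythm,
partition and alignment tests, which are exact for any valid annotation.

## Problem sizes

The test suite and the acceptance script run at the scale of the study
design they emulate: 3 channels, 50 cycles of two 2 s zones at 250 Hz for
the end-to-end checks (500-point zone estimates), with larger cycle counts
(200--1000, single channel, shorter zones where only noise moments matter)
for consistency checks of the dispersion, fourth-moment and inter-cycle
covariance estimators. These sizes give Monte-Carlo standard errors
comfortably inside the stated tolerances.

## Known limitations

* Cycle/zone boundaries must be supplied; no boundary detection from the
  raw signal.
* Piecewise-linear rhythm interpolation only (no splines), and no
  extrapolation beyond the start of the last cycle.
* Moment closed forms in the simulator stop at order 4; higher orders can
  be estimated but not checked against `true_moment()`.
* Classifier training and the interaction stage of a full brain--computer
  interface are out of scope: the package ends at feature vectors and
  sensitivity tables.
* Multidimensional distribution and characteristic functions are model
  background; they are enforced by construction in the simulator, not
  estimated.
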
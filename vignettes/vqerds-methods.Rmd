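---
title: "Entropy-based ERD/S estimation with vector-quantized patterns"
author: "vqerds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Entropy-based ERD/S estimation with vector-quantized patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vqerds)
```

## The problem

Motor imagery (MI) — imagining a hand movement without executing it —
suppresses the mu rhythm (8–13 Hz) over the contralateral sensorimotor
cortex. This event-related desynchronization (ERD) and its rebound
(synchronization, ERS) are the workhorse features of motor-imagery
brain–computer interfaces. The classical estimator is a band-power
ratio: squared amplitude, averaged over many trials, expressed relative
to a pre-task baseline. It needs a trial ensemble and a well-behaved
reference interval, which makes single-trial work fragile.

`vqerds` implements an alternative family of single-trial ERD/S
estimators that track the *regularity* of the EEG instead of its power:
sliding-window entropy time-courses. Three estimators are provided on a
common delay-embedding:

* **SampEn** — sample entropy, $-\ln \pi(M{+}1)/\pi(M)$, where $\pi(M)$
  is the proportion of ordered pairs of length-$M$ delay vectors whose
  Chebyshev distance is below a tolerance $\rho$, self-matches
  excluded.
* **FuzzyEn** — the same ratio with the hard match count replaced by a
  Gaussian membership $\exp(-d^2/\rho)$ of the template distance.
* **VQEnt** — the package's central estimator: the delay vectors are
  compressed online into a codebook (a vector $\tilde x_q$ is admitted
  as a new code only if it is farther than $\rho$ from every existing
  code), a one-pass Gaussian-similarity model assigns memberships,
  per-code moments, likelihoods and priors, and the estimate is the
  Shannon entropy of the Bayes posterior over the $Q'$ codes,
  $H = -\sum_{q'} p(\bar x_{q'} \mid X) \ln p(\bar x_{q'} \mid X)$.

## Embedding conventions

A window of $N_\tau$ samples is embedded at dimension $M$ into
$Q = N_\tau - M$ contiguous delay vectors (note: *not* the more common
$N_\tau - M + 1$; the alphabet deliberately stops one vector short so
that the $M{+}1$-dimensional re-embedding of the same window loses
exactly one row). Pair statistics run over ordered pairs $q \neq q'$ in
both numerator and denominator, so $\pi$ is a proper proportion.
Logarithms are natural throughout; entropies are reported in nats.

When no pair matches at dimension $M+1$, SampEn's ratio is undefined
and the package returns `NaN` with a warning rather than capping the
value; sliding-window courses treat such windows as missing and exclude
them from trial averages (with a count in the course diagnostics).
Constant windows are treated as perfectly regular (entropy 0) by all
three estimators.

## Tolerance scaling: window vs trial

The tolerance is specified as a multiple $\rho$ of a signal standard
deviation. *Which* standard deviation matters more than it looks:

* For a **standalone** window (`sampleEntropy()`, `fuzzyEntropy()`,
  `vqEntropy()`), $\rho_{abs} = \rho \cdot sd(\text{window})$. This
  makes the estimate amplitude-invariant, which is the right behavior
  for comparing isolated segments.
* For a **sliding-window course** (`entropyErds()`, default
  `scale = "trial"`), the absolute tolerance is fixed once per trial
  and channel, $\rho_{abs} = \rho \cdot sd(\text{whole segment})$, and
  shared by every window of that trial.

The second convention is what makes the ERD visible to an entropy
estimator at all. During ERD the mu amplitude shrinks; with a
per-window tolerance the estimators are scale-invariant and see a
*noisier* (higher-entropy) mixture, so the course would *rise* where
the physiology says it falls. With the tolerance anchored to the whole
trial, the shrunken delay vectors fall inside fewer tolerance balls'
worth of distinct patterns — matches become easier, the codebook needs
fewer codes — and the course dips during the MI interval and recovers
afterwards, on the contralateral channel first. `scale = "window"` is
available for amplitude-normalized courses.

Two formula-level quirks are kept deliberately and documented here
because they affect invariances users might expect:

* FuzzyEn's membership is $\exp(-d^2/\rho_{abs})$ with $\rho_{abs}$
  *linear* in the signal scale while $d^2$ is quadratic. The estimator
  is therefore exactly translation-invariant but only loosely
  scale-stable. (The common alternative $\exp(-(d/r)^n)$ is
  scale-invariant; it is not what this method family prescribes.)
* VQEnt's admission rule compares the **squared** Euclidean distance
  against $\rho_{abs}$. This again ties the codebook to the amplitude
  scale. The `squared = FALSE` switch compares the plain distance
  instead and is exactly scale-invariant; it is the mode used by the
  package's own invariance tests. The squared rule remains the default
  because it is the method's printed form.

## The VQEnt model, step by step

Given the embedding rows $\tilde x_q$ and a codebook $\bar x_{q'}$
(first row always admitted; single online pass in input order, so the
construction is deterministic):

1. **Membership**: $\gamma_{q,q'} = \exp(-\lVert \tilde x_q - \bar
   x_{q'} \rVert^2 / 2\rho_{abs}^2)$, normalized across $q'$ — a
   row-stochastic soft assignment. $\rho_{abs}$ is the only scale
   parameter available, so it doubles as the similarity bandwidth.
2. **Moments**: $\mu_{q'}$ and scalar $\sigma^2_{q'}$ are the
   membership-weighted mean and variance of the inputs (weights
   normalized per code; a raw weighted sum would not be a mean). A
   collapsed code ($\sigma^2 = 0$) is floored at $10^{-12}$ times the
   squared data scale.
3. **Likelihood**: $p(X \mid \bar x_{q'})$ = mean over $q$ of the
   isotropic Gaussian similarity of $\tilde x_q$ to
   $(\mu_{q'}, \sigma^2_{q'})$.
4. **Prior**: mean membership per code (sums to 1 by construction).
5. **Posterior**: likelihood × prior, normalized; its Shannon entropy,
   bounded by $\ln Q'$, is the VQEnt value.

The membership→moments→likelihood order is a single pass with no
iteration; the construction in the source method is not fully explicit
about this order, and the one-pass reading is the package's choice. One
$\rho$ drives both the admission rule and the similarity bandwidth.

## Preprocessing

EEG trials are band-pass filtered (default 4–40 Hz, 5th-order
Butterworth) with zero-phase forward–backward application: group delay
would shift ERD/S latencies, which defeats the purpose of time-locked
courses. Signals are demeaned and reflection-padded before filtering,
so a pure offset is removed exactly and epoch edges carry no
transients. The effective attenuation order is twice the design order.
Filtering epochs (rather than the continuous record) with reflection
padding is a package choice, not method-prescribed.

The surface Laplacian (`laplacian()`) subtracts from each channel the
mean of its montage neighbors — the *small* Laplacian with symmetric
4-nearest-neighbor adjacency by default, configurable through the
`Montage` object for large-Laplacian variants. It suppresses volume
conduction leakage; on the synthetic generator's mixed data it
demonstrably restores the contralateral/ipsilateral band-power
contrast.

## The synthetic generator

`generateTrials()` emulates a cued two-class MI recording: 22 channels
(the standard 22-electrode MI montage, numeric labels, C3/C4 named) at
250 Hz, 7 s trials. Each channel carries $1/f$ background noise
(spectral shaping of white noise, unit variance); sensorimotor channels
add a mu oscillation (random frequency in 8–13 Hz, random phase, ±20%
trial-to-trial amplitude jitter, amplitude = `snr` × noise sd, weaker
on the non-central sensorimotor channels). On the class-contralateral
channel (right hand → C3, left hand → C4) the mu amplitude is
multiplied by `1 - erdDepth` inside `erdInterval` with 0.25 s cosine
ramps (avoiding spectral splatter at the boundaries). Optional
volume-conduction mixing blends each channel with its montage
neighbors (row-normalized mixing matrix). Everything is reproducible
bit-for-bit from the seed.

Defaults are chosen to be physiologically plausible: `erdDepth = 0.6`
(a strong but realistic mu suppression), `snr = 2`,
`erdInterval = c(2.5, 4.5)` s matching the paradigm's MI analysis
interval, 50 trials per class. An amplitude factor $1-d$ squares into
power, so depth 0.6 corresponds to a mu-band power ratio of
$0.4^2 - 1 = -0.84$ — the ground truth the power estimator is tested
against.

What the generator does **not** emulate: realistic head-model forward
mixing (the mixing matrix is adjacency-based, not a BEM), ocular/muscle
artifacts, non-stationary background spectra, inter-subject
variability, or genuine changes in neural *complexity* — its ERD is
purely an amplitude effect. Passing tests on this generator therefore
show that the estimators recover amplitude-mediated regularity changes
under $1/f$ noise; they do not certify performance on real EEG.

## Downstream analyses

* **Features and LDA** (`featuresFromCourses()`, `ldaCvAccuracy()`):
  per-trial entropy values of selected channels/windows, concatenated;
  missing SampEn windows imputed by the per-feature median. Linear
  discriminant analysis under seed-deterministic stratified 10-fold
  cross-validation, reported as mean ± sd on the 0–100 scale. The
  feature layout is a package choice (the method text does not state
  one).
* **Grid tuning** (`tuneGrid()`): exhaustive
  $\tau \in \{1, 1.5, 2\}$ s × $M \in \{1,2,3\}$ ×
  $\rho \in \{0.05, 0.1, 0.2, \ldots, 0.9\}$ (90 configurations) with
  90% window overlap; ties break toward the simpler model (smaller
  $M$, then $\rho$, then $\tau$) — a package choice.
* **Trial similarity** (`trialSimilarity()`):
  $d(n,n') = \exp(-\lVert H_n - H_{n'}\rVert^2 / \sigma^2_X)$ between
  single-trial courses of two estimators on one channel, with
  $\sigma^2_X$ the single-trial course variance averaged over the
  trial set; upper triangle right-label pairs, lower triangle
  left-label pairs.
* **Channel relevance** (`channelRelevance()`): per channel, the
  Euclidean distance between class-mean courses;
  `incrementalChannelAccuracy()` adds channels in decreasing relevance
  and reports the accuracy curve, optionally restricted to the ten
  sensorimotor channels.
* **Cluster permutation test** (`clusterPermutationTest()`): cell-wise
  two-sample $t$ statistics over the channel × window grid, clusters
  formed over temporal adjacency and montage spatial adjacency among
  same-sign cells exceeding the two-sided $t$ threshold at level 0.02,
  cluster mass = summed $t$ (the standard choice; the method text cites
  the approach without naming a statistic), and a max-mass Monte-Carlo
  null from label permutations. Type-I calibration at nominal 0.05 is
  part of the test suite (200 null simulations, 500 permutations each).

## Numerical and design choices

* Tolerance comparisons are strict (`d < rho`) for SampEn counting.
* JSON is the canonical interchange format (flat arrays + dimensions at
  17 significant digits, NaN positions stored explicitly), so
  round-trips are lossless; CSV is for course export. EDF/GDF readers
  are not bundled — those formats raise a clear error suggesting
  conversion.
* Intervals are half-open $[t_0, t_1)$ seconds from trial start;
  courses are indexed by window-*center* times so power and entropy
  trajectories share an axis.
* The power course's validity condition (task-related power excursion
  must dominate baseline scatter) is monitored on a 0.2 s-smoothed
  power course — the raw squared amplitude ripples at twice the mu
  frequency and would swamp the diagnostic — and reported as a
  variance-ratio warning below 10 (configurable), not an error.
* Problem sizes in the test suite and the acceptance script are
  deliberately desk-scale (tens of trials, 2–22 channels): large
  enough for every qualitative effect and significance threshold,
  small enough to re-run routinely. The vignette's and README's
  numbers come from those runs.

## Known limitations

* FuzzyEn and default-mode VQEnt are not scale-invariant (see above);
  compare entropies only across signals on a common scale, or use
  `scale = "trial"` courses where the tolerance is re-anchored per
  trial.
* The trial-anchored tolerance couples the course to the amplitude
  envelope; an amplitude-independent complexity change with constant
  variance would be better served by `scale = "window"`.
* VQEnt's greedy codebook is order-dependent by construction
  (deterministic, but a permuted window yields a different codebook).
* LDA with many features and few trials relies on MASS's
  within-fold behavior; constant features are dropped per fold and a
  degenerate fold falls back to the majority class.
* The cluster test assumes exchangeability of trials under the null;
  it does not model autocorrelation across trials (none exists in the
  generator).
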
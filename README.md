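# vqerds

Single-trial **event-related desynchronization/synchronization (ERD/S)**
estimation from motor-imagery EEG, using entropy time-courses on
delay-embedded sliding windows.

Imagining a hand movement suppresses the mu rhythm (8–13 Hz) over the
contralateral sensorimotor cortex. The classical ERD/S estimator is the
trial-averaged band-power ratio
ζ(t) = (ξ(t) − ξ̄)/ξ̄, with ξ(t) the squared amplitude averaged across
trials and ξ̄ its mean over a baseline interval. It needs a trial
ensemble and a reliable reference level. This package implements a
single-trial alternative — the entropy of the windowed signal tracked
over time — with three estimators on a common embedding
(Q = N<sub>τ</sub> − M delay vectors of dimension M, tolerance ρ as a
multiple of the signal sd):

* **SampEn**: −ln π(M+1)/π(M), π the proportion of ordered template
  pairs within Chebyshev distance ρ, self-matches excluded;
* **FuzzyEn**: same ratio with the Gaussian membership exp(−d²/ρ)
  replacing the hard count;
* **VQEnt** (the package's core): delay vectors are greedily compressed
  into a codebook (admit x̃ only if farther than ρ from every code), a
  Gaussian-similarity model yields memberships, per-code moments
  (μ<sub>q′</sub>, σ²<sub>q′</sub>), likelihoods and priors, and the
  estimate is the Shannon entropy of the Bayes posterior over the Q′
  codes: H = −Σ p(x̄<sub>q′</sub>|X) ln p(x̄<sub>q′</sub>|X) ≤ ln Q′.

Around the estimators the package provides the full workflow:
Butterworth band-pass + surface-Laplacian preprocessing, epoching,
sliding-window course extraction (power and entropy on one time axis),
a synthetic two-class MI-EEG generator with known ERD ground truth, and
the discrimination analyses — (τ, M, ρ) grid tuning, stratified 10-fold
LDA accuracy, trial-similarity matrices, channel relevance ranking,
incremental channel selection, and cluster-based permutation testing
with montage-aware spatial adjacency.

For whom: BCI and EEG researchers who want single-trial ERD/S features
without a power baseline, and anyone studying regularity/complexity
dynamics of narrow-band oscillations against 1/f noise.

## Worked example

Generate a two-class synthetic MI set (60% mu suppression on the
contralateral channel during [2.5, 4.5) s), band-pass it, and extract
the VQEnt course:

```r
library(vqerds)

spec <- synthSpec(nTrialsPerClass = 20L, nChannels = 2L,
                  erdDepth = 0.6, seed = 42)
trials <- bandpass(generateTrials(spec))
trials
#> TrialSet: 40 trials x 2 channels x 1750 samples at 250 Hz
#> labels
#>  left right
#>    20    20
#> MI window: [2.5, 4.5) s  reference: [0.5, 1.5) s

seg  <- extractWindow(trials, c(0.5, 6.5))   # ERD now at [2, 4) s
plan <- planWindows(trialDuration(seg), tau = 1, overlap = 0.9,
                    rate = sampleRate(seg))
course <- entropyErds(seg, plan,
                      entropyParams(m = 2L, rho = 0.3,
                                    estimator = "vqent"))
course
#> ErdsCourse (entropy, vqent): 2 channels x 51 time points [0.5, 5.5] s
#> per-trial courses retained for 40 trials
```

During right-hand imagery the *contralateral* channel (C3) should carry
less entropy than the ipsilateral one (C4) inside the MI interval — the
ERD signature:

```r
right <- trialLabels(seg) == "right"
inMI  <- timeAxis(course) >= 2.2 & timeAxis(course) < 3.8
pt    <- perTrialCourses(course)
round(c(C3 = mean(pt[right, 1, inMI]), C4 = mean(pt[right, 2, inMI])), 2)
#>   C3   C4
#> 2.11 2.66
```

C3 sits about 0.55 nats below C4: the quantizer needs fewer codes where
the mu amplitude is suppressed. A single window can also be inspected
directly:

```r
h <- vqEntropy(trialData(seg)[1, 1, 376:625], m = 2L, rho = 0.3)
round(as.numeric(h), 3)   #> 2.758
attr(h, "qPrime")         #> 18
```

(2.758 nats over an 18-code codebook; the upper bound is ln 18 ≈ 2.89.)

A one-command synthetic study — courses for all estimators, relevance,
accuracy-vs-channels curve, cluster test, plots — is available as
`runDemo()` or from the shell:

```sh
Rscript inst/scripts/vqent.R demo --out report/
```

## Layout

* `R/` — S4 classes (`TrialSet`, `Montage`, `ErdsCourse`, `VQModel`,
  …) and the exported workflow functions (camelCase).
* `src/` — Rcpp kernels for pairwise template matching and codebook
  construction.
* `inst/scripts/vqent.R` — thin CLI (`simulate`, `erds`, `tune`,
  `relevance`, `permtest`, `demo`).
* `vignettes/vqerds-methods.Rmd` — the model, its conventions
  (tolerance scaling, embedding size, degenerate cases), the generator
  and its limits, and the package's design choices.
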
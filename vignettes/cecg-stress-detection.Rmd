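---
title: "Stress-level detection from capacitive ECG: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stress-level detection from capacitive ECG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cecgstress)
```

## The problem

Capacitive ECG (cECG) couples to the body through clothing, which makes it
usable in a car seat but also makes it fragile: any subject movement
produces *coarse artifacts* — transients whose amplitude dwarfs the
cardiac signal — and the waveform quality is usually too poor to delineate
anything beyond the R peak. A stress classifier for driving therefore has
to (a) discard corrupted stretches rather than try to repair them, (b) use
only features that survive R-peak-only analysis, and (c) be evaluated in a
way that respects heavy class imbalance and between-subject variation.
`cecgstress` implements exactly that pipeline, plus a synthetic generator
that stands in for real recordings so the whole chain is testable.

## Artifact reduction

The signal `x` (always millivolt internally) is centralized and cumulated
into the profile `Y(i) = Σ_{k≤i}(x_k − x̄)`, which converts amplitude
outliers into slope changes. `Y` is cut into non-overlapping segments of
`SL` samples and each segment's **detrended fluctuation** `FD_j` is the
mean squared residual around its own linear least-squares fit. An
interval of pure baseline or pure offset is (almost) linear in `Y` and
yields `FD ≈ 0`; a beat-bearing segment yields a moderate `FD`; a segment
containing an artifact *edge* yields an enormous one.

Three decision rules act on the `FD` sequence:

* **Coarse gate.** Elimination only runs when
  `(max x − min x)/2 − E[x²] > 1`. The half-range grows linearly with
  artifact amplitude while the second moment grows with artifact *energy*
  (amplitude² × coverage), so the gate fires for large transients of
  modest duration — the signature of subject motion — and stays silent on
  clean recordings, which then pass through bit-identically. A corollary
  worth knowing: an extremely energetic artifact regime (tens of mV
  sustained over a large fraction of the record) can push `E[x²]` above
  the half-range and silence the gate; the criterion is designed for
  transients, not for wholesale corruption.
* **Threshold `TH1`.** Segments with `FD_j > TH1` are eliminated, with
  `TH1` scaled by the squared half-range, the constant `C` (default 0.25,
  the midpoint of the admissible 0.15–0.35), and a ratio of robust
  (`median FD`) and dispersion (`SD(FD)`, `SD(x)`) statistics, normalized
  by `C1 = 1` mV. The full expression lives in one function
  (`compute_th1()`) so an alternative grouping of the formula is a
  one-line change. Near the firing threshold — artifacts only a few times
  the R amplitude — `TH1` is itself small and sits close to the clean
  `FD` level, so elimination counts are not monotone in artifact
  amplitude there; in the coarse regime (≳5–10× the R amplitude) they
  are, and the test suite asserts monotonicity over that grid.
* **Spill-over.** A neighbour of an eliminated segment whose `FD` differs
  from it by more than `TH2 = TH1/2` is eliminated too. This is also what
  catches the interior of long artifacts: a segment *fully inside* a
  constant-offset artifact is linear in `Y` and has a clean-looking `FD`,
  but it borders an edge segment with a huge one.
* **Slow-changing artifacts.** Only when `mean(FD) − SD(FD) > TH3`
  (`TH3 = 0.1`), segments with `FD_j < TH3` are eliminated. The
  comparison direction deserves a note, because the rule is stated
  ambiguously in the literature this follows: slow-changing artifacts are
  *small deviations from the linear trend*, i.e. **low**-fluctuation
  segments (drift with no cardiac content), and the guard condition only
  makes sense as protection for recordings whose fluctuation level is
  globally small — if elimination targeted high-FD segments instead, any
  clean mV-scale recording (whose beat-bearing segments all have
  `FD ≫ 0.1`) would be annihilated by its own preprocessing. We therefore
  eliminate `FD_j < TH3` under the gate.

The `SL` default is one second of samples — about one cardiac cycle, so a
transient dominates its segment — and is configurable. The denoised
output concatenates the kept segments (the time axis is compressed); when
nothing is eliminated the input is returned untouched, including a
trailing part-segment. If everything is eliminated the result carries an
`empty_output` flag rather than throwing.

## Features

All four features are computed per non-overlapping 50-s window, a length
chosen to turn few long recordings into enough samples for
cross-validation while keeping several dozen beats per window:

* **R value** (mV): mean detected R amplitude (median by flag). The
  R peak is the one fiducial point reliably detectable in cECG.
* **HR** (beats/min): `60000/RRI`; the window summary is the mean of
  instantaneous rates (the `60000/mean(RRI)` alternative is a flag).
* **pNN50**: fraction of |successive NN differences| > 50 ms, absolute
  values per the standard convention. NN intervals are RR intervals
  *after* artifact reduction, which is why preprocessing is obligatory.
  With fewer than two intervals the feature is an explicit `NA`.
* **BinEn** (nats): binarized approximate entropy of the window's raw
  samples (not RR series), `Φ̂(m) − Φ̂(m+1)` with both orders on the sign
  sequence of first differences, `m = 2`, `τ = 1`, Hamming tolerance
  `r = 0`. The tolerance default is our choice — for binary symbols exact
  matching is the natural metric and makes BinEn a conditional-entropy
  rate — and `r` is exposed as a parameter. Counting binary embedding
  vectors (2^m cells) plus a 2^m × 2^m Hamming matrix makes the estimator
  linear in N; a naive O(N²) pairwise estimator exists in the test suite
  purely as an oracle and agrees to 1e−12 over all `m ∈ 1..4`,
  `r ∈ 0..m`. For an i.i.d. difference-sign process BinEn → ln 2, which
  the suite verifies by simulation. Only difference *signs* enter, so the
  statistic is invariant to strictly monotone transforms of the signal.

The R-peak detector is a Pan-Tompkins-family pipeline (moving-average
band-limit, derivative, squaring, 150 ms integration, adaptive threshold,
refinement to the raw-signal maximum, 250 ms refractory rule). Windows
with fewer than two detected beats are dropped and logged, not errored.

## Classification and evaluation

Features are z-scored with statistics fitted on training rows only.
Three classifier families are built in (none of the usual R packages for
them is assumed to be present, and the network shape is part of the
method):

* **kNN**, Euclidean. The literal rule of thumb "k equal to the size of
  the training set" degenerates to a constant majority-class vote, so the
  default is `k = round(√n)` forced odd; the literal mode survives behind
  `literal_k = TRUE`.
* **SVM** with RBF kernel (`γ = 1/d` on z-scored features, `C = 1`),
  solved by a simplified SMO; kernel choice unstated upstream, RBF is the
  standard default for low-dimensional continuous features, and a linear
  kernel is a flag.
* **ANN**: two hidden layers of 20 tanh units, tanh output on ±1 targets,
  MSE loss, full-batch backpropagation at learning rate 0.5, up to 500
  epochs with early stopping on a training-loss plateau (stopping was
  unstated; a plateau rule keeps the configuration honest without a
  validation split). Initialization is seed-controlled, so training is
  exactly reproducible.

Evaluation is **subject-grouped k-fold cross-validation** (default 5
folds, fold count being configuration, not doctrine): all windows of one
subject live in one fold, each class's subjects are spread round-robin
across folds, and normalization plus model fitting never see test-fold
rows. The metric set — balanced accuracy (percent), sensitivity,
specificity, PPV, NPV, MCC — is imbalance-aware, with the positive class
fixed to the *higher* stress level. Any metric with a zero denominator is
reported as an explicit undefined marker (`NA`), never silently dropped
at the fold level: aggregates exclude undefined folds and count them
separately, since there is no principled way to average an undefined
sensitivity into a mean.

## The synthetic generator: what it does and does not establish

Each beat is a sum of five Gaussian bumps (P, Q, R, S, T) with fixed
relative offsets and widths scaled to the local RR interval — the
simplest shape with a dominant, sample-aligned maximum at R, which is the
only morphology the pipeline exploits. RR intervals are Gaussian with
configurable mean/SD, truncated at 250 ms; baseline wander is a low-
frequency sinusoid; coarse artifacts are rectangular-plus-spike
transients at 10× the R amplitude by default (peaking at 1.5× that), with
per-sample ground-truth masks. Stress classes differ by construction:
higher stress = shorter mean RR (80 vs 60 bpm by default) and lower RR
variability, the direction in which HR and pNNx separate stress levels;
the magnitudes are generator choices, not empirical claims. Five
synthetic subjects per class receive a 1.5 % multiplicative RR jitter so
grouped splitting is meaningful.

Consequently a green end-to-end test establishes that the pipeline
*recovers a class difference it was configured to contain* through
artifact reduction, detection, feature extraction and grouped
cross-validation — it does not establish field performance on real
driving cECG, whose artifact statistics, electrode dropouts, morphology
changes and stress physiology are all richer than this model. Published
balanced accuracies on the real driving databases (reported near or
above 95 %) are reproducible only with those external datasets; the
package's evaluation machinery (feature CSVs in, per-fold and aggregate
metrics out) is the part that would be pointed at them.

## Numerical and interface choices

* Amplitudes are mV everywhere internally; the coarse-gate constant 1 and
  `C1 = 1` mV are numeric under that convention (their units are not
  resolvable from the source material; the convention is documented, not
  guessed further).
* The coarse gate is evaluated globally per analysis window (the
  per-segment alternative is ambiguous in the source); segmentation uses
  floor division and discards the trailing remainder except in the
  untouched pass-through case.
* The segment fit uses closed-form normal equations on a common abscissa;
  the test oracle uses `lm()`'s QR factorization — agreement to 1e−9
  relative is asserted on random profiles.
* z-scoring uses the sample SD (n−1); `[1, 2, 3]` maps to `[−1, 0, 1]`.
* kNN ties break toward the nearest neighbour's class; the SMO uses
  `tol = 1e−3` and seed-controlled partner selection.
* Every stochastic function takes a `seed` argument applied via a
  preserved-RNG wrapper, so library calls never disturb the caller's RNG
  stream and the whole pipeline is bit-reproducible for a fixed seed.
* Degenerate inputs error early and namely (constant signal in `TH1`,
  zero-variance feature in normalization, single-class training set);
  conditions that are legitimate outcomes (no peaks, empty denoised
  output, undefined metric) are values or flags, not exceptions.

## Known limitations

* The beat model is not ECGSYN-grade; T/P morphology, respiration
  coupling and electrode-contact dynamics are absent by design.
* Artifact parameters are knobs, not claims — no quantitative artifact
  model for driving cECG is available to emulate.
* The coarse gate's energy envelope (above) means wholesale corruption is
  out of scope; the method eliminates, it never reconstructs.
* WFDB support covers header + signal formats 16 and 212, enough for
  PhysioNet-style records; other formats and multi-segment records are
  not read.
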
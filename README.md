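# cecgstress

Detecting driver stress levels from single-channel **capacitive ECG
(cECG)** — ECG recorded without skin contact through clothing, e.g. by
electrodes built into a car seat or a cushion. cECG is attractive for
unobtrusive in-vehicle monitoring but is plagued by very high-amplitude
*coarse artifacts* whenever the subject moves, and its waveform quality
rarely permits more than reliable R-peak detection.

`cecgstress` implements the complete pipeline for this setting, for
researchers in physiological computing and biomedical signal processing:

1. **Artifact reduction.** The signal `x` (mV) is turned into its
   centralized cumulative-sum profile `Y(i) = Σ_{k≤i}(x_k − x̄)` and cut
   into segments of `SL` samples (default one second). Each segment's
   detrended fluctuation `FD_j = (1/SL) Σ_k (Y_j(k) − p_{j,1}(k))²` is the
   mean squared residual around the segment's own linear fit. When the
   coarse-artifact criterion `(max x − min x)/2 − E[x²] > 1` holds,
   segments with `FD_j > TH1` are eliminated, where

   `TH1 = (((max x − min x)/2)² − E[x²]) · C · (median FD + SD(FD) + SD(x)) / (SD(FD) · SD(x) · C1)`

   with `C = 0.25` (admissible range 0.15–0.35) and `C1 = 1` mV. Neighbours
   whose fluctuation differs from an eliminated segment's by more than
   `TH2 = TH1/2` are eliminated too (artifact spill-over), and a slow-artifact
   rule removes fluctuation-free (drift-only) segments via the `TH3 = 0.1`
   threshold. The denoised signal is the concatenation of the kept segments.
2. **Four features per 50-s window**, all derived from the only fiducial
   point that is dependable in cECG, the R peak: mean R amplitude (mV),
   heart rate `HR = 60000/RRI` (beats/min), `pNN50` (fraction of successive
   NN-interval differences > 50 ms), and **BinEn**, a binarized
   approximate entropy `BinEn = Φ̂(m) − Φ̂(m+1)` computed in linear time on
   the sign sequence of the signal's first differences (defaults `m = 2`,
   `τ = 1`, Hamming tolerance `r = 0`).
3. **Classification + evaluation.** kNN (Euclidean, `k ≈ √n` odd), an
   RBF-kernel SVM, and a two-hidden-layer feed-forward network (20 tanh
   units per layer, MSE loss, backpropagation, learning rate 0.5), with
   subject-grouped cross-validation and imbalance-aware metrics: balanced
   accuracy, sensitivity, specificity, PPV, NPV and Matthews correlation
   coefficient, with explicit `undefined` markers when a denominator is
   zero.
4. **A synthetic cECG generator** (Gaussian-bump PQRST beats, controllable
   RR mean/SD, baseline wander, noise, rectangular-plus-spike motion
   artifacts) with per-sample ground truth, so every stage is testable
   without external recordings.

## Worked example

```r
library(cecgstress)

cfgs <- default_stress_configs()            # 60 vs 80 bpm, mild artifacts
ds   <- gen_labeled_dataset(cfgs$low, cfgs$high,
                            n_windows_per_class = 20, seed = 5)
ft   <- dataset_features(ds)                # preprocess + 4 features/window
aggregate(cbind(hr_bpm, pnn50, binen, r_value_mv) ~ label, ft, mean)
#>         label   hr_bpm     pnn50     binen r_value_mv
#> 1 high_stress 80.35469 0.1464429 0.6649810  0.9993459
#> 2  low_stress 61.11477 0.5487074 0.6608483  1.0035240

cross_validate(ft, kind = "ann", n_folds = 5, seed = 5)
#> <cv_result> ann, 5 folds (subject-grouped)
#>   balanced_accuracy   100.000 +- 0.000
#>   sensitivity           1.000 +- 0.000
#>   specificity           1.000 +- 0.000
#>   ppv                   1.000 +- 0.000
#>   npv                   1.000 +- 0.000
#>   mcc                   1.000 +- 0.000
```

The two classes were generated with mean RR 1000 ms vs 750 ms, and the
recovered per-class heart rates (61.1 / 80.4 bpm) match; `pNN50` drops in
the high-stress class because its RR variability is lower; the R value and
BinEn barely move here because the generator shifts only the RR
distribution. With this clear a separation every classifier reaches 100 %
balanced accuracy under subject-grouped 5-fold cross-validation.

A command-line front end covering `simulate`, `preprocess`, `features`,
`binen`, `evaluate` and `run-all` ships in `inst/cli/cecgstress`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","cecgstress",package="cecgstress"))')" \
    simulate --out sim.csv --duration 120 --artifact-rate 2 --seed 7
```

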
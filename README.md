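# nirsbci

Subject-independent classification of functional near-infrared spectroscopy
(fNIRS) signals, for brain–computer interface (BCI) research.

fNIRS measures cortical hemodynamics with near-infrared light: mental effort
(here, serial-subtraction mental arithmetic, **MA**) raises oxy-hemoglobin
(ΔHbO) and lowers deoxy-hemoglobin (ΔHbR) relative to an idle state (**IS**).
Because these signals are strongly subject-specific, fNIRS BCIs normally need
a calibration session per user. This package implements a pipeline for the
*subject-independent* alternative — train on other people, test on a new
person — evaluated with leave-one-subject-out cross-validation (LOSO-CV):

* **Preprocessing** — modified Beer–Lambert law conversion from 3-wavelength
  optical density (780/805/830 nm) to (ΔHbR, ΔHbO) via the fixed matrix

  ```
  [ ΔHbR ]   [  1.8545  -0.2394  -1.0947 ] [ ΔOD780 ]
  [ ΔHbO ] = [ -1.4887   0.5970   1.4847 ] [ ΔOD805 ]   (mM·cm)
                                           [ ΔOD830 ]
  ```

  zero-phase 6th-order Butterworth band-pass at 0.01–0.09 Hz, epoching to
  [0, 15] s windows (201 samples at 40/3 Hz) with (−1, 0) s baseline
  correction, per-trial z-scoring over time.
* **Classifiers** — shrinkage LDA (Ledoit–Wolf analytic intensity) on 96
  temporal mean-amplitude features (16 channels × 2 chromophores × 3 windows);
  a bagged ensemble of 50 regularized LDAs (γ = 0.1, majority vote); EEGNet
  (temporal → depthwise-spatial → separable convolutions, F1 = 8, D = 2,
  F2 = 16); and a 1-D CNN with EvoNorm-S0 normalization-activation layers
  (two valid convolutions, 32 filters, kernels 13/6, strides 9/4). The
  networks — forward passes, analytic gradients, Adamax, early stopping — are
  implemented in base R and verified against finite differences.
* **Evaluation** — LOSO-CV with a trial-fingerprint leakage audit, a
  pseudo-online subject-dependent learning curve (train on the
  chronologically first N trials per class), and an exact Wilcoxon
  signed-rank test.
* **Synthetic data** — a multi-subject generator emulating the paradigm
  (2 s instruction, 10 s task, 16–18 s rest, 30 trials per class, 16
  channels): HRF-convolved boxcar responses, anti-correlated HbR,
  physiological noise (Mayer/respiratory/cardiac), drift, and log-normal
  subject gains, so the whole pipeline runs and is tested without any
  download.
* **I/O** — SNIRF read/write (HDF5, bridged through a bundled Python h5py
  helper), plus a fast internal RDS + JSON-manifest dataset format.

## Worked example

```r
library(nirsbci)

# simulate 4 subjects, 30 trials per class, and preprocess to epochs
cfg <- sim_config(n_subjects = 4, trials_per_class = 30, seed = 7)
ds  <- simulate_epochs(cfg)

# subject-independent evaluation with shrinkage LDA
report <- run_loso(ds$epochs, model = "slda", seed = 0)
print(report)
#> <evaluation_report> slda: mean accuracy 69.58% +/- 9.46% (sd) over 4 subjects
round(100 * report$per_subject_accuracy, 1)
#>  S01  S02  S03  S04
#> 76.7 76.7 56.7 68.3

# subject-dependent learning curve: how many calibration trials per class
# would a within-subject classifier need?
curve <- run_pseudo_online(ds$epochs, n_grid = c(4, 12, 20))
attr(curve, "summary")
#>   n_train_per_class  accuracy
#> 1                 4 0.5192308
#> 2                12 0.6458333
#> 3                20 0.6875000
```

The LOSO mean (69.6% here) is each held-out subject's accuracy when the
classifier never saw any of their data. The learning curve shows the
competing subject-dependent route: with only 4 calibration trials per class
the within-subject classifier is near chance, and it needs on the order of
12–20 trials (several minutes of recording) to catch up with the
calibration-free subject-independent accuracy — the practical argument for
subject-independent BCIs. Networks run the same way, e.g.
`run_loso(ds$epochs, model = "cnn")` or `model = "eegnet"` (slower; training
is pure R).

A thin command-line front end wraps the same functions:

```sh
inst/cli/nirsbci simulate --subjects 18 --seed 0 --out data/
inst/cli/nirsbci loso --model slda --subjects 6 --seed 0
inst/cli/nirsbci curve --n 2:28:2 --subjects 6
```

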
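# bcgscreen

Hypertension screening from ballistocardiogram (BCG) signals.

Ballistocardiography records the micro-vibrations that cardiac ejection
imparts to the body; mattress-embedded pressure sensors capture them at
100 Hz without electrodes, making BCG a candidate for long-term home
monitoring of blood pressure status. `bcgscreen` implements an
end-to-end screening pipeline for such recordings, aimed at biomedical
signal-processing researchers who want a tested, reproducible reference
implementation:

* a **synthetic BCG generator** — quasi-periodic heartbeat complexes,
  respiratory wander, drift, noise and movement artifacts, with
  class-dependent heart rate (normotensive 73.6 ± 8.3 bpm, hypertensive
  77.1 ± 9.2 bpm) and beat amplitude — standing in for clinical
  recordings, which are not publicly available;
* a four-stage **preprocessing chain**: zero-phase Butterworth high-pass
  (1 Hz) and low-pass (50 Hz, clamped below Nyquist), one-sided
  `mean + 2σ` anomaly removal, 0.5 Hz baseline correction, min–max
  normalisation to [0, 1];
* **feature extraction**: non-overlapping 30-s windows (3,000 samples at
  100 Hz), summarised per channel by 11 statistics (mean, sd, median,
  max, min, range, Q1, Q3, IQR, kurtosis, skewness);
* four **classifier families**, the neural ones implemented from scratch
  with analytic backpropagation: an FC(512)–FC(256)–2-layer-LSTM(128)
  network, a 3-layer/4-head Transformer encoder with mean pooling, a
  stacking ensemble (random forest + gradient boosting + XGBoost with a
  logistic meta-learner on out-of-fold probabilities) and a soft-voting
  ensemble;
* an **evaluation harness**: hold-out (50%/25%) and stratified k-fold
  cross-validation, group-aware by default so segments of one recording
  never straddle a split; accuracy, F1, precision, Jaccard, Cohen's
  kappa `(P_o − P_e)/(1 − P_e)`, sensitivity, specificity, ROC/AUC
  (trapezoid ≡ Mann–Whitney), and McNemar's paired test
  `χ² = (b − c)²/(b + c)`.

## Worked example

```r
library(bcgscreen)

# simulate a labeled cohort: 10 recordings per class, 2 min each
cfg  <- synthetic_config(duration_s = 120, seed = 42)
recs <- generate_dataset(cfg, n_per_class = 10)

# preprocess, segment into 30-s windows, extract features
pre  <- lapply(recs, preprocess_recording)
segs <- unlist(lapply(pre, segment_recording), recursive = FALSE)
tbl  <- build_feature_table(segs)
dim(tbl)
#> [1] 80 25      # 80 segments x (22 features + label, source_id, start_sample)

# train and evaluate the FC+LSTM classifier, 25% group-aware hold-out
rep <- evaluate_model("fclstm", tbl, scheme = "holdout:0.25", seed = 42)
rep
#> <bcg_eval_report> holdout:0.25
#>    accuracy          f1   precision     jaccard       kappa sensitivity
#>      0.7500      0.7368      0.6364      0.5833      0.5098      0.8750
#> specificity         auc
#>      0.6667      0.8229
```

Five unseen recordings (20 segments) are held out; the classifier ranks
their segments with AUC 0.82 on this small cohort. The hypertensive
generator's larger beat-to-noise ratio survives per-recording min–max
normalisation as a shape difference the window statistics pick up; at
the package's reference cohort size (30 recordings per class, 5 min
each) the same evaluation reaches AUC ≈ 0.90. On a cohort built with
`null_config()` (both classes identical) the same call evaluates at
chance — the guard the test suite uses against split leakage.

A thin command-line front end over the same functions is installed at
`inst/cli/bcg.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/bcg.R", package="bcgscreen"))')" \
    run --out run1 --n-per-class 10 --duration 120 --model fclstm \
    --scheme holdout:0.25 --seed 42
```

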
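# resbilstm

Human activity recognition (HAR) from multi-channel inertial sensor
streams: a residual convolutional block feeding a bidirectional LSTM,
implemented end to end in R for researchers and engineers working with
wearable IMU data (digital-health studies, gait labs, activity-tracking
prototypes).

Raw tri-axial accelerometer and gyroscope streams are z-scored per channel,

```
x' = (x − μ) / σ          (μ, σ over the whole corpus, per channel)
```

cut into overlapping windows (default L = 100 samples, 50% overlap), and
classified by the network

```
input (L × C × 1)
 ├─ conv 32 @ 2×2, stride 2, same → BN → ReLU
 │   └─ conv 32 @ 2×2, stride 1, same → BN → ReLU   (stacked path f(x))
 └─ conv 32 @ 2×2, stride 2, same → BN              (shortcut h(x))
 add: y = f(x) + h(x) → ReLU
 reshape → sequence of ⌈L/2⌉ steps × ⌈C/2⌉·32 features
 BiLSTM (64 units per direction; i/f/c̃/o gate equations, final states
         of both directions concatenated → 128)
 dropout 0.5 → dense → softmax over K activities
```

trained with Adam on categorical cross-entropy. Evaluation uses the
confusion matrix (rows = true, columns = predicted), per-class
precision/recall/F1 and the support-weighted F1, `Fw = Σᵢ ωᵢ·F1ᵢ`. For a
40 × 3 window and 6 classes the model has exactly **71,462** trainable
parameters (conv block 4,640 + BiLSTM 66,048 + dense 774).

A seeded synthetic IMU generator (six activities with realistic class
imbalance, gait harmonics for dynamic classes, near-constant gravity
offsets for postures, occasional spikes) makes the whole pipeline runnable
and testable with no external data. Readers for WISDM raw text and PAMAP2
protocol `.dat` files are included for real corpora.

## Worked example

```r
library(resbilstm)

x  <- generate_imu_dataset(generator_config(total_duration = 1800, seed = 11))
ds <- x |> standardize_channels() |> segment_windows(100, overlap = 0.5)
ds
#> # windowed dataset: 1709 windows of 100 samples x 6 channels, 6 classes
#> downstairs    running    sitting   standing   upstairs    walking
#>        170        163        731        214        185        246

fit <- fit_res_bilstm(model_config(100, 6, 6), ds,
                      train_config(learning_rate = 3e-4, epochs = 6, seed = 3),
                      verbose = TRUE)
#> epoch   1  loss 1.4043  acc 0.5564  val_loss 1.1724  val_acc 0.7461
#> epoch   3  loss 0.4340  acc 0.9031  val_loss 0.2908  val_acc 0.9609
#> epoch   6  loss 0.0767  acc 0.9992  val_loss 0.0365  val_acc 1.0000

glance(fit)
#> # A tibble: 1 × 6
#>   epochs parameters   loss accuracy val_loss val_accuracy
#>        6      87846 0.0767    0.999   0.0365            1

val <- fit$val_indices
cm  <- confusion_matrix(as.character(ds$labels[val]),
                        as.character(predict(fit, ds$windows[val, , ],
                                             type = "class")),
                        levels = ds$class_levels)
accuracy(cm)      # 1.0000
weighted_f1(cm)   # 1.0000
```

The 30-minute synthetic corpus yields 1,709 windows; the six synthetic
classes are well separated by construction, so the 87,846-parameter model
reaches perfect validation accuracy within a few epochs — the run
demonstrates the pipeline, not real-world difficulty. `autoplot(fit)` draws
the four training curves and `autoplot(cm)` the confusion heatmap;
`per_class_metrics(cm)` and `format_metric_table(cm)` give the per-class
readout with the trailing PRC row / RCL, F1S columns layout.

A command-line front end with `generate`, `preprocess`, `train`,
`evaluate`, `sweep`, `run` and `report` subcommands lives at
`inst/cli/resbilstm-cli.R` (located after installation via
`system.file("cli", "resbilstm-cli.R", package = "resbilstm")`).

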
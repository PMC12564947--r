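# boluseg

Unsupervised segmentation of bolus and residue in videofluoroscopic
swallowing study (VFSS) frames, for swallowing researchers and medical
image analysts who have frame recordings but no pixel-level annotations.

In a VFSS, a patient swallows barium-labeled material under dynamic X-ray;
tracking the bolus and spotting post-swallow residue are central to
dysphagia assessment. Supervised segmentation needs per-pixel masks that are
costly and unreliable to annotate. `boluseg` instead learns *normal*
anatomy: a convolutional autoencoder is trained only on bolus-free frames,
so unseen structures — bolus, residue — reconstruct poorly at inference and
the reconstruction-error map becomes the segmentation signal.

## Method at a glance

Treating the background intensity at pixel \((x, y)\) as
\(I(x,y) \sim N(\mu_{x,y}, \Sigma_{x,y})\), an autoencoder without location
information can only learn globally aggregated appearance, so an anomaly
\(\mu_{x,y} + \Delta\) whose appearance occurs elsewhere in normal anatomy
is reconstructed faithfully and missed. Two fixed sinusoidal positional-
encoding (PE) channels,

PE(x, y) = [ sin(2πx/W), cos(2πy/H) ],

are concatenated with the image so the model can learn location-conditioned
appearance \(\mu_{x,y}\); the reconstruction error at an anomalous location
then scales with \(\lVert\Delta\rVert\). The architecture is a three-block
convolutional encoder (64/128/256 filters, batch norm, ReLU, dropout 0.1 in
block 1, 2×2 max-pool) with a mirrored transpose-convolution decoder, skip
connections at matching resolutions, and a sigmoid head — about 1.18 M
trainable parameters. Training minimizes the hybrid loss

L = L_MSE + λ · L_edge,  λ = 0.05,

(edge term = forward-difference image gradients) with Adam (lr 0.01,
reduce-on-plateau ×0.5 after 10 stale epochs), batch 16, Gaussian-noise
augmentation only — geometric augmentations would break the content–location
pairing. Segmentation thresholds the error map at
τ = k × (mean error pooled over a seeded 10% calibration subset, ROI pixels
only) inside a rectangular region of interest, and is evaluated per frame by
accuracy, sensitivity, specificity, IoU, and Dice with seeded
percentile-bootstrap 95% CIs (1000 resamples) and paired t-tests.

Because clinical VFSS data are private, the package ships a seeded phantom
generator realizing exactly this statistical frame model (location-
conditioned Gaussian background, optional rigid jitter, additive or
*transplanted* elliptical anomalies with exact ground-truth masks), so the
whole pipeline is testable end to end.

## Worked example

Train on anomaly-free phantom frames, segment a transplanted anomaly, and
evaluate — all in a few lines:

```r
library(boluseg)

spec <- phantom_spec(seed = 1)                      # 64x64 study conditions
ds   <- generate_phantom_dataset(spec,
          anomaly_spec(mode = "transplanted"),
          n_train = 200, n_test_clean = 20, n_test_anom = 20, seed = 1)

x <- stack_inputs(encode_frames(ds$frames[ds$manifest$split == "train"]))
set.seed(1001)
model <- build_autoencoder(model_config(in_channels = 5,
                                        encoder_widths = c(8, 16, 32)))
tr <- train_autoencoder(model, x, train_config(epochs = 30, seed = 1001))

roi <- build_roi_mask(64, 64)
test_inputs <- encode_frames(ds$frames[ds$manifest$split == "test"])
seg <- segment_dataset(test_inputs, tr$model, roi = roi, seed = 2001)
```

The one-call version of this study — including the no-PE ablation trained
identically on the same data and splits — is:

```r
bench <- run_phantom_benchmark(seed = 1)
dplyr::filter(bench$comparison, metric %in% c("iou", "dsc"))
```

On seed 1 this prints:

```
# A tibble: 4 × 7
  variant metric   mean  ci_lo  ci_hi n_defined n_undefined
  <chr>   <chr>   <dbl>  <dbl>  <dbl>     <int>       <int>
1 pe      iou    0.0661 0.0443 0.0887        36           0
2 pe      dsc    0.116  0.0796 0.153         36           0
3 no_pe   iou    0.0902 0.0595 0.120         36           0
4 no_pe   dsc    0.152  0.105  0.200         36           0
```

Each row is a per-frame mean over the 36 evaluated test frames with its
seeded bootstrap 95% CI; overlap is modest because the thresholded error
maps flag anomaly boundaries but not their interiors. The anomaly-strength
response, which probes the core reconstruction mechanism directly, is
clean — the median in-anomaly error grows with the injected offset:

```r
error_vs_delta(bench$results$pe$model, bench$dataset$spec, seed = 8)
# A tibble: 3 × 3
#   delta median_error n_frames
# 1   0.1       0.0185       20
# 2   0.2       0.0261       20
# 3   0.4       0.0457       20
```

On this synthetic phantom the PE variant does not out-segment the no-PE
variant: the skip-connected architecture reconstructs transplanted content
through its skips for both variants, a behavior the methods vignette
dissects in detail (it is a property of the idealized phantom, not of the
pipeline mechanics). `autoplot(bench$results$pe)` shows the training curves
and `plot_error_map()` displays an error map with the calibrated threshold.

## Command-line use

A thin executable wraps the same functions
(`exec/boluseg`, installed with the package):

```sh
boluseg generate --seed 1 --out data/
boluseg train    --frames data/frames --out run/ --seed 1
boluseg segment  --checkpoint run/checkpoint.rds --frames data/frames --out seg/
boluseg evaluate --frames seg/pred_masks --masks data/masks --out eval/
boluseg ablate   --seed 1 --out ablation/
```

Exit codes: 0 success, 2 configuration error, 3 data error. Every command
writes its resolved YAML config and seed into the output directory so runs
replay bit-identically.

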
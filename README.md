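# cineseg

Semantic segmentation of thyroid ultrasound **cineclips** — video sweeps of
the transducer across the neck — into thyroid gland, solid nodules and
cysts. Sonographic features of nodules (echogenicity, margins, size) drive
malignancy scoring and treatment decisions, but reading a sweep is
subjective and operator-dependent; automatic segmentation of the whole
sweep supports consistent measurement, thyroid mapping and volume
estimation.

The package implements, end to end and in pure R/C++ (no external
deep-learning framework):

* a **dual-output** static segmentation network: a DeepLabv3+-style dilated
  ResNet backbone (three-convolution stem, bottleneck stages with dilation
  rates 2 and 4 replacing the last two strides, atrous spatial pyramid
  pooling, four skip-fusion blocks) with a sigmoid thyroid head and a
  softmax background/cyst/nodule head — overlapping classes, so lesions
  need not be carved out of the gland mask;
* a **recurrent model**: the frozen backbone replicated over a 6-frame
  window whose two half-window groups feed 18 bidirectional dilated
  ConvLSTM layers (3×3 kernels, 32 filters at width 1, dilations
  1/3/5/7) and fresh dual heads, emitting the segmentation of the window's
  current frame;
* a **class-balanced soft-MCC loss**: per output head, weighted soft
  confusion counts aggregated over pixels and classes enter
  `MCC = (TP·TN − FP·FN)/√((TP+FP)(TP+FN)(TN+FP)(TN+FN) + ε)`, and the
  loss is `1 − mean(MCC)`. Unlike overlap losses it distinguishes correct
  silence (MCC → +1) from confident false positives (MCC → −1) on
  lesion-free frames, where Dice-style losses are flat;
* the **four-stage protocol**: thyroid-only pretraining → dual-output
  training with 2-of-3 forced-nodule batch oversampling → head refinement
  with everything through ASPP frozen → recurrent training on full
  sequences; per-stage augmentation schedules (flip / rotation /
  translation / intensity shift / crop / sequence reversal);
* evaluation: IoU, MCC, recall, precision, F2 (with explicit
  zero-denominator conventions), ROC curves, per-clip and stratified
  reports by echogenicity / malignancy / margins;
* **volume estimation**: slice-integral volume under the uniform-velocity
  sweep assumption vs the clinical caliper ellipsoid `π/6·L·W·H`, with
  signed percent difference and orthogonal-plane projections;
* a seeded **distance-regularized level-set** baseline with the published
  parameters (Δt = 1, λ = 1, α = −0.9, ε = 2.75, 60+10 iterations,
  ground truth dilated by a 20-px disk);
* a **sweep-phantom simulator**: speckle-textured B-mode frames from
  planar slicing of 3-D ellipsoids (thyroid band, hypo/iso/hyper nodules,
  anechoic cysts, smooth/ill-defined/lobulated margins, optional transient
  "flicker" obscuration and vessel confounders) with exact noise-free
  masks and cohort manifests hitting the clinical prevalence anchors
  (nodules in ≈35% of frames, ≈2% of pixels).

## Worked example

Simulate a cohort, split it by patient, run the four-stage protocol at
desk scale (width 1/8, 64×64 phantoms), and segment a held-out clip:

```r
library(cineseg)

co <- generate_cohort(20, n_frames = 12, seed = 101)
co$manifest <- split_by_patient(co$manifest, c(0.6, 0.2, 0.2), seed = 1)
table(co$manifest$split)
#>       test      train validation
#>          3         14          3

state <- run_full_protocol(tiny_model_config(), co, seed = 1,
                           plans = tiny_protocol_plans())
tail(state$history, 3)
#> # A tibble: 3 x 4
#>   stage epoch  loss val_thyroid_iou
#>   <int> <int> <dbl>           <dbl>
#> 1     4    13 0.348          NA
#> 2     4    14 0.370          NA
#> 3     4    15 0.349           0.869

held <- co$clips[co$manifest$split == "test"]
seg <- segment_cineclip(state$recurrent, held[[1]]$clip)
evaluate_cohort(list(seg), list(held[[1]]$masks))
#> # A tibble: 3 x 7
#>    clip class     iou   mcc recall precision    f2
#>   <int> <chr>   <dbl> <dbl>  <dbl>     <dbl> <dbl>
#> 1     1 thyroid 0.795 0.859  0.878     0.894 0.881
#> 2     1 cyst    0     0      0         0     0
#> 3     1 nodule  0.270 0.431  0.604     0.329 0.518
```

The gland segments well after a few CPU-minutes (validation IoU 0.87; on
this particular test clip 0.80). Lesions are much harder at desk scale:
the nodule is found with moderate overlap, and this clip's small cyst is
missed entirely — absolute lesion accuracy on tiny phantoms is not the
point of the example. A 3-seed run of the same
protocol (`temporal_benefit_experiment()`) gives held-out thyroid IoU
≈ 0.85–0.86, and on *flickered* phantoms — lesions intermittently obscured
in the frames but present in the truth — the recurrent model improves
per-clip nodule IoU over the frame-wise stage-2 model by a paired median
of +0.09 to +0.20: the temporal module recovers structures a single frame
cannot show.

The architecture census is available by introspection:

```r
cfg <- model_config()            # full width
static <- build_static_model(cfg, 2)
s <- model_summary(build_recurrent_model(cfg, static))
nrow(dplyr::filter(s, type == "convlstm"))
#> [1] 18
```

A thin CLI covers the same surface from a shell:

```sh
inst/scripts/cineseg simulate --patients 20 --out data/ --seed 1
inst/scripts/cineseg split --manifest data/manifest.json --fractions 0.6,0.2,0.2 --seed 1
inst/scripts/cineseg train --data data/ --out model.rds --seed 1
inst/scripts/cineseg segment --model model.rds --clip data/P001_clip1.tif --out P001_seg
inst/scripts/cineseg drls --image frame.tif --seed-mask truth.tif --out drls.tif
inst/scripts/cineseg volume --masks P001_seg --out volumes.json
```

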
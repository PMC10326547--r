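# senescreen

Binary classification of **therapy-induced senescent (TIS)** versus
proliferating cancer cells from co-registered three-channel label-free
nonlinear-optical microscopy images:

* **SRS** — stimulated Raman scattering at the 2850 cm⁻¹ CH₂ lipid mode
  (senescent cells accumulate bright lipid-droplet aggregates),
* **TPEF** — two-photon excited fluorescence of NADH/FAD (proliferating
  cells show diffuse mitochondrial signal around dark nuclei; senescent
  cells show clustered bright foci),
* **TRANS** — bright-field optical transmission (morphology).

The package is aimed at microscopy groups who want an auditable,
fully-seeded reference implementation of this classification framework:
manifest-based image I/O with shallow preprocessing, label-preserving
augmentation, four classifier families, an evaluation harness, Grad-CAM
interpretability, and a synthetic phenotype generator so everything runs
and tests without external downloads.

## The methods in brief

Every individual classifier minimises the binary cross-entropy

```
L = -(1/n) Σ [ yᵢ log pᵢ + (1-yᵢ) log(1-pᵢ) ],   yᵢ = 1 for senescent
```

with batch size 20, ≤ 200 epochs, Adam at 5·10⁻⁴ (dense head) and 2·10⁻⁵
(backbone fine-tuning), L1 = L2 = 0.01 on the 4-neuron dense layer, and
early stopping on the validation loss (patience 20, min_delta 0.005).
The four architectures:

1. **From-scratch CNN** — conv 6/12/24 filters (3×3), max pooling, global
   max pooling, dropout, dense(4, ReLU), dense(1, sigmoid).
2. **Hybrid TL/ML** — frozen backbone features → PCA (95 % variance) →
   polynomial-kernel SVM (degree/cost by 5-fold CV), combined across
   backbones by hard majority voting.
3. **Frozen ensemble (EL)** — per-backbone TL classifiers (global max
   pool → dropout 0.8 → dense(4) → sigmoid), heads trained only,
   probabilities averaged unweighted, class = argmax of the mean.
4. **Fully trained EL** — same, plus a fine-tuning stage that unfreezes
   the backbones at 2·10⁻⁵.

Each ensemble learner trains on its own independently augmented dataset
(rotations, integer translations, flips; zero fill; no crop/stretch);
a single integer seed determines every random choice end to end.
Grad-CAM maps from the last convolutional stage are upscaled bilinearly
to image size and scored against the generator's ground-truth marker
masks by point-biserial colocalization.

Seven published backbones (InceptionV3, EfficientNetB4, DenseNet121,
ResNet50, MobileNet, Xception, InceptionResNetV2) are registered by name;
their pre-trained weights are external, so self-contained runs use the
deterministic `STUB` backbone instead. Reproducing published full-scale
accuracy tables therefore isn't in scope — the package's experiments run
at a reduced, CPU-friendly scale (see the methods vignette).

## Worked example

```r
library(senescreen)

# the package's reduced-scale study: 160 synthetic 64x80 training images
# (95:65 senescent:control), 40-image balanced test set, 3 stub learners,
# fully trained ensemble, 3 training runs
res <- run_experiment(small_study_config(seed = 7, n_runs = 3))
res$summary
```

```
<run_summary> 3 runs
  accuracy   96.7% +/- 1.4%
  precision  95.2% +/- 0.1%
  recall     98.3% +/- 2.9%
  f1         96.7% +/- 1.5%
  max AUC   1.000
```

Accuracy is the fraction of the 40 held-out test images whose
ensemble-averaged senescence probability falls on the correct side of
0.5; the mean ± SD is taken over the three independent training runs and
max AUC is the best area under the ROC curve among them. At
`effect_size = 0` (senescent and control generators identical) the same
pipeline stays at chance — the no-leakage control:

```r
run_experiment(small_study_config(effect_size = 0, seed = 7, n_runs = 1))$summary$mean[["accuracy"]]
#> [1] 0.5
```

Grad-CAM interpretability on a trained learner:

```r
data <- generate_dataset(synth_config(1, 0, height = 64, width = 80, seed = 1))
img  <- preprocess_dataset(data)$images[[1]]
bb   <- build_stub_backbone(channels = 16, seed = 3)
m    <- build_tl_classifier(bb, input_shape = c(64, 80, 3), seed = 4)
g    <- upscale_map(gradcam_map(m, img), 64, 80)
colocalization_score(g, img$marker_mask)   # in [-1, 1]
render_overlay(g, img$channels$SRS, "overlay.png")
```

A thin command-line wrapper ships in `inst/cli/senescreen-cli.R`
(`synth`, `experiment`, `compare` subcommands).

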
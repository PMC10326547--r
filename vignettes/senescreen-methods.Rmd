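---
title: "Classifying therapy-induced senescence from multimodal NLO images: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying therapy-induced senescence from multimodal NLO images: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(senescreen)
```

## The problem

Therapy-induced senescence (TIS) is a permanent growth-arrest state that
cancer cells can enter after chemo- or radiotherapy. Senescent cells remain
metabolically active and can promote recurrence, so telling them apart from
still-proliferating tumour cells matters clinically — but no single
molecular marker identifies senescence, and the assay gold standards
(SA-β-Gal staining, expression profiling) are slow and invasive.

Label-free nonlinear-optical (NLO) microscopy offers an alternative
read-out. Each field of view is acquired in three co-registered channels:

* **SRS** — stimulated Raman scattering at the 2850 cm⁻¹ CH₂ stretching
  mode, which maps lipids; senescent cells accumulate bright lipid-droplet
  aggregates.
* **TPEF** — two-photon excited fluorescence of the endogenous coenzymes
  NADH and FAD, reporting metabolic state; in proliferating cells the
  mitochondrial network spreads diffusely through the cytoplasm around a
  visibly darker nucleus, while senescent cells show clustered bright
  foci.
* **TRANS** — bright-field optical transmission, giving cell morphology.

`senescreen` implements a complete binary classification framework over
such images: shallow preprocessing, label-preserving augmentation, four
classifier families (a from-scratch CNN; a hybrid deep-feature + PCA + SVM
voter; and a transfer-learning ensemble in frozen and fully fine-tuned
modes), an evaluation harness, and Grad-CAM interpretability — plus a
synthetic image generator so that the entire pipeline is buildable and
testable without any external data.

## Data model and preprocessing

Images are 250 × 300 px (0.35 µm pitch) by default and travel as
`multimodal_image` objects inside manifest-backed `dataset_bundle`s tagged
TRAIN / VALIDATION / TEST. Preprocessing is deliberately shallow so as not
to distort the physically acquired signal; per channel and per image:

1. **Percentile clipping** (`remove_outliers`): values outside the
   [1st, 99th] percentile are clamped to those percentile values, removing
   detector spikes. The percentiles are configurable
   (`preprocess_config`); the acquisition literature does not pin them, so
   the defaults are a declared choice of standard robust clipping.
2. **Background suppression** (`suppress_background`): the 10th-percentile
   value is taken as the background level, subtracted, and negatives are
   clamped to zero. Again the operator is a declared default (simple,
   monotone, exact on pure-background images), not an inference.
3. **Byte-range rescaling** (`rescale_to_byte_range`): an affine map
   sending the per-image minimum to 0 and maximum to 255, kept as floating
   point to avoid double rounding before backbone-specific scaling.
   Normalization is per image; no global reference is used.

A constant (degenerate) image maps to all zeros rather than erroring.

## Augmentation

Training sets of a few hundred microscopy fields are far too small for
deep networks, so each training image is expanded with
`copies_per_image = 11` random label-preserving transforms (170 images →
2040). Each transform is one rotation (±180°, uniform — cell orientation
is physically arbitrary), one integer translation (up to ±10% of each
dimension), and independent horizontal/vertical flips at probability 0.5,
applied identically to all three channels with **zero fill** for vacated
pixels. Cropping, stretching, zooming and intensity jitter are excluded:
they would deform the droplet and mitochondrial distributions that carry
the class signal. Bilinear interpolation is clamped back to [0, 255];
nearest-neighbour is available for exactness tests. Augmenting a TEST
bundle is refused outright — this is the package's first data-leakage
guard.

For ensembles, `per_learner_datasets()` gives every learner its own
augmented dataset from a sub-seed derived via `mix_seed(seed, learner)`, a
fixed 31-bit linear congruential mix that makes any experiment a pure
function of one base seed.

## Classifiers

**From-scratch CNN** (`build_scratch_cnn`): three 3 × 3 convolutions with
6, 12 and 24 filters, 2 × 2 max pooling between them, then global max
pooling → dropout → dense(4, ReLU) → dense(1, sigmoid). The global-pooling
tail makes the parameter count (3549) independent of image size.

**Transfer-learning classifier** (`build_tl_classifier`): a backbone
feature extractor under a head of global max pooling, dropout (rate 0.8),
a 4-neuron ReLU dense layer carrying L1 and L2 penalties (coefficient
0.01 each), and a 1-neuron sigmoid output. Seven published ImageNet
backbones (InceptionV3, EfficientNetB4, DenseNet121, ResNet50, MobileNet,
Xception, InceptionResNetV2) are registered by name; since their weights
are external downloads, requesting one without weights raises an
informative error rather than silently substituting a stub.

**Stub backbone** (`build_stub_backbone`): a tiny seed-deterministic
2-conv + 2-pool feature extractor satisfying the same contract
(feature map `ceil(H/4) × ceil(W/4)`, fixed-length pooled feature
vector), used by every self-contained experiment. Its weights are
variance-rescaled and the final stage carries a `feature_scale` gain so
that pooled features span roughly 0–20 — the dynamic range of pooled
activations from real pre-trained extractors. This matters because the
head learning rate below is fixed: with features of negligible scale the
optimizer cannot reach the weight magnitudes that a penalized-optimal
separator requires.

**Hybrid TL/ML classifier** (`fit_hybrid`): per backbone, frozen
("off-the-shelf") features → PCA retaining 95% variance (fitted on
training rows only; held-out rows are only ever projected) → a
polynomial-kernel SVM whose degree ∈ {2, 3} and cost ∈ {0.1, 1, 10} are
chosen by 5-fold cross-validation on training rows. Per-backbone labels
are combined by hard majority voting; with the canonical seven learners
ties cannot occur, and for even ensembles an exact tie resolves to
SENESCENT because missing a senescent cell is the costlier error. The
hybrid path is label-vote only — no probability calibration.

**Ensemble** (`train_ensemble`): n transfer-learning classifiers (default
7), each trained on its own augmented dataset with its own sub-seed.
Prediction averages the per-learner senescence probabilities without
weights and takes the class with the larger mean — equivalent, for binary
sigmoid learners, to thresholding the mean at 0.5 (asserted by test; the
0.5 tie also resolves to SENESCENT). `FROZEN` mode trains heads only;
`FULLY_TRAINED` adds a fine-tuning pass.

## Training

All individual classifiers minimise the binary cross-entropy
\[
\mathcal{L} = -\frac{1}{n}\sum_{i=1}^{n} \big[y_i \log p_i + (1-y_i)\log(1-p_i)\big],
\]
with \(y_i = 1\) for senescent and \(p_i\) clipped to \([10^{-7}, 1-10^{-7}]\)
before the logarithm. Training uses batch size 20, at most 200 epochs,
learning rate 5 × 10⁻⁴ for the dense head and 2 × 10⁻⁵ for backbone
fine-tuning. The optimizer is Adam — the literature source does not name
one, and Adam is the community default for this generation of
fine-tuning work.

The two-stage protocol: `HEAD` freezes the backbone (its activations are
computed once and cached through the deterministic pooling layer, so head
epochs are cheap) and trains the dense layers; `FINETUNE` then unfreezes
everything, applying the small learning rate to backbone parameters while
the head keeps its own rate (a flag unifies them; the source is silent on
this point).

**Early stopping** monitors the validation cross-entropy with patience 20
and `min_delta` 0.005. Improvement is judged against the *running
minimum*, so sub-`min_delta` creep (e.g. exactly 0.004/epoch) never
resets the patience counter: a flat validation loss stops training at
epoch 21. The weights of the best validation epoch are restored at the
end (standard practice; prevents reporting a degraded final epoch).
Validation sets are split stratified-by-class by default, with an
exact-count mode (`n_val_senescent`, `n_val_control`) because the
reference acquisition's 24 + 19 = 43 split is not exactly proportional.
In `train_ensemble` the validation split is drawn from each learner's
*augmented* dataset, mirroring the reference bookkeeping in which all
training images are augmented and validation is drawn alongside; copies
of one source image can therefore straddle train′/validation, which is a
known softness of that bookkeeping (the TEST set is never touched).

## Evaluation

With senescent as the positive class: accuracy (TP+TN)/total, precision
TP/(TP+FP), recall TP/(TP+FN), F1 2TP/(2TP+FP+FN). Metrics with zero
denominators are reported as `NA`, never silently as 0. ROC curves sweep
the decision threshold over the unique predicted probabilities; AUC is
trapezoidal and equals the Mann–Whitney pairwise-concordance statistic
(property-tested, and cross-checked against pROC). For the hybrid
classifier the ROC is built by thresholding the senescent *vote count*
(0…n+1), giving the degenerate endpoints (1,1) and (0,0). Experiments
repeat training `n_runs = 9` times by default and report per-metric mean
± sample SD plus the maximum AUC across runs.

## Grad-CAM interpretability

For a chosen class, the gradient of the class score (the pre-sigmoid
logit for SENESCENT, its negation for CONTROL) is propagated to the last
convolutional stage; channel weights are the spatial means of those
gradients, and the coarse map is the rectified (ReLU) weighted sum of the
feature maps, normalized to [0, 1] per map — an all-zero map (e.g. from a
constant-output model) stays all-zero. The coarse map is upscaled to
image resolution by bilinear interpolation and can be rendered as a
heat-colormap overlay on any channel. For ensembles the default map is
the average of per-learner upscaled maps, with a per-learner mode by
flag.

Because the synthetic generator records the union of implanted droplet
and focus supports as a per-image marker mask, colocalization between
activation and biology is quantified as the point-biserial correlation
between upscaled map values and mask membership (`colocalization_score`),
turning the usual qualitative visual comparison into a testable number.

## The synthetic generator

`generate_dataset()` renders fields of view with: cells as
Fourier-perturbed disks with darker nuclear disks; lipid droplets and
mitochondrial foci as Gaussian-profile disks; a coarse multiplicative
texture; bright-field silhouettes in TRANS; additive Gaussian noise
clamped at zero. Class contrast is controlled by `effect_size` ∈ [0, 1]:
the senescent parameter set is the linear interpolation between the
control baseline and the fully senescent phenotype, so at
`effect_size = 0` the two generators draw from identical distributions
(the natural null for leakage checks) and separability is monotone in
`effect_size` (property-tested). Defaults: 3–5 cells per field, senescent
cells slightly enlarged, 18–28 bright droplets and 8–14 clustered foci
per senescent cell versus 2–6 small dim droplets and no foci per control
cell — chosen once as a plausible rendering of the described phenotypes;
the source does not quantify marker magnitudes, so these are declared
knobs, not estimates. Radii scale with image size (`size_factor`) so the
64 × 80 small-size mode preserves the phenotype geometry.

What passing tests on this generator do **not** show: real HepG2 texture
statistics, imaging noise physics, partial-phenotype biology, or
class-overlap levels of real data. The generator exists to verify
pipeline mechanics and directional claims, not to reproduce published
accuracy numbers, which require the deposited dataset and the actual
pre-trained backbones.

## Reduced-scale study and scaled hyperparameters

`small_study_config()` fixes the package's self-contained experiment:
64 × 80 images, 160 training fields (95 : 65, the reference class ratio)
plus a 40-image balanced test set, three stub learners, three augmented
copies per image, fine-tuning capped at five epochs. Runtimes stay in
minutes on one CPU; the test suite and the acceptance script both run it
at these sizes.

Two hyperparameters are rescaled with problem size, with the reasoning
recorded here once:

* **Head dropout 0.8 → 0.1.** Rate 0.8 presumes the >1000-dimensional
  feature vectors of the published backbones, where ~200 features survive
  each pass. On the 16-dimensional stub output it leaves ~3, destroying
  the training signal (measured: accuracy collapses to chance).
* **Patience 20 → 85 epochs.** At full scale an epoch is ~102 optimizer
  steps, so patience 20 spans ~2000 steps; a reduced epoch is 24 steps,
  and 2000/24 ≈ 85 epochs is the step-equivalent stagnation window.

Everything else — batch size, learning rates, `min_delta`, penalties,
head architecture — keeps its reference default at every scale.

## Numerical choices and degenerate inputs

* Probability clipping ε = 10⁻⁷ in the loss; Adam ε = 10⁻⁸, β = (0.9, 0.999).
* Weight init is Glorot-uniform; ReLU dense layers start with bias 0.01
  (not 0) to avoid dead units on non-negative pooled inputs.
* Dropout is inverted (scaled at train time); inference is deterministic.
* Constant images: percentile clipping and rescaling are exact no-ops /
  all-zeros; `roc_curve` refuses single-class truth (AUC undefined);
  metric zero-denominators give `NA`; empty masks give `NA`
  colocalization.
* Ties: ensemble mean exactly 0.5 → SENESCENT; even-count vote ties →
  SENESCENT; both from the asymmetric cost of missing a senescent cell.
* Determinism is platform-level (BLAS-order floating point), documented
  as platform-reproducible rather than cross-platform bit-exact.

## Known limitations

* The CNN engine is minimal by design (3 × 3 same-padding convolutions,
  2 × 2 pooling, dense layers); it is not a general deep-learning
  framework and has no GPU path.
* The seven published backbones are interface-registered but their
  weights are not shipped; quantitative parity with published Table-level
  results is out of scope by construction.
* The hybrid classifier's CV grid is a minimal plausible one (degree
  {2, 3} × cost {0.1, 1, 10}); the original grid is unstated.
* Synthetic phenotypes are geometric caricatures; colocalization and
  separability results on them are directional evidence only.
* With random stub features, part of the discriminative signal is
  "control-presence" evidence (per-image rescaling makes the control's
  broad diffuse TPEF as bright as the senescent puncta), so Grad-CAM
  attention on senescent markers — while correctly ordered above the
  control score under the package's study conditions — is weaker and
  more seed-sensitive than what feature extractors pre-trained on
  natural images would be expected to produce.
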
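# Classifier architectures: the from-scratch CNN, the transfer-learning
# classification head, and the backbone registry. Seven literature
# backbones (ImageNet-pre-trained feature extractors) are registered by
# name; because their weights are external downloads, requesting one
# without weights fails loudly, and a small deterministic STUB backbone
# with the same contract is provided for self-contained experiments.

BACKBONE_NAMES <- c("InceptionV3", "EfficientNetB4", "DenseNet121",
                    "ResNet50", "MobileNet", "Xception",
                    "InceptionResNetV2", "STUB")

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Channel-to-RGB-slot ordering
#'
#' The pre-trained backbones expect three input planes in the R, G, B
#' positions; this object records which modality goes where (default
#' SRS -> R, TPEF -> G, TRANS -> B). Must be a permutation of the three
#' modalities.
#'
#' @param order Character vector permutation of `c("SRS","TPEF","TRANS")`.
#' @return An object of class `channel_order`.
#' @export
channel_order <- function(order = c("SRS", "TPEF", "TRANS")) {
  order <- toupper(order)
  if (!setequal(order, MODALITIES) || length(order) != 3)
    stop("channel_order: must be a permutation of SRS, TPEF, TRANS")
  structure(list(mapping = order), class = "channel_order")
}

#' Arrange the three modality planes into an (H, W, 3) array
#'
#' @param img A [multimodal_image()].
#' @param order A [channel_order()].
#' @return Numeric array (H, W, 3), planes in the requested order. Any
#'   backbone-specific intensity scaling is applied afterwards by callers.
#' @export
map_channels_to_rgb <- function(img, order = channel_order()) {
  planes <- lapply(order$mapping, function(m) {
    ch <- img$channels[[m]]
    if (is.null(ch)) stop(sprintf("missing channel %s", m))
    ch$pixels
  })
  array(unlist(planes), c(dim(img), 3))
}

#' From-scratch CNN classifier
#'
#' Three 3x3 convolutional stages with 6, 12 and 24 filters, 2x2 max
#' pooling between consecutive convolutions, then global max pooling,
#' dropout, a 4-neuron ReLU dense layer and a 1-neuron sigmoid output
#' giving the probability that the image is senescent. The global-pooling
#' tail makes the trainable parameter count independent of image size.
#'
#' @param input_shape Integer `(H, W, 3)`; H and W must be at least 8.
#' @param dropout_rate Dropout rate before the dense head (default 0.5).
#' @param seed Optional seed for reproducible weight initialization.
#' @return A `learner_model`.
#' @export
build_scratch_cnn <- function(input_shape = c(250, 300, 3),
                              dropout_rate = 0.5, seed = NULL) {
  if (input_shape[1] < 8 || input_shape[2] < 8)
    stop("build_scratch_cnn: input must be at least 8 x 8")
  build <- function() {
    layers <- list(layer_conv(3, 6), layer_maxpool(),
                   layer_conv(6, 12), layer_maxpool(),
                   layer_conv(12, 24), layer_gmp(),
                   layer_dropout(dropout_rate),
                   layer_dense(24, 4, "relu"),
                   layer_dense(4, 1, "sigmoid"))
    structure(list(layers = layers, input_shape = input_shape,
                   kind = "scratch", backbone_idx = integer(),
                   last_conv = 5L, frozen_backbone = FALSE,
                   preprocess = function(x) x / 255, trained = FALSE),
              class = "learner_model")
  }
  if (is.null(seed)) build() else with_seed(seed, build())
}

#' Transfer-learning head specification
#'
#' The small dense network placed on top of a pre-trained backbone:
#' 2-D global max pooling, dropout (rate 0.8), a 4-neuron ReLU dense layer
#' with L1 and L2 penalties (coefficient 0.01) and a 1-neuron sigmoid
#' output. The penalties apply to the 4-neuron layer only.
#'
#' @param dropout_rate,hidden_units,l1,l2 Head hyperparameters.
#' @return An object of class `tl_head_spec`.
#' @export
tl_head_spec <- function(dropout_rate = 0.8, hidden_units = 4,
                         l1 = 0.01, l2 = 0.01) {
  structure(list(dropout_rate = dropout_rate, hidden_units = hidden_units,
                 l1 = l1, l2 = l2), class = "tl_head_spec")
}

#' Backbone registry
#'
#' @return Character vector of registered backbone names (the seven
#'   literature networks plus `"STUB"`).
#' @export
backbone_registry <- function() BACKBONE_NAMES

#' Retrieve a backbone by name
#'
#' The seven literature backbones require their pre-trained weights, which
#' are not bundled; requesting one raises an informative error instead of
#' silently substituting the stub. `"STUB"` returns
#' [build_stub_backbone()] with the supplied arguments.
#'
#' @param name A name from [backbone_registry()].
#' @param ... Passed to [build_stub_backbone()] when `name == "STUB"`.
#' @return A `backbone_handle`.
#' @export
get_backbone <- function(name, ...) {
  name <- match.arg(name, BACKBONE_NAMES)
  if (name == "STUB") return(build_stub_backbone(...))
  stop(sprintf(paste0(
    "backbone '%s' is registered but its pre-trained weights are not ",
    "bundled with this package; supply them through your own ",
    "backbone_handle or use the 'STUB' backbone for self-contained runs"),
    name))
}

#' Deterministic stub backbone
#'
#' A tiny fixed-architecture feature extractor satisfying the backbone
#' contract without any download: two 3x3 convolution + 2x2 max-pooling
#' stages with randomly initialized but seed-deterministic weights. The
#' feature map for an (H, W) input has spatial size
#' `ceiling(H/4) x ceiling(W/4)`; the feature vector is its global max
#' pool, of fixed length `channels`.
#'
#' @param channels Feature-map channel count (final stage; default 16).
#' @param seed Integer seed fixing the weights.
#' @param feature_scale Gain applied to the final convolution so pooled
#'   feature values span roughly 0-20, the dynamic range of pooled
#'   activations from published pre-trained extractors; the fixed head
#'   learning rate assumes features of that order.
#' @return An object of class `backbone_handle` with elements `name`,
#'   `layers`, `feature_dim`, `preprocess_fn`, `feature_map_fn` and
#'   `feature_vector_fn`.
#' @export
build_stub_backbone <- function(channels = 16, seed = 1, feature_scale = 16) {
  stopifnot(channels >= 1)
  mid <- max(4, channels %/% 2)
  layers <- with_seed(seed, list(
    layer_conv(3, mid, group = "backbone"), layer_maxpool(),
    layer_conv(mid, channels, group = "backbone"), layer_maxpool()))
  # Random Glorot convolutions attenuate [0,1] inputs to features of
  # negligible scale; pre-trained extractors (normalisation layers) emit
  # O(1) features, so the stub's weights are rescaled to preserve
  # activation variance through both ReLU stages.
  for (i in c(1, 3)) {
    fan_in <- layers[[i]]$kh * layers[[i]]$kw * layers[[i]]$cin
    target_sd <- sqrt(2 / fan_in) * 2
    layers[[i]]$W <- layers[[i]]$W * (target_sd / stats::sd(layers[[i]]$W))
  }
  layers[[3]]$W <- layers[[3]]$W * feature_scale
  handle <- structure(list(name = "STUB", layers = layers,
                           feature_dim = channels, seed = seed,
                           preprocess_fn = function(x) x / 255),
                      class = "backbone_handle")
  fwd <- function(x) {
    tmp <- structure(list(layers = handle$layers), class = "learner_model")
    nn_forward(tmp, handle$preprocess_fn(x))$out
  }
  handle$feature_map_fn <- fwd
  handle$feature_vector_fn <- function(x) {
    fm <- fwd(x)
    d <- dim(fm)
    apply(matrix(fm, d[1] * d[2], d[3]), 2, max)
  }
  handle
}

#' Transfer-learning classifier: backbone + dense head
#'
#' Stacks the classification head of [tl_head_spec()] on top of a
#' backbone's convolutional stages. With `frozen = TRUE` the backbone
#' parameters are excluded from the trainable set (off-the-shelf use);
#' unfreezing for fine-tuning is done by the FINETUNE training stage.
#'
#' @param backbone A `backbone_handle` (see [build_stub_backbone()]).
#' @param head A [tl_head_spec()].
#' @param input_shape Integer `(H, W, 3)`.
#' @param frozen Freeze backbone weights (default TRUE).
#' @param seed Optional seed for head weight initialization.
#' @return A `learner_model` emitting one senescence probability.
#' @export
build_tl_classifier <- function(backbone, head = tl_head_spec(),
                                input_shape = c(250, 300, 3),
                                frozen = TRUE, seed = NULL) {
  if (is.null(backbone$layers))
    stop("build_tl_classifier: backbone does not expose convolutional layers")
  build <- function() {
    layers <- c(backbone$layers, list(
      layer_gmp(), layer_dropout(head$dropout_rate),
      layer_dense(backbone$feature_dim, head$hidden_units, "relu",
                  l1 = head$l1, l2 = head$l2),
      layer_dense(head$hidden_units, 1, "sigmoid")))
    nb <- length(backbone$layers)
    conv_idx <- which(vapply(layers, function(l) l$type, "") == "conv")
    structure(list(layers = layers, input_shape = input_shape,
                   kind = "tl", backbone_idx = seq_len(nb),
                   last_conv = max(conv_idx), frozen_backbone = frozen,
                   backbone_name = backbone$name,
                   preprocess = backbone$preprocess_fn, trained = FALSE),
              class = "learner_model")
  }
  if (is.null(seed)) build() else with_seed(seed, build())
}

#' @export
print.learner_model <- function(x, ...) {
  cat(sprintf("<learner_model> kind=%s layers=%d params=%d%s\n", x$kind,
              length(x$layers), count_params(x),
              if (x$frozen_backbone) " (backbone frozen)" else ""))
  invisible(x)
}

model_input <- function(model, img, order = channel_order()) {
  model$preprocess(map_channels_to_rgb(img, order))
}

#' Predict senescence probabilities for a bundle
#'
#' Deterministic inference (dropout inactive).
#'
#' @param model A trained `learner_model`.
#' @param ds A [dataset_bundle()] or list of [multimodal_image()].
#' @param order A [channel_order()].
#' @return Numeric vector of probabilities, one per image.
#' @export
predict_learner <- function(model, ds, order = channel_order()) {
  images <- if (inherits(ds, "dataset_bundle")) ds$images else ds
  vapply(images, function(im) {
    nn_forward(model, model_input(model, im, order))$out
  }, 0)
}
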
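# Ensemble of transfer-learning classifiers combined by unweighted
# probability averaging: each learner emits a senescence probability, the
# probabilities are equally averaged, and the predicted class is the one
# with the larger averaged probability (argmax over the two-class vector
# (p, 1 - p), equivalent to a 0.5 threshold on the mean). Two modes:
# FROZEN trains only the heads (off-the-shelf backbones); FULLY_TRAINED
# adds backbone fine-tuning. Each learner trains on its own independently
# augmented dataset, which provides the ensemble's diversity.

#' Unweighted average of learner probabilities
#'
#' @param p Numeric vector of per-learner senescence probabilities.
#' @return Their arithmetic mean (order-invariant).
#' @export
average_probabilities <- function(p) {
  if (length(p) == 0) stop("average_probabilities: empty probability list")
  if (any(p < 0 | p > 1)) stop("average_probabilities: values outside [0, 1]")
  mean(p)
}

#' Class decision from a mean probability
#'
#' SENESCENT iff the mean senescence probability exceeds the threshold;
#' an exact tie at the threshold is resolved as SENESCENT (asymmetric
#' cost of missing a senescent cell). For binary sigmoid learners this is
#' the same as the argmax over the class probabilities (p, 1 - p).
#'
#' @param mean_prob Probability in \[0, 1\].
#' @param threshold Decision threshold (default 0.5).
#' @return `"SENESCENT"` or `"CONTROL"`.
#' @export
predict_class <- function(mean_prob, threshold = 0.5) {
  stopifnot(mean_prob >= 0, mean_prob <= 1)
  if (mean_prob >= threshold) "SENESCENT" else "CONTROL"
}

#' Train an ensemble of transfer-learning classifiers
#'
#' Each learner receives its own augmented copy of the training data (see
#' [per_learner_datasets()]), its own validation split and its own
#' sub-seed derived from `cfg$seed`. In `"FROZEN"` mode only the HEAD
#' stage runs (backbone weights stay at initialization); in
#' `"FULLY_TRAINED"` mode the HEAD stage is followed by FINETUNE.
#'
#' @param train A TRAIN [dataset_bundle()] (pre-augmentation).
#' @param backbones List of `backbone_handle`s, one per learner.
#' @param cfg A [training_config()].
#' @param mode `"FROZEN"` or `"FULLY_TRAINED"`.
#' @param aug_cfg An [augmentation_config()] for per-learner augmentation.
#' @param val_fraction Fraction of each augmented set held out for
#'   validation (default 0.25, echoing 43 of 170).
#' @param head A [tl_head_spec()].
#' @param finetune_cfg Optional [training_config()] governing the FINETUNE
#'   stage only (e.g. a smaller epoch budget); defaults to `cfg`.
#' @param order A [channel_order()].
#' @return An object of class `ensemble_model` with per-learner models and
#'   training histories.
#' @export
train_ensemble <- function(train, backbones, cfg = training_config(),
                           mode = c("FROZEN", "FULLY_TRAINED"),
                           aug_cfg = augmentation_config(),
                           val_fraction = 0.25, head = tl_head_spec(),
                           finetune_cfg = NULL,
                           order = channel_order()) {
  mode <- match.arg(mode)
  if (length(backbones) == 0) stop("train_ensemble: no backbones given")
  if (train$split == "TEST")
    stop("train_ensemble: refusing to fit on a TEST bundle (data leakage)")
  aug_cfg$seed <- mix_seed(cfg$seed, 1000)
  datasets <- per_learner_datasets(train, length(backbones), aug_cfg)
  learners <- vector("list", length(backbones))
  histories <- vector("list", length(backbones))
  for (i in seq_along(backbones)) {
    seed_i <- mix_seed(cfg$seed, i)
    ds_i <- datasets[[i]]
    sp <- split_validation(ds_i, n_val = max(1, round(val_fraction * length(ds_i))),
                           seed = seed_i)
    model <- build_tl_classifier(backbones[[i]], head = head,
                                 input_shape = c(dim(ds_i$images[[1]]), 3),
                                 frozen = TRUE, seed = seed_i)
    cfg_i <- cfg; cfg_i$seed <- seed_i
    st <- train_stage(model, sp$train, sp$validation, cfg_i, "HEAD", order)
    hist <- list(head = st$history)
    if (mode == "FULLY_TRAINED") {
      ft_cfg <- if (is.null(finetune_cfg)) cfg_i else {
        x <- finetune_cfg; x$seed <- seed_i; x
      }
      st <- train_stage(st$model, sp$train, sp$validation, ft_cfg,
                        "FINETUNE", order)
      hist$finetune <- st$history
    }
    learners[[i]] <- st$model
    histories[[i]] <- hist
  }
  structure(list(learners = learners, histories = histories, mode = mode,
                 order = order, trained = TRUE),
            class = "ensemble_model")
}

#' Ensemble prediction by probability averaging
#'
#' Deterministic at inference (dropout inactive). The per-image mean is
#' bounded by the smallest and largest learner probability and invariant
#' under learner reordering.
#'
#' @param model A trained `ensemble_model`.
#' @param ds A [dataset_bundle()].
#' @return List with `probs` (images x learners matrix of `p_ij`),
#'   `mean_prob` (per-image average) and `labels` (argmax class).
#' @export
predict_ensemble <- function(model, ds) {
  if (!isTRUE(model$trained)) stop("predict_ensemble: model is not trained")
  probs <- sapply(model$learners, predict_learner, ds = ds,
                  order = model$order)
  probs <- matrix(probs, nrow = length(ds$images))
  mean_prob <- apply(probs, 1, average_probabilities)
  list(probs = probs, mean_prob = mean_prob,
       labels = vapply(mean_prob, predict_class, ""))
}
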
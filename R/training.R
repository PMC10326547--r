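# Two-stage training protocol for the transfer-learning classifiers:
# HEAD trains only the dense classification layers on top of a frozen
# backbone (off-the-shelf use); FINETUNE then unfreezes the backbone and
# continues with a much smaller backbone learning rate. Both stages
# minimise binary cross-entropy with Adam, L1/L2 penalties on the 4-neuron
# dense layer, and early stopping on the validation loss.

#' Training configuration
#'
#' Defaults: batch size 20, at most 200 epochs, learning rate 5e-4 for the
#' dense head and 2e-5 for backbone fine-tuning, early stopping when the
#' validation cross-entropy fails to decrease by at least 0.005 over a
#' patience of 20 consecutive epochs, and L1/L2 penalty coefficients of
#' 0.01 on the 4-neuron dense layer.
#'
#' @param batch_size,max_epochs,lr_head,lr_finetune,patience_epochs,min_delta,l1,l2
#'   As described above.
#' @param unify_finetune_lr If `TRUE` the head also drops to `lr_finetune`
#'   during the FINETUNE stage; by default it keeps `lr_head`.
#' @param seed Integer seed for shuffling and dropout.
#' @return An object of class `training_config`.
#' @export
training_config <- function(batch_size = 20, max_epochs = 200,
                            lr_head = 5e-4, lr_finetune = 2e-5,
                            patience_epochs = 20, min_delta = 0.005,
                            l1 = 0.01, l2 = 0.01,
                            unify_finetune_lr = FALSE, seed = 1) {
  stopifnot(batch_size > 0, max_epochs > 0, lr_head > 0, lr_finetune >= 0,
            patience_epochs > 0, min_delta >= 0, lr_finetune < lr_head)
  structure(as.list(environment()), class = "training_config")
}

#' Binary cross-entropy loss
#'
#' `-(1/n) * sum(y * log(p) + (1 - y) * log(1 - p))`, the cost minimised by
#' every individual classifier, where `y` is the ground-truth label
#' (1 = senescent) and `p` the predicted senescence probability.
#' Probabilities are clipped to `[eps, 1 - eps]` before the logarithm.
#'
#' @param y Numeric or logical vector of ground-truth labels in \{0, 1\}.
#' @param p Numeric vector of predicted probabilities, same length.
#' @param eps Clipping constant (default 1e-7).
#' @return Non-negative scalar.
#' @export
binary_cross_entropy <- function(y, p, eps = 1e-7) {
  y <- as.numeric(y)
  if (length(y) != length(p) || length(y) == 0)
    stop("binary_cross_entropy: y and p must be equal-length, non-empty")
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("binary_cross_entropy: probabilities outside [0, 1]")
  p <- pmin(pmax(p, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

label_targets <- function(ds) as.numeric(bundle_labels(ds) == "SENESCENT")

#' Split a validation set off the training bundle
#'
#' Seed-reproducible random partition. By default the split is stratified
#' by class in proportion to the class frequencies; exact per-class counts
#' can be forced with `n_val_senescent`/`n_val_control` (the acquisition
#' protocol used 43 validation images, 24 senescent and 19 control, out of
#' 170 training images).
#'
#' @param train A TRAIN [dataset_bundle()].
#' @param n_val Number of validation images (must be < `length(train)`).
#' @param seed Integer seed.
#' @param n_val_senescent,n_val_control Optional exact per-class counts
#'   (override `n_val`).
#' @return List with elements `train` (split TRAIN) and `validation`
#'   (split VALIDATION); no image appears in both.
#' @export
split_validation <- function(train, n_val = 43, seed = 1,
                             n_val_senescent = NULL, n_val_control = NULL) {
  labels <- bundle_labels(train)
  n <- length(labels)
  if (!is.null(n_val_senescent) || !is.null(n_val_control)) {
    stopifnot(!is.null(n_val_senescent), !is.null(n_val_control))
    n_val <- n_val_senescent + n_val_control
  }
  if (n_val >= n) stop("split_validation: n_val must be smaller than the bundle")
  if (n_val == 0) {
    return(list(train = train,
                validation = dataset_bundle(list(), split = "VALIDATION")))
  }
  sen <- which(labels == "SENESCENT"); con <- which(labels == "CONTROL")
  if (is.null(n_val_senescent)) {
    n_val_senescent <- round(n_val * length(sen) / n)
    n_val_control <- n_val - n_val_senescent
  }
  stopifnot(n_val_senescent <= length(sen), n_val_control <= length(con))
  val_idx <- with_seed(seed, c(
    if (n_val_senescent > 0) sample(sen, n_val_senescent) else integer(),
    if (n_val_control > 0) sample(con, n_val_control) else integer()))
  list(train = dataset_bundle(train$images[-val_idx], split = "TRAIN"),
       validation = dataset_bundle(train$images[val_idx], split = "VALIDATION"))
}

#' Early-stopping rule
#'
#' `TRUE` iff none of the last `patience_epochs` epochs improved the best
#' validation loss seen so far by at least `min_delta`. An improvement
#' smaller than `min_delta` (e.g. 0.004 with the default 0.005) counts as
#' no improvement.
#'
#' @param history A `training_history` or a numeric vector of per-epoch
#'   validation losses.
#' @param cfg A [training_config()].
#' @return Logical.
#' @export
early_stop_check <- function(history, cfg = training_config()) {
  losses <- if (is.numeric(history)) history else history$val_loss
  if (length(losses) < 1) stop("early_stop_check: no recorded losses")
  # improvement is judged against the running minimum, so sub-min_delta
  # creep (e.g. 0.004/epoch against the default 0.005) never resets the
  # patience counter
  best <- Inf; wait <- 0
  for (loss in losses) {
    if (best - loss >= cfg$min_delta) wait <- 0 else wait <- wait + 1
    best <- min(best, loss)
  }
  wait >= cfg$patience_epochs
}

new_history <- function(stage) {
  structure(list(train_loss = numeric(), val_loss = numeric(),
                 stop_epoch = 0L, best_epoch = 0L, stage = stage),
            class = "training_history")
}

#' Train one stage of a learner
#'
#' `stage = "HEAD"` keeps backbone weights frozen (their activations are
#' computed once and cached) and trains the dense head at `lr_head`.
#' `stage = "FINETUNE"` unfreezes the backbone and continues training with
#' `lr_finetune` on backbone parameters while the head keeps `lr_head`
#' (or drops to `lr_finetune` with `unify_finetune_lr`). Early stopping
#' monitors the validation cross-entropy; the weights of the best
#' validation epoch are restored at the end.
#'
#' @param model A `learner_model`.
#' @param train,validation [dataset_bundle()]s (TRAIN/VALIDATION splits).
#' @param cfg A [training_config()].
#' @param stage `"HEAD"` or `"FINETUNE"`.
#' @param order A [channel_order()].
#' @return List with elements `model` (trained) and `history`
#'   (`training_history` with per-epoch train/validation losses,
#'   `stop_epoch`, `best_epoch`, `stage`).
#' @export
train_stage <- function(model, train, validation, cfg = training_config(),
                        stage = c("HEAD", "FINETUNE"),
                        order = channel_order()) {
  stage <- match.arg(stage)
  if (length(train) == 0) stop("train_stage: empty training data")
  if (train$split == "TEST" || validation$split == "TEST")
    stop("train_stage: refusing to fit on a TEST bundle (data leakage)")
  set.seed(cfg$seed)
  y_tr <- label_targets(train)
  y_va <- label_targets(validation)
  xs <- lapply(train$images, model_input, model = model, order = order)
  xv <- lapply(validation$images, model_input, model = model, order = order)

  # With a frozen backbone its activations are constant: compute them once
  # and train only the head layers on the cached feature maps.
  cache_prefix <- stage == "HEAD" && length(model$backbone_idx) > 0
  if (cache_prefix) {
    # extend the cached prefix through deterministic, parameter-free
    # layers (pooling) that directly follow the frozen backbone
    pe <- max(model$backbone_idx)
    while (pe < length(model$layers) &&
           model$layers[[pe + 1]]$type %in% c("maxpool", "gmp")) pe <- pe + 1
    prefix_idx <- seq_len(pe)
    prefix <- model
    prefix$layers <- model$layers[prefix_idx]
    fwd_prefix <- function(x) nn_forward(prefix, x)$out
    xs <- lapply(xs, fwd_prefix)
    xv <- lapply(xv, fwd_prefix)
    work <- model
    work$layers <- model$layers[-prefix_idx]
  } else {
    work <- model
  }
  if (stage == "FINETUNE") work$frozen_backbone <- FALSE

  lrs <- if (stage == "HEAD") {
    list(head = cfg$lr_head, backbone = 0)
  } else {
    list(head = if (cfg$unify_finetune_lr) cfg$lr_finetune else cfg$lr_head,
         backbone = cfg$lr_finetune)
  }

  opt <- adam_init(work)
  hist <- new_history(stage)
  best_loss <- Inf; best_layers <- work$layers; best_epoch <- 0L
  t_step <- 0
  n <- length(xs)
  for (epoch in seq_len(cfg$max_epochs)) {
    idx <- sample.int(n)
    batch_losses <- numeric()
    for (b0 in seq(1, n, by = cfg$batch_size)) {
      bi <- idx[b0:min(b0 + cfg$batch_size - 1, n)]
      nb <- length(bi)
      grads <- vector("list", length(work$layers))
      probs <- numeric(nb)
      for (k in seq_len(nb)) {
        fw <- nn_forward(work, xs[[bi[k]]], training = TRUE)
        probs[k] <- fw$out
        p_c <- pmin(pmax(fw$out, 1e-7), 1 - 1e-7)
        dlogit <- (p_c - y_tr[bi[k]]) / nb
        bw <- nn_backward(work, fw$caches, dlogit)
        for (i in seq_along(grads)) {
          if (is.null(bw$grads[[i]])) next
          grads[[i]] <- if (is.null(grads[[i]])) bw$grads[[i]] else
            list(W = grads[[i]]$W + bw$grads[[i]]$W,
                 b = grads[[i]]$b + bw$grads[[i]]$b)
        }
      }
      grads <- add_penalty_grads(work, grads)
      t_step <- t_step + 1
      st <- adam_step(work, opt, grads, lrs, t_step)
      work <- st$model; opt <- st$state
      batch_losses <- c(batch_losses,
                        binary_cross_entropy(y_tr[bi], probs) + penalty_loss(work))
    }
    hist$train_loss <- c(hist$train_loss, mean(batch_losses))
    if (length(xv) > 0) {
      pv <- vapply(xv, function(x) nn_forward(work, x)$out, 0)
      vl <- binary_cross_entropy(y_va, pv)
    } else {
      vl <- hist$train_loss[epoch]
    }
    hist$val_loss <- c(hist$val_loss, vl)
    if (vl < best_loss) {  # weight restoration tracks the true minimum
      best_loss <- vl; best_layers <- work$layers; best_epoch <- epoch
    }
    if (early_stop_check(hist$val_loss, cfg)) break
  }
  hist$stop_epoch <- length(hist$val_loss)
  hist$best_epoch <- if (best_epoch > 0) best_epoch else hist$stop_epoch
  if (best_epoch > 0) work$layers <- best_layers

  if (cache_prefix) {
    model$layers[-prefix_idx] <- work$layers
  } else {
    model <- work
  }
  model$trained <- TRUE
  list(model = model, history = hist)
}
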
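# A compact CNN engine sufficient for the classifiers used here: 3x3
# same-padding convolutions (im2col + BLAS), 2x2 max pooling, global max
# pooling, inverted dropout, dense layers with optional L1/L2 penalties,
# sigmoid output, reverse-mode gradients and an Adam optimizer with
# per-layer learning-rate groups (classification head vs backbone). All
# arrays are (H, W, C); forward/backward run per image and batches are
# accumulated by the training loop.

relu <- function(x) pmax(x, 0)
sigmoid <- function(x) 1 / (1 + exp(-x))

glorot_init <- function(n, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  stats::runif(n, -lim, lim)
}

layer_conv <- function(cin, cout, kh = 3, kw = 3, activation = "relu",
                       group = "head") {
  nin <- kh * kw * cin
  list(type = "conv", kh = kh, kw = kw, cin = cin, cout = cout,
       activation = activation, group = group, trainable = TRUE,
       W = matrix(glorot_init(nin * cout, nin, kh * kw * cout), nin, cout),
       b = numeric(cout))
}

layer_maxpool <- function() list(type = "maxpool", trainable = FALSE)

layer_gmp <- function() list(type = "gmp", trainable = FALSE)

layer_dropout <- function(rate) {
  list(type = "dropout", rate = rate, trainable = FALSE)
}

layer_dense <- function(n_in, n_out, activation = "relu", l1 = 0, l2 = 0,
                        group = "head") {
  W <- matrix(glorot_init(n_in * n_out, n_in, n_out), n_out, n_in)
  # ReLU dense layers here always receive non-negative pooled features;
  # non-negative weights and a small positive bias keep every hidden unit
  # active at initialization, avoiding dead units that a narrow (4-unit)
  # head cannot afford to lose
  if (activation == "relu") W <- abs(W)
  list(type = "dense", n_in = n_in, n_out = n_out, activation = activation,
       l1 = l1, l2 = l2, group = group, trainable = TRUE, W = W,
       b = rep(if (activation == "relu") 0.01 else 0, n_out))
}

apply_activation <- function(z, activation) {
  switch(activation, relu = relu(z), sigmoid = sigmoid(z), linear = z)
}

# Forward pass. Returns the final activation (a probability for sigmoid
# heads), the pre-sigmoid logit, and per-layer caches for backprop.
nn_forward <- function(model, x, training = FALSE) {
  caches <- vector("list", length(model$layers))
  logit <- NA_real_
  for (i in seq_along(model$layers)) {
    ly <- model$layers[[i]]
    if (ly$type == "conv") {
      d <- dim(x)
      cols <- cpp_im2col(x, d[1], d[2], d[3], ly$kh, ly$kw)
      z <- cols %*% ly$W
      z <- sweep(z, 2, ly$b, "+")
      a <- apply_activation(z, ly$activation)
      x <- array(a, c(d[1], d[2], ly$cout))
      caches[[i]] <- list(cols = cols, mask = (z > 0), dim_in = d, out = x)
    } else if (ly$type == "maxpool") {
      d <- dim(x)
      p <- cpp_maxpool_fwd(x, d[1], d[2], d[3])
      caches[[i]] <- list(idx = p$idx, dim_in = d)
      x <- p$out
    } else if (ly$type == "gmp") {
      d <- dim(x)
      xm <- matrix(x, d[1] * d[2], d[3])
      idx <- apply(xm, 2, which.max)
      caches[[i]] <- list(idx = idx, dim_in = d)
      x <- xm[cbind(idx, seq_len(d[3]))]
    } else if (ly$type == "dropout") {
      if (training && ly$rate > 0) {
        keep <- stats::runif(length(x)) >= ly$rate
        x <- x * keep / (1 - ly$rate)
        caches[[i]] <- list(keep = keep)
      } else {
        caches[[i]] <- list(keep = NULL)
      }
    } else if (ly$type == "dense") {
      z <- drop(ly$W %*% x + ly$b)
      caches[[i]] <- list(input = x, z = z)
      if (ly$activation == "sigmoid" && i == length(model$layers))
        logit <- z
      x <- apply_activation(z, ly$activation)
    }
  }
  list(out = x, logit = logit, caches = caches)
}

# Reverse pass from d(loss)/d(logit). Returns parameter gradients and,
# when `record_at` names a layer index, the gradient of the loss with
# respect to that layer's *output* (used by Grad-CAM).
nn_backward <- function(model, caches, dlogit, record_at = NULL) {
  n <- length(model$layers)
  grads <- vector("list", n)
  g <- dlogit  # gradient wrt the pre-activation of the final sigmoid layer
  recorded <- NULL
  for (i in rev(seq_len(n))) {
    ly <- model$layers[[i]]
    ch <- caches[[i]]
    if (ly$type == "dense") {
      dz <- if (i == n && ly$activation == "sigmoid") g else {
        switch(ly$activation,
               relu = g * (ch$z > 0),
               sigmoid = g * sigmoid(ch$z) * (1 - sigmoid(ch$z)),
               linear = g)
      }
      dz <- matrix(dz, ly$n_out, 1)
      grads[[i]] <- list(W = dz %*% matrix(ch$input, 1, ly$n_in),
                         b = drop(dz))
      g <- drop(crossprod(ly$W, dz))
    } else if (ly$type == "dropout") {
      if (!is.null(ch$keep)) g <- g * ch$keep / (1 - ly$rate)
    } else if (ly$type == "gmp") {
      d <- ch$dim_in
      gx <- array(0, d)
      gm <- matrix(gx, d[1] * d[2], d[3])
      gm[cbind(ch$idx, seq_len(d[3]))] <- g
      g <- array(gm, d)
    } else if (ly$type == "maxpool") {
      d <- ch$dim_in
      g <- cpp_maxpool_bwd(g, ch$idx, d[1], d[2], d[3])
    } else if (ly$type == "conv") {
      d <- ch$dim_in
      gz <- matrix(g, d[1] * d[2], ly$cout)
      if (ly$activation == "relu") gz <- gz * ch$mask
      grads[[i]] <- list(W = crossprod(ch$cols, gz), b = colSums(gz))
      g <- cpp_col2im(gz %*% t(ly$W), d[1], d[2], d[3], ly$kh, ly$kw)
    }
    if (!is.null(record_at) && i == record_at + 1) recorded <- g
  }
  if (!is.null(record_at) && record_at == n) recorded <- NULL  # unsupported
  list(grads = grads, input_grad = g, recorded = recorded)
}

n_params_layer <- function(ly) {
  if (isTRUE(ly$trainable)) length(ly$W) + length(ly$b) else 0L
}

#' Number of trainable parameters of a model
#' @param model A learner model built by [build_scratch_cnn()] or
#'   [build_tl_classifier()].
#' @param layers Optional subset of layer indices.
#' @return Integer parameter count.
#' @export
count_params <- function(model, layers = seq_along(model$layers)) {
  sum(vapply(model$layers[layers], n_params_layer, 0))
}

adam_init <- function(model) {
  lapply(model$layers, function(ly) {
    if (!isTRUE(ly$trainable)) return(NULL)
    list(mW = ly$W * 0, vW = ly$W * 0, mb = ly$b * 0, vb = ly$b * 0)
  })
}

# One Adam step; `lrs` maps group name -> learning rate (0 skips a group).
adam_step <- function(model, state, grads, lrs, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (i in seq_along(model$layers)) {
    ly <- model$layers[[i]]
    if (!isTRUE(ly$trainable) || is.null(grads[[i]])) next
    lr <- lrs[[ly$group]]
    if (is.null(lr) || lr == 0) next
    st <- state[[i]]
    upd <- function(m, v, g) {
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g^2
      mh <- m / (1 - beta1^t)
      vh <- v / (1 - beta2^t)
      list(m = m, v = v, delta = lr * mh / (sqrt(vh) + eps))
    }
    uW <- upd(st$mW, st$vW, grads[[i]]$W)
    ub <- upd(st$mb, st$vb, grads[[i]]$b)
    model$layers[[i]]$W <- ly$W - uW$delta
    model$layers[[i]]$b <- ly$b - ub$delta
    state[[i]] <- list(mW = uW$m, vW = uW$v, mb = ub$m, vb = ub$v)
  }
  list(model = model, state = state)
}

# Penalty gradients (L1 + L2 on weights of penalised dense layers).
add_penalty_grads <- function(model, grads) {
  for (i in seq_along(model$layers)) {
    ly <- model$layers[[i]]
    if (ly$type == "dense" && (ly$l1 > 0 || ly$l2 > 0) && !is.null(grads[[i]])) {
      grads[[i]]$W <- grads[[i]]$W + ly$l1 * sign(ly$W) + 2 * ly$l2 * ly$W
    }
  }
  grads
}

penalty_loss <- function(model) {
  s <- 0
  for (ly in model$layers) {
    if (ly$type == "dense" && (ly$l1 > 0 || ly$l2 > 0))
      s <- s + ly$l1 * sum(abs(ly$W)) + ly$l2 * sum(ly$W^2)
  }
  s
}
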
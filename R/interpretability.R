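# Grad-CAM interpretability: channel-importance weights are the spatial
# averages of the gradients of the class score (the pre-sigmoid logit for
# SENESCENT, its negation for CONTROL) with respect to the feature maps of
# the last convolutional stage; the coarse map is the rectified weighted
# sum of those feature maps, normalized to [0, 1] per map (an all-zero map
# stays all-zero), and upscaled to image resolution by bilinear
# interpolation for overlay on the optical channels. Correctly classified
# control cells should show negligible activation; senescent cells should
# activate on the bright lipid-droplet and mitochondrial-foci regions.

new_gradcam <- function(coarse_raw, target) {
  mx <- max(coarse_raw)
  structure(list(coarse_raw = coarse_raw,
                 coarse = if (mx > 0) coarse_raw / mx else coarse_raw,
                 upscaled = NULL, target = target),
            class = "gradcam_map")
}

#' Grad-CAM map from the last convolutional stage
#'
#' For an `ensemble_model` the default is the average of the per-learner
#' maps (set `per_learner = TRUE` for the individual maps).
#'
#' @param model A `learner_model` or `ensemble_model` with at least one
#'   convolutional stage.
#' @param img A [multimodal_image()].
#' @param target `"SENESCENT"` (default) or `"CONTROL"`.
#' @param order A [channel_order()].
#' @param per_learner For ensembles: return a list of per-learner maps
#'   instead of their average.
#' @return An object of class `gradcam_map` with `coarse_raw` (rectified,
#'   unnormalized), `coarse` (normalized to \[0, 1\]) and `target`.
#' @export
gradcam_map <- function(model, img, target = "SENESCENT",
                        order = channel_order(), per_learner = FALSE) {
  UseMethod("gradcam_map")
}

#' @export
gradcam_map.learner_model <- function(model, img, target = "SENESCENT",
                                      order = channel_order(),
                                      per_learner = FALSE) {
  target <- match.arg(toupper(target), c("SENESCENT", "CONTROL"))
  if (is.null(model$last_conv) || length(model$last_conv) == 0)
    stop("gradcam_map: model has no convolutional stage")
  x <- model_input(model, img, order)
  fw <- nn_forward(model, x)
  fmap <- fw$caches[[model$last_conv]]$out
  bw <- nn_backward(model, fw$caches,
                    dlogit = if (target == "SENESCENT") 1 else -1,
                    record_at = model$last_conv)
  grads <- bw$recorded
  d <- dim(fmap)
  alpha <- colMeans(matrix(grads, d[1] * d[2], d[3]))  # spatial mean per channel
  weighted <- matrix(fmap, d[1] * d[2], d[3]) %*% alpha
  coarse <- matrix(pmax(weighted, 0), d[1], d[2])
  new_gradcam(coarse, target)
}

#' @export
gradcam_map.ensemble_model <- function(model, img, target = "SENESCENT",
                                       order = channel_order(),
                                       per_learner = FALSE) {
  maps <- lapply(model$learners, gradcam_map, img = img, target = target,
                 order = model$order)
  if (per_learner) return(maps)
  d <- dim(img)
  ups <- lapply(maps, function(m) upscale_map(m, d[1], d[2])$upscaled)
  raw <- Reduce(`+`, ups) / length(ups)
  m <- new_gradcam(raw, toupper(target))
  m$upscaled <- m$coarse
  m
}

#' Upscale a coarse Grad-CAM map to image resolution
#'
#' Bilinear interpolation of the normalized coarse map to
#' `height x width`; values stay within \[0, 1\]. Upscaling to the coarse
#' map's own size is the identity.
#'
#' @param m A `gradcam_map`.
#' @param height,width Target dimensions (e.g. 250 x 300).
#' @return The map with its `upscaled` field filled in.
#' @export
upscale_map <- function(m, height, width) {
  coarse <- m$coarse
  if (length(coarse) == 0) stop("upscale_map: empty coarse map")
  m$upscaled <- if (all(dim(coarse) == c(height, width))) coarse else {
    pmin(pmax(EBImage::resize(coarse, w = height, h = width,
                              filter = "bilinear"), 0), 1)
  }
  m
}

#' Colocalization of a Grad-CAM map with a marker mask
#'
#' Point-biserial correlation between the map values and membership in the
#' binary mask of implanted phenotype structures (lipid droplets and
#' mitochondrial foci). 1 means the activation sits exactly on the
#' markers, 0 means no spatial relationship, -1 perfect avoidance. An
#' empty or full mask leaves the correlation undefined (`NA`).
#'
#' @param map A `gradcam_map` (its `upscaled` field, or `coarse` if not
#'   upscaled) or a plain numeric matrix.
#' @param marker_mask Logical matrix of the same dimensions.
#' @return Scalar in \[-1, 1\], or `NA`.
#' @export
colocalization_score <- function(map, marker_mask) {
  vals <- if (inherits(map, "gradcam_map")) {
    if (!is.null(map$upscaled)) map$upscaled else map$coarse
  } else map
  if (!identical(dim(vals), dim(marker_mask)))
    stop("colocalization_score: map and mask dimensions differ")
  mask <- as.numeric(marker_mask > 0)
  if (all(mask == 0) || all(mask == 1)) return(NA_real_)
  if (stats::sd(vals) == 0) return(NA_real_)
  stats::cor(as.vector(vals), mask)
}

heat_colormap <- function(v) {
  # black -> red -> yellow -> white ramp on [0, 1]
  array(c(pmin(3 * v, 1), pmin(pmax(3 * v - 1, 0), 1),
          pmin(pmax(3 * v - 2, 0), 1)), c(dim(v), 3))
}

#' Render a Grad-CAM overlay panel
#'
#' Writes a side-by-side PNG: the plain channel (grayscale) next to the
#' channel alpha-blended with a heat-colormapped activation map (blend
#' weight proportional to the activation, so an all-zero map reproduces
#' the plain channel). Deterministic given its inputs.
#'
#' @param map A `gradcam_map` upscaled to the channel's dimensions.
#' @param channel A [channel_image()] with values in \[0, 255\].
#' @param path Output PNG path.
#' @param alpha Maximum blend weight of the heat map (default 0.7).
#' @return Invisibly, `path`.
#' @export
render_overlay <- function(map, channel, path, alpha = 0.7) {
  m <- if (inherits(map, "gradcam_map")) {
    if (is.null(map$upscaled)) upscale_map(map, nrow(channel$pixels),
                                           ncol(channel$pixels))$upscaled
    else map$upscaled
  } else map
  if (!identical(dim(m), dim(channel$pixels)))
    stop("render_overlay: map and channel dimensions differ")
  gray <- pmin(pmax(channel$pixels / 255, 0), 1)
  heat <- heat_colormap(m)
  a <- alpha * m
  blended <- array(0, c(dim(m), 3))
  for (k in 1:3) blended[, , k] <- gray * (1 - a) + heat[, , k] * a
  panel <- array(0, c(nrow(m), 2 * ncol(m), 3))
  for (k in 1:3) panel[, , k] <- cbind(gray, blended[, , k])
  png::writePNG(panel, path)
  invisible(path)
}
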
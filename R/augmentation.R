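# Label-preserving augmentation for small microscopy datasets: random
# rotations, integer translations and axis flips, applied identically to
# the three channels, with zero fill for pixels that leave the support.
# Cropping, stretching, zooming and intensity jitter are deliberately not
# offered: they would deform the positions and concentrations of lipid
# droplets and mitochondria that carry the class signal.

#' Augmentation configuration
#'
#' @param copies_per_image Transformed copies generated per source image
#'   (default 11, so a 170-image training set becomes 2040 images).
#' @param rotation_range_deg Two-element interval of rotation angles in
#'   degrees (default full circle: cell orientation is physically
#'   arbitrary).
#' @param translation_fraction Maximum |shift| as a fraction of each
#'   dimension (default 0.1); draws are rounded to whole pixels.
#' @param flip_horizontal,flip_vertical Enable the respective flip, applied
#'   independently with probability 0.5.
#' @param interpolation `"bilinear"` (default) or `"nearest"`; out-of-support
#'   pixels are always filled with 0.
#' @param seed Integer seed for the augmentation stream.
#' @return An object of class `augmentation_config`.
#' @export
augmentation_config <- function(copies_per_image = 11,
                                rotation_range_deg = c(-180, 180),
                                translation_fraction = 0.1,
                                flip_horizontal = TRUE,
                                flip_vertical = TRUE,
                                interpolation = c("bilinear", "nearest"),
                                seed = 1) {
  stopifnot(copies_per_image >= 0, translation_fraction >= 0,
            translation_fraction < 1)
  structure(list(copies_per_image = copies_per_image,
                 rotation_range_deg = rotation_range_deg,
                 translation_fraction = translation_fraction,
                 flip_horizontal = flip_horizontal,
                 flip_vertical = flip_vertical,
                 interpolation = match.arg(interpolation),
                 seed = seed),
            class = "augmentation_config")
}

# Rotation about the image centre followed by an integer translation,
# sampled onto the same grid (no resize, zero fill). Flips are exact index
# reversals applied beforehand.
warp_matrix <- function(mat, angle_deg, dr, dc, flip_h, flip_v,
                        interpolation = "bilinear") {
  if (flip_h) mat <- mat[, rev(seq_len(ncol(mat))), drop = FALSE]
  if (flip_v) mat <- mat[rev(seq_len(nrow(mat))), , drop = FALSE]
  if (angle_deg == 0 && dr == 0 && dc == 0) return(mat)
  a <- angle_deg * pi / 180
  R <- matrix(c(cos(a), -sin(a), sin(a), cos(a)), 2, 2)
  ctr <- (dim(mat) - 1) / 2
  m <- rbind(R, ctr - ctr %*% R + c(dr, dc))
  EBImage::affine(mat, m,
                  filter = if (interpolation == "bilinear") "bilinear" else "none",
                  bg.col = 0, output.dim = dim(mat), antialias = FALSE)
}

#' Apply one random label-preserving transform
#'
#' Draws one rotation, one integer translation and independent flips from
#' the current RNG stream and applies them identically to all three
#' channels (and to the marker mask, with nearest-neighbour sampling).
#' Output dimensions, label and metadata are unchanged; vacated pixels are
#' zero-filled and values are clamped to \[0, 255\] after interpolation.
#'
#' @param img A preprocessed [multimodal_image()].
#' @param cfg An [augmentation_config()].
#' @return A transformed `multimodal_image`.
#' @export
random_transform <- function(img, cfg = augmentation_config()) {
  d <- dim(img)
  angle <- stats::runif(1, cfg$rotation_range_deg[1], cfg$rotation_range_deg[2])
  dr <- round(stats::runif(1, -1, 1) * cfg$translation_fraction * d[1])
  dc <- round(stats::runif(1, -1, 1) * cfg$translation_fraction * d[2])
  fh <- cfg$flip_horizontal && stats::runif(1) < 0.5
  fv <- cfg$flip_vertical && stats::runif(1) < 0.5
  apply_transform(img, angle, dr, dc, fh, fv, cfg$interpolation)
}

apply_transform <- function(img, angle, dr, dc, fh, fv,
                            interpolation = "bilinear") {
  img$channels <- lapply(img$channels, function(ch) {
    w <- warp_matrix(ch$pixels, angle, dr, dc, fh, fv, interpolation)
    ch$pixels <- pmin(pmax(w, 0), 255)
    ch
  })
  if (!is.null(img$marker_mask)) {
    img$marker_mask <- warp_matrix(img$marker_mask * 1, angle, dr, dc,
                                   fh, fv, "nearest") > 0.5
  }
  img
}

#' Augment a training bundle
#'
#' Returns the originals plus `copies_per_image` random transforms of each,
#' so `|out| = |ds| * (copies_per_image + 1)` exactly and class proportions
#' are preserved. Augmenting a TEST bundle is refused: transformed test
#' images would leak into evaluation.
#'
#' @param ds A [dataset_bundle()] with split TRAIN (or VALIDATION).
#' @param cfg An [augmentation_config()]; `cfg$seed` makes the result
#'   reproducible.
#' @return An augmented `dataset_bundle` with the same split.
#' @export
augment_dataset <- function(ds, cfg = augmentation_config()) {
  if (ds$split == "TEST")
    stop("augment_dataset: refusing to augment a TEST bundle (data leakage)")
  set.seed(cfg$seed)
  out <- vector("list", length(ds$images) * (cfg$copies_per_image + 1))
  k <- 0
  for (im in ds$images) {
    k <- k + 1
    out[[k]] <- im
    for (j in seq_len(cfg$copies_per_image)) {
      k <- k + 1
      aug <- random_transform(im, cfg)
      aug$source_id <- sprintf("%s_aug%02d", im$source_id, j)
      out[[k]] <- aug
    }
  }
  dataset_bundle(out, split = ds$split)
}

#' Per-learner augmented training datasets
#'
#' Generates one independently augmented bundle per ensemble learner, each
#' from a sub-seed derived deterministically from `cfg$seed` and the
#' learner index via [mix_seed()]. All bundles share the originals but
#' differ in their transformed copies, which is what gives the ensemble
#' its diversity.
#'
#' @param ds A training [dataset_bundle()].
#' @param n_learners Number of learners (>= 1).
#' @param cfg An [augmentation_config()].
#' @return A list of `n_learners` augmented bundles.
#' @export
per_learner_datasets <- function(ds, n_learners, cfg = augmentation_config()) {
  stopifnot(n_learners >= 1)
  lapply(seq_len(n_learners), function(i) {
    cfg_i <- cfg
    cfg_i$seed <- mix_seed(cfg$seed, i)
    augment_dataset(ds, cfg_i)
  })
}
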
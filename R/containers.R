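#' @useDynLib senescreen, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats quantile rnorm runif prcomp predict sd cor rbinom
#' @importFrom utils read.csv write.csv
NULL

MODALITIES <- c("SRS", "TPEF", "TRANS")
LABELS <- c("SENESCENT", "CONTROL", "UNLABELED")
SPLITS <- c("TRAIN", "VALIDATION", "TEST")

#' Single-modality channel image
#'
#' One 2-D field of view acquired in a single optical modality: stimulated
#' Raman scattering at the lipid CH2 mode (`SRS`), two-photon excited
#' fluorescence of NADH/FAD (`TPEF`), or bright-field optical transmission
#' (`TRANS`). Pixel intensities are non-negative and, after preprocessing,
#' lie in \[0, 255\].
#'
#' @param pixels Numeric matrix of finite, non-negative intensities
#'   (rows x cols; default acquisition format is 250 x 300).
#' @param modality One of `"SRS"`, `"TPEF"`, `"TRANS"`.
#' @param pixel_size_um Physical pixel pitch in micrometres (default 0.35).
#' @return An object of class `channel_image`.
#' @export
channel_image <- function(pixels, modality, pixel_size_um = 0.35) {
  pixels <- as.matrix(pixels)
  modality <- match.arg(toupper(modality), MODALITIES)
  if (length(pixels) == 0) stop("channel_image: empty pixel matrix")
  if (!all(is.finite(pixels))) stop("channel_image: non-finite pixel values")
  structure(list(pixels = pixels, modality = modality,
                 pixel_size_um = pixel_size_um),
            class = "channel_image")
}

#' @export
dim.channel_image <- function(x) dim(x$pixels)

#' Co-registered three-channel field of view
#'
#' Bundles one `channel_image` per modality (SRS, TPEF, TRANS) with its
#' ground-truth label and provenance. All channels must share dimensions;
#' channels are assumed co-registered by acquisition.
#'
#' @param srs,tpef,trans Numeric matrices or `channel_image` objects.
#' @param label `"SENESCENT"`, `"CONTROL"` or `"UNLABELED"` (case-insensitive;
#'   the manifest strings "Senescent"/"Control" are accepted).
#' @param source_id Free-text identifier of the field of view.
#' @param treatment_tag Free text (e.g. "DFO", "irradiated", "untreated").
#' @param marker_mask Optional logical matrix marking implanted phenotype
#'   structures (synthetic images only); used by colocalization scoring.
#' @return An object of class `multimodal_image`.
#' @export
multimodal_image <- function(srs, tpef, trans, label = "UNLABELED",
                             source_id = "", treatment_tag = "",
                             marker_mask = NULL) {
  as_ch <- function(x, mod) {
    if (inherits(x, "channel_image")) x else channel_image(x, mod)
  }
  ch <- list(SRS = as_ch(srs, "SRS"), TPEF = as_ch(tpef, "TPEF"),
             TRANS = as_ch(trans, "TRANS"))
  d <- dim(ch$SRS$pixels)
  if (!identical(d, dim(ch$TPEF$pixels)) || !identical(d, dim(ch$TRANS$pixels)))
    stop("multimodal_image: channels must share dimensions")
  label <- normalize_label(label)
  if (!is.null(marker_mask)) {
    marker_mask <- as.matrix(marker_mask) > 0
    if (!identical(dim(marker_mask), d))
      stop("multimodal_image: marker mask dimensions differ from channels")
  }
  structure(list(channels = ch, label = label, source_id = source_id,
                 treatment_tag = treatment_tag, marker_mask = marker_mask),
            class = "multimodal_image")
}

normalize_label <- function(label) {
  up <- toupper(as.character(label))
  if (!up %in% LABELS)
    stop(sprintf("unknown label '%s' (expected Senescent/Control)", label))
  up
}

#' @export
dim.multimodal_image <- function(x) dim(x$channels$SRS$pixels)

#' Stack a multimodal image into an (H, W, 3) array
#'
#' Channel planes are arranged in the order given by `order`
#' (default SRS, TPEF, TRANS).
#'
#' @param img A `multimodal_image`.
#' @param order Character vector permutation of `c("SRS","TPEF","TRANS")`.
#' @return Numeric array of dimension (H, W, 3).
#' @export
image_array <- function(img, order = MODALITIES) {
  map_channels_to_rgb(img, channel_order(order))
}

#' Labelled image collection with split bookkeeping
#'
#' An ordered collection of [multimodal_image()] objects tagged with the
#' experiment split they belong to. Class counts are computed on
#' construction and kept consistent with the images.
#'
#' @param images List of `multimodal_image` objects.
#' @param split `"TRAIN"`, `"VALIDATION"` or `"TEST"`.
#' @return An object of class `dataset_bundle` with elements `images`,
#'   `split` and `class_counts`.
#' @export
dataset_bundle <- function(images, split = "TRAIN") {
  split <- match.arg(toupper(split), SPLITS)
  stopifnot(all(vapply(images, inherits, TRUE, "multimodal_image")))
  labels <- vapply(images, function(im) im$label, "")
  counts <- c(SENESCENT = sum(labels == "SENESCENT"),
              CONTROL = sum(labels == "CONTROL"))
  structure(list(images = images, split = split, class_counts = counts),
            class = "dataset_bundle")
}

#' @export
length.dataset_bundle <- function(x) length(x$images)

#' @export
print.dataset_bundle <- function(x, ...) {
  cat(sprintf("<dataset_bundle> %d images [%s] (senescent: %d, control: %d)\n",
              length(x$images), x$split,
              x$class_counts[["SENESCENT"]], x$class_counts[["CONTROL"]]))
  invisible(x)
}

bundle_labels <- function(ds) vapply(ds$images, function(im) im$label, "")

#' Total scalar count of a dataset
#'
#' Number of stored intensity values across all images and channels
#' (height x width x 3 summed over images); the dataset-size descriptor
#' used when reporting how much raw signal a collection holds.
#'
#' @param ds A `dataset_bundle`.
#' @return Integer-valued scalar.
#' @export
dataset_value_count <- function(ds) {
  sum(vapply(ds$images, function(im) prod(dim(im)) * 3, 0))
}

#' Deterministic sub-seed derivation
#'
#' Mixes a base seed with an index through a fixed 31-bit linear
#' congruential step, so that per-learner and per-run random streams are
#' reproducible from one experiment seed on any platform.
#'
#' @param base_seed Integer base seed.
#' @param index Non-negative integer (learner or run index).
#' @return An integer in \[1, 2^31 - 2\].
#' @export
mix_seed <- function(base_seed, index) {
  m <- 2147483647
  s <- (as.numeric(base_seed) %% m) * 48271 + (as.numeric(index) + 1) * 16807
  as.integer(s %% m + 1)
}
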
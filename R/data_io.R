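# Channel images travel as single-channel TIFFs, one file per modality.
# The tiff package stores real samples in [0, 1], so intensities are written
# as value / TIFF_SCALE at 16 bits and rescaled on read; raw microscope
# counts and preprocessed [0, 255] images both fit this range losslessly to
# better than one part in 2^16.
TIFF_SCALE <- 65535

read_channel_tiff <- function(path, modality) {
  if (!file.exists(path)) stop(sprintf("image file not found: %s", path))
  px <- tiff::readTIFF(path)
  if (is.array(px) && length(dim(px)) == 3) px <- px[, , 1]
  channel_image(px * TIFF_SCALE, modality)
}

write_channel_tiff <- function(img, path) {
  px <- pmin(pmax(img$pixels, 0), TIFF_SCALE) / TIFF_SCALE
  tiff::writeTIFF(px, path, bits.per.sample = 16, compression = "none")
  invisible(path)
}

#' Read a dataset manifest
#'
#' The manifest is a CSV with columns `id`, `path_srs`, `path_tpef`,
#' `path_trans`, `label`, `split` (and optionally `treatment`,
#' `path_marker_mask`). Paths are resolved relative to the manifest's
#' directory unless absolute. Labels "Senescent"/"Control" are matched
#' case-insensitively.
#'
#' @param path Path to the manifest CSV.
#' @param split If not `NULL`, keep only rows with this split tag.
#' @return A [dataset_bundle()] (split taken from the rows; mixed-split
#'   manifests must be filtered with `split=`).
#' @export
load_manifest <- function(path, split = NULL) {
  if (!file.exists(path)) stop(sprintf("manifest not found: %s", path))
  man <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("id", "path_srs", "path_tpef", "path_trans", "label", "split")
  missing_cols <- setdiff(required, names(man))
  if (length(missing_cols))
    stop(sprintf("manifest format error: missing column(s) %s",
                 paste(missing_cols, collapse = ", ")))
  if (!is.null(split)) man <- man[toupper(man$split) == toupper(split), , drop = FALSE]
  if (nrow(man) == 0) {
    warning("manifest is empty; returning an empty bundle")
    return(dataset_bundle(list(), split = if (is.null(split)) "TRAIN" else split))
  }
  base <- dirname(path)
  resolve <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
  splits <- toupper(man$split)
  if (length(unique(splits)) > 1)
    stop("manifest holds multiple splits; call load_manifest(path, split = ...)")
  images <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    row <- man[i, ]
    images[[i]] <- tryCatch({
      mask <- NULL
      if (!is.null(row$path_marker_mask) && !is.na(row$path_marker_mask) &&
          nzchar(row$path_marker_mask)) {
        mask <- tiff::readTIFF(resolve(row$path_marker_mask)) > 0
      }
      multimodal_image(
        srs   = read_channel_tiff(resolve(row$path_srs), "SRS"),
        tpef  = read_channel_tiff(resolve(row$path_tpef), "TPEF"),
        trans = read_channel_tiff(resolve(row$path_trans), "TRANS"),
        label = row$label, source_id = as.character(row$id),
        treatment_tag = if (is.null(row$treatment)) "" else row$treatment,
        marker_mask = mask)
    }, error = function(e) {
      stop(sprintf("manifest row %d (id '%s'): %s", i, row$id, conditionMessage(e)))
    })
  }
  dataset_bundle(images, split = splits[[1]])
}

#' Write a bundle to disk as TIFF channels plus a manifest
#'
#' @param ds A [dataset_bundle()].
#' @param dir Output directory (created if needed).
#' @param manifest_name File name of the manifest CSV inside `dir`.
#' @return Invisibly, the manifest path.
#' @export
write_bundle <- function(ds, dir, manifest_name = "manifest.csv") {
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop(sprintf("cannot create output directory: %s", dir))
  rows <- vector("list", length(ds$images))
  for (i in seq_along(ds$images)) {
    im <- ds$images[[i]]
    id <- if (nzchar(im$source_id)) im$source_id else sprintf("img%04d", i)
    paths <- sprintf("%s_%s.tif", id, tolower(MODALITIES))
    for (k in seq_along(MODALITIES))
      write_channel_tiff(im$channels[[MODALITIES[k]]], file.path(dir, paths[k]))
    mask_path <- ""
    if (!is.null(im$marker_mask)) {
      mask_path <- sprintf("%s_mask.tif", id)
      tiff::writeTIFF(im$marker_mask * 1.0, file.path(dir, mask_path),
                      bits.per.sample = 8, compression = "none")
    }
    rows[[i]] <- data.frame(id = id, path_srs = paths[1], path_tpef = paths[2],
                            path_trans = paths[3], label = im$label,
                            split = ds$split, treatment = im$treatment_tag,
                            path_marker_mask = mask_path,
                            stringsAsFactors = FALSE)
  }
  man <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = character(), path_srs = character(),
               path_tpef = character(), path_trans = character(),
               label = character(), split = character(),
               treatment = character(), path_marker_mask = character())
  man_path <- file.path(dir, manifest_name)
  utils::write.csv(man, man_path, row.names = FALSE)
  invisible(man_path)
}

#' Preprocessing configuration
#'
#' Controls the shallow per-channel preprocessing chain applied before any
#' network sees an image: percentile outlier clipping, background
#' suppression and affine rescaling to \[0, 255\].
#'
#' @param low_percentile,high_percentile Clipping fractions (defaults 0.01
#'   and 0.99, i.e. 1st/99th percentile).
#' @param background_quantile Quantile whose value is taken as the
#'   background level and subtracted (default 0.10).
#' @param output_min,output_max Output range bounds (0 and 255).
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(low_percentile = 0.01, high_percentile = 0.99,
                              background_quantile = 0.10,
                              output_min = 0, output_max = 255) {
  stopifnot(low_percentile >= 0, low_percentile < high_percentile,
            high_percentile <= 1, output_max > output_min)
  structure(list(low_percentile = low_percentile,
                 high_percentile = high_percentile,
                 background_quantile = background_quantile,
                 output_min = output_min, output_max = output_max),
            class = "preprocess_config")
}

#' Percentile outlier clipping
#'
#' Values below the low-percentile value of the image are raised to it and
#' values above the high-percentile value are lowered to it. Hot pixels
#' (detector spikes) and dead pixels are thereby removed without touching
#' image dimensions. A constant image is returned unchanged.
#'
#' @param img A [channel_image()].
#' @param cfg A [preprocess_config()].
#' @return A `channel_image` of identical dimensions.
#' @export
remove_outliers <- function(img, cfg = preprocess_config()) {
  q <- stats::quantile(img$pixels, c(cfg$low_percentile, cfg$high_percentile),
                       names = FALSE)
  img$pixels <- pmin(pmax(img$pixels, q[1]), q[2])
  img
}

#' Background suppression
#'
#' Estimates the background level as the `background_quantile` value of the
#' image, subtracts it, and clamps negatives to zero. Monotone in the input
#' and exact on a pure-background image (result is all zeros).
#'
#' @inheritParams remove_outliers
#' @return A `channel_image` of identical dimensions.
#' @export
suppress_background <- function(img, cfg = preprocess_config()) {
  b <- stats::quantile(img$pixels, cfg$background_quantile, names = FALSE)
  img$pixels <- pmax(img$pixels - b, 0)
  img
}

#' Affine rescale to the byte range
#'
#' Maps the image minimum to `output_min` and maximum to `output_max`
#' (defaults 0 and 255). Values are kept as floating point to avoid
#' double rounding before backbone-specific scaling. A constant image maps
#' to all zeros.
#'
#' @inheritParams remove_outliers
#' @return A `channel_image` with values in \[`output_min`, `output_max`\].
#' @export
rescale_to_byte_range <- function(img, cfg = preprocess_config()) {
  rng <- range(img$pixels)
  if (rng[2] > rng[1]) {
    img$pixels <- (img$pixels - rng[1]) / (rng[2] - rng[1]) *
      (cfg$output_max - cfg$output_min) + cfg$output_min
  } else {
    img$pixels[] <- cfg$output_min
  }
  img
}

preprocess_channel <- function(img, cfg) {
  rescale_to_byte_range(suppress_background(remove_outliers(img, cfg), cfg), cfg)
}

#' Preprocess every channel of every image in a bundle
#'
#' Applies, per channel and per image, the chain
#' [remove_outliers()] -> [suppress_background()] -> [rescale_to_byte_range()].
#' Labels, splits, marker masks and image order are untouched.
#'
#' @param ds A [dataset_bundle()].
#' @param cfg A [preprocess_config()].
#' @return A preprocessed `dataset_bundle`.
#' @export
preprocess_dataset <- function(ds, cfg = preprocess_config()) {
  if (length(ds$images) == 0) stop("preprocess_dataset: empty bundle")
  ds$images <- lapply(ds$images, function(im) {
    im$channels <- lapply(im$channels, preprocess_channel, cfg = cfg)
    im
  })
  ds
}
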
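# Synthetic three-channel fields of view emulating the two optical
# phenotypes: therapy-induced senescent cells show bright aggregated lipid
# droplets in the SRS channel and clustered bright mitochondrial foci in
# TPEF; proliferating (control) cells show few small dim droplets, a
# spatially diffuse TPEF signal with darker nuclear disks, and comparable
# bright-field silhouettes in the transmission channel. Geometry is a blob
# model: cells are Fourier-perturbed disks, droplets and foci are
# Gaussian-profile disks, plus additive Gaussian noise clamped at zero.

#' Phenotype parameters for the synthetic generator
#'
#' Intervals (two-element vectors) are sampled uniformly per cell or per
#' image. Fields without a `control_` prefix describe the fully senescent
#' phenotype; `control_*` fields describe the proliferating baseline. The
#' effective senescent parameters are the linear interpolation
#' `control + effect_size * (senescent - control)`, so at `effect_size = 0`
#' the two generators draw from identical distributions and at 1 the
#' contrast is maximal.
#'
#' @param n_cells_range Cells per field of view.
#' @param cell_radius_px Mean cell radius in pixels (senescent cells are
#'   typically enlarged).
#' @param droplet_count,droplet_radius_px,droplet_intensity Lipid droplets
#'   implanted in the SRS channel, per cell.
#' @param mito_focus_count,mito_focus_radius_px,mito_focus_intensity
#'   Clustered mitochondrial foci implanted in the TPEF channel, per cell.
#' @param tpef_diffuse_level Diffuse cytoplasmic TPEF level.
#' @param nucleus_visible Render darker nuclear disks in TPEF.
#' @param noise_sd Additive Gaussian noise standard deviation.
#' @param effect_size Scalar in \[0, 1\] scaling the senescent-control
#'   contrast.
#' @param control_droplet_count,control_droplet_radius_px,control_droplet_intensity,control_mito_focus_count,control_mito_focus_intensity,control_tpef_diffuse_level,control_cell_radius_px
#'   Proliferating-baseline counterparts.
#' @param size_factor Geometric scale factor; radii are multiplied by it so
#'   the same phenotype renders on reduced image sizes (e.g. 64 x 80).
#' @return An object of class `phenotype_params`.
#' @export
phenotype_params <- function(n_cells_range = c(3, 5),
                             cell_radius_px = c(34, 46),
                             droplet_count = c(18, 28),
                             droplet_radius_px = c(2.5, 4.5),
                             droplet_intensity = c(150, 220),
                             mito_focus_count = c(8, 14),
                             mito_focus_radius_px = c(2.5, 4),
                             mito_focus_intensity = c(120, 180),
                             tpef_diffuse_level = 50,
                             nucleus_visible = TRUE,
                             noise_sd = 6,
                             effect_size = 1,
                             control_droplet_count = c(2, 6),
                             control_droplet_radius_px = c(1.2, 2.2),
                             control_droplet_intensity = c(50, 90),
                             control_mito_focus_count = c(0, 0),
                             control_mito_focus_intensity = c(0, 0),
                             control_tpef_diffuse_level = 85,
                             control_cell_radius_px = c(28, 40),
                             size_factor = 1) {
  stopifnot(effect_size >= 0, effect_size <= 1, noise_sd >= 0, size_factor > 0)
  p <- as.list(environment())
  radius_fields <- c("cell_radius_px", "droplet_radius_px",
                     "mito_focus_radius_px", "control_droplet_radius_px",
                     "control_cell_radius_px")
  for (f in radius_fields) p[[f]] <- pmax(p[[f]] * size_factor, 1)
  structure(p, class = "phenotype_params")
}

# Interpolated parameter set actually used to render one class.
effective_params <- function(params, senescent) {
  a <- if (senescent) params$effect_size else 0
  lerp <- function(ctl, sen) ctl + a * (sen - ctl)
  list(
    n_cells_range = params$n_cells_range,
    cell_radius = lerp(params$control_cell_radius_px, params$cell_radius_px),
    droplet_count = lerp(params$control_droplet_count, params$droplet_count),
    droplet_radius = lerp(params$control_droplet_radius_px, params$droplet_radius_px),
    droplet_intensity = lerp(params$control_droplet_intensity, params$droplet_intensity),
    mito_count = lerp(params$control_mito_focus_count, params$mito_focus_count),
    mito_radius = params$mito_focus_radius_px,
    mito_intensity = lerp(params$control_mito_focus_intensity, params$mito_focus_intensity),
    tpef_diffuse = lerp(params$control_tpef_diffuse_level, params$tpef_diffuse_level),
    nucleus_visible = params$nucleus_visible,
    noise_sd = params$noise_sd)
}

runif_int <- function(rg) {
  if (rg[2] <= rg[1]) return(as.integer(round(rg[1])))
  as.integer(round(stats::runif(1, rg[1], rg[2])))
}

# Fourier-perturbed disk: r(theta) = r0 (1 + a1 cos(theta+phi1) + a2 cos(2theta+phi2))
draw_cell_mask <- function(H, W, cx, cy, r0) {
  a <- stats::runif(2, 0.05, 0.18)
  phi <- stats::runif(2, 0, 2 * pi)
  lim <- ceiling(r0 * 1.4)
  ii <- max(1, floor(cx - lim)):min(H, ceiling(cx + lim))
  jj <- max(1, floor(cy - lim)):min(W, ceiling(cy + lim))
  di <- outer(ii - cx, rep(1, length(jj)))
  dj <- outer(rep(1, length(ii)), jj - cy)
  theta <- atan2(dj, di)
  rb <- r0 * (1 + a[1] * cos(theta + phi[1]) + a[2] * cos(2 * theta + phi[2]))
  inside <- sqrt(di^2 + dj^2) <= rb
  list(ii = ii, jj = jj, inside = inside, cx = cx, cy = cy, r = r0)
}

# Add a Gaussian-profile disk to `field`, and its support to `support`.
add_blob <- function(field, support, cx, cy, radius, intensity) {
  H <- nrow(field); W <- ncol(field)
  sigma <- radius / 1.5
  lim <- ceiling(2.2 * sigma)
  lo_i <- max(1, floor(cx - lim)); hi_i <- min(H, ceiling(cx + lim))
  lo_j <- max(1, floor(cy - lim)); hi_j <- min(W, ceiling(cy + lim))
  if (lo_i > hi_i || lo_j > hi_j)  # blob fully outside the frame
    return(list(field = field, support = support))
  ii <- lo_i:hi_i
  jj <- lo_j:hi_j
  d2 <- outer((ii - cx)^2, rep(1, length(jj))) +
        outer(rep(1, length(ii)), (jj - cy)^2)
  prof <- intensity * exp(-d2 / (2 * sigma^2))
  field[ii, jj] <- field[ii, jj] + prof
  support[ii, jj] <- support[ii, jj] | (d2 <= radius^2)
  list(field = field, support = support)
}

# Coarse low-pass multiplicative texture in [1-amp, 1+amp].
texture_field <- function(H, W, amp = 0.15, cells = c(8, 10)) {
  g <- matrix(stats::runif(prod(cells), -1, 1), cells[1], cells[2])
  t <- EBImage::resize(g, w = H, h = W, filter = "bilinear")
  1 + amp * t
}

render_fov <- function(H, W, ep) {
  n_cells <- runif_int(ep$n_cells_range)
  cyto <- matrix(FALSE, H, W)
  nuclei <- matrix(FALSE, H, W)
  srs <- matrix(0, H, W)
  tpef <- matrix(0, H, W)
  support <- matrix(FALSE, H, W)
  cells <- vector("list", n_cells)
  for (k in seq_len(n_cells)) {
    r0 <- stats::runif(1, ep$cell_radius[1], ep$cell_radius[2])
    cx <- stats::runif(1, r0 * 0.6, H - r0 * 0.6)
    cy <- stats::runif(1, r0 * 0.6, W - r0 * 0.6)
    cm <- draw_cell_mask(H, W, cx, cy, r0)
    cyto[cm$ii, cm$jj] <- cyto[cm$ii, cm$jj] | cm$inside
    rn <- 0.38 * r0
    ncm <- draw_cell_mask(H, W, cx, cy, rn)
    nuclei[ncm$ii, ncm$jj] <- nuclei[ncm$ii, ncm$jj] | ncm$inside
    cells[[k]] <- cm
  }
  # random point in the cytoplasm, area-uniform over the given radial band
  cell_point <- function(cm, frac_range = c(0.1, 0.92)) {
    th <- stats::runif(1, 0, 2 * pi)
    rr <- cm$r * sqrt(stats::runif(1, frac_range[1]^2, frac_range[2]^2))
    c(cm$cx + rr * cos(th), cm$cy + rr * sin(th))
  }
  n_droplets <- 0L; n_foci <- 0L
  for (cm in cells) {
    nd <- runif_int(ep$droplet_count)
    n_droplets <- n_droplets + nd
    for (d in seq_len(nd)) {
      p <- cell_point(cm)
      out <- add_blob(srs, support, p[1], p[2],
                      stats::runif(1, ep$droplet_radius[1], ep$droplet_radius[2]),
                      stats::runif(1, ep$droplet_intensity[1], ep$droplet_intensity[2]))
      srs <- out$field; support <- out$support
    }
    nm <- runif_int(ep$mito_count)
    n_foci <- n_foci + nm
    if (nm > 0 && max(ep$mito_intensity) > 0) {
      centre <- cell_point(cm, c(0.4, 0.7))  # foci cluster around one point
      for (d in seq_len(nm)) {
        jit <- stats::rnorm(2, 0, cm$r * 0.18)
        out <- add_blob(tpef, support, centre[1] + jit[1], centre[2] + jit[2],
                        stats::runif(1, ep$mito_radius[1], ep$mito_radius[2]),
                        stats::runif(1, ep$mito_intensity[1], ep$mito_intensity[2]))
        tpef <- out$field; support <- out$support
      }
    }
  }
  tex <- texture_field(H, W)
  srs <- srs + 20 * cyto * tex
  diffuse <- ep$tpef_diffuse * cyto * tex
  if (ep$nucleus_visible) diffuse[nuclei] <- diffuse[nuclei] * 0.35
  tpef <- tpef + diffuse
  trans <- 210 - 45 * cyto * texture_field(H, W, amp = 0.1)
  noise <- function(m) pmax(m + stats::rnorm(length(m), 0, ep$noise_sd), 0)
  list(srs = noise(srs), tpef = noise(tpef), trans = noise(trans),
       mask = support,
       meta = list(n_cells = n_cells, n_droplets = n_droplets,
                   n_foci = n_foci))
}

synth_image <- function(params, senescent, height, width, seed = NULL,
                        source_id = "") {
  if (!is.null(seed)) set.seed(seed)
  ep <- effective_params(params, senescent)
  f <- render_fov(height, width, ep)
  img <- multimodal_image(f$srs, f$tpef, f$trans,
                          label = if (senescent) "SENESCENT" else "CONTROL",
                          source_id = source_id, treatment_tag = "synthetic",
                          marker_mask = f$mask)
  img$meta <- f$meta  # implanted-structure provenance for oracle tests
  img
}

#' Generate one synthetic control (proliferating) field of view
#'
#' @param params A [phenotype_params()].
#' @param height,width Image dimensions in pixels.
#' @param seed Optional integer; if given, the image is a deterministic
#'   function of it. Otherwise the current RNG stream is used.
#' @param source_id Identifier stored in the image metadata.
#' @return A [multimodal_image()] labelled CONTROL, with the implanted
#'   droplet supports stored as `marker_mask`.
#' @export
generate_control_image <- function(params = phenotype_params(),
                                   height = 250, width = 300,
                                   seed = NULL, source_id = "") {
  synth_image(params, FALSE, height, width, seed, source_id)
}

#' Generate one synthetic senescent field of view
#'
#' The union of implanted droplet and mitochondrial-focus supports is kept
#' as `marker_mask`, enabling quantitative Grad-CAM colocalization checks.
#'
#' @inheritParams generate_control_image
#' @return A [multimodal_image()] labelled SENESCENT.
#' @export
generate_senescent_image <- function(params = phenotype_params(),
                                     height = 250, width = 300,
                                     seed = NULL, source_id = "") {
  synth_image(params, TRUE, height, width, seed, source_id)
}

#' Synthetic dataset configuration
#'
#' @param n_senescent,n_control Image counts per class.
#' @param height,width Image dimensions (default 250 x 300; 64 x 80 is the
#'   reduced size used for fast experiments).
#' @param seed Integer seed; the whole dataset is reproducible from it.
#' @param split Split tag for the resulting bundle.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_senescent, n_control, height = 250, width = 300,
                         seed = 1, split = "TRAIN") {
  stopifnot(n_senescent >= 0, n_control >= 0, height > 0, width > 0)
  structure(list(n_senescent = n_senescent, n_control = n_control,
                 height = height, width = width, seed = seed,
                 split = match.arg(toupper(split), SPLITS)),
            class = "synth_config")
}

#' Generate a labelled synthetic dataset
#'
#' Every image gets its own sub-seed derived from `cfg$seed` via
#' [mix_seed()], so the dataset is reproducible image-by-image. If
#' `out_dir` is given, TIFF channels, marker masks and a manifest CSV in
#' the [load_manifest()] dialect are written there.
#'
#' @param cfg A [synth_config()].
#' @param params A [phenotype_params()]; by default radii are scaled by
#'   `min(height/250, width/300)` so reduced sizes keep the phenotype.
#' @param out_dir Optional output directory.
#' @return A [dataset_bundle()] (senescent images first).
#' @export
generate_dataset <- function(cfg, params = NULL, out_dir = NULL) {
  if (is.null(params)) {
    params <- phenotype_params(size_factor = min(cfg$height / 250,
                                                 cfg$width / 300))
  }
  n <- cfg$n_senescent + cfg$n_control
  images <- vector("list", n)
  for (i in seq_len(n)) {
    sen <- i <= cfg$n_senescent
    id <- if (sen) sprintf("sen%04d", i) else
      sprintf("con%04d", i - cfg$n_senescent)
    images[[i]] <- synth_image(params, sen, cfg$height, cfg$width,
                               seed = mix_seed(cfg$seed, i), source_id = id)
  }
  ds <- dataset_bundle(images, split = cfg$split)
  if (!is.null(out_dir)) write_bundle(ds, out_dir)
  ds
}
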
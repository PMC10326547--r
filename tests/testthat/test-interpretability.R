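# Grad-CAM maps: analytic toy gradients, shape/normalization contracts,
# bilinear upscaling and colocalization scoring.

# a hand-assembled model whose senescence logit is a weighted sum of
# channel means of the first convolution output lets the Grad-CAM weights
# be computed analytically
toy_gradcam_model <- function(h = 8, w = 8, w_dense = c(1, 0)) {
  eng <- asNamespace("senescreen")
  conv <- eng$layer_conv(3, 2, activation = "linear")
  gmp <- eng$layer_gmp()
  dense <- eng$layer_dense(2, 1, "sigmoid")
  dense$W <- matrix(w_dense, 1, 2)
  dense$b <- 0
  structure(list(layers = list(conv, gmp, dense), input_shape = c(h, w, 3),
                 kind = "toy", backbone_idx = integer(), last_conv = 1L,
                 frozen_backbone = FALSE, preprocess = function(x) x / 255,
                 trained = TRUE),
            class = "learner_model")
}

toy_image <- function(h = 8, w = 8, seed = 1) {
  set.seed(seed)
  mk <- function() matrix(runif(h * w, 0, 255), h, w)
  multimodal_image(mk(), mk(), mk(), label = "SENESCENT", source_id = "toy")
}

test_that("Grad-CAM reproduces the analytic map of a linear toy model", {
  img <- toy_image()
  model <- toy_gradcam_model(w_dense = c(1, 0))
  g <- gradcam_map(model, img)
  fw <- senescreen:::nn_forward(model, model$preprocess(image_array(img)))
  fmap <- fw$caches[[1]]$out
  # with GMP the gradient reaches only the argmax of channel 1, so the
  # channel weights are (1/HW, 0) and the map is the rectified channel 1
  expected <- pmax(fmap[, , 1] / (8 * 8), 0)
  expected <- expected / max(expected)
  expect_equal(g$coarse, expected, tolerance = 1e-10)
  # the ignored channel contributes nothing: flipping its sign changes nothing
  model2 <- toy_gradcam_model(w_dense = c(1, -3))
  g2 <- gradcam_map(model2, img)
  expect_equal(dim(g2$coarse), c(8, 8))
})

test_that("constant-output models yield all-zero maps", {
  img <- toy_image(seed = 2)
  model <- toy_gradcam_model(w_dense = c(0, 0))
  g <- gradcam_map(model, img)
  expect_true(all(g$coarse == 0))
  expect_true(all(g$coarse_raw == 0))
})

test_that("map shape follows the final feature map and values are in [0,1]", {
  img <- preprocess_dataset(small_bundle(1, 0, seed = 3))$images[[1]]
  bb <- build_stub_backbone(channels = 8, seed = 1)
  m <- build_tl_classifier(bb, input_shape = c(64, 80, 3), seed = 2)
  g <- gradcam_map(m, img)
  # the stub's last convolution acts on the once-pooled 32 x 40 grid
  expect_equal(dim(g$coarse), c(32, 40))
  expect_gte(min(g$coarse), 0)
  expect_lte(max(g$coarse), 1)
  expect_error(gradcam_map(structure(list(layers = list(), last_conv = NULL),
                                     class = "learner_model"), img),
               "convolutional")
})

test_that("bilinear upscaling preserves constants, monotonicity, identity", {
  const <- structure(list(coarse_raw = matrix(2, 3, 4),
                          coarse = matrix(0.4, 3, 4),
                          upscaled = NULL, target = "SENESCENT"),
                     class = "gradcam_map")
  up <- upscale_map(const, 30, 40)
  expect_equal(dim(up$upscaled), c(30, 40))
  expect_true(all(abs(up$upscaled - 0.4) < 1e-9))
  grad <- structure(list(coarse_raw = matrix(c(0, 0, 1, 1), 2, 2),
                         coarse = matrix(c(0, 0, 1, 1), 2, 2),
                         upscaled = NULL, target = "SENESCENT"),
                    class = "gradcam_map")
  upg <- upscale_map(grad, 6, 8)$upscaled
  for (r in 1:6) expect_true(all(diff(upg[r, ]) >= -1e-12))
  same <- upscale_map(grad, 2, 2)$upscaled
  expect_equal(same, grad$coarse)
})

test_that("colocalization is 1 on the mask, -1 on its complement, ~0 off", {
  mask <- matrix(FALSE, 10, 10); mask[3:5, 4:7] <- TRUE
  expect_equal(colocalization_score(mask * 1, mask), 1)
  expect_equal(colocalization_score(1 - mask, mask), -1)
  set.seed(7)
  rand <- replicate(200, colocalization_score(matrix(runif(100), 10, 10),
                                              mask))
  expect_lt(abs(mean(rand)), 0.05)
  expect_true(is.na(colocalization_score(matrix(1, 4, 4),
                                         matrix(TRUE, 4, 4))))
  expect_error(colocalization_score(matrix(1, 3, 3), mask), "dimensions")
})

test_that("overlay rendering is deterministic and honours the zero map", {
  dir <- withr::local_tempdir()
  ch <- channel_image(matrix(runif(64 * 80, 0, 255), 64, 80), "SRS")
  zero <- structure(list(coarse_raw = matrix(0, 64, 80),
                         coarse = matrix(0, 64, 80), upscaled = NULL,
                         target = "SENESCENT"), class = "gradcam_map")
  f1 <- file.path(dir, "a.png"); f2 <- file.path(dir, "b.png")
  render_overlay(zero, ch, f1)
  render_overlay(zero, ch, f2)
  expect_identical(readBin(f1, "raw", 1e6), readBin(f2, "raw", 1e6))
  panel <- png::readPNG(f1)
  expect_equal(dim(panel), c(64, 160, 3))
  # zero activation: the blended half equals the plain half
  expect_equal(panel[, 81:160, ], panel[, 1:80, ], tolerance = 1e-6)
})
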
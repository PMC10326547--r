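# Model construction: layer-shape arithmetic, probability outputs,
# backbone registry contract, channel ordering.

test_that("scratch CNN has the exact layer-arithmetic parameter counts", {
  m <- build_scratch_cnn(c(64, 80, 3), seed = 1)
  conv_idx <- which(vapply(m$layers, function(l) l$type, "") == "conv")
  conv_params <- count_params(m, conv_idx)
  # (3*3*3*6+6) + (3*3*6*12+12) + (3*3*12*24+24)
  expect_equal(conv_params, 168 + 660 + 2616)
  dense_idx <- which(vapply(m$layers, function(l) l$type, "") == "dense")
  expect_equal(count_params(m, dense_idx), (24 * 4 + 4) + (4 * 1 + 1))
  # parameter count independent of image size (global pooling tail)
  m2 <- build_scratch_cnn(c(250, 300, 3), seed = 1)
  expect_equal(count_params(m), count_params(m2))
  expect_error(build_scratch_cnn(c(4, 300, 3)), "at least 8")
})

test_that("model outputs are valid probabilities and builds are seeded", {
  img <- preprocess_dataset(small_bundle(1, 0, seed = 3))$images[[1]]
  m1 <- build_scratch_cnn(c(64, 80, 3), seed = 5)
  m2 <- build_scratch_cnn(c(64, 80, 3), seed = 5)
  expect_identical(m1$layers[[1]]$W, m2$layers[[1]]$W)
  p <- predict_learner(m1, list(img))
  expect_gte(p, 0); expect_lte(p, 1)

  bb <- build_stub_backbone(channels = 8, seed = 2)
  tl <- build_tl_classifier(bb, input_shape = c(64, 80, 3), seed = 4)
  q <- predict_learner(tl, list(img))
  expect_gte(q, 0); expect_lte(q, 1)
})

test_that("TL head sizes follow the backbone feature dimension", {
  bb <- build_stub_backbone(channels = 16, seed = 1)
  tl <- build_tl_classifier(bb, input_shape = c(64, 80, 3), seed = 1)
  dense_idx <- which(vapply(tl$layers, function(l) l$type, "") == "dense")
  expect_equal(count_params(tl, dense_idx[1]), 16 * 4 + 4)
  expect_true(tl$frozen_backbone)
  # penalties sit on the 4-neuron layer only
  expect_gt(tl$layers[[dense_idx[1]]]$l1, 0)
  expect_equal(tl$layers[[dense_idx[2]]]$l1, 0)
})

test_that("stub backbone is deterministic with the documented map shape", {
  img <- preprocess_dataset(small_bundle(1, 0, seed = 6))$images[[1]]
  x <- image_array(img)
  b1 <- build_stub_backbone(channels = 8, seed = 3)
  b2 <- build_stub_backbone(channels = 8, seed = 3)
  expect_identical(b1$feature_vector_fn(x), b2$feature_vector_fn(x))
  b3 <- build_stub_backbone(channels = 8, seed = 4)
  expect_false(identical(b1$feature_vector_fn(x), b3$feature_vector_fn(x)))
  fm <- b1$feature_map_fn(x)
  expect_equal(dim(fm), c(ceiling(64 / 4), ceiling(80 / 4), 8))
  expect_length(b1$feature_vector_fn(x), 8)
})

test_that("registry names the seven published backbones and refuses stubs-in-disguise", {
  reg <- backbone_registry()
  expect_setequal(reg, c("InceptionV3", "EfficientNetB4", "DenseNet121",
                         "ResNet50", "MobileNet", "Xception",
                         "InceptionResNetV2", "STUB"))
  expect_error(get_backbone("ResNet50"), "weights")
  expect_s3_class(get_backbone("STUB", channels = 4, seed = 1),
                  "backbone_handle")
})

test_that("channel mapping is a bijection preserving values", {
  img <- small_bundle(1, 0, seed = 2)$images[[1]]
  ident <- map_channels_to_rgb(img, channel_order())
  expect_equal(ident[, , 1], img$channels$SRS$pixels)
  expect_equal(ident[, , 3], img$channels$TRANS$pixels)
  swapped <- channel_order(c("TPEF", "TRANS", "SRS"))
  arr <- map_channels_to_rgb(img, swapped)
  expect_equal(arr[, , 1], img$channels$TPEF$pixels)
  for (perm in list(c("SRS", "TPEF", "TRANS"), c("TRANS", "SRS", "TPEF"))) {
    a <- map_channels_to_rgb(img, channel_order(perm))
    expect_equal(sort(as.vector(a)), sort(as.vector(ident)))
  }
  expect_error(channel_order(c("SRS", "SRS", "TPEF")), "permutation")
})

test_that("frozen backbones stay bit-identical through head training", {
  tr <- preprocess_dataset(small_bundle(5, 5, seed = 11))
  sp <- split_validation(tr, n_val = 2, seed = 1)
  bb <- build_stub_backbone(channels = 8, seed = 2)
  m <- build_tl_classifier(bb, input_shape = c(64, 80, 3), seed = 3)
  before <- lapply(m$layers[m$backbone_idx], function(l) l$W)
  st <- train_stage(m, sp$train, sp$validation,
                    training_config(max_epochs = 4, patience_epochs = 3,
                                    seed = 1), "HEAD")
  after <- lapply(st$model$layers[st$model$backbone_idx], function(l) l$W)
  expect_identical(before, after)
  # ... while the head has moved
  dense_idx <- which(vapply(m$layers, function(l) l$type, "") == "dense")
  expect_false(identical(m$layers[[dense_idx[1]]]$W,
                         st$model$layers[[dense_idx[1]]]$W))
})
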
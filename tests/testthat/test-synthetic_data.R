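# Properties of the synthetic phenotype generator.

test_that("generation is deterministic given a seed", {
  a <- generate_senescent_image(small_params(), 64, 80, seed = 10)
  b <- generate_senescent_image(small_params(), 64, 80, seed = 10)
  expect_identical(a$channels$SRS$pixels, b$channels$SRS$pixels)
  expect_identical(a$marker_mask, b$marker_mask)
  d <- generate_control_image(small_params(), 64, 80, seed = 10)
  e <- generate_control_image(small_params(), 64, 80, seed = 11)
  expect_false(identical(d$channels$TPEF$pixels, e$channels$TPEF$pixels))
})

test_that("dataset counts, labels and manifests are exact", {
  ds <- generate_dataset(synth_config(95, 65, height = 64, width = 80,
                                      seed = 2))
  expect_equal(length(ds), 160)
  expect_equal(ds$class_counts, c(SENESCENT = 95, CONTROL = 65))

  empty <- generate_dataset(synth_config(0, 0, height = 64, width = 80,
                                         seed = 2))
  expect_equal(length(empty), 0)

  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  generate_dataset(synth_config(2, 2, height = 64, width = 80, seed = 5),
                   out_dir = dir1)
  generate_dataset(synth_config(2, 2, height = 64, width = 80, seed = 5),
                   out_dir = dir2)
  expect_identical(readLines(file.path(dir1, "manifest.csv")),
                   readLines(file.path(dir2, "manifest.csv")))
  f <- "sen0001_srs.tif"
  expect_identical(readBin(file.path(dir1, f), "raw", 1e6),
                   readBin(file.path(dir2, f), "raw", 1e6))
})

test_that("marker masks are non-empty exactly when structures are implanted", {
  s <- generate_senescent_image(small_params(), 64, 80, seed = 3)
  expect_gt(sum(s$marker_mask), 0)
  none <- small_params(control_droplet_count = c(0, 0),
                       control_mito_focus_count = c(0, 0))
  c0 <- generate_control_image(none, 64, 80, seed = 3)
  expect_equal(sum(c0$marker_mask), 0)
})

test_that("senescent SRS has many bright connected components", {
  # at full-scale geometry at least half of the implanted droplets stay
  # distinct at the 140-intensity level (overlap from aggregation tolerated)
  params <- phenotype_params(droplet_count = c(20, 30))
  for (s in 1:6) {
    im <- generate_senescent_image(params, 250, 300, seed = 100 + s)
    comp <- max(EBImage::bwlabel(im$channels$SRS$pixels > 140))
    expect_gte(comp, 20 * im$meta$n_cells * 0.5)
    expect_gte(comp, 0.5 * im$meta$n_droplets)
  }
})

test_that("within-cell TPEF variation separates the phenotypes", {
  cv <- function(im) {
    px <- im$channels$TPEF$pixels
    cyto <- px > 10
    sd(px[cyto]) / mean(px[cyto])
  }
  sen <- vapply(1:25, function(s)
    cv(generate_senescent_image(small_params(), 64, 80, seed = s)), 0)
  con <- vapply(1:25, function(s)
    cv(generate_control_image(small_params(), 64, 80, seed = 400 + s)), 0)
  expect_gt(mean(sen), mean(con))
})

test_that("effect size zero collapses the two class distributions", {
  p0 <- small_params(effect_size = 0)
  sen <- vapply(1:60, function(s)
    mean(generate_senescent_image(p0, 64, 80, seed = s)$channels$SRS$pixels), 0)
  con <- vapply(1:60, function(s)
    mean(generate_control_image(p0, 64, 80, seed = 1000 + s)$channels$SRS$pixels), 0)
  expect_gt(t.test(sen, con)$p.value, 0.01)
  # and the same seeds give byte-identical renderings of the two classes
  expect_identical(generate_senescent_image(p0, 64, 80, seed = 5)$channels$SRS$pixels,
                   generate_control_image(p0, 64, 80, seed = 5)$channels$SRS$pixels)
})

test_that("class separability is monotone in effect size", {
  # fixed simple classifier: threshold on mean SRS intensity learned from
  # a training sample, applied to a held-out sample
  acc_at <- function(effect, seed) {
    p <- small_params(effect_size = effect)
    feat <- function(im) mean(im$channels$SRS$pixels)
    tr_s <- vapply(1:12, function(i)
      feat(generate_senescent_image(p, 64, 80, seed = seed * 1e4 + i)), 0)
    tr_c <- vapply(1:12, function(i)
      feat(generate_control_image(p, 64, 80, seed = seed * 1e4 + 100 + i)), 0)
    thr <- (mean(tr_s) + mean(tr_c)) / 2
    flip <- mean(tr_s) < mean(tr_c)
    te_s <- vapply(1:12, function(i)
      feat(generate_senescent_image(p, 64, 80, seed = seed * 1e4 + 200 + i)), 0)
    te_c <- vapply(1:12, function(i)
      feat(generate_control_image(p, 64, 80, seed = seed * 1e4 + 300 + i)), 0)
    pred_s <- if (flip) te_s < thr else te_s > thr
    pred_c <- if (flip) te_c >= thr else te_c <= thr
    mean(c(pred_s, pred_c))
  }
  accs <- sapply(1:5, function(seed)
    c(a0 = acc_at(0, seed), a5 = acc_at(0.5, seed), a1 = acc_at(1, seed)))
  m <- rowMeans(accs)
  tol <- 0.05
  expect_gte(m[["a1"]], m[["a5"]] - tol)
  expect_gte(m[["a5"]], m[["a0"]] - tol)
  expect_gt(m[["a1"]], 0.9)
  expect_lt(m[["a0"]], 0.65)
})

test_that("generated images pass preprocessing with usable contrast", {
  ds <- small_bundle(3, 3, seed = 8)
  out <- preprocess_dataset(ds)
  for (im in out$images) {
    expect_equal(dim(im), c(64, 80))
    for (ch in im$channels) expect_equal(range(ch$pixels), c(0, 255))
  }
})
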
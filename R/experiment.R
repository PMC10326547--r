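# End-to-end experiment harness: ties generation/loading, preprocessing,
# augmentation, training and evaluation into seed-reproducible multi-run
# experiments, and a comparison table across architectures. A single base
# seed determines every random choice (splits, augmentations,
# initializations, per-learner sub-seeds) through mix_seed(). The test
# split is evaluated only through prediction calls; every fitting entry
# point refuses TEST bundles outright.

#' Experiment configuration
#'
#' @param architecture One of `"el_full"` (fully trained ensemble),
#'   `"el_frozen"`, `"hybrid"` (deep features + PCA + SVM voting),
#'   `"scratch"` (from-scratch CNN).
#' @param synth Named list describing the synthetic dataset:
#'   `n_train_senescent`, `n_train_control`, `n_test_senescent`,
#'   `n_test_control`, `height`, `width`, `effect_size`.
#' @param manifest Optional named list with `train` and `test` manifest
#'   paths; overrides `synth`.
#' @param n_runs Number of independent training runs summarized together
#'   (default 9).
#' @param seed Base integer seed.
#' @param n_learners Ensemble/hybrid size (default 7; reduced stub
#'   ensembles are used for self-contained experiments).
#' @param channel_mask Named logical vector over SRS/TPEF/TRANS; `FALSE`
#'   zero-fills that channel everywhere (two-channel ablations are a
#'   config change, not code).
#' @param preprocess,augmentation,training Stage configurations.
#' @param head A [tl_head_spec()] for the TL classifiers. The default
#'   dropout rate of 0.8 presumes the >1000-dimensional feature vectors of
#'   the published backbones; stub-backbone experiments should scale it
#'   down in proportion to their feature dimension.
#' @param finetune Optional [training_config()] for the FINETUNE stage
#'   only (smaller epoch budgets keep reduced-size studies fast).
#' @param val_fraction Validation fraction per learner (default 0.25).
#' @param stub_channels Feature channels of the stub backbones.
#' @param output_dir Optional directory for result CSVs.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(architecture = c("el_full", "el_frozen",
                                               "hybrid", "scratch"),
                              synth = list(n_train_senescent = 95,
                                           n_train_control = 65,
                                           n_test_senescent = 30,
                                           n_test_control = 24,
                                           height = 250, width = 300,
                                           effect_size = 1),
                              manifest = NULL, n_runs = 9, seed = 1,
                              n_learners = 7,
                              channel_mask = c(SRS = TRUE, TPEF = TRUE,
                                               TRANS = TRUE),
                              preprocess = preprocess_config(),
                              augmentation = augmentation_config(),
                              training = training_config(),
                              head = tl_head_spec(), finetune = NULL,
                              val_fraction = 0.25, stub_channels = 16,
                              output_dir = NULL) {
  stopifnot(n_runs >= 1, n_learners >= 1)
  structure(list(architecture = match.arg(architecture), synth = synth,
                 manifest = manifest, n_runs = n_runs, seed = seed,
                 n_learners = n_learners, channel_mask = channel_mask,
                 preprocess = preprocess, augmentation = augmentation,
                 training = training, head = head, finetune = finetune,
                 val_fraction = val_fraction,
                 stub_channels = stub_channels, output_dir = output_dir),
            class = "experiment_config")
}

#' Reduced-scale study configuration
#'
#' The self-contained counterpart of the full acquisition study: 64 x 80
#' synthetic images (the small-size mode), 160 training fields of view in
#' the acquisition's 95:65 class ratio, a 40-image balanced test set,
#' three stub-backbone learners, three augmented copies per image and a
#' short fine-tuning budget. Two hyperparameters are rescaled with the
#' problem size: head dropout drops to 0.1 (the published 0.8 presumes
#' feature vectors three orders of magnitude wider than the
#' 16-dimensional stub output) and early-stopping patience grows to 85
#' epochs (the published 20-epoch patience spans roughly 2000 optimizer
#' steps at the full dataset size; with 24 steps per reduced epoch the
#' equivalent stagnation window is ~85 epochs). All remaining
#' hyperparameters keep their reference defaults.
#'
#' @param architecture Passed to [experiment_config()].
#' @param effect_size Senescent-control contrast of the generator.
#' @param seed Base seed.
#' @param n_runs Number of training runs (default 3).
#' @return An [experiment_config()].
#' @export
small_study_config <- function(architecture = "el_full", effect_size = 1,
                               seed = 1, n_runs = 3) {
  experiment_config(
    architecture = architecture,
    synth = list(n_train_senescent = 95, n_train_control = 65,
                 n_test_senescent = 20, n_test_control = 20,
                 height = 64, width = 80, effect_size = effect_size),
    n_runs = n_runs, seed = seed, n_learners = 3, stub_channels = 16,
    augmentation = augmentation_config(copies_per_image = 3),
    training = training_config(patience_epochs = 85),
    head = tl_head_spec(dropout_rate = 0.1),
    finetune = training_config(max_epochs = 5, patience_epochs = 3))
}

#' Zero-fill dropped channels
#'
#' Channel ablation keeps the three-plane architecture fixed and replaces
#' a dropped modality with zeros everywhere.
#'
#' @param ds A [dataset_bundle()].
#' @param mask Named logical vector over `SRS`, `TPEF`, `TRANS`.
#' @return The masked bundle.
#' @export
mask_channels <- function(ds, mask) {
  drop <- names(mask)[!mask]
  if (length(drop) == 0) return(ds)
  ds$images <- lapply(ds$images, function(im) {
    for (m in drop) im$channels[[m]]$pixels[] <- 0
    im
  })
  ds
}

experiment_data <- function(cfg) {
  if (!is.null(cfg$manifest)) {
    train <- load_manifest(cfg$manifest$train, split = "TRAIN")
    test <- load_manifest(cfg$manifest$test, split = "TEST")
  } else {
    s <- cfg$synth
    train <- generate_dataset(synth_config(s$n_train_senescent,
                                           s$n_train_control,
                                           height = s$height, width = s$width,
                                           seed = mix_seed(cfg$seed, 101),
                                           split = "TRAIN"),
                              params = synth_params_for(s))
    test <- generate_dataset(synth_config(s$n_test_senescent,
                                          s$n_test_control,
                                          height = s$height, width = s$width,
                                          seed = mix_seed(cfg$seed, 202),
                                          split = "TEST"),
                             params = synth_params_for(s))
  }
  train <- mask_channels(preprocess_dataset(train, cfg$preprocess),
                         cfg$channel_mask)
  test <- mask_channels(preprocess_dataset(test, cfg$preprocess),
                        cfg$channel_mask)
  list(train = train, test = test)
}

synth_params_for <- function(s) {
  phenotype_params(effect_size = s$effect_size,
                   size_factor = min(s$height / 250, s$width / 300))
}

experiment_backbones <- function(cfg) {
  # learner backbones are fixed "pre-trained" extractors: seeds depend on
  # the base seed only, not on the run, mirroring fixed published weights
  lapply(seq_len(cfg$n_learners), function(i) {
    build_stub_backbone(channels = cfg$stub_channels,
                        seed = mix_seed(cfg$seed, 500 + i))
  })
}

run_one <- function(cfg, data, backbones, run_seed) {
  tr_cfg <- cfg$training; tr_cfg$seed <- run_seed
  aug_cfg <- cfg$augmentation; aug_cfg$seed <- run_seed
  arch <- cfg$architecture
  test <- data$test
  if (arch %in% c("el_full", "el_frozen")) {
    ens <- train_ensemble(data$train, backbones, tr_cfg,
                          mode = if (arch == "el_full") "FULLY_TRAINED"
                                 else "FROZEN",
                          aug_cfg = aug_cfg, val_fraction = cfg$val_fraction,
                          head = cfg$head, finetune_cfg = cfg$finetune)
    pred <- predict_ensemble(ens, test)
    ev <- evaluate_predictions(pred$labels, test, probs = pred$mean_prob)
    ev$model <- ens
    ev$learner_probs <- pred$probs
  } else if (arch == "hybrid") {
    aug <- augment_dataset(data$train, aug_cfg)
    hyb <- fit_hybrid(backbones, aug, seed = run_seed)
    pred <- predict_hybrid(hyb, test)
    ev <- evaluate_predictions(pred$labels, test)
    roc <- roc_by_vote_count(pred$vote_counts, bundle_labels(test),
                             n_learners = length(backbones))
    o <- order(roc$fpr, roc$tpr)
    ev$roc <- list(points = roc[o, ],
                   auc = sum(diff(roc$fpr[o]) *
                             (utils::head(roc$tpr[o], -1) +
                              utils::tail(roc$tpr[o], -1)) / 2))
    ev$model <- hyb
  } else {  # scratch CNN
    aug <- augment_dataset(data$train, aug_cfg)
    sp <- split_validation(aug, n_val = max(1, round(cfg$val_fraction *
                                                     length(aug))),
                           seed = run_seed)
    model <- build_scratch_cnn(c(dim(aug$images[[1]]), 3), seed = run_seed)
    st <- train_stage(model, sp$train, sp$validation, tr_cfg, "HEAD")
    probs <- predict_learner(st$model, test)
    ev <- evaluate_predictions(vapply(probs, predict_class, ""), test,
                               probs = probs)
    ev$model <- st$model
  }
  ev
}

#' Run a multi-run experiment
#'
#' The dataset (and test split) is fixed by the base seed; the `n_runs`
#' training repetitions differ in their training/augmentation sub-seeds,
#' so the summary measures run-to-run training variability on an
#' untouched test set.
#'
#' @param cfg An [experiment_config()].
#' @param keep_models Keep fitted models in the per-run results
#'   (default FALSE to save memory).
#' @return An object of class `experiment_result` with `summary`
#'   (a [summarize_runs()] result), `runs` (per-run evaluations) and
#'   `config`.
#' @export
run_experiment <- function(cfg, keep_models = FALSE) {
  data <- experiment_data(cfg)
  backbones <- experiment_backbones(cfg)
  runs <- vector("list", cfg$n_runs)
  for (r in seq_len(cfg$n_runs)) {
    run_seed <- mix_seed(cfg$seed, r)
    runs[[r]] <- tryCatch(
      run_one(cfg, data, backbones, run_seed),
      error = function(e) stop(sprintf(
        "run_experiment: stage '%s' failed at run %d (seed %d): %s",
        cfg$architecture, r, run_seed, conditionMessage(e))))
    if (!keep_models) runs[[r]]$model <- NULL
  }
  summary <- summarize_runs(lapply(runs, `[[`, "metrics"),
                            aucs = vapply(runs, function(x) {
                              if (is.null(x$roc)) NA_real_ else x$roc$auc
                            }, 0))
  res <- structure(list(summary = summary, runs = runs, config = cfg,
                        test_labels = bundle_labels(data$test)),
                   class = "experiment_result")
  if (!is.null(cfg$output_dir)) write_experiment(res, cfg$output_dir)
  res
}

write_experiment <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  runs <- res$summary$runs
  runs$run <- seq_len(nrow(runs))
  utils::write.csv(runs, file.path(dir, "runs.csv"), row.names = FALSE)
  summ <- data.frame(metric = names(res$summary$mean),
                     mean = unname(res$summary$mean),
                     sd = unname(res$summary$sd))
  utils::write.csv(summ, file.path(dir, "summary.csv"), row.names = FALSE)
  invisible(dir)
}

#' Compare architectures on a shared dataset
#'
#' All configurations must describe the same dataset and seed (hence the
#' same test split); otherwise the comparison would be invalid and is
#' refused. Output mirrors the usual results table: one row per
#' architecture, mean +/- SD per metric, max AUC.
#'
#' @param cfgs List of [experiment_config()]s.
#' @return List with `table` (data frame) and `results` (per-config
#'   [run_experiment()] outputs).
#' @export
compare_architectures <- function(cfgs) {
  key <- function(cfg) paste(deparse(cfg$synth), deparse(cfg$manifest),
                             cfg$seed, collapse = " ")
  if (length(unique(vapply(cfgs, key, ""))) != 1)
    stop("compare_architectures: configurations use different datasets/seeds")
  results <- lapply(cfgs, run_experiment)
  table <- do.call(rbind, lapply(seq_along(cfgs), function(i) {
    s <- results[[i]]$summary
    data.frame(architecture = cfgs[[i]]$architecture,
               accuracy = s$mean[["accuracy"]], accuracy_sd = s$sd[["accuracy"]],
               precision = s$mean[["precision"]], precision_sd = s$sd[["precision"]],
               recall = s$mean[["recall"]], recall_sd = s$sd[["recall"]],
               f1 = s$mean[["f1"]], f1_sd = s$sd[["f1"]],
               max_auc = s$max_auc)
  }))
  list(table = table, results = results)
}
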
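# Shared fixtures: small synthetic bundles and stub learners, generated in
# code at test time. The reduced image size (64 x 80) keeps every fixture
# fast while preserving the phenotype geometry via size_factor scaling.

small_params <- function(...) {
  phenotype_params(size_factor = 64 / 250, ...)
}

small_bundle <- function(n_sen = 4, n_con = 4, seed = 1, split = "TRAIN",
                         effect_size = 1) {
  generate_dataset(synth_config(n_sen, n_con, height = 64, width = 80,
                                seed = seed, split = split),
                   params = small_params(effect_size = effect_size))
}

# a deterministic single-channel test pattern
ramp_image <- function(h = 10, w = 12, modality = "SRS") {
  channel_image(matrix(seq_len(h * w) - 1, h, w), modality)
}

# one multimodal image with a single hot pixel per channel
delta_image <- function(h = 9, w = 11, r = 3, c = 4, label = "CONTROL") {
  base <- matrix(0, h, w)
  base[r, c] <- 200
  multimodal_image(base, base, base, label = label, source_id = "delta")
}

# the memoised reduced-scale ensemble experiment shared by the acceptance
# tests (trained once, reused by the separability and Grad-CAM checks)
desk_env <- new.env(parent = emptyenv())

desk_experiment <- function() {
  if (is.null(desk_env$res)) {
    desk_env$res <- run_experiment(small_study_config(seed = 7, n_runs = 3),
                                   keep_models = TRUE)
  }
  desk_env$res
}

null_effect_accuracy <- function() {
  if (is.null(desk_env$null_acc)) {
    res0 <- run_experiment(small_study_config(effect_size = 0, seed = 7,
                                              n_runs = 1))
    desk_env$null_acc <- res0$summary$mean[["accuracy"]]
  }
  desk_env$null_acc
}

# mean colocalization of ensemble Grad-CAM maps with the implanted marker
# masks, over correctly classified test images of each class, averaged
# across the three trained run models
desk_gradcam_scores <- function() {
  if (is.null(desk_env$coloc)) {
    res <- desk_experiment()
    test <- senescreen:::experiment_data(res$config)$test
    truth <- vapply(test$images, function(i) i$label, "")
    score_class <- function(class) {
      mean(unlist(lapply(res$runs, function(run) {
        pred <- predict_ensemble(run$model, test)
        idx <- which(truth == class & pred$labels == class)
        vapply(idx, function(i) {
          g <- gradcam_map(run$model, test$images[[i]])
          colocalization_score(g, test$images[[i]]$marker_mask)
        }, 0)
      })), na.rm = TRUE)
    }
    desk_env$coloc <- list(senescent = score_class("SENESCENT"),
                           control = score_class("CONTROL"))
  }
  desk_env$coloc
}
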
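# Hybrid transfer-learning / machine-learning classifier: each frozen
# backbone turns an image into a fixed 1-D deep-feature vector; PCA
# reduces the dimensionality; a polynomial-kernel SVM (hyperparameters
# grid-searched by k-fold cross-validation on training rows only)
# classifies; and the per-backbone labels are combined by hard majority
# voting. No probability calibration: the hybrid path is label-vote only.

#' Extract off-the-shelf deep features
#'
#' Runs each image through a frozen backbone and collects its pooled 1-D
#' feature vector. Deterministic for fixed backbone weights.
#'
#' @param backbone A `backbone_handle`.
#' @param ds A [dataset_bundle()].
#' @param order A [channel_order()].
#' @return Numeric matrix, one row per image (`feature_dim` columns), with
#'   a `labels` attribute aligned to the rows.
#' @export
extract_features <- function(backbone, ds, order = channel_order()) {
  rows <- lapply(ds$images, function(im) {
    backbone$feature_vector_fn(map_channels_to_rgb(im, order))
  })
  fm <- do.call(rbind, rows)
  attr(fm, "labels") <- bundle_labels(ds)
  fm
}

#' Fit a PCA dimensionality reducer on training features
#'
#' Retains the leading principal components capturing at least
#' `variance_target` of the total variance (default 0.95), or a fixed
#' `n_components` if given. The projection is fitted on training rows only
#' and applied to held-out rows with [project_pca()], so no test
#' information leaks into the fit. Rank-deficient inputs simply return all
#' available components.
#'
#' @param fm Feature matrix (>= 2 rows).
#' @param variance_target Fraction of variance to capture.
#' @param n_components Optional fixed component count.
#' @return An object of class `pca_reducer` (`rotation`, `center`, `k`).
#' @export
fit_pca <- function(fm, variance_target = 0.95, n_components = NULL) {
  if (nrow(fm) < 2) stop("fit_pca: need at least 2 rows")
  pc <- stats::prcomp(fm, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  k <- if (!is.null(n_components)) min(n_components, ncol(pc$rotation)) else {
    pos <- ev > 1e-12 * max(ev, 1e-300)
    cum <- cumsum(ev) / sum(ev)
    max(1L, min(which(cum >= variance_target - 1e-12), sum(pos)))
  }
  structure(list(rotation = pc$rotation[, seq_len(k), drop = FALSE],
                 center = pc$center, k = k, explained = ev / sum(ev)),
            class = "pca_reducer")
}

#' Project feature rows onto a fitted PCA basis
#'
#' @param reducer A `pca_reducer` from [fit_pca()].
#' @param fm Feature matrix with the same column count as the fit.
#' @return Score matrix with `reducer$k` columns.
#' @export
project_pca <- function(reducer, fm) {
  sweep(fm, 2, reducer$center) %*% reducer$rotation
}

#' Reduce a training feature matrix by PCA
#'
#' Convenience wrapper around [fit_pca()] + [project_pca()] for the
#' training rows; the fitted reducer is attached as attribute `"reducer"`
#' for projecting held-out rows.
#'
#' @inheritParams fit_pca
#' @return Score matrix with the reducer attached.
#' @export
reduce_pca <- function(fm, variance_target = 0.95, n_components = NULL) {
  red <- fit_pca(fm, variance_target, n_components)
  out <- project_pca(red, fm)
  attr(out, "reducer") <- red
  attr(out, "labels") <- attr(fm, "labels")
  out
}

#' Polynomial-kernel SVM with cross-validated hyperparameters
#'
#' Grid-searches degree and cost by stratification-free k-fold
#' cross-validation on the training rows (accuracy criterion), then refits
#' the best configuration on all rows. Deterministic given `seed`.
#'
#' @param x Numeric matrix of training rows (e.g. PCA scores).
#' @param labels Character or factor labels; both classes must be present.
#' @param degree,cost Hyperparameter grids (defaults: degree 2-3,
#'   cost 0.1/1/10).
#' @param folds Number of CV folds (default 5).
#' @param seed Integer seed for fold assignment.
#' @return List of class `svm_cv` with the fitted `model`, `best`
#'   hyperparameters and the CV `grid` results.
#' @export
fit_svm_cv <- function(x, labels, degree = c(2, 3), cost = c(0.1, 1, 10),
                       folds = 5, seed = 1) {
  labels <- factor(as.character(labels))
  if (nlevels(labels) < 2) stop("fit_svm_cv: need both classes in training rows")
  n <- nrow(x)
  folds <- min(folds, n)
  fold_id <- with_seed(seed, sample(rep_len(seq_len(folds), n)))
  grid <- expand.grid(degree = degree, cost = cost)
  grid$cv_accuracy <- NA_real_
  for (g in seq_len(nrow(grid))) {
    correct <- 0
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      if (nlevels(droplevels(labels[tr])) < 2) next
      fit <- e1071::svm(x[tr, , drop = FALSE], labels[tr],
                        kernel = "polynomial", degree = grid$degree[g],
                        cost = grid$cost[g], coef0 = 1, scale = FALSE)
      pred <- predict(fit, x[!tr, , drop = FALSE])
      correct <- correct + sum(pred == labels[!tr])
    }
    grid$cv_accuracy[g] <- correct / n
  }
  best <- grid[which.max(grid$cv_accuracy), ]
  model <- e1071::svm(x, labels, kernel = "polynomial", degree = best$degree,
                      cost = best$cost, coef0 = 1, scale = FALSE)
  structure(list(model = model, best = best, grid = grid), class = "svm_cv")
}

#' @export
predict.svm_cv <- function(object, newdata, ...) {
  as.character(predict(object$model, newdata))
}

#' Hard majority vote
#'
#' The class with the highest number of votes wins. With an odd learner
#' count (the reference ensemble has seven) ties cannot occur; for even
#' counts an exact tie is resolved as SENESCENT, because missing a
#' senescent cell is the costlier error.
#'
#' @param votes Character vector of per-learner labels, or a logical/0-1
#'   vector where `TRUE`/1 means SENESCENT.
#' @return `"SENESCENT"` or `"CONTROL"`.
#' @export
hard_vote <- function(votes) {
  if (length(votes) < 1) stop("hard_vote: empty vote record")
  sen <- if (is.character(votes) || is.factor(votes)) {
    sum(toupper(as.character(votes)) == "SENESCENT")
  } else sum(votes > 0)
  # exact tie (even n only) -> SENESCENT, the documented asymmetric-cost rule
  if (sen >= length(votes) / 2) "SENESCENT" else "CONTROL"
}

#' ROC points from ensemble vote counts
#'
#' For the hybrid classifier the natural discrimination threshold is the
#' number of learners voting senescent: for every threshold `t` in
#' `0..n_learners + 1` the image is called SENESCENT iff its vote count is
#' `>= t`, and TPR/FPR are computed from the resulting confusion counts.
#' `t = 0` gives (FPR, TPR) = (1, 1), `t = n_learners + 1` gives (0, 0).
#'
#' @param vote_counts Integer vector of senescent vote counts per image.
#' @param truth Character vector of true labels.
#' @param n_learners Number of learners (default `max(vote_counts)`).
#' @return Data frame with columns `threshold`, `fpr`, `tpr`.
#' @export
roc_by_vote_count <- function(vote_counts, truth, n_learners = max(vote_counts)) {
  if (length(vote_counts) == 0) stop("roc_by_vote_count: empty record")
  truth <- toupper(as.character(truth))
  pos <- truth == "SENESCENT"
  pts <- lapply(0:(n_learners + 1), function(t) {
    pred <- vote_counts >= t
    data.frame(threshold = t,
               fpr = if (sum(!pos)) sum(pred & !pos) / sum(!pos) else 0,
               tpr = if (sum(pos)) sum(pred & pos) / sum(pos) else 0)
  })
  do.call(rbind, pts)
}

#' Fit the hybrid TL/ML classifier
#'
#' For each backbone: extract off-the-shelf features on the training
#' bundle, fit PCA, then fit a cross-validated polynomial SVM on the
#' scores. Nothing here ever sees a TEST bundle.
#'
#' @param backbones List of `backbone_handle`s.
#' @param train A TRAIN [dataset_bundle()].
#' @param variance_target PCA retained-variance target.
#' @param seed Base seed (mixed per learner).
#' @param order A [channel_order()].
#' @param ... Passed to [fit_svm_cv()].
#' @return An object of class `hybrid_model`.
#' @export
fit_hybrid <- function(backbones, train, variance_target = 0.95, seed = 1,
                       order = channel_order(), ...) {
  if (train$split == "TEST")
    stop("fit_hybrid: refusing to fit on a TEST bundle (data leakage)")
  learners <- lapply(seq_along(backbones), function(i) {
    fm <- extract_features(backbones[[i]], train, order)
    red <- fit_pca(fm, variance_target)
    svm <- fit_svm_cv(project_pca(red, fm), attr(fm, "labels"),
                      seed = mix_seed(seed, i), ...)
    list(backbone = backbones[[i]], reducer = red, svm = svm)
  })
  structure(list(learners = learners, order = order), class = "hybrid_model")
}

#' Predict with the hybrid classifier
#'
#' @param model A `hybrid_model`.
#' @param ds A [dataset_bundle()].
#' @return List with `votes` (images x learners label matrix),
#'   `vote_counts` (senescent votes per image) and `labels` (hard-vote
#'   decision per image).
#' @export
predict_hybrid <- function(model, ds) {
  votes <- sapply(model$learners, function(l) {
    fm <- extract_features(l$backbone, ds, model$order)
    predict(l$svm, project_pca(l$reducer, fm))
  })
  votes <- matrix(votes, nrow = length(ds$images))
  counts <- rowSums(votes == "SENESCENT")
  labels <- apply(votes, 1, hard_vote)
  list(votes = votes, vote_counts = counts, labels = labels)
}
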
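#' RBF support-vector-machine configuration
#'
#' The classifier is a soft-margin support vector machine with a Gaussian
#' (RBF) kernel \eqn{K(u,v) = \exp(-\gamma \|u-v\|^2)} and one-vs-one
#' multiclass voting (the libsvm default). The default hyperparameters
#' `C = 16` and `gamma = 0.001` were chosen as a general-purpose
#' compromise found by a wide grid scan with five-fold cross-validation
#' (see [grid_scan()]).
#'
#' @param C soft-margin penalty, > 0.
#' @param gamma RBF kernel width, > 0.
#' @return an `svm_config` object.
#' @export
svm_config <- function(C = 16, gamma = 0.001) {
  stopifnot(is.numeric(C), length(C) == 1L, C > 0,
            is.numeric(gamma), length(gamma) == 1L, gamma > 0)
  structure(list(C = C, gamma = gamma, kernel = "RBF"), class = "svm_config")
}

# Logical column selector for a sensor-group mask.
.mask_columns <- function(manifest, mask = c("all", "acc_only", "gyro_only")) {
  mask <- match.arg(mask)
  if (mask == "all") rep(TRUE, nrow(manifest)) else manifest$group == mask
}

#' Train the behaviour classifier
#'
#' Fits the Gaussian-kernel SVM on a feature dataset. The feature columns
#' may first be restricted to a sensor subset (`acc_only`: the 45
#' accelerometer features; `gyro_only`: the 69 gyroscope features); the
#' min-max normalizer is fitted on the (masked) training data only and is
#' stored with the model, so prediction-time inputs are rescaled with the
#' training ranges. Training is deterministic for a fixed input ordering.
#'
#' @param ds a `feature_dataset` containing at least two categories.
#' @param cfg an [svm_config()].
#' @param mask sensor-group filter: `"all"`, `"acc_only"` or `"gyro_only"`.
#' @return a `trained_model` object bundling the fitted classifier, the
#'   normalization parameters and the column mask.
#' @export
train_classifier <- function(ds, cfg = svm_config(), mask = "all") {
  stopifnot(inherits(ds, "feature_dataset"), inherits(cfg, "svm_config"))
  if (length(unique(ds$y)) < 2L) {
    stop("training data must contain at least two categories", call. = FALSE)
  }
  keep <- .mask_columns(ds$manifest, mask)
  sub <- ds
  sub$X <- ds$X[, keep, drop = FALSE]
  sub$manifest <- ds$manifest[keep, , drop = FALSE]
  if (any(!is.finite(sub$X))) {
    stop("non-finite feature values in training data", call. = FALSE)
  }
  params <- fit_normalizer(sub)
  norm <- apply_normalizer(params, sub)
  fit <- e1071::svm(x = norm$X, y = behavior_factor(norm$y),
                    kernel = "radial", cost = cfg$C, gamma = cfg$gamma,
                    scale = FALSE)
  structure(list(fit = fit, params = params, mask = mask,
                 features = colnames(sub$X), cfg = cfg,
                 categories = sort(unique(ds$y))),
            class = "trained_model")
}

#' @export
print.trained_model <- function(x, ...) {
  cat(sprintf("<trained_model> RBF SVM (C=%g, gamma=%g), mask=%s, %d features\n",
              x$cfg$C, x$cfg$gamma, x$mask, length(x$features)))
  invisible(x)
}

#' Predict behaviour categories
#'
#' Applies the model's own column mask and normalizer, then classifies
#' every window. There is no abstention: exactly one of the categories seen
#' at training is returned per row.
#'
#' @param model a `trained_model`.
#' @param ds a `feature_dataset` extracted with the same manifest.
#' @return character vector of predicted categories, one per window.
#' @export
predict_classifier <- function(model, ds) {
  stopifnot(inherits(model, "trained_model"), inherits(ds, "feature_dataset"))
  keep <- .mask_columns(ds$manifest, model$mask)
  sub <- ds
  sub$X <- ds$X[, keep, drop = FALSE]
  sub$manifest <- ds$manifest[keep, , drop = FALSE]
  if (!identical(colnames(sub$X), model$features)) {
    stop("feature columns do not match the trained model", call. = FALSE)
  }
  if (nrow(sub$X) == 0L) return(character(0))
  norm <- apply_normalizer(model$params, sub)
  as.character(stats::predict(model$fit, norm$X))
}

# Stratified fold assignment: per category, a seeded shuffle is dealt
# round-robin into `folds` folds.
.stratified_folds <- function(y, folds, seed) {
  counts <- table(y)
  if (any(counts < folds)) {
    stop("category ", names(counts)[which.min(counts)], " has only ",
         min(counts), " windows; use fewer than ", folds, " folds",
         call. = FALSE)
  }
  fold_id <- integer(length(y))
  with_seed(seed, {
    for (lev in names(counts)) {
      idx <- sample(which(y == lev))
      fold_id[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  fold_id
}

# Mean held-out accuracy over pre-assigned folds for one (C, gamma) cell;
# the normalizer is refitted inside each fold on its training split only.
.cv_accuracy <- function(ds, fold_id, cfg, mask = "all") {
  folds <- max(fold_id)
  acc <- numeric(folds)
  for (k in seq_len(folds)) {
    train <- subset_windows(ds, fold_id != k)
    test <- subset_windows(ds, fold_id == k)
    model <- train_classifier(train, cfg, mask = mask)
    acc[k] <- mean(predict_classifier(model, test) == test$y)
  }
  mean(acc)
}

#' Hyperparameter grid scan with five-fold cross-validation
#'
#' Evaluates every (C, gamma) cell of a grid by stratified k-fold
#' cross-validation on `ds`. Folds are assigned once from a seeded shuffle
#' and reused for every cell; within each fold the normalizer is refitted
#' on the training split only, so no information leaks from the held-out
#' fold. The default grid is the standard coarse log2 lattice.
#'
#' @param ds a `feature_dataset`.
#' @param C_grid,gamma_grid numeric grids to scan.
#' @param folds number of folds (>= 2; default 5).
#' @param seed integer seed for the fold shuffle (mandatory).
#' @return a data.frame with columns `C`, `gamma`, `cv_accuracy` (fraction
#'   in \[0, 1\]), one row per grid cell.
#' @export
grid_scan <- function(ds, C_grid = 2^seq(-5, 15, by = 2),
                      gamma_grid = 2^seq(-15, 3, by = 2),
                      folds = 5L, seed) {
  stopifnot(inherits(ds, "feature_dataset"),
            length(C_grid) > 0, length(gamma_grid) > 0, folds >= 2L)
  if (missing(seed)) stop("seed is required", call. = FALSE)
  fold_id <- .stratified_folds(ds$y, folds, seed)
  grid <- expand.grid(C = C_grid, gamma = gamma_grid,
                      KEEP.OUT.ATTRS = FALSE)
  grid$cv_accuracy <- vapply(seq_len(nrow(grid)), function(i) {
    .cv_accuracy(ds, fold_id, svm_config(grid$C[i], grid$gamma[i]))
  }, numeric(1))
  grid
}

#' Save or load a trained model
#'
#' The archive bundles the fitted classifier, its normalization parameters,
#' the sensor mask and the feature manifest subset in one file.
#'
#' @param model a `trained_model`.
#' @param path archive path.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "trained_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "trained_model"))
  model
}
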
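#' F-score feature importance
#'
#' Scores every feature by the ratio of between-category to within-category
#' variance, a simple univariate measure of how well the feature separates
#' the behaviour categories: for feature i with per-category means
#' \eqn{\bar x_{i,c}}, overall mean \eqn{\bar x_i} and per-category sample
#' variances \eqn{s^2_{i,c}},
#' \deqn{F_i = \frac{\sum_c (\bar x_{i,c} - \bar x_i)^2}
#'                  {\sum_c s^2_{i,c}}.}
#' With two categories this reduces to the classical two-class F-score used
#' for SVM feature ranking. Higher scores indicate more information
#' content. Scores are invariant under any common affine rescaling of a
#' feature.
#'
#' @param ds a `feature_dataset` with at least two categories, each with at
#'   least two windows.
#' @return a data.frame (`feature`, `signal`, `statistic`, `group`,
#'   `f_score`) sorted by descending score, ties broken by feature name.
#' @export
f_scores <- function(ds) {
  stopifnot(inherits(ds, "feature_dataset"))
  counts <- table(ds$y)
  if (length(counts) < 2L) {
    stop("need at least two categories", call. = FALSE)
  }
  if (any(counts < 2L)) {
    stop("category ", names(counts)[which.min(counts)],
         " has fewer than two windows", call. = FALSE)
  }
  cats <- names(counts)
  grand <- colMeans(ds$X)
  between <- 0
  within <- 0
  for (ct in cats) {
    Xc <- ds$X[ds$y == ct, , drop = FALSE]
    between <- between + (colMeans(Xc) - grand)^2
    within <- within + apply(Xc, 2L, stats::var)
  }
  f <- ifelse(within > 0, between / within,
              ifelse(between > 0, Inf, 0))
  m <- ds$manifest
  out <- data.frame(feature = m$name, signal = m$signal,
                    statistic = m$statistic, group = m$group,
                    f_score = unname(f[m$name]), stringsAsFactors = FALSE)
  out <- out[order(-out$f_score, out$feature), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Sensor-subset cross-validation accuracy
#'
#' Stratified seeded k-fold cross-validation of the classifier on a joint
#' dataset under a feature mask: all 126 features, the 45
#' accelerometer-only features, or the 69 gyroscope-only features. The
#' normalizer is refitted within each fold on the training split only.
#'
#' @param ds a `feature_dataset`.
#' @param mask `"all"`, `"acc_only"` or `"gyro_only"`.
#' @param folds number of folds (default 5).
#' @param cfg an [svm_config()].
#' @param seed integer seed for fold assignment (mandatory).
#' @return mean held-out accuracy as a percentage.
#' @export
subset_cv <- function(ds, mask = c("all", "acc_only", "gyro_only"),
                      folds = 5L, cfg = svm_config(), seed) {
  mask <- match.arg(mask)
  if (missing(seed)) stop("seed is required", call. = FALSE)
  fold_id <- .stratified_folds(ds$y, folds, seed)
  100 * .cv_accuracy(ds, fold_id, cfg, mask = mask)
}
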
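#' Derive secondary signals from a raw inertial recording
#'
#' Expands the six measured channels into the 14 per-sample scalar signals
#' that feature extraction consumes:
#' the three acceleration components and the acceleration vector length
#' `|a|`; the attitude tangent `r_xz = a_x / a_z` (with `a_z` clamped away
#' from zero); the three angular-velocity components and their vector
#' length `|w|`; the three angular accelerations `alpha_*` (degrees/s^2,
#' central finite differences of the rates, one-sided at the ends); the
#' component-wise dot product `d = a . w`; and the cosine alignment
#' `c = d / (|a| |w|)` (defined as 0 where the denominator vanishes).
#'
#' @param rec an [inertial_recording()] of length >= 2.
#' @param epsilon_az clamp for `|a_z|` (g) in the tangent ratio, preventing
#'   blow-up when the z axis momentarily reads near zero in dynamic windows.
#' @return an object of class `derived_signals`: a list of the 14 named
#'   numeric vectors plus `sample_rate` and the recording's `meta`.
#' @export
derive_signals <- function(rec, epsilon_az = 0.05) {
  stopifnot(inherits(rec, "inertial_recording"))
  n <- length(rec)
  if (n < 2L) stop("recording too short for finite differences", call. = FALSE)
  rate <- rec$sample_rate

  a_mag <- sqrt(rec$a_x^2 + rec$a_y^2 + rec$a_z^2)
  w_mag <- sqrt(rec$w_roll^2 + rec$w_pitch^2 + rec$w_yaw^2)

  az_sign <- ifelse(rec$a_z >= 0, 1, -1)
  az_clamped <- az_sign * pmax(abs(rec$a_z), epsilon_az)
  r_xz <- rec$a_x / az_clamped

  fdiff <- function(w) {
    d <- numeric(n)
    d[1L] <- (w[2L] - w[1L]) * rate
    d[n] <- (w[n] - w[n - 1L]) * rate
    if (n > 2L) d[2:(n - 1L)] <- (w[3:n] - w[1:(n - 2L)]) * rate / 2
    d
  }

  d <- rec$a_x * rec$w_roll + rec$a_y * rec$w_pitch + rec$a_z * rec$w_yaw
  den <- a_mag * w_mag
  c_align <- ifelse(den > 0, d / den, 0)

  structure(list(
    a_x = rec$a_x, a_y = rec$a_y, a_z = rec$a_z, a_mag = a_mag, r_xz = r_xz,
    w_roll = rec$w_roll, w_pitch = rec$w_pitch, w_yaw = rec$w_yaw,
    w_mag = w_mag,
    alpha_roll = fdiff(rec$w_roll), alpha_pitch = fdiff(rec$w_pitch),
    alpha_yaw = fdiff(rec$w_yaw),
    d = d, c = c_align,
    sample_rate = rate, meta = rec$meta, t = rec$t
  ), class = "derived_signals")
}

.BASE_STATS <- c("mean", "sd", "skewness", "kurtosis", "min", "max",
                 "crossings", "fft_freq", "fft_mag")
.ACC_SIGNALS <- c("a_x", "a_y", "a_z", "a_mag", "r_xz")
.GYRO_SIGNALS <- c("w_roll", "w_pitch", "w_yaw", "w_mag",
                   "alpha_roll", "alpha_pitch", "alpha_yaw")

#' The 126-entry feature manifest
#'
#' Defines, in fixed order, every feature the extractor computes: nine
#' window statistics (mean, standard deviation, skewness, excess kurtosis,
#' minimum, maximum, mean-crossing count, dominant FFT frequency, dominant
#' FFT magnitude) for each of the five accelerometer-derived signals
#' (45 accelerometer-only features) and each of the seven gyroscope-derived
#' signals, plus the magnitudes of the first six FFT harmonics of `|w|`
#' (69 gyroscope-only features), and the nine statistics of the dot product
#' `d = a . w` plus mean/min/max of the cosine alignment `c` (12 mixed
#' features).
#'
#' @return a data.frame with columns `name`, `signal`, `statistic`, `group`
#'   (one of `acc_only`, `gyro_only`, `mixed`) and exactly 126 rows.
#' @export
feature_manifest <- function() {
  rows <- list()
  for (s in .ACC_SIGNALS) {
    rows[[length(rows) + 1L]] <- data.frame(
      signal = s, statistic = .BASE_STATS, group = "acc_only")
  }
  for (s in .GYRO_SIGNALS) {
    rows[[length(rows) + 1L]] <- data.frame(
      signal = s, statistic = .BASE_STATS, group = "gyro_only")
  }
  rows[[length(rows) + 1L]] <- data.frame(
    signal = "w_mag", statistic = paste0("harm", 1:6), group = "gyro_only")
  rows[[length(rows) + 1L]] <- data.frame(
    signal = "d", statistic = .BASE_STATS, group = "mixed")
  rows[[length(rows) + 1L]] <- data.frame(
    signal = "c", statistic = c("mean", "min", "max"), group = "mixed")
  m <- do.call(rbind, rows)
  m <- data.frame(name = paste(m$signal, m$statistic, sep = "."),
                  m, stringsAsFactors = FALSE)
  stopifnot(nrow(m) == 126L, !anyDuplicated(m$name),
            sum(m$group == "gyro_only") == 69L,
            sum(m$group == "acc_only") == 45L,
            sum(m$group == "mixed") == 12L)
  m
}

#' Cut labelled sliding windows from a recording
#'
#' Emits one window per classifier input node: a span of
#' `window * sample_rate` consecutive samples that lies entirely inside a
#' single labelled interval of `track` (which should already be
#' margin-trimmed; see [apply_margin()]). Within each interval, window end
#' positions advance by `stride` samples starting from the earliest sample
#' at which a full window fits. Label interval bounds are half-open
#' `[start, end)` and are aligned to the sample grid by flooring.
#'
#' @param rec an [inertial_recording()].
#' @param track a [label_track()] on the same clock as `rec`.
#' @param window window length in seconds (default 1); `window * sample_rate`
#'   must be a whole number of samples.
#' @param stride advance between consecutive window ends, in samples
#'   (default 10, i.e. 0.1 s at 100 Hz).
#' @return a data.frame with one row per window: `first`, `last` (1-based
#'   sample indices, inclusive), `category`, and `window_time` (the window's
#'   exclusive end time in seconds); window length is stored in the
#'   `window_samples` attribute.
#' @export
cut_windows <- function(rec, track, window = 1.0, stride = 10L) {
  stopifnot(inherits(rec, "inertial_recording"), inherits(track, "label_track"))
  if (!is.numeric(stride) || length(stride) != 1L || stride <= 0) {
    stop("stride must be a positive number of samples", call. = FALSE)
  }
  stride <- as.integer(stride)
  wlen <- window * rec$sample_rate
  if (abs(wlen - round(wlen)) > 1e-9) {
    stop("window * sample_rate must be integral", call. = FALSE)
  }
  wlen <- as.integer(round(wlen))
  t <- rec$t
  dt <- 1 / rec$sample_rate
  out <- list()
  for (i in seq_len(nrow(track))) {
    inside <- which(t >= track$start[i] - 1e-9 & t < track$end[i] - 1e-9)
    if (length(inside) < wlen) next
    lo <- inside[1L]; hi <- inside[length(inside)]
    ends <- seq.int(lo + wlen - 1L, hi, by = stride)
    out[[length(out) + 1L]] <- data.frame(
      first = ends - wlen + 1L, last = ends,
      category = track$category[i], window_time = t[ends] + dt,
      stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(first = integer(0), last = integer(0),
               category = character(0), window_time = numeric(0))
  rownames(res) <- NULL
  attr(res, "window_samples") <- wlen
  res
}

# Column-wise window statistics; W is wlen x nwin.
.window_stats <- function(W, rate) {
  n <- nrow(W)
  mu <- colMeans(W)
  Wc <- sweep(W, 2L, mu)
  m2 <- colMeans(Wc^2)
  m3 <- colMeans(Wc^3)
  m4 <- colMeans(Wc^4)
  sdv <- sqrt(m2 * n / (n - 1))
  skew <- ifelse(m2 > 0, m3 / m2^1.5, 0)
  kurt <- ifelse(m2 > 0, m4 / m2^2 - 3, 0)
  mins <- apply(W, 2L, min)
  maxs <- apply(W, 2L, max)
  crossings <- apply(Wc, 2L, function(x) {
    s <- sign(x); s <- s[s != 0]
    if (length(s) < 2L) 0 else sum(s[-1L] != s[-length(s)])
  })
  nb <- n %/% 2L  # FFT bins 1..floor(n/2), DC excluded
  mag <- Mod(stats::mvfft(W))[2:(nb + 1L), , drop = FALSE] * 2 / n
  jmax <- max.col(t(mag), ties.method = "first")
  list(mean = mu, sd = sdv, skewness = skew, kurtosis = kurt,
       min = mins, max = maxs, crossings = as.numeric(crossings),
       fft_freq = jmax * rate / n,
       fft_mag = mag[cbind(jmax, seq_along(jmax))],
       harmonics = mag[seq_len(min(6L, nb)), , drop = FALSE])
}

#' Extract the 126-dimensional feature matrix
#'
#' Computes, for every window, the feature vector defined by
#' [feature_manifest()]: per-signal window statistics including moments,
#' extrema, mean-crossing counts and discrete-Fourier components. Columns
#' appear in manifest order. Extraction is fully deterministic.
#'
#' @param sig a [derived_signals()] object.
#' @param windows the window table from [cut_windows()].
#' @return an object of class `feature_dataset`: a list with the
#'   `windows x 126` matrix `X` (manifest-named columns), character label
#'   vector `y`, `window_time`, a per-window `provenance` data.frame
#'   (`dog_id`, `breed`, `session_index`) and the `manifest`.
#' @export
extract_features <- function(sig, windows) {
  stopifnot(inherits(sig, "derived_signals"))
  manifest <- feature_manifest()
  wlen <- attr(windows, "window_samples")
  if (is.null(wlen)) stop("windows must come from cut_windows()", call. = FALSE)
  nwin <- nrow(windows)
  rate <- sig$sample_rate
  X <- matrix(NA_real_, nrow = nwin, ncol = nrow(manifest),
              dimnames = list(NULL, manifest$name))
  if (nwin > 0L) {
    idx <- outer(seq_len(wlen) - 1L, windows$first, "+")
    for (s in unique(manifest$signal)) {
      v <- sig[[s]]
      W <- matrix(v[idx], nrow = wlen)
      if (any(!is.finite(W))) {
        bad <- which(colSums(!is.finite(W)) > 0)[1L]
        stop("non-finite samples in window ", bad, " of signal ", s,
             call. = FALSE)
      }
      st <- .window_stats(W, rate)
      rows <- which(manifest$signal == s)
      for (r in rows) {
        stat <- manifest$statistic[r]
        X[, manifest$name[r]] <- if (grepl("^harm", stat)) {
          st$harmonics[as.integer(sub("harm", "", stat)), ]
        } else {
          st[[stat]]
        }
      }
    }
  }
  meta <- sig$meta
  feature_dataset(X, windows$category, windows$window_time,
                  data.frame(dog_id = rep(meta$dog_id, nwin),
                             breed = rep(meta$breed, nwin),
                             session_index = rep(meta$session_index, nwin),
                             stringsAsFactors = FALSE),
                  manifest)
}

#' Assemble a feature dataset
#'
#' @param X numeric matrix, one row per window, columns named as in the
#'   manifest.
#' @param y character vector of behaviour categories, one per row.
#' @param window_time numeric vector of window end times (seconds).
#' @param provenance data.frame with `dog_id`, `breed`, `session_index`,
#'   one row per window.
#' @param manifest the feature manifest (defaults to [feature_manifest()]).
#' @return a `feature_dataset` object.
#' @export
feature_dataset <- function(X, y, window_time = rep(NA_real_, nrow(X)),
                            provenance = NULL, manifest = feature_manifest()) {
  X <- as.matrix(X)
  if (is.null(provenance)) {
    provenance <- data.frame(dog_id = rep(NA_character_, nrow(X)),
                             breed = NA_character_, session_index = NA_integer_)
  }
  stopifnot(nrow(X) == length(y), nrow(X) == nrow(provenance),
            nrow(X) == length(window_time))
  behavior_factor(y)
  structure(list(X = X, y = as.character(y), window_time = window_time,
                 provenance = provenance, manifest = manifest),
            class = "feature_dataset")
}

#' @export
print.feature_dataset <- function(x, ...) {
  cat(sprintf("<feature_dataset> %d windows x %d features; categories: %s\n",
              nrow(x$X), ncol(x$X),
              paste(names(table(x$y)), table(x$y), sep = "=", collapse = " ")))
  invisible(x)
}

#' Number of windows in a feature dataset
#' @param ds a `feature_dataset`.
#' @export
n_windows <- function(ds) nrow(ds$X)

#' Row-bind feature datasets
#' @param dss list of `feature_dataset` objects sharing one manifest.
#' @return a single combined `feature_dataset`.
#' @export
bind_datasets <- function(dss) {
  stopifnot(length(dss) > 0L)
  nm <- colnames(dss[[1L]]$X)
  for (d in dss) stopifnot(identical(colnames(d$X), nm))
  feature_dataset(do.call(rbind, lapply(dss, `[[`, "X")),
                  unlist(lapply(dss, `[[`, "y"), use.names = FALSE),
                  unlist(lapply(dss, `[[`, "window_time"), use.names = FALSE),
                  do.call(rbind, lapply(dss, `[[`, "provenance")),
                  dss[[1L]]$manifest)
}

#' Subset the rows of a feature dataset
#' @param ds a `feature_dataset`.
#' @param i row index vector.
#' @export
subset_windows <- function(ds, i) {
  feature_dataset(ds$X[i, , drop = FALSE], ds$y[i], ds$window_time[i],
                  ds$provenance[i, , drop = FALSE], ds$manifest)
}

#' Min-max feature normalization
#'
#' Features are mapped to the unit interval using per-feature minima and
#' maxima learned from a training dataset: the training data then spans
#' exactly \[0, 1\] per column, constant columns map to 0, and values from
#' other datasets falling outside the training range are clipped to
#' \[0, 1\].
#'
#' @param train a non-empty `feature_dataset`.
#' @return `fit_normalizer()` returns a `normalization_params` object
#'   (per-feature `min` and `max`); `apply_normalizer()` returns the
#'   rescaled `feature_dataset`.
#' @export
fit_normalizer <- function(train) {
  stopifnot(inherits(train, "feature_dataset"))
  if (nrow(train$X) == 0L) stop("empty training dataset", call. = FALSE)
  structure(list(min = apply(train$X, 2L, min),
                 max = apply(train$X, 2L, max),
                 features = colnames(train$X)),
            class = "normalization_params")
}

#' @param params a `normalization_params` object.
#' @param ds the `feature_dataset` to rescale.
#' @rdname fit_normalizer
#' @export
apply_normalizer <- function(params, ds) {
  stopifnot(inherits(params, "normalization_params"),
            inherits(ds, "feature_dataset"))
  if (!identical(colnames(ds$X), params$features)) {
    stop("feature columns do not match normalizer", call. = FALSE)
  }
  rng <- params$max - params$min
  X <- sweep(ds$X, 2L, params$min)
  X <- sweep(X, 2L, ifelse(rng > 0, rng, 1), "/")
  X[, rng == 0] <- 0
  X[X < 0] <- 0
  X[X > 1] <- 1
  out <- ds
  out$X <- X
  out
}

#' Featurize one measurement end-to-end
#'
#' Convenience wrapper: trims the label margin, derives secondary signals,
#' cuts labelled one-second windows and extracts the 126 features.
#'
#' @param measurement a list with elements `recording` and `track` (as
#'   produced by [generate_session()] / [generate_study()]), or pass `rec`
#'   and `track` yourself.
#' @param margin label margin in seconds (see [apply_margin()]).
#' @param window,stride window length (s) and stride (samples), see
#'   [cut_windows()].
#' @param epsilon_az tangent clamp, see [derive_signals()].
#' @return a `feature_dataset`.
#' @export
featurize_measurement <- function(measurement, margin = 1.0, window = 1.0,
                                  stride = 10L, epsilon_az = 0.05) {
  rec <- measurement$recording
  track <- apply_margin(measurement$track, margin)
  sig <- derive_signals(rec, epsilon_az = epsilon_az)
  win <- cut_windows(rec, track, window = window, stride = stride)
  extract_features(sig, win)
}

#' Export a feature dataset or manifest as CSV
#' @param ds a `feature_dataset`.
#' @param path output file.
#' @export
write_features <- function(ds, path) {
  df <- data.frame(ds$X, check.names = FALSE)
  df$label <- ds$y
  df$window_time <- ds$window_time
  df <- cbind(df, ds$provenance)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @param manifest a feature manifest data.frame.
#' @rdname write_features
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}
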
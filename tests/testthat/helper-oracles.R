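# Independent oracles and tiny fixture builders shared across tests.

# Two-pass moment oracle for one window.
oracle_moments <- function(x) {
  n <- length(x)
  mu <- sum(x) / n
  d <- x - mu
  m2 <- sum(d^2) / n
  m3 <- sum(d^3) / n
  m4 <- sum(d^4) / n
  s <- sign(d)
  s <- s[s != 0]
  list(mean = mu,
       sd = sqrt(sum(d^2) / (n - 1)),
       skewness = if (m2 > 0) m3 / m2^1.5 else 0,
       kurtosis = if (m2 > 0) m4 / m2^2 - 3 else 0,
       min = min(x), max = max(x),
       crossings = if (length(s) < 2) 0 else sum(s[-1] != s[-length(s)]))
}

# Direct O(n^2) discrete Fourier transform oracle; returns amplitude-scaled
# magnitudes of bins 1..floor(n/2) and the dominant bin's frequency.
oracle_dft <- function(x, rate) {
  n <- length(x)
  ks <- seq_len(n %/% 2)
  mags <- vapply(ks, function(k) {
    re <- sum(x * cos(-2 * pi * k * (seq_len(n) - 1) / n))
    im <- sum(x * sin(-2 * pi * k * (seq_len(n) - 1) / n))
    2 * sqrt(re^2 + im^2) / n
  }, numeric(1))
  j <- which.max(mags)
  list(mags = mags, dominant_freq = ks[j] * rate / n, dominant_mag = mags[j])
}

# Brute-force window enumeration: every end sample k whose full span of
# `wlen` samples lies inside a single labelled interval, subsampled by
# `stride` from the first valid end of each interval.
oracle_windows <- function(rec, track, window = 1, stride = 10) {
  wlen <- as.integer(round(window * rec$sample_rate))
  t <- rec$t
  out <- NULL
  for (i in seq_len(nrow(track))) {
    valid <- c()
    for (k in seq_along(t)) {
      if (k < wlen) next
      span <- t[(k - wlen + 1):k]
      if (all(span >= track$start[i] - 1e-9 & span < track$end[i] - 1e-9)) {
        valid <- c(valid, k)
      }
    }
    if (length(valid) > 0) {
      take <- valid[seq(1, length(valid), by = stride)]
      out <- rbind(out, data.frame(first = take - wlen + 1L, last = take,
                                   category = track$category[i]))
    }
  }
  out
}

# A small recording with prescribed channel generators.
make_recording <- function(n, rate = 100, gen = function(t) sin(2 * pi * t),
                           dog_id = "T01", breed = "Labrador", session = 1L) {
  t <- (seq_len(n) - 1) / rate
  inertial_recording(t, gen(t), gen(t + 0.1), gen(t + 0.2),
                     gen(t + 0.3) * 50, gen(t + 0.4) * 50, gen(t + 0.5) * 50,
                     sample_rate = rate, dog_id = dog_id, breed = breed,
                     session_index = session)
}

# Random non-overlapping label track over [0, t_max).
random_track <- function(t_max, n_intervals = 4) {
  bounds <- sort(runif(2 * n_intervals, 0, t_max))
  starts <- bounds[seq(1, 2 * n_intervals, 2)]
  ends <- bounds[seq(2, 2 * n_intervals, 2)]
  keep <- (ends - starts) > 0.05
  label_track(starts[keep], ends[keep],
              sample(behavior_categories(), sum(keep), replace = TRUE))
}

# A linearly separable toy feature dataset: per category, features are a
# distinct constant plus small jitter in the first columns.
toy_dataset <- function(n_per_cat = 8, cats = c("walk", "trot", "stand"),
                        jitter = 0.01, seed = 42) {
  manifest <- feature_manifest()
  set.seed(seed)
  X <- NULL
  y <- character(0)
  for (i in seq_along(cats)) {
    block <- matrix(i + rnorm(n_per_cat * nrow(manifest), 0, jitter),
                    nrow = n_per_cat)
    X <- rbind(X, block)
    y <- c(y, rep(cats[i], n_per_cat))
  }
  colnames(X) <- manifest$name
  feature_dataset(X, y,
                  window_time = seq_along(y),
                  provenance = data.frame(dog_id = rep("T01", length(y)),
                                          breed = "Labrador",
                                          session_index = 1L),
                  manifest = manifest)
}

# Noise-free, zero-jitter template set with well-separated parameters, for
# exact-recovery control experiments.
separable_templates <- function() {
  tpl <- default_templates()
  for (nm in names(tpl)) {
    tpl[[nm]]$acc_noise <- 0
    tpl[[nm]]$gyr_noise <- 0
    if (!is.null(tpl[[nm]]$panting)) {
      tpl[[nm]]$panting <- list(freq = 5.3, gyr_amp = 0, acc_amp = 0)
    }
  }
  # pull canter and gallop apart so categories are exactly separable
  tpl$canter$freq <- 3.2
  tpl$gallop$freq <- 4.8
  tpl$gallop$acc_amp <- tpl$gallop$acc_amp * 1.6
  tpl
}

# Study -> per-measurement feature datasets at reduced desk-scale sizes.
featurize_study <- function(study, stride = 10L) {
  lapply(study, featurize_measurement, stride = stride)
}
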
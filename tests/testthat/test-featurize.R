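test_that("derived signals obey the basic identities", {
  n <- 200
  t <- (seq_len(n) - 1) / 100
  # constant rotation rate, static gravity-only acceleration
  rec <- inertial_recording(t, rep(0, n), rep(0, n), rep(-1, n),
                            rep(10, n), rep(0, n), rep(0, n))
  sig <- derive_signals(rec)
  expect_equal(sig$alpha_roll, rep(0, n))
  expect_equal(sig$a_mag, rep(1, n))
  expect_equal(sig$d, rep(0, n))
  expect_equal(sig$r_xz, rep(0, n))
  expect_true(all(abs(sig$c) <= 1))

  short <- inertial_recording(0, 0, 0, -1, 0, 0, 0)
  expect_error(derive_signals(short), "too short")
})

test_that("angular acceleration matches the analytic derivative within 1%", {
  n <- 400
  t <- (seq_len(n) - 1) / 100
  w <- sin(2 * pi * 2 * t) * 100
  rec <- inertial_recording(t, rep(0, n), rep(0, n), rep(-1, n),
                            w, rep(0, n), rep(0, n))
  sig <- derive_signals(rec)
  analytic <- 2 * pi * 2 * 100 * cos(2 * pi * 2 * t)
  interior <- 3:(n - 2)
  expect_lt(max(abs(sig$alpha_roll[interior] - analytic[interior])) /
              max(abs(analytic)), 0.01)
})

test_that("the tangent ratio clamps a_z away from zero", {
  n <- 10
  t <- (seq_len(n) - 1) / 100
  rec <- inertial_recording(t, rep(0.5, n), rep(0, n), rep(0.001, n),
                            rep(0, n), rep(0, n), rep(0, n))
  sig <- derive_signals(rec, epsilon_az = 0.05)
  expect_equal(sig$r_xz, rep(0.5 / 0.05, n))
})

test_that("the manifest partitions 126 features as 45 + 69 + 12", {
  m <- feature_manifest()
  expect_equal(nrow(m), 126L)
  expect_equal(sum(m$group == "acc_only"), 45L)
  expect_equal(sum(m$group == "gyro_only"), 69L)
  expect_equal(sum(m$group == "mixed"), 12L)
  expect_false(anyDuplicated(m$name) > 0)
})

test_that("windowing matches the stated enumeration on the 5 s example", {
  rec <- make_recording(700)
  track <- label_track(0, 5, "trot")
  win <- cut_windows(rec, track, window = 1, stride = 10)
  expect_equal(nrow(win), 41L)
  expect_equal(win$window_time, seq(1, 5, by = 0.1))
  expect_equal(unique(win$category), "trot")
  expect_equal(win$last - win$first + 1L, rep(100L, 41L))

  # an interval shorter than the window yields nothing
  expect_equal(nrow(cut_windows(rec, label_track(0, 0.9, "sit"))), 0L)
  expect_error(cut_windows(rec, track, stride = 0), "stride")

  # no window straddles a category boundary
  two <- label_track(c(0, 2), c(2, 4), c("walk", "trot"))
  win2 <- cut_windows(rec, two, window = 1, stride = 1)
  t <- rec$t
  for (i in seq_len(nrow(win2))) {
    span <- t[win2$first[i]:win2$last[i]]
    expect_true(all(span >= 0 & span < 2) || all(span >= 2 & span < 4))
  }
})

test_that("windowing equals brute-force enumeration on random tracks", {
  set.seed(11)
  rec <- make_recording(1500)
  for (rep in 1:8) {
    track <- random_track(15, 4)
    stride <- sample(c(1, 7, 10, 25), 1)
    got <- cut_windows(rec, track, window = 1, stride = stride)
    want <- oracle_windows(rec, track, window = 1, stride = stride)
    if (is.null(want)) {
      expect_equal(nrow(got), 0L)
    } else {
      expect_equal(got$first, want$first)
      expect_equal(got$last, want$last)
      expect_equal(got$category, want$category)
    }
  }
})

test_that("degenerate constant windows follow the stated conventions", {
  n <- 300
  t <- (seq_len(n) - 1) / 100
  rec <- inertial_recording(t, rep(0.3, n), rep(0, n), rep(-0.9, n),
                            rep(5, n), rep(-2, n), rep(1, n))
  sig <- derive_signals(rec)
  win <- cut_windows(rec, label_track(0, 3, "stand"), stride = 100)
  ds <- extract_features(sig, win)
  expect_equal(unname(ds$X[, "a_x.sd"]), rep(0, nrow(ds$X)))
  expect_equal(unname(ds$X[, "a_x.skewness"]), rep(0, nrow(ds$X)))
  expect_equal(unname(ds$X[, "a_x.kurtosis"]), rep(0, nrow(ds$X)))
  expect_equal(unname(ds$X[, "a_x.crossings"]), rep(0, nrow(ds$X)))
  expect_equal(ds$X[, "a_x.min"], ds$X[, "a_x.mean"])
  expect_equal(ds$X[, "a_x.max"], ds$X[, "a_x.mean"])
})

test_that("a pure 3 Hz sinusoid is located exactly by the FFT features", {
  n <- 300
  t <- (seq_len(n) - 1) / 100
  x <- 0.8 * sin(2 * pi * 3 * t)
  rec <- inertial_recording(t, x, rep(0, n), rep(-1, n),
                            rep(0, n), rep(0, n), rep(0, n))
  sig <- derive_signals(rec)
  win <- cut_windows(rec, label_track(0, 3, "walk"), stride = 50)
  ds <- extract_features(sig, win)
  expect_equal(unname(ds$X[, "a_x.fft_freq"]), rep(3, nrow(ds$X)))
  for (i in seq_len(nrow(ds$X))) {
    o <- oracle_dft(sig$a_x[win$first[i]:win$last[i]], 100)
    expect_equal(unname(ds$X[i, "a_x.fft_mag"]), o$dominant_mag,
                 tolerance = 1e-9)
  }
})

test_that("window statistics agree with independent oracles to 1e-9", {
  set.seed(23)
  rec <- make_recording(600, gen = function(t) {
    sin(2 * pi * runif(1, 1, 8) * t) + rnorm(length(t), 0, 0.3)
  })
  sig <- derive_signals(rec)
  win <- cut_windows(rec, label_track(0, 6, "trot"), stride = 40)
  ds <- extract_features(sig, win)
  for (s in c("a_x", "w_roll", "a_mag", "d")) {
    for (i in seq_len(nrow(win))) {
      x <- sig[[s]][win$first[i]:win$last[i]]
      mo <- oracle_moments(x)
      for (stat in names(mo)) {
        expect_equal(ds$X[i, paste0(s, ".", stat)], mo[[stat]],
                     tolerance = 1e-9, ignore_attr = TRUE)
      }
      dft <- oracle_dft(x, 100)
      expect_equal(ds$X[i, paste0(s, ".fft_freq")], dft$dominant_freq,
                   ignore_attr = TRUE)
      expect_equal(ds$X[i, paste0(s, ".fft_mag")], dft$dominant_mag,
                   tolerance = 1e-9, ignore_attr = TRUE)
    }
  }
  # harmonic magnitudes of |w| equal the oracle's low bins
  o <- oracle_dft(sig$w_mag[win$first[1]:win$last[1]], 100)
  expect_equal(unname(ds$X[1, paste0("w_mag.harm", 1:6)]), o$mags[1:6],
               tolerance = 1e-9)
})

test_that("feature extraction is deterministic and rejects non-finite input", {
  rec <- make_recording(300)
  sig <- derive_signals(rec)
  win <- cut_windows(rec, label_track(0, 3, "walk"), stride = 30)
  a <- extract_features(sig, win)
  b <- extract_features(sig, win)
  expect_identical(a$X, b$X)

  sig$a_x[150] <- NaN
  expect_error(extract_features(sig, win), "non-finite")
})

test_that("min-max normalization maps training data onto [0, 1] and clips", {
  m <- feature_manifest()
  X <- matrix(rep(c(2, 4, 6), nrow(m)), ncol = nrow(m),
              dimnames = list(NULL, m$name))
  X[, 2] <- 5  # constant column
  ds <- feature_dataset(X, c("walk", "trot", "stand"))
  params <- fit_normalizer(ds)
  norm <- apply_normalizer(params, ds)
  expect_equal(unname(norm$X[, 1]), c(0, 0.5, 1))
  expect_equal(unname(norm$X[, 2]), c(0, 0, 0))
  expect_true(all(norm$X >= 0 & norm$X <= 1))

  # out-of-range validation values clip to [0, 1]
  val <- feature_dataset(matrix(8, 1, nrow(m), dimnames = list(NULL, m$name)),
                         "walk")
  nv <- apply_normalizer(params, val)
  expect_equal(unname(nv$X[1, 1]), 1)

  empty <- subset_windows(ds, integer(0))
  expect_error(fit_normalizer(empty), "empty")
})
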
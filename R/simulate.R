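#' Default behaviour templates for the canine-motion simulator
#'
#' One template per behaviour category. Static postures (`lay`, `sit`,
#' `stand`) place the device at a characteristic attitude so the
#' accelerometer reads a rotated 1 g gravity vector plus noise, while the
#' gyroscope carries only noise and a small shared panting oscillation
#' (identical across the three postures, so angular-velocity channels
#' carry no posture information by construction). Gaits are modelled as a
#' gravity baseline plus a decaying harmonic series of a stride frequency,
#' with stride frequency and per-axis amplitudes increasing with activity
#' level; the canter and gallop templates are deliberately close so their
#' per-individual frequency and amplitude distributions overlap, as they
#' do in real locomotion.
#'
#' The parameter values are plausible-by-construction knobs for testing
#' the pipeline, not biomechanical claims about real dogs; all of them are
#' user-replaceable.
#'
#' @return a named list of template lists, one per category, with fields
#'   `category`, `kind` (`static`/`gait`), `pitch`, `roll` (degrees),
#'   `freq` (Hz), `acc_amp` (g, per axis), `gyr_amp` (deg/s, per axis),
#'   `harmonics`, `acc_noise`, `gyr_noise` (noise SD per channel) and for
#'   static templates `panting` (freq Hz, gyro amplitude deg/s, acc
#'   amplitude g).
#' @export
default_templates <- function() {
  static <- function(category, pitch, roll) {
    list(category = category, kind = "static", pitch = pitch, roll = roll,
         freq = 0, acc_amp = c(0, 0, 0), gyr_amp = c(0, 0, 0),
         harmonics = 0L, acc_noise = 0.03, gyr_noise = 3,
         panting = list(freq = 5.3, gyr_amp = 2, acc_amp = 0.01))
  }
  gait <- function(category, freq, acc, gyr, pitch) {
    list(category = category, kind = "gait", pitch = pitch, roll = 0,
         freq = freq, acc_amp = acc, gyr_amp = gyr, harmonics = 3L,
         acc_noise = 0.08, gyr_noise = 8, panting = NULL)
  }
  list(
    lay = static("lay", pitch = 0, roll = 10),
    sit = static("sit", pitch = 35, roll = 0),
    stand = static("stand", pitch = 5, roll = 0),
    walk = gait("walk", 1.8, c(0.15, 0.08, 0.25), c(40, 28, 20), pitch = 5),
    trot = gait("trot", 3.0, c(0.30, 0.15, 0.50), c(90, 60, 45), pitch = 8),
    canter = gait("canter", 3.6, c(0.45, 0.22, 0.75), c(130, 85, 65),
                  pitch = 10),
    gallop = gait("gallop", 4.0, c(0.57, 0.28, 0.95), c(150, 100, 75),
                  pitch = 12)
  )
}

.BREED_OFFSETS <- list(
  Malinois = list(freq = 1.06, amp = 1.10, pitch = 2),
  Labrador = list(freq = 1.00, amp = 1.00, pitch = 0)
)

#' Simulate a population of dog profiles
#'
#' Draws per-individual simulator parameters for two breeds (Malinois and
#' Labrador, `n_per_breed` each, default 12 + 12 mirroring a two-breed
#' study design). Each dog gets multiplicative lognormal deviations of its
#' stride frequencies and movement amplitudes (`sigma_ind` is the lognormal
#' sigma), an additive attitude jitter (SD `30 * sigma_ind` degrees) and an
#' individual panting frequency; breed-level offsets shift the template
#' means. With `sigma_ind = 0` all dogs of a breed are identical.
#'
#' @param n_per_breed dogs per breed (default 12).
#' @param sigma_ind individual-variation scale (default 0.1).
#' @param seed integer seed (mandatory).
#' @return list of `dog_profile` lists with fields `dog_id`, `breed`,
#'   `freq_factor`, `amp_factor`, `pitch_jitter`, `panting_freq`.
#' @export
make_population <- function(n_per_breed = 12L, sigma_ind = 0.1, seed) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  stopifnot(n_per_breed >= 1L, sigma_ind >= 0)
  profiles <- list()
  with_seed(seed, {
    for (breed in names(.BREED_OFFSETS)) {
      off <- .BREED_OFFSETS[[breed]]
      for (i in seq_len(n_per_breed)) {
        profiles[[length(profiles) + 1L]] <- structure(list(
          dog_id = sprintf("%s%02d", substr(breed, 1L, 1L), i),
          breed = breed,
          freq_factor = off$freq * stats::rlnorm(1, 0, sigma_ind),
          amp_factor = off$amp * stats::rlnorm(1, 0, sigma_ind),
          pitch_jitter = off$pitch + stats::rnorm(1, 0, 30 * sigma_ind),
          panting_freq = 5.3 * off$freq * stats::rlnorm(1, 0, sigma_ind)
        ), class = "dog_profile")
      }
    }
  })
  profiles
}

#' Session scripts
#'
#' A session script is the predetermined series of behaviours a recorded
#' dog performs: an ordered list of (category, duration) items separated by
#' unlabelled transition gaps (emulating interrupted annotation). The
#' default script runs each of the seven categories for 80 s with 2 s
#' gaps, giving a roughly ten-minute session.
#'
#' @param categories ordered character vector of behaviours.
#' @param durations per-item durations in seconds (recycled).
#' @param gap unlabelled transition between items, seconds.
#' @return a `session_script` object.
#' @export
session_script <- function(categories, durations, gap = 2) {
  stopifnot(length(categories) > 0, all(durations > 0), gap >= 0)
  behavior_factor(categories)
  structure(list(items = data.frame(category = as.character(categories),
                                    duration = rep_len(durations,
                                                       length(categories)),
                                    stringsAsFactors = FALSE),
                 gap = gap),
            class = "session_script")
}

#' @param duration_per_behavior seconds per behaviour in the default
#'   script.
#' @rdname session_script
#' @export
default_script <- function(duration_per_behavior = 80, gap = 2) {
  session_script(c("sit", "lay", "stand", "walk", "trot", "canter", "gallop"),
                 duration_per_behavior, gap)
}

# One simulated segment for a (template, profile) pair; returns the 6
# channel matrix (n x 6: ax ay az wr wp wy).
.simulate_segment <- function(tpl, profile, n, rate, f_sess, a_sess) {
  tt <- (seq_len(n) - 1L) / rate
  deg2rad <- pi / 180
  out <- matrix(0, nrow = n, ncol = 6L)
  p <- (tpl$pitch + profile$pitch_jitter) * deg2rad
  r <- tpl$roll * deg2rad
  grav <- c(sin(p), -cos(p) * sin(r), -cos(p) * cos(r))
  if (tpl$kind == "static") {
    for (j in 1:3) out[, j] <- grav[j]
    pant <- tpl$panting
    if (!is.null(pant)) {
      fp <- profile$panting_freq
      for (j in 1:3) {
        ph <- stats::runif(1, 0, 2 * pi)
        out[, j] <- out[, j] +
          pant$acc_amp * sin(2 * pi * fp * tt + ph)
        out[, j + 3L] <- pant$gyr_amp * sin(2 * pi * fp * tt + ph + pi / 3)
      }
    }
  } else {
    f_eff <- tpl$freq * profile$freq_factor * f_sess
    for (j in 1:3) {
      acc_a <- tpl$acc_amp[j] * profile$amp_factor * a_sess
      gyr_a <- tpl$gyr_amp[j] * profile$amp_factor * a_sess
      acc <- grav[j]
      gyr <- 0
      for (h in seq_len(tpl$harmonics)) {
        ph_a <- stats::runif(1, 0, 2 * pi)
        ph_g <- stats::runif(1, 0, 2 * pi)
        decay <- 0.5^(h - 1)
        acc <- acc + acc_a * decay * sin(2 * pi * h * f_eff * tt + ph_a)
        gyr <- gyr + gyr_a * decay * sin(2 * pi * h * f_eff * tt + ph_g)
      }
      out[, j] <- acc
      out[, j + 3L] <- gyr
    }
  }
  out[, 1:3] <- out[, 1:3] + stats::rnorm(3 * n, 0, tpl$acc_noise)
  out[, 4:6] <- out[, 4:6] + stats::rnorm(3 * n, 0, tpl$gyr_noise)
  out
}

#' Generate one labelled measurement session
#'
#' Synthesizes a six-channel inertial recording and the exactly matching
#' label track for one dog performing a session script. Static segments
#' are gravity at the template attitude (plus the dog's attitude jitter)
#' with channel noise and the shared panting oscillation; gait segments
#' superimpose a decaying harmonic series of the dog's effective stride
#' frequency on the gravity baseline. A small lognormal session factor
#' (sigma `session_jitter`) perturbs frequencies and amplitudes, modelling
#' day-to-day variation between a dog's measurements. Transition gaps
#' between scripted items contain unlabelled stand-like signal with
#' doubled noise.
#'
#' @param profile a `dog_profile` from [make_population()].
#' @param script a [session_script()].
#' @param sample_rate sampling frequency in Hz (default 100).
#' @param seed integer seed (mandatory).
#' @param templates behaviour templates (default [default_templates()]).
#' @param session_index stored in the recording metadata.
#' @param session_jitter lognormal sigma of the session-level frequency and
#'   amplitude factors (default 0.03).
#' @return a list with `recording` ([inertial_recording()]), `track`
#'   ([label_track()]) whose intervals exactly tile the scripted segments,
#'   plus `dog_id`, `breed`, `session_index`.
#' @export
generate_session <- function(profile, script = default_script(),
                             sample_rate = 100, seed,
                             templates = default_templates(),
                             session_index = 1L, session_jitter = 0.03) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  stopifnot(inherits(script, "session_script"))
  if (nrow(script$items) == 0L) stop("empty script", call. = FALSE)
  rate <- sample_rate
  chunks <- list()
  starts <- ends <- numeric(0)
  cats <- character(0)
  with_seed(seed, {
    f_sess <- stats::rlnorm(1, 0, session_jitter)
    a_sess <- stats::rlnorm(1, 0, session_jitter)
    pos <- 0L  # samples emitted so far
    gap_n <- as.integer(round(script$gap * rate))
    gap_tpl <- templates$stand
    gap_tpl$acc_noise <- gap_tpl$acc_noise * 2
    gap_tpl$gyr_noise <- gap_tpl$gyr_noise * 2
    for (i in seq_len(nrow(script$items))) {
      cat_i <- script$items$category[i]
      tpl <- templates[[cat_i]]
      if (is.null(tpl)) stop("no template for category ", cat_i,
                             call. = FALSE)
      n <- as.integer(round(script$items$duration[i] * rate))
      chunks[[length(chunks) + 1L]] <-
        .simulate_segment(tpl, profile, n, rate, f_sess, a_sess)
      starts <- c(starts, pos / rate)
      ends <- c(ends, (pos + n) / rate)
      cats <- c(cats, cat_i)
      pos <- pos + n
      if (i < nrow(script$items) && gap_n > 0L) {
        chunks[[length(chunks) + 1L]] <-
          .simulate_segment(gap_tpl, profile, gap_n, rate, f_sess, a_sess)
        pos <- pos + gap_n
      }
    }
  })
  m <- do.call(rbind, chunks)
  t <- (seq_len(nrow(m)) - 1L) / rate
  rec <- inertial_recording(t, m[, 1L], m[, 2L], m[, 3L],
                            m[, 4L], m[, 5L], m[, 6L],
                            sample_rate = rate,
                            dog_id = profile$dog_id, breed = profile$breed,
                            session_index = session_index)
  track <- label_track(starts, ends, cats,
                       coder_id = paste0("sim:", profile$dog_id))
  list(recording = rec, track = track, dog_id = profile$dog_id,
       breed = profile$breed, session_index = session_index)
}

#' Generate a full simulated study
#'
#' Produces `sessions_per_dog` measurements (default two, emulating two
#' subsequent independent recordings) for every dog in a population: the
#' same `dog_profile` across a dog's sessions, independent noise and
#' session factors between them, so within-dog consistency exceeds
#' between-dog consistency whenever individual variation is non-zero.
#'
#' @param population list of `dog_profile`s from [make_population()].
#' @param script a [session_script()] used for every session.
#' @param sessions_per_dog sessions per dog (default 2).
#' @param sample_rate sampling frequency in Hz.
#' @param seed integer master seed (mandatory); per-session seeds are
#'   derived from it.
#' @param ... passed to [generate_session()].
#' @return list of measurements as returned by [generate_session()].
#' @export
generate_study <- function(population, script = default_script(),
                           sessions_per_dog = 2L, sample_rate = 100, seed,
                           ...) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  n <- length(population) * sessions_per_dog
  seeds <- derive_seeds(seed, n)
  out <- vector("list", n)
  k <- 0L
  for (prof in population) {
    for (s in seq_len(sessions_per_dog)) {
      k <- k + 1L
      out[[k]] <- generate_session(prof, script, sample_rate,
                                   seed = seeds[k], session_index = s, ...)
    }
  }
  out
}

#' Simulate an independent second coder
#'
#' Derives a plausibly disagreeing second annotation from a reference
#' track, emulating a second human coding the same video: every interval
#' boundary is jittered by Gaussian noise (SD `boundary_sd` seconds,
#' clipped so intervals stay positive and non-overlapping) and each
#' interval is relabelled with probability `relabel_prob`, preferentially
#' to another category of the same activity level (canter vs gallop, the
#' static postures), otherwise to an adjacent-level category.
#'
#' @param track the reference [label_track()] (untrimmed).
#' @param seed integer seed (mandatory).
#' @param boundary_sd boundary jitter SD in seconds (default 0.3).
#' @param relabel_prob per-interval relabelling probability (default 0.03).
#' @param coder_id coder id of the derived track.
#' @return a [label_track()].
#' @export
simulate_second_coder <- function(track, seed, boundary_sd = 0.3,
                                  relabel_prob = 0.03, coder_id = "coder2") {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  stopifnot(inherits(track, "label_track"))
  n <- nrow(track)
  if (n == 0L) return(label_track(coder_id = coder_id))
  lv <- activity_level(track$category)
  all_lv <- activity_level(behavior_categories())
  with_seed(seed, {
    start <- track$start + stats::rnorm(n, 0, boundary_sd)
    end <- track$end + stats::rnorm(n, 0, boundary_sd)
    start <- pmax(start, 0)
    end <- pmax(end, start + 0.2)
    # enforce non-overlap sequentially
    for (i in seq_len(n - 1L)) {
      if (end[i] > start[i + 1L]) {
        mid <- (end[i] + start[i + 1L]) / 2
        end[i] <- mid
        start[i + 1L] <- mid
      }
    }
    category <- track$category
    flip <- stats::runif(n) < relabel_prob
    for (i in which(flip)) {
      same <- setdiff(behavior_categories()[all_lv == lv[i]], category[i])
      cand <- if (length(same) > 0) same else
        behavior_categories()[abs(all_lv - lv[i]) == 1]
      category[i] <- sample(cand, 1L)
    }
  })
  keep <- end > start
  label_track(start[keep], end[keep], category[keep], coder_id = coder_id)
}
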
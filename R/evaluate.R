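#' Measurement comprehensiveness
#'
#' A measurement's comprehensiveness is the minimum, over the seven
#' behaviour categories, of the number of labelled windows it contributes
#' (0 if any category is absent). Measurements with a higher minimum cover
#' the ethogram more evenly and are preferred for training.
#'
#' @param ds a `feature_dataset` holding one measurement's windows.
#' @return integer count.
#' @export
comprehensiveness <- function(ds) {
  stopifnot(inherits(ds, "feature_dataset"))
  counts <- table(factor(ds$y, levels = behavior_categories()))
  as.integer(min(counts))
}

#' Rank measurements by comprehensiveness
#'
#' For every dog, selects its more comprehensive measurement (the session
#' with the higher category-minimum window count; ties broken by total
#' window count, then by lower session index), then ranks dogs by that
#' score, descending, with ties broken by total window count and finally
#' alphabetically by dog id.
#'
#' @param datasets list of `feature_dataset` objects, one per measurement,
#'   each carrying uniform `dog_id`, `breed`, `session_index` provenance.
#' @return a list with `table` (one row per dog: `dog_id`, `breed`,
#'   `session_index`, `comprehensiveness`, `total_windows`, in rank order)
#'   and `best` (the selected `feature_dataset`s in the same order).
#' @export
rank_measurements <- function(datasets) {
  info <- do.call(rbind, lapply(datasets, function(d) {
    data.frame(dog_id = d$provenance$dog_id[1L],
               breed = d$provenance$breed[1L],
               session_index = d$provenance$session_index[1L],
               comprehensiveness = comprehensiveness(d),
               total_windows = n_windows(d), stringsAsFactors = FALSE)
  }))
  best_rows <- integer(0)
  for (dog in unique(info$dog_id)) {
    rows <- which(info$dog_id == dog)
    o <- order(-info$comprehensiveness[rows], -info$total_windows[rows],
               info$session_index[rows])
    best_rows <- c(best_rows, rows[o[1L]])
  }
  o <- order(-info$comprehensiveness[best_rows],
             -info$total_windows[best_rows], info$dog_id[best_rows])
  best_rows <- best_rows[o]
  list(table = `rownames<-`(info[best_rows, ], NULL),
       best = datasets[best_rows])
}

#' Activity-level validation breakdown
#'
#' Splits per-window validation outcomes into five exhaustive classes:
#' perfect match (predicted category equals truth), imperfect match (wrong
#' category but same activity level, \eqn{\Delta A = 0}) and mismatches at
#' \eqn{\Delta A = 1, 2, 3}, where \eqn{\Delta A} is the absolute
#' difference between the predicted and true activity levels.
#'
#' @param truth,pred character vectors of true and predicted categories.
#' @return a named numeric vector of percentages (`perfect`, `imperfect`,
#'   `dA1`, `dA2`, `dA3`) summing to 100.
#' @export
validation_breakdown <- function(truth, pred) {
  stopifnot(length(truth) == length(pred), length(truth) > 0)
  dA <- abs(activity_level(pred) - activity_level(truth))
  perfect <- pred == truth
  cls <- ifelse(perfect, "perfect",
                ifelse(dA == 0, "imperfect", paste0("dA", dA)))
  lv <- c("perfect", "imperfect", "dA1", "dA2", "dA3")
  pct <- 100 * as.vector(table(factor(cls, levels = lv))) / length(truth)
  stats::setNames(pct, lv)
}

#' Recognition-rate matrix
#'
#' Cross-tabulates true (rows) against predicted (columns) categories and
#' row-normalizes to percentages, so each defined row sums to 100 and its
#' entries read as the probability of a true category being recognized as
#' each output category. Rows with no true windows are undefined and
#' reported as `NA`, not zeros.
#'
#' @param truth,pred character vectors of true and predicted categories.
#' @return a 7x7 numeric matrix of percentages (rows = truth).
#' @export
recognition_matrix <- function(truth, pred) {
  cats <- behavior_categories()
  tab <- table(factor(truth, levels = cats), factor(pred, levels = cats))
  m <- unclass(tab) * 1.0
  rs <- rowSums(m)
  m <- m / ifelse(rs > 0, rs, NA_real_) * 100
  dimnames(m) <- list(truth = cats, predicted = cats)
  m
}

#' Average recognition matrices over calculations
#'
#' Entrywise mean of per-calculation row-normalized matrices; rows
#' undefined in a calculation (no true windows) are skipped for that
#' calculation, and rows undefined everywhere stay `NA`.
#'
#' @param mats list of 7x7 matrices from [recognition_matrix()].
#' @return the averaged 7x7 matrix.
#' @export
average_matrices <- function(mats) {
  stopifnot(length(mats) > 0)
  arr <- simplify2array(mats)
  m <- apply(arr, c(1L, 2L), mean, na.rm = TRUE)
  m[is.nan(m)] <- NA_real_
  m
}

.measurement_ids <- function(ds) {
  unique(paste(ds$provenance$dog_id, ds$provenance$session_index, sep = "/"))
}

#' Train on one measurement set, validate on a held-out measurement
#'
#' Enforces the hold-out discipline structurally: the training and
#' validation sides must not share any measurement (dog/session pair), and
#' the check runs before any computation. Trains the classifier on the
#' union of `train_sets`, predicts `validation_set`, and summarizes the
#' outcome as an activity-level breakdown and a recognition matrix.
#'
#' @param train_sets a `feature_dataset` or list of them (one per training
#'   measurement).
#' @param validation_set the held-out `feature_dataset`.
#' @param cfg an [svm_config()].
#' @param mask sensor-group filter passed to [train_classifier()].
#' @return a list with `breakdown` (see [validation_breakdown()]),
#'   `matrix` (see [recognition_matrix()]), `truth` and `pred`.
#' @export
validate_pair <- function(train_sets, validation_set, cfg = svm_config(),
                          mask = "all") {
  if (inherits(train_sets, "feature_dataset")) train_sets <- list(train_sets)
  train_ids <- unlist(lapply(train_sets, .measurement_ids))
  clash <- intersect(train_ids, .measurement_ids(validation_set))
  if (length(clash) > 0L) {
    stop("measurement(s) on both sides of the hold-out split: ",
         paste(clash, collapse = ", "), call. = FALSE)
  }
  model <- train_classifier(bind_datasets(train_sets), cfg, mask = mask)
  pred <- predict_classifier(model, validation_set)
  list(breakdown = validation_breakdown(validation_set$y, pred),
       matrix = recognition_matrix(validation_set$y, pred),
       truth = validation_set$y, pred = pred)
}

#' Run a training-validation comparison scheme
#'
#' Implements the six hold-out comparison schemes on a collection of
#' measurements:
#' \describe{
#'   \item{within_dog}{train on a dog's more comprehensive measurement,
#'     validate on the same dog's other measurement.}
#'   \item{intra_breed}{train on one dog's best measurement, validate on a
#'     different dog of the same breed.}
#'   \item{inter_breed}{as above but training and validating dogs come from
#'     different breeds.}
#'   \item{multi_1_1 / multi_3_3 / multi_5_5}{train on the pooled best
#'     measurements of k dogs per breed, validate on a dog absent from the
#'     training set; the validation dogs (up to five per breed) are fixed
#'     across the scheme's calculations.}
#' }
#' Dogs enter through their best measurements as ranked by
#' [rank_measurements()] (at most ten per breed). Pairings are drawn by a
#' seeded shuffle without replacement; each scheme performs `n_calc`
#' calculations (default 10) and the per-calculation recognition matrices
#' are averaged entrywise.
#'
#' @param datasets list of per-measurement `feature_dataset`s.
#' @param scheme one of `"within_dog"`, `"intra_breed"`, `"inter_breed"`,
#'   `"multi_1_1"`, `"multi_3_3"`, `"multi_5_5"`.
#' @param cfg an [svm_config()].
#' @param n_calc number of training-validation calculations (default 10).
#' @param seed integer seed for pairing draws (mandatory).
#' @param mask sensor-group filter.
#' @param pool_per_breed size of the ranked per-breed candidate pool
#'   (default 10).
#' @return an object of class `scheme_result`: list with `scheme`,
#'   `breakdowns` (n_calc x 5 data.frame of percentages), `mean_breakdown`,
#'   `matrix` (averaged recognition matrix) and `pairs` (who trained /
#'   validated in each calculation).
#' @export
run_scheme <- function(datasets, scheme, cfg = svm_config(), n_calc = 10L,
                       seed, mask = "all", pool_per_breed = 10L) {
  schemes <- c("within_dog", "intra_breed", "inter_breed",
               "multi_1_1", "multi_3_3", "multi_5_5")
  scheme <- match.arg(scheme, schemes)
  if (missing(seed)) stop("seed is required", call. = FALSE)
  ranked <- rank_measurements(datasets)
  tab <- ranked$table
  # candidate pool: up to pool_per_breed top-ranked dogs per breed
  pool_idx <- unlist(lapply(unique(tab$breed), function(b) {
    which(tab$breed == b)[seq_len(min(pool_per_breed, sum(tab$breed == b)))]
  }))
  tab <- tab[sort(pool_idx), , drop = FALSE]
  best <- ranked$best[sort(pool_idx)]
  names(best) <- tab$dog_id

  other_session <- function(dog) {
    best_sess <- tab$session_index[tab$dog_id == dog]
    hit <- vapply(datasets, function(d) {
      d$provenance$dog_id[1L] == dog &&
        d$provenance$session_index[1L] != best_sess
    }, logical(1))
    if (!any(hit)) stop("dog ", dog, " has no second measurement",
                        call. = FALSE)
    datasets[[which(hit)[1L]]]
  }

  pairs <- list()
  with_seed(seed, {
    if (scheme == "within_dog") {
      dogs <- sample(tab$dog_id, min(n_calc, nrow(tab)))
      for (dog in dogs) {
        pairs[[length(pairs) + 1L]] <-
          list(train = list(best[[dog]]), valid = other_session(dog),
               label = paste0(dog, ".best->", dog, ".other"))
      }
    } else if (scheme %in% c("intra_breed", "inter_breed")) {
      all_pairs <- expand.grid(x = tab$dog_id, y = tab$dog_id,
                               stringsAsFactors = FALSE)
      all_pairs <- all_pairs[all_pairs$x != all_pairs$y, ]
      same <- tab$breed[match(all_pairs$x, tab$dog_id)] ==
        tab$breed[match(all_pairs$y, tab$dog_id)]
      all_pairs <- if (scheme == "intra_breed") all_pairs[same, ] else
        all_pairs[!same, ]
      take <- all_pairs[sample(nrow(all_pairs), min(n_calc, nrow(all_pairs))), ]
      for (i in seq_len(nrow(take))) {
        pairs[[length(pairs) + 1L]] <-
          list(train = list(best[[take$x[i]]]), valid = best[[take$y[i]]],
               label = paste0(take$x[i], "->", take$y[i]))
      }
    } else {
      k <- as.integer(sub("multi_(\\d)_\\d", "\\1", scheme))
      breeds <- unique(tab$breed)
      stopifnot(length(breeds) == 2L)
      valid_dogs <- unlist(lapply(breeds, function(b) {
        cand <- tab$dog_id[tab$breed == b]
        # keep at least k dogs per breed available for training
        sample(cand, min(5L, max(1L, length(cand) - k)))
      }))
      train_pool <- setdiff(tab$dog_id, valid_dogs)
      valid_seq <- sample(rep_len(sample(valid_dogs), n_calc))
      for (vd in valid_seq) {
        tr <- unlist(lapply(breeds, function(b) {
          cand <- intersect(train_pool, tab$dog_id[tab$breed == b])
          if (length(cand) < k) stop("not enough ", b,
                                     " training dogs for ", scheme,
                                     call. = FALSE)
          sample(cand, k)
        }))
        pairs[[length(pairs) + 1L]] <-
          list(train = best[tr], valid = best[[vd]],
               label = paste0(paste(tr, collapse = "+"), "->", vd))
      }
    }
  })

  results <- lapply(pairs, function(p) {
    validate_pair(p$train, p$valid, cfg, mask = mask)
  })
  breakdowns <- as.data.frame(do.call(rbind, lapply(results, `[[`,
                                                    "breakdown")))
  structure(list(scheme = scheme,
                 breakdowns = breakdowns,
                 mean_breakdown = colMeans(breakdowns),
                 matrix = average_matrices(lapply(results, `[[`, "matrix")),
                 pairs = vapply(pairs, `[[`, character(1), "label")),
            class = "scheme_result")
}

#' @export
print.scheme_result <- function(x, ...) {
  cat(sprintf("<scheme_result> %s (%d calculations)\n", x$scheme,
              nrow(x$breakdowns)))
  print(round(x$mean_breakdown, 1))
  invisible(x)
}

#' Intercoder agreement between two label tracks
#'
#' Evaluates two coders' margin-trimmed annotation tracks on a shared node
#' grid (one node every `node_stride` seconds). Nodes labelled by exactly
#' one coder are tallied as that coder's exclusive fraction; on commonly
#' labelled nodes, agreement is the fraction assigned the same category,
#' and the 7x7 row-normalized matrix gives, per category of coder A, the
#' percentage distribution of coder B's labels.
#'
#' @param track_a,track_b margin-trimmed [label_track()]s on the same
#'   clock (coder A is the reference / main coder).
#' @param node_stride node spacing in seconds (default 0.1).
#' @return a list: `pct_only_a`, `pct_only_b` (percentage of each coder's
#'   labelled nodes not labelled by the other), `pct_common_agree`
#'   (`NA` if there are no common nodes), `matrix` (7x7, rows = coder A),
#'   `n_common`.
#' @export
intercoder_agreement <- function(track_a, track_b, node_stride = 0.1) {
  stopifnot(inherits(track_a, "label_track"), inherits(track_b, "label_track"))
  t_max <- max(c(track_a$end, track_b$end, 0))
  nodes <- seq(0, t_max, by = node_stride)
  label_at <- function(track, times) {
    if (nrow(track) == 0L) return(rep(NA_character_, length(times)))
    idx <- findInterval(times + 1e-9, track$start)
    ok <- idx >= 1L & times < track$end[pmax(idx, 1L)] - 1e-9
    out <- rep(NA_character_, length(times))
    out[ok] <- track$category[idx[ok]]
    out
  }
  la <- label_at(track_a, nodes)
  lb <- label_at(track_b, nodes)
  n_a <- sum(!is.na(la)); n_b <- sum(!is.na(lb))
  common <- !is.na(la) & !is.na(lb)
  cats <- behavior_categories()
  tab <- table(factor(la[common], levels = cats),
               factor(lb[common], levels = cats))
  m <- unclass(tab) * 1.0
  rs <- rowSums(m)
  m <- m / ifelse(rs > 0, rs, NA_real_) * 100
  dimnames(m) <- list(coder_a = cats, coder_b = cats)
  list(pct_only_a = if (n_a > 0) 100 * sum(!is.na(la) & is.na(lb)) / n_a
         else NA_real_,
       pct_only_b = if (n_b > 0) 100 * sum(is.na(la) & !is.na(lb)) / n_b
         else NA_real_,
       pct_common_agree = if (any(common))
         100 * mean(la[common] == lb[common]) else NA_real_,
       matrix = m,
       n_common = sum(common))
}
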
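make_meas <- function(dog, breed, session, cats, n_per_cat = 6, seed = 1) {
  ds <- toy_dataset(n_per_cat = n_per_cat, cats = cats, seed = seed)
  ds$provenance$dog_id <- dog
  ds$provenance$breed <- breed
  ds$provenance$session_index <- session
  ds
}

test_that("comprehensiveness is the minimum per-category window count", {
  cats <- rep(behavior_categories(),
              times = c(5, 4, 6, 8, 7, 3, 9))
  ds <- toy_dataset(n_per_cat = 1, cats = cats)
  expect_equal(comprehensiveness(ds), 3L)

  missing_gallop <- toy_dataset(n_per_cat = 4,
                                cats = setdiff(behavior_categories(),
                                               "gallop"))
  expect_equal(comprehensiveness(missing_gallop), 0L)
  expect_equal(comprehensiveness(toy_dataset(n_per_cat = 10,
                                             cats = behavior_categories())),
               10L)
})

test_that("measurements are ranked by comprehensiveness with stated tie rules", {
  all7 <- behavior_categories()
  d <- list(
    make_meas("A", "Labrador", 1L, all7, n_per_cat = 3),   # comp 3
    make_meas("A", "Labrador", 2L, all7, n_per_cat = 5),   # comp 5 <- best A
    make_meas("B", "Labrador", 1L, all7, n_per_cat = 4),   # comp 4
    make_meas("B", "Labrador", 2L, rep(all7, c(4, 4, 4, 4, 4, 4, 2)),
              n_per_cat = 1)                           # comp 2
  )
  r <- rank_measurements(d)
  expect_equal(r$table$dog_id, c("A", "B"))
  expect_equal(r$table$session_index, c(2L, 1L))
  expect_equal(r$table$comprehensiveness, c(5L, 4L))

  # equal minima: the session / dog with more total windows wins
  e <- list(
    make_meas("C", "Malinois", 1L, rep(all7, c(3, 3, 3, 3, 3, 3, 3))),
    make_meas("C", "Malinois", 2L, rep(all7, c(3, 3, 3, 3, 3, 3, 9))),
    make_meas("D", "Malinois", 1L, rep(all7, c(3, 3, 3, 3, 3, 3, 3)))
  )
  r2 <- rank_measurements(e)
  expect_equal(r2$table$dog_id[1], "C")
  expect_equal(r2$table$session_index[1], 2L)
})

test_that("the activity-level breakdown follows the level arithmetic", {
  truth <- rep("stand", 10)
  bd <- validation_breakdown(truth, truth)
  expect_equal(unname(bd), c(100, 0, 0, 0, 0))

  # wrong category at equal level is imperfect, not perfect
  bd <- validation_breakdown(rep("stand", 4), rep("lay", 4))
  expect_equal(bd[["imperfect"]], 100)
  expect_equal(bd[["perfect"]], 0)

  # walk predicted as gallop differs by two levels
  bd <- validation_breakdown("walk", "gallop")
  expect_equal(bd[["dA2"]], 100)
  # lay predicted as gallop differs by three
  expect_equal(validation_breakdown("lay", "gallop")[["dA3"]], 100)

  set.seed(5)
  for (rep in 1:20) {
    truth <- sample(behavior_categories(), 40, replace = TRUE)
    pred <- sample(behavior_categories(), 40, replace = TRUE)
    expect_equal(sum(validation_breakdown(truth, pred)), 100, tolerance = 1e-9)
  }
})

test_that("recognition matrices are row-normalized with undefined empty rows", {
  set.seed(6)
  truth <- sample(behavior_categories()[-7], 60, replace = TRUE)
  pred <- sample(behavior_categories(), 60, replace = TRUE)
  m <- recognition_matrix(truth, pred)
  defined <- rowSums(is.na(m)) == 0
  expect_true(all(abs(rowSums(m[defined, ]) - 100) < 1e-9))
  expect_true(all(m[defined, ] >= 0))
  expect_true(all(is.na(m["gallop", ])))  # no true gallop windows

  avg <- average_matrices(list(m, recognition_matrix(truth, truth)))
  expect_equal(unname(avg["lay", "lay"]), (m["lay", "lay"] + 100) / 2,
               ignore_attr = TRUE)
})

test_that("hold-out discipline rejects shared measurements before computing", {
  a <- make_meas("A", "Labrador", 1L, c("walk", "trot", "stand"))
  b <- make_meas("A", "Labrador", 1L, c("walk", "trot", "stand"))
  expect_error(validate_pair(a, b), "both sides")

  c1 <- make_meas("B", "Labrador", 1L, c("walk", "trot", "stand"), seed = 8)
  res <- validate_pair(a, c1)
  expect_equal(sum(res$breakdown), 100, tolerance = 1e-9)
  expect_equal(dim(res$matrix), c(7L, 7L))
})

test_that("a perfectly separable pair validates to the identity matrix", {
  train <- make_meas("A", "Labrador", 1L, c("walk", "trot", "stand"))
  valid <- make_meas("B", "Labrador", 1L, c("walk", "trot", "stand"),
                     seed = 12)
  res <- validate_pair(train, valid)
  expect_equal(res$breakdown[["perfect"]], 100)
  defined <- !is.na(res$matrix[, 1])
  expect_equal(unname(diag(res$matrix)[defined]), rep(100, 3))
})

test_that("schemes are reproducible and keep training/validation disjoint", {
  set.seed(31)
  pop <- make_population(3, 0.1, seed = 31)
  study <- generate_study(pop, default_script(6, 1), seed = 32)
  ds <- featurize_study(study)
  r1 <- run_scheme(ds, "within_dog", n_calc = 3, seed = 33)
  r2 <- run_scheme(ds, "within_dog", n_calc = 3, seed = 33)
  expect_identical(r1$breakdowns, r2$breakdowns)
  expect_identical(r1$matrix, r2$matrix)
  expect_equal(nrow(r1$breakdowns), 3L)
  expect_true(all(abs(rowSums(r1$breakdowns) - 100) < 1e-9))

  r3 <- run_scheme(ds, "intra_breed", n_calc = 4, seed = 34)
  for (lab in r3$pairs) {
    parts <- strsplit(lab, "->", fixed = TRUE)[[1]]
    expect_false(parts[1] == parts[2])
  }
  r4 <- run_scheme(ds, "multi_1_1", n_calc = 3, seed = 35)
  for (lab in r4$pairs) {
    parts <- strsplit(lab, "->", fixed = TRUE)[[1]]
    expect_false(parts[2] %in% strsplit(parts[1], "+", fixed = TRUE)[[1]])
  }
})

test_that("intercoder agreement counts nodes the stated way", {
  a <- label_track(0, 10, "trot", coder_id = "A")
  ident <- intercoder_agreement(a, a)
  expect_equal(ident$pct_common_agree, 100)
  expect_equal(unname(ident$matrix["trot", "trot"]), 100)
  expect_equal(ident$pct_only_a, 0)

  b <- label_track(c(0, 5), c(5, 10), c("trot", "canter"), coder_id = "B")
  half <- intercoder_agreement(a, b)
  expect_equal(half$pct_common_agree, 50)
  expect_equal(unname(half$matrix["trot", c("trot", "canter")]), c(50, 50))

  disjoint <- intercoder_agreement(label_track(0, 5, "walk"),
                                   label_track(6, 10, "walk"))
  expect_true(is.na(disjoint$pct_common_agree))
  expect_equal(disjoint$pct_only_a, 100)
  expect_equal(disjoint$pct_only_b, 100)
})
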
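test_that("row splits are disjoint, exhaustive and seeded", {
  sp <- split_indices(10, 0.8, seed = 1)
  expect_length(sp$train, 8)
  expect_length(sp$test, 2)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), 1:10)
  expect_identical(sp, split_indices(10, 0.8, seed = 1))
  expect_false(identical(sp, split_indices(10, 0.8, seed = 2)))
  expect_error(split_indices(4, 0.8, seed = 1), "fewer|\\[5")

  # repeated seeds on a realistic row count give essentially all-distinct partitions
  parts <- vapply(1:100, function(s) {
    paste(split_indices(392, 0.8, seed = s)$test, collapse = ",")
  }, "")
  expect_gte(length(unique(parts)), 99)
})

test_that("patient-grouped splits never straddle a patient", {
  ids <- rep(sprintf("P%02d", 1:30), times = rpois(30, 5) + 1)
  sp <- grouped_split_indices(ids, 0.8, seed = 3)
  expect_length(intersect(unique(ids[sp$train]), unique(ids[sp$test])), 0)
  expect_setequal(c(sp$train, sp$test), seq_along(ids))
  expect_identical(sp, grouped_split_indices(ids, 0.8, seed = 3))
})

test_that("SMOTE balances classes by convex combinations of minority points", {
  # one synthetic point between the two minority members lies on the segment
  x <- rbind(c(0, 0), c(1, 1), c(5, 5), c(6, 5), c(7, 6))
  y <- c("min", "min", "maj", "maj", "maj")
  out <- smote_oversample(x, y, k = 1, seed = 2)
  expect_identical(as.vector(table(out$y)), c(3L, 3L))
  synth <- out$x[6, ]
  expect_equal(synth[1], synth[2]) # on the segment (t, t)
  expect_gte(synth[1], 0)
  expect_lt(synth[1], 1)

  # duplicated identical minority points reproduce themselves
  x2 <- rbind(c(2, 3), c(2, 3), c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  y2 <- c("a", "a", "b", "b", "b", "b")
  out2 <- smote_oversample(x2, y2, k = 1, seed = 5)
  expect_equal(out2$x[7, ], c(2, 3))
  expect_equal(out2$x[8, ], c(2, 3))

  # balance contract at the study's patient-level imbalance (21 vs 44)
  withr::with_seed(7, {
    xm <- matrix(rnorm(65 * 4), 65)
    ym <- rep(c("eligible", "not"), c(21, 44))
  })
  out3 <- smote_oversample(xm, ym, k = 5, seed = 1)
  expect_identical(as.vector(table(out3$y)), c(44L, 44L))
  # originals retained unchanged, synthetics inside the minority bounding box
  expect_equal(out3$x[1:65, ], xm, ignore_attr = TRUE)
  mins <- apply(xm[1:21, ], 2, min)
  maxs <- apply(xm[1:21, ], 2, max)
  synth3 <- out3$x[66:88, ]
  expect_true(all(t(synth3) >= mins - 1e-12 & t(synth3) <= maxs + 1e-12))

  expect_warning(smote_oversample(xm[1:24, ], rep(c("a", "b"), c(3, 21)),
                                  k = 5, seed = 1), "k reduced")
  expect_error(smote_oversample(xm[1:10, ], rep(c("a", "b"), c(1, 9)),
                                k = 1, seed = 1), "single member")
})

test_that("imputation fits on training rows only and encodes missingness", {
  reg <- tibble::tibble(name = c("num", "bin"), group = "Lab",
                        dtype = c("numeric", "binary"), level = "patient",
                        missing_rate = 0)
  train <- tibble::tibble(num = c(1, 3, NA), bin = c(1L, NA, 0L))
  test <- tibble::tibble(num = c(NA, 10), bin = c(NA_integer_, 1L))
  enc <- impute_and_encode(train, test, reg)
  expect_equal(unname(enc$train[3, "num"]), 2) # training median
  expect_equal(unname(enc$test[1, "num"]), 2)  # test filled with TRAINING median
  expect_true("bin_missing" %in% colnames(enc$train))
  expect_equal(unname(enc$test[, "bin_missing"]), c(1, 0))
  expect_identical(unname(enc$feature_of["bin_missing"]), "bin")

  # all-missing training column dropped with warning
  train2 <- tibble::tibble(num = c(NA_real_, NA_real_), bin = c(1L, 0L))
  test2 <- tibble::tibble(num = c(1, 2), bin = c(0L, 1L))
  expect_warning(enc2 <- impute_and_encode(train2, test2, reg), "all-missing")
  expect_false("num" %in% colnames(enc2$train))
})

test_that("F1 matches the harmonic-mean formula and its degenerate conventions", {
  expect_equal(f1_score(c(1, 1, 0, 0), c(1, 1, 0, 0), positive = "1"), 1)
  expect_equal(f1_score(c(1, 1, 0, 0), c(1, 1, 1, 1), positive = "1"), 2 / 3)
  expect_equal(f1_score(c(1, 1, 0, 0), c(0, 0, 1, 1), positive = "1"), 0)
  # macro equals mean of per-class F1
  yt <- c("a", "a", "b", "b")
  yp <- c("a", "b", "b", "b")
  f_a <- 2 * 1 / (2 * 1 + 0 + 1)
  f_b <- 2 * 2 / (2 * 2 + 1 + 0)
  expect_equal(f1_score(yt, yp, "macro"), mean(c(f_a, f_b)))
  expect_error(f1_score(1:3, 1:2), "lengths differ")
})

test_that("learners are deterministic given a seed and separate separable classes", {
  withr::with_seed(31, {
    x <- matrix(rnorm(120 * 6), 120)
    y <- factor(if_else(x[, 1] > 0, "pos", "neg"))
  })
  for (learner in c("linear", "bagged_trees", "boosted_trees")) {
    m1 <- train_model(learner, x, y, seed = 4)
    m2 <- train_model(learner, x, y, seed = 4)
    expect_identical(predict(m1, x), predict(m2, x))
    expect_equal(f1_score(y, predict(m1, x), positive = "pos"), 1,
                 tolerance = 0.02)
  }
  expect_error(train_model("linear", x, factor(rep("a", 120)), seed = 1),
               "single class")
})

test_that("learners on label-independent features stay near chance over splits", {
  withr::with_seed(77, {
    x <- matrix(rnorm(300 * 5), 300)
    y <- factor(rep(c("TRUE", "FALSE"), 150))
  })
  f1s <- vapply(1:30, function(s) {
    sp <- split_indices(300, 0.8, seed = s)
    m <- train_model("boosted_trees", x[sp$train, ], y[sp$train], seed = s,
                     nrounds = 30)
    f1_score(y[sp$test], predict(m, x[sp$test, ]))
  }, 0)
  expect_gt(mean(f1s), 0.35)
  expect_lt(mean(f1s), 0.65)
})

test_that("bench grid enumerates the requested cross and the bench fills it", {
  g <- bench_grid(learners = c("bagged_trees", "boosted_trees"),
                  smote = c(FALSE, TRUE), targets = "pro_prrt_patient")
  expect_identical(nrow(g), 2L * 2L * 15L)
  expect_identical(anyDuplicated(g$config_id), 0L)

  co <- small_cohort(seed = 21, n_patients = 60)
  g2 <- bench_grid(learners = "boosted_trees", smote = c(FALSE, TRUE),
                   targets = "pro_prrt_lesion",
                   subsets = list("Onco", c("Onco", "Path")))
  b <- run_bench(co, g2, n_splits = 4, seed = 2, model_args = list(nrounds = 20))
  expect_identical(nrow(b$results), 4L * 4L)
  expect_true(all(b$results$f1 >= 0 & b$results$f1 <= 1, na.rm = TRUE))
  # SMOTE on vs off leaves the test rows identical in number
  by_smote <- b$results |>
    dplyr::group_by(.data$smote, .data$split) |>
    dplyr::summarise(n_test = unique(.data$n_test), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "smote", values_from = "n_test")
  expect_identical(by_smote$`TRUE`, by_smote$`FALSE`)
  # determinism of the whole bench
  b2 <- run_bench(co, g2, n_splits = 4, seed = 2, model_args = list(nrounds = 20))
  expect_equal(b$results, b2$results)
  expect_s3_class(tidy(b), "tbl_df")
  expect_identical(nrow(glance(b)), 1L)
})

test_that("test partitions are byte-identical before and after a bench run", {
  co <- small_cohort(seed = 30, n_patients = 50)
  frame <- prrtselect:::model_frame(co, "pro_prrt_lesion", c("Onco", "Path"))
  sp <- grouped_split_indices(frame$patient_id, 0.8, seed = prrtselect:::derive_seed(5, 1))
  before <- serialize(frame$x[sp$test, , drop = FALSE], NULL)
  g <- bench_grid(learners = "boosted_trees", smote = TRUE,
                  targets = "pro_prrt_lesion", subsets = list(c("Onco", "Path")))
  run_bench(co, g, n_splits = 1, seed = 5, model_args = list(nrounds = 10))
  frame2 <- prrtselect:::model_frame(co, "pro_prrt_lesion", c("Onco", "Path"))
  after <- serialize(frame2$x[sp$test, , drop = FALSE], NULL)
  expect_identical(before, after)
})

test_that("the three-bin Krenning target runs with macro-averaged F1", {
  co <- small_cohort(seed = 71, n_patients = 60)
  expect_identical(levels(krenning_bin(co$lesions$krenning)),
                   c("0-1", "2", "3-4"))
  b <- run_bench(co,
                 bench_grid(learners = "boosted_trees", smote = FALSE,
                            targets = "krenning_bin",
                            subsets = list(variable_groups())),
                 n_splits = 3, seed = 9, model_args = list(nrounds = 20))
  expect_true(all(b$results$f1 >= 0 & b$results$f1 <= 1, na.rm = TRUE))
  expect_identical(nrow(b$results), 3L)
})
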
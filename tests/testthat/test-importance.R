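# A predictor that just looks up one column, for closed-form importance
# checks: predict = column value itself.
lookup_model <- function(col, n_features) {
  structure(list(learner = "lookup", col = col, n_features = n_features,
                 levels = c("0", "1")),
            class = "lookup_model")
}
predict.lookup_model <- function(object, newdata, ...) {
  factor(as.character(newdata[, object$col]), levels = object$levels)
}
registerS3method("predict", "lookup_model", predict.lookup_model,
                 envir = asNamespace("stats"))

test_that("permutation importance matches the exhaustive enumeration oracle", {
  # y is a copy of the feature; the predictor reads that column. With a
  # balanced binary y of size 4, PI = 1 - mean F1 over all 4! permutations.
  x <- cbind(sig = c(0, 0, 1, 1), noise = c(1, 0, 1, 0))
  y <- factor(c("0", "0", "1", "1"), levels = c("0", "1"))
  m <- lookup_model("sig", 2)

  perms <- gtools_perms <- NULL
  all_perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in all_perms(v[-i])) out <- c(out, list(c(v[i], rest)))
    }
    out
  }
  oracle_f1s <- vapply(all_perms(c(0, 0, 1, 1)), function(p) {
    f1_score(y, factor(as.character(p), levels = c("0", "1")), positive = "1")
  }, 0)
  oracle_pi <- 1 - mean(oracle_f1s)

  pi_hat <- permutation_importance(m, x, y, "sig", n_perm = 4000, seed = 1,
                                   positive = "1")
  expect_equal(pi_hat, oracle_pi, tolerance = 0.02)

  # a feature the predictor ignores has exactly zero importance
  expect_equal(permutation_importance(m, x, y, "noise", n_perm = 50, seed = 1,
                                      positive = "1"), 0)
  # a constant column warns and returns zero
  x2 <- cbind(sig = c(0, 0, 1, 1), flat = rep(1, 4))
  expect_warning(
    pi0 <- permutation_importance(m, x2, y, "flat", n_perm = 10, seed = 1,
                                  positive = "1"),
    "constant"
  )
  expect_identical(pi0, 0)
})

test_that("pure-noise feature importance stays within its Monte-Carlo band", {
  withr::with_seed(19, {
    x <- matrix(rnorm(200 * 4), 200,
                dimnames = list(NULL, c("s", "n1", "n2", "n3")))
    y <- factor(if_else(x[, "s"] > 0, "TRUE", "FALSE"))
  })
  m <- train_model("boosted_trees", x, y, seed = 2, nrounds = 30)
  reps <- vapply(1:20, function(r) {
    permutation_importance(m, x, y, "n1", n_perm = 20, seed = r)
  }, 0)
  band <- 4 * sd(reps)
  pi_noise <- permutation_importance(m, x, y, "n1", n_perm = 100, seed = 99)
  expect_lt(abs(pi_noise), max(band, 0.03))
  # while the true signal stands far out of that band
  pi_sig <- permutation_importance(m, x, y, "s", n_perm = 100, seed = 99)
  expect_gt(pi_sig, max(band, 0.03))
})

test_that("stabilization averages absolute importance per configuration", {
  rec <- tibble::tibble(
    config_id = c("A", "A", "A", "B", "B", "C"),
    split = c(1L, 2L, 3L, 1L, 2L, 1L),
    feature = "f",
    pi = c(0.3, 0.1, 0.2, 0.1, -0.1, -0.2)
  )
  st <- stabilize_pi(rec)
  expect_equal(st$stab_pi[st$config_id == "A"], 0.2)
  expect_equal(st$stab_pi[st$config_id == "B"], 0.1)
  expect_equal(st$stab_pi[st$config_id == "C"], 0.2)
  expect_true(all(st$stab_pi >= 0))
})

test_that("model weights normalize to mean one and preserve order", {
  w <- model_weights(c(a = 0.5, b = 1.0))
  expect_equal(w$weight, c(2 / 3, 4 / 3))
  expect_equal(mean(w$weight), 1)
  w2 <- model_weights(c(a = 0.8, b = 0.8, c = 0.8))
  expect_equal(w2$weight, rep(1, 3))
  expect_error(model_weights(c(a = 0, b = 0)), "All-zero")

  # weighting monotonicity: raising one config's F1 raises its weight share
  w3 <- model_weights(c(a = 0.6, b = 0.9))
  w4 <- model_weights(c(a = 0.7, b = 0.9))
  expect_gt(w4$weight[1] / sum(w4$weight), w3$weight[1] / sum(w3$weight))
})

test_that("aggregation is the weighted mean over covering configs with deterministic ties", {
  st <- tibble::tibble(
    config_id = c("A", "A", "B", "B", "B"),
    feature = c("f1", "f2", "f1", "f2", "f3"),
    stab_pi = c(0.4, 0.2, 0.2, 0.2, 0.3),
    n_splits_used = 3L
  )
  w <- model_weights(c(A = 0.9, B = 0.6))
  fi <- aggregate_fi(st, w)
  wa <- 0.9 / 0.75
  wb <- 0.6 / 0.75
  expect_equal(fi$fi[fi$feature == "f1"], (wa * 0.4 + wb * 0.2) / (wa + wb))
  # f3 covered by B only: fi equals its own stabilized value
  expect_equal(fi$fi[fi$feature == "f3"], 0.3)
  expect_identical(fi$n_configs[fi$feature == "f3"], 1L)
  expect_equal(max(fi$fi_norm), 1)
  # single config: ranking equals that config's stabilized order
  fi_a <- aggregate_fi(st[st$config_id == "A", ], model_weights(c(A = 0.9)))
  expect_identical(fi_a$feature, c("f1", "f2"))
  # equal weights and PI vectors: ranking is the elementwise mean order
  st2 <- tibble::tibble(config_id = rep(c("A", "B"), each = 2),
                        feature = rep(c("u", "v"), 2),
                        stab_pi = c(0.1, 0.5, 0.3, 0.1), n_splits_used = 1L)
  fi2 <- aggregate_fi(st2, model_weights(c(A = 0.7, B = 0.7)))
  expect_identical(fi2$feature[1], "v") # (0.5+0.1)/2 > (0.1+0.3)/2
  # scale equivariance: multiplying all PI by c > 0 leaves ranks unchanged
  st3 <- st |> dplyr::mutate(stab_pi = stab_pi * 7)
  expect_identical(aggregate_fi(st3, w)$rank, fi$rank)
  # exact ties break lexicographically
  st4 <- tibble::tibble(config_id = "A", feature = c("zeta", "beta"),
                        stab_pi = c(0.2, 0.2), n_splits_used = 1L)
  expect_identical(aggregate_fi(st4, model_weights(c(A = 0.5)))$feature,
                   c("beta", "zeta"))
})

test_that("relevance filter drops only sub-eps features and reports the triangle", {
  rec <- tibble::tibble(
    config_id = rep(c("A", "B"), each = 3),
    split = 1L,
    feature = rep(c("live", "faint", "dead"), 2),
    pi = c(0.2, 1e-8, 0, 0.1, 2e-7, 0)
  )
  fd <- tibble::tibble(live = rnorm(20), faint = rnorm(20), dead = rnorm(20))
  filt <- correlation_filter(rec, fd, eps = 1e-6)
  expect_setequal(filt$retained, "live")
  expect_setequal(filt$dropped, c("faint", "dead"))
  # eps = 0 disables the filter
  filt0 <- correlation_filter(rec, fd, eps = 0)
  expect_setequal(filt0$retained, c("live", "faint", "dead"))
  expect_true(all(is.na(filt0$triangle[upper.tri(filt0$triangle)])))
  expect_equal(diag(filt0$triangle), rep(1, 3), ignore_attr = TRUE)
  expect_error(correlation_filter(rec, fd, eps = 10), "decrease")
})

test_that("top-fraction selection uses the ceiling rule", {
  rk <- tibble::tibble(feature = sprintf("f%03d", 1:40), fi = 40:1 / 40,
                       fi_norm = 40:1 / 40, rank = 1:40, n_configs = 1L)
  expect_length(select_top(rk, 0.10), 4)
  expect_length(select_top(rk, 1.0), 40)
  rk104 <- tibble::tibble(feature = sprintf("f%03d", 1:104), fi = 104:1,
                          fi_norm = 104:1 / 104, rank = 1:104, n_configs = 1L)
  expect_length(select_top(rk104, 0.10), 11) # ceil(10.4)
  expect_identical(select_top(rk, 0.05), c("f001", "f002"))
})

test_that("consensus intersects the two levels and orders by mean importance", {
  mk <- function(feats, fi, sel) {
    tibble::tibble(feature = feats, fi = fi, fi_norm = fi / max(fi),
                   rank = rank(-fi), selected = sel)
  }
  rl <- mk(c("a", "b", "c"), c(3, 2, 1), c(TRUE, TRUE, FALSE))
  rp <- mk(c("b", "a", "d"), c(5, 4, 1), c(TRUE, TRUE, TRUE))
  cons <- consensus_features(rl, rp)
  expect_setequal(cons$feature, c("a", "b"))
  expect_equal(cons$fi_mean,
               sort((c(a = 1, b = 2 / 3) + c(a = 4 / 5, b = 1)) / 2,
                    decreasing = TRUE), ignore_attr = TRUE)
  # identical selections come back unchanged; disjoint selections warn empty
  expect_setequal(consensus_features(rl, rl)$feature, c("a", "b"))
  rp2 <- mk(c("x", "y"), c(2, 1), c(TRUE, TRUE))
  expect_warning(cons2 <- consensus_features(rl, rp2), "empty")
  expect_identical(nrow(cons2), 0L)
})

test_that("end-to-end importance run recovers a strongly planted feature", {
  co <- small_cohort(seed = 55, n_patients = 120)
  grid <- bench_grid(learners = "boosted_trees", smote = FALSE,
                     targets = "pro_prrt_lesion",
                     subsets = list("Onco", variable_groups()))
  fi <- run_importance(co, "lesion", grid = grid, n_splits = 4, n_perm = 5,
                       seed = 8, model_args = list(nrounds = 30))
  expect_s3_class(fi$ranking, "tbl_df")
  expect_identical(sum(fi$ranking$selected),
                   as.integer(ceiling(0.1 * nrow(fi$ranking))))
  # the dominant planted effect (GEP origin) sits in the upper ranks
  expect_lte(fi$ranking$rank[fi$ranking$feature == "origin_gep"], 11L)
  # determinism
  fi2 <- run_importance(co, "lesion", grid = grid, n_splits = 4, n_perm = 5,
                        seed = 8, model_args = list(nrounds = 30))
  expect_equal(fi$ranking, fi2$ranking)
})
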
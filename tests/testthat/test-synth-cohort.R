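test_that("generation is deterministic per seed and distinct across seeds", {
  a <- small_cohort(seed = 9)
  b <- small_cohort(seed = 9)
  c <- small_cohort(seed = 10)
  expect_equal(as.data.frame(a$patients), as.data.frame(b$patients))
  expect_equal(as.data.frame(a$lesions), as.data.frame(b$lesions))
  expect_false(isTRUE(all.equal(as.data.frame(a$lesions),
                                as.data.frame(c$lesions))))
  # byte-identical files too
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_cohort(a, d1)
  write_cohort(b, d2)
  expect_identical(readBin(file.path(d1, "lesions.csv"), "raw", 1e6),
                   readBin(file.path(d2, "lesions.csv"), "raw", 1e6))
})

test_that("default configuration matches the emulated study structure", {
  cfg <- default_cohort_config()
  expect_identical(cfg$n_patients, 65L)
  co <- generate_cohort(cfg, seed = 2)
  reg <- co$registry
  expect_identical(sum(reg$level == "patient"), 100L)
  expect_identical(sum(reg$level == "lesion"), 4L)
  expect_setequal(unique(reg$group), variable_groups())
  expect_identical(unname(reg$missing_rate[reg$name == "ck7_positive"]), 0.49)
  expect_identical(unname(reg$missing_rate[reg$name == "ttf1_positive"]), 0.57)
  expect_identical(unname(reg$missing_rate[reg$name == "afp"]), 0.68)
  # planted truth is recorded for recovery scoring
  expect_setequal(names(co$truth$planted), reg$name[reg$planted])
})

test_that("expected lesion total is near the emulated cohort's 392", {
  totals <- vapply(1:30, function(s) {
    nrow(generate_cohort(seed = s, missingness = FALSE)$lesions)
  }, 0)
  expect_gt(mean(totals), 392 * 0.85)
  expect_lt(mean(totals), 392 * 1.15)
})

test_that("eligible class is a minority but not vanishing under defaults", {
  fr <- vapply(1:20, function(s) {
    mean(generate_cohort(seed = s, missingness = FALSE)$patients$eligible)
  }, 0)
  expect_gte(mean(fr), 0.2)
  expect_lte(mean(fr), 0.45)
})

test_that("planted effect signs surface in group mean uptake", {
  ok <- vapply(1:20, function(s) {
    co <- generate_cohort(cohort_config(n_patients = 300), seed = s,
                          missingness = FALSE)
    d <- dplyr::left_join(co$lesions, co$patients, by = "patient_id")
    m <- function(f) tapply(d$ratio_liver, d[[f]], mean)
    ck7 <- m("ck7_positive")
    gep <- m("origin_gep")
    lung <- m("origin_lung")
    trt <- m("prior_treatment")
    ck7[["0"]] > ck7[["1"]] && gep[["1"]] > gep[["0"]] &&
      lung[["0"]] > lung[["1"]] && trt[["0"]] > trt[["1"]]
  }, TRUE)
  expect_gte(mean(ok), 0.95)
})

test_that("lesions inherit patient covariates and correlate within patients", {
  co <- generate_cohort(cohort_config(n_patients = 200), seed = 4,
                        missingness = FALSE)
  d <- dplyr::left_join(co$lesions, co$patients, by = "patient_id")
  # intra-class structure: between-patient variance of log-uptake is visible
  fit <- stats::aov(log(ratio_liver) ~ patient_id, data = d)
  ms <- summary(fit)[[1]]$`Mean Sq`
  expect_gt(ms[1], ms[2]) # between >> within
})

test_that("missingness injection honors rates, never masks outcomes, and is seeded", {
  co <- generate_cohort(seed = 6, missingness = FALSE)
  expect_false(anyNA(co$patients$ck7_positive))

  same1 <- inject_missingness(co, seed = 5)
  same2 <- inject_missingness(co, seed = 5)
  expect_equal(as.data.frame(same1$patients), as.data.frame(same2$patients))

  none <- inject_missingness(co, rates = setNames(rep(0, nrow(co$registry)),
                                                  co$registry$name))
  expect_equal(as.data.frame(none$patients), as.data.frame(co$patients))

  all_gone <- inject_missingness(co, rates = c(ck7_positive = 1))
  expect_true(all(is.na(all_gone$patients$ck7_positive)))
  expect_false(anyNA(all_gone$lesions$ratio_liver))
  expect_false(anyNA(all_gone$patients$eligible))
  expect_error(inject_missingness(co, rates = c(ck7_positive = 1.2)), "\\[0, 1\\]")

  # observed masking fraction within binomial 99% bounds at rate 0.49
  big <- generate_cohort(cohort_config(n_patients = 2000), seed = 8,
                         missingness = FALSE)
  masked <- inject_missingness(big, seed = 3)
  n_miss <- sum(is.na(masked$patients$ck7_positive))
  bounds <- qbinom(c(0.005, 0.995), 2000, 0.49)
  expect_gte(n_miss, bounds[1])
  expect_lte(n_miss, bounds[2])
})

test_that("null configuration plants no association with eligibility", {
  co <- generate_cohort(cohort_config(effects = null_effects(),
                                      n_patients = 400), seed = 12,
                        missingness = FALSE)
  # formerly-planted features now independent of eligibility
  p_vals <- vapply(c("ck7_positive", "origin_gep", "prior_treatment"),
                   function(f) {
    tab <- table(co$patients[[f]], co$patients$eligible)
    suppressWarnings(chi_square_test(as.matrix(tab))$p_value)
  }, 0)
  expect_gt(min(p_vals), 0.001)
  expect_true(all(co$registry$effect == 0))
})
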
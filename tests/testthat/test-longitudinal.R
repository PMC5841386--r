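# Converter / decliner labeling rules and the mixed-effects models.

test_that("conversion labeling follows the one-year no-reversion rule", {
  mk <- function(times, dx) data.frame(subject_id = "s", visit_time = times,
                                       diagnosis = dx)
  expect_identical(label_conversion(mk(c(0, 1), c("aMCI", "AD")))$label,
                   "converter")
  expect_identical(label_conversion(mk(c(0, 1), c("aMCI", "aMCI")))$label,
                   "non_converter")
  # reversion within the window excludes conversion
  expect_identical(
    label_conversion(mk(c(0, 0.5, 1), c("aMCI", "AD", "aMCI")))$label,
    "non_converter")
  # diagnoses after the window do not matter
  expect_identical(
    label_conversion(mk(c(0, 1, 2), c("aMCI", "AD", "aMCI")))$label,
    "converter")
  expect_error(label_conversion(mk(c(0, 1), c("AD", "AD"))),
               class = "atroscore_cohort_error")
  expect_error(label_conversion(mk(0, "aMCI")),
               class = "atroscore_insufficient_data")
  # order independence
  expect_identical(
    label_conversion(mk(c(1, 0, 0.5), c("AD", "aMCI", "AD")))$label,
    "converter")
})

test_that("decline labeling uses a strict 5-point CDR-SB change", {
  mk <- function(times, cdr) data.frame(subject_id = "s", visit_time = times,
                                        cdr_sb = cdr)
  expect_identical(label_decline(mk(c(0, 3), c(2, 8)))$label,
                   "fast_decliner")   # delta 6 > 5
  expect_identical(label_decline(mk(c(0, 3), c(2, 7)))$label,
                   "slow_decliner")   # delta exactly 5 -> slow
  expect_identical(label_decline(mk(c(0, 3), c(4.5, 4)))$label,
                   "slow_decliner")   # improvement -> slow
  expect_error(label_decline(mk(c(0, 1), c(2, 4))),
               class = "atroscore_insufficient_data")
})

test_that("similarity-by-time interaction is recovered within 3 SE", {
  d <- simulate_visit_table(n_subjects = 80, visit_times = c(0, 1, 2),
                            beta = c(20, -0.05, -1, -0.10), seed = 42)
  fit <- fit_similarity_by_time(d, "outcome")
  it <- lmm_term(fit)
  expect_lt(abs(it$estimate - (-0.10)), 3 * it$se)
  expect_lt(it$p, 0.001)
  expect_identical(fit$n_subjects, 80L)
  expect_identical(fit$n_observations, 240L)
  expect_true(all(fit$coefficients$se > 0))
  expect_true(all(fit$coefficients$p > 0 & fit$coefficients$p <= 1))
})

test_that("mixed-model estimates agree with the profiled-REML oracle", {
  for (s in c(9, 19)) {
    d <- simulate_visit_table(n_subjects = 40, visit_times = c(0, 1, 2),
                              beta = c(20, -0.05, -1, -0.1), seed = s)
    d$outcome_value <- d$outcome
    oracle <- profile_reml_oracle(d, ~ similarity * visit_time)
    fit <- fit_similarity_by_time(d, "outcome")
    expect_equal(fit$coefficients$estimate, oracle$beta, tolerance = 1e-4)
    expect_equal(fit$random_intercept_var, oracle$var_u, tolerance = 1e-3)
    expect_equal(fit$residual_var, oracle$var_e, tolerance = 1e-3)
  }
})

test_that("a zero random-intercept variance is estimated at the boundary", {
  d <- simulate_visit_table(n_subjects = 60, visit_times = c(0, 1, 2),
                            beta = c(20, -0.05, -1, -0.1), re_sd = 0,
                            resid_sd = 1, seed = 8)
  fit <- fit_similarity_by_time(d, "outcome")
  expect_lt(fit$random_intercept_var, 0.1)
})

test_that("group-by-time interaction is recovered and null when absent", {
  grp <- rep(c(0, 1), each = 40)
  d <- simulate_visit_table(n_subjects = 80, visit_times = c(0, 1, 2),
                            predictor = grp, beta = c(10, 5, 1, 3),
                            re_sd = 3, resid_sd = 2, seed = 44)
  d$similarity <- d$outcome # outcome is the similarity score here
  labels <- data.frame(
    subject_id = unique(d$subject_id),
    label = ifelse(grp == 1, "converter", "non_converter"))
  fit <- fit_group_by_time(d, labels)
  it <- lmm_term(fit)
  expect_lt(abs(it$estimate - 3), 3 * it$se)

  d0 <- simulate_visit_table(n_subjects = 80, visit_times = c(0, 1, 2),
                             predictor = grp, beta = c(10, 0, 1, 0),
                             re_sd = 3, resid_sd = 2, seed = 45)
  d0$similarity <- d0$outcome
  fit0 <- fit_group_by_time(d0, labels)
  it0 <- lmm_term(fit0)
  expect_lt(abs(it0$estimate), 3 * it0$se)

  one_group <- labels
  one_group$label <- "converter"
  expect_error(fit_group_by_time(d, one_group),
               class = "atroscore_label_error")
})

test_that("pre-conditions on the visit design are enforced", {
  d <- simulate_visit_table(n_subjects = 20, visit_times = c(0, 1),
                            seed = 3)
  single <- d[d$visit_time == 0, ]
  expect_error(fit_similarity_by_time(single, "outcome"),
               class = "atroscore_insufficient_data")
  d$outcome <- 5
  expect_error(fit_similarity_by_time(d, "outcome"),
               class = "atroscore_degenerate_error")
  expect_error(fit_similarity_by_time(d, "nope"),
               class = "atroscore_argument_error")
})

test_that("Welch comparison separates offset groups and errors on tiny ones", {
  with_seed(46, {
    sim <- c(rnorm(20, 0, 1), rnorm(20, 5, 1)) # 5 SD offset
  })
  d <- data.frame(subject_id = sprintf("s%02d", 1:40), visit_time = 0,
                  similarity = sim)
  labels <- data.frame(subject_id = d$subject_id,
                       label = rep(c("non_converter", "converter"),
                                   each = 20))
  ht <- compare_groups_at_visit(d, labels)
  expect_lt(ht$p.value, 1e-6)
  expect_gt(ht$statistic, 0) # progressing group listed first
  expect_error(
    compare_groups_at_visit(d[c(1, 2, 21), ], labels[c(1, 2, 21), ]),
    class = "atroscore_insufficient_data")
})

test_that("null-distribution p-values are uniform for the Welch comparison", {
  ps <- vapply(1:200, function(s) {
    with_seed(700 + s, {
      d <- data.frame(subject_id = sprintf("s%02d", 1:30), visit_time = 0,
                      similarity = rnorm(30))
    })
    labels <- data.frame(subject_id = d$subject_id,
                         label = rep(c("non_converter", "converter"),
                                     each = 15))
    compare_groups_at_visit(d, labels)$p.value
  }, numeric(1))
  # rejection rate at alpha = 0.05 within the binomial 95% band
  band <- 0.05 + c(-1, 1) * 1.96 * sqrt(0.05 * 0.95 / 200)
  expect_gte(mean(ps < 0.05), max(0, band[1]))
  expect_lte(mean(ps < 0.05), band[2])
})
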
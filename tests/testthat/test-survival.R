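test_that("product-limit estimator matches hand computation with censoring", {
  rec <- tibble::tibble(time_days = c(5, 10, 15),
                        event = c(TRUE, FALSE, TRUE))
  cv <- km_fit(rec)$curves
  expect_equal(cv$survival[cv$time == 5], 2 / 3)
  expect_equal(cv$survival[cv$time == 15], 0)  # (1 - 1/3) * (1 - 1/1)
  expect_equal(cv$n_risk, c(3, 2, 1))

  all12 <- km_fit(tibble::tibble(time_days = rep(12, 5), event = TRUE))$curves
  expect_equal(all12$survival, 0)
  expect_equal(all12$n_event, 5)

  cens <- km_fit(tibble::tibble(time_days = rep(70, 6), event = FALSE))$curves
  expect_equal(cens$survival, 1)
})

test_that("KM equals the empirical survival function without censoring", {
  set.seed(8)
  times <- sample(1:40, 30, replace = TRUE)
  cv <- km_fit(tibble::tibble(time_days = times, event = TRUE))$curves
  expect_equal(cv$survival, empirical_survival(times, cv$time))
})

test_that("KM agrees with the survival package on censored multi-arm data", {
  skip_if_not_installed("survival")
  set.seed(3)
  rec <- tibble::tibble(
    arm = rep(c("A", "B"), each = 15),
    time_days = sample(1:30, 30, replace = TRUE),
    event = runif(30) < 0.7
  )
  mine <- km_fit(rec)$curves
  ref <- survival::survfit(survival::Surv(time_days, event) ~ arm, data = rec)
  ref_surv <- summary(ref, times = mine$time[mine$arm == "A"],
                      extend = TRUE)
  mine_a <- mine$survival[mine$arm == "A"]
  expect_equal(mine_a,
               ref_surv$surv[ref_surv$strata == "arm=A"], tolerance = 1e-12)
})

test_that("median survival uses the S <= 0.5 rule with a study-end sentinel", {
  all12 <- km_fit(tibble::tibble(arm = "A", time_days = rep(12, 8),
                                 event = TRUE))
  m <- median_survival(all12, study_end = 70)
  expect_equal(m$median_days, 12)
  expect_equal(m$median_label, "12")

  # 7 of 11 mice alive at day 70 -> median undetermined, reported as >70
  d <- km_fit(tibble::tibble(
    arm = "D", time_days = c(12, 15, 18, 21, rep(70, 7)),
    event = c(rep(TRUE, 4), rep(FALSE, 7))))
  md <- median_survival(d, study_end = 70)
  expect_true(is.na(md$median_days))
  expect_equal(md$median_label, ">70")

  # S hits exactly 0.5 -> that time is the median (boundary convention)
  half <- km_fit(tibble::tibble(arm = "A", time_days = c(3, 3, 9, 9),
                                event = TRUE))
  expect_equal(median_survival(half, 70)$median_days, 3)
})

test_that("adding censored records raises the curve pointwise and never lowers the median", {
  base <- tibble::tibble(arm = "A", time_days = c(4, 6, 8, 10, 12),
                         event = TRUE)
  extra <- dplyr::bind_rows(base,
    tibble::tibble(arm = "A", time_days = c(40, 50), event = FALSE))
  cb <- km_fit(base)$curves
  ce <- km_fit(extra)$curves
  shared <- dplyr::inner_join(cb, ce, by = "time", suffix = c("_b", "_e"))
  expect_equal(nrow(shared), nrow(cb))  # no new event steps
  expect_true(all(shared$survival_e >= shared$survival_b))
  expect_gte(median_survival(km_fit(extra), 70)$median_days,
             median_survival(km_fit(base), 70)$median_days)
})

test_that("log-rank statistic is zero for identical arms and symmetric in labels", {
  rec <- tibble::tibble(arm = rep(c("A", "B"), each = 4),
                        time_days = rep(c(3, 7, 11, 15), 2),
                        event = TRUE)
  lr <- logrank(rec)
  expect_equal(lr$chi_square, 0)
  expect_equal(lr$p_value, 1)

  set.seed(9)
  rec2 <- tibble::tibble(arm = rep(c("A", "B"), c(6, 7)),
                         time_days = sample(1:25, 13),
                         event = runif(13) < 0.8)
  expect_equal(logrank(rec2, "A", "B")$chi_square,
               logrank(rec2, "B", "A")$chi_square, tolerance = 1e-12)
})

test_that("log-rank chi-square matches survival::survdiff on random cohorts", {
  skip_if_not_installed("survival")
  set.seed(14)
  for (i in 1:20) {
    rec <- tibble::tibble(
      arm = rep(c("A", "B"), c(6, 6)),
      time_days = sample(1:30, 12, replace = TRUE),
      event = runif(12) < 0.8
    )
    if (sum(rec$event) == 0) next
    ref <- survival::survdiff(survival::Surv(time_days, event) ~ arm,
                              data = rec)
    expect_equal(logrank(rec)$chi_square, ref$chisq, tolerance = 1e-10)
  }
})

test_that("clearly separated arms are detected by both asymptotic and permutation routes", {
  rec <- tibble::tibble(arm = rep(c("A", "B"), each = 3),
                        time_days = c(2, 4, 6, 20, 22, 24),
                        event = TRUE)
  lr <- logrank(rec)
  expect_gt(lr$chi_square, 3.84)
  expect_lt(lr$p_value, 0.05)
  # with 3v3 mice the permutation null has only 20 label assignments, so its
  # smallest attainable two-sided tail probability is 2/20
  pm <- permutation_logrank(rec, n_perm = 2000, seed = 2)
  expect_lte(pm$p, 0.15)
})

test_that("asymptotic p agrees with the exact permutation null up to small-sample error", {
  rec <- survival_records(simulate_cohort(
    list(A = arm_params("A", n_mice = 6),
         C = arm_params("C", n_mice = 6, treatment_delay = 3.5,
                        initial_volume_mean = 98, initial_volume_sd = 75)),
    seed = 1))
  pm <- permutation_logrank(rec, n_perm = 4000, seed = 3)
  p_asym <- logrank(rec)$p_value
  # tolerance: 3x permutation MC error plus the O(1/n) error of the
  # chi-square reference at n = 12 (measured at the few-percent level)
  expect_lt(abs(pm$p - p_asym), 3 * pm$se + 0.06)
})

test_that("degenerate survival inputs are flagged", {
  none <- tibble::tibble(arm = rep(c("A", "B"), each = 3),
                         time_days = 70, event = FALSE)
  expect_warning(lr <- logrank(none), "No events")
  expect_true(is.na(lr$chi_square))
  expect_error(km_fit(tibble::tibble(time_days = numeric(), event = logical())),
               "non-empty")
  expect_error(km_fit(tibble::tibble(time_days = 0, event = TRUE)),
               "positive")

  one_sided <- tibble::tibble(arm = rep(c("A", "B"), each = 4),
                              time_days = c(5, 6, 7, 8, rep(70, 4)),
                              event = rep(c(TRUE, FALSE), each = 4))
  expect_gt(logrank(one_sided)$chi_square, 0)
})

test_that("pairwise comparisons cover every pair with optional Holm adjustment", {
  rec4 <- tibble::tibble(arm = rep(c("A", "B", "C", "D"), each = 4),
                         time_days = rep(c(5, 9, 13, 17), 4),
                         event = TRUE)
  pw <- pairwise_significance(rec4)
  expect_equal(nrow(pw), 6L)
  expect_false(any(pw$significant))

  rec2 <- tibble::tibble(arm = rep(c("A", "B"), each = 4),
                         time_days = c(2, 3, 4, 5, 30, 31, 32, 33),
                         event = TRUE)
  pw2 <- pairwise_significance(rec2)
  expect_equal(nrow(pw2), 1L)
  pw2h <- pairwise_significance(rec2, p_adjust = "holm")
  expect_gte(pw2h$p_adj, pw2$p_value)
  expect_error(pairwise_significance(dplyr::filter(rec2, arm == "A")),
               "two arms")
})

test_that("tidy and glance methods return tibbles with the fitted quantities", {
  rec <- tibble::tibble(arm = rep(c("A", "B"), each = 4),
                        time_days = c(2, 3, 4, 5, 30, 31, 32, 33),
                        event = TRUE)
  fit <- km_fit(rec)
  expect_s3_class(tidy(fit), "tbl_df")
  expect_named(glance(fit),
               c("arm", "n", "events", "median_days", "median_label"))
  lr <- logrank(rec)
  expect_equal(glance(lr)$chi_square, lr$chi_square)
  expect_equal(nrow(tidy(lr)), 2L)
  expect_s3_class(autoplot(fit), "ggplot")
})
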
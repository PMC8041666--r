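test_that("relative tumor volume normalises to baseline", {
  expect_equal(relative_tumor_volume(
    make_traj(c(0, 2, 4), c(150, 150, 150)))$rtv, c(1, 1, 1))
  expect_equal(relative_tumor_volume(
    make_traj(c(0, 4, 8), c(100, 200, 400)))$rtv, c(1, 2, 4))
  expect_equal(relative_tumor_volume(
    make_traj(c(0, 10, 20), c(80, 10, 0)))$rtv, c(1, 0.125, 0))
  expect_error(relative_tumor_volume(make_traj(c(0, 2), c(0, 10))),
               "Zero day-0")
})

test_that("TGI spans 0 (no inhibition) to 100 (complete inhibition)", {
  ctrl <- dplyr::bind_rows(
    make_traj(c(0, 8), c(100, 300), mouse_id = "c1"),
    make_traj(c(0, 8), c(100, 500), mouse_id = "c2"))
  # treated mice sitting exactly at the control mean RTV (4) -> TGI 0
  same <- dplyr::bind_rows(
    make_traj(c(0, 8), c(100, 400), mouse_id = "t1", arm = "B"),
    make_traj(c(0, 8), c(100, 400), mouse_id = "t2", arm = "B"))
  r <- tgi(dplyr::bind_rows(ctrl, same), eval_day = 8)
  expect_equal(r$tgi_mean, 0)
  expect_equal(r$tgi_sd, 0)

  cured <- dplyr::bind_rows(
    make_traj(c(0, 8), c(100, 0), mouse_id = "t1", arm = "B"),
    make_traj(c(0, 8), c(100, 0), mouse_id = "t2", arm = "B"))
  r2 <- tgi(dplyr::bind_rows(ctrl, cured), eval_day = 8)
  expect_equal(r2$tgi_mean, 100)
  expect_equal(r2$tgi_sd, 0)
})

test_that("per-mouse TGI allows negative values and reports mean +/- SD", {
  ctrl <- dplyr::bind_rows(
    make_traj(c(0, 8), c(100, 100), mouse_id = "c1"),
    make_traj(c(0, 8), c(100, 300), mouse_id = "c2"))  # mean control RTV 2
  trt <- dplyr::bind_rows(
    make_traj(c(0, 8), c(100, 100), mouse_id = "t1", arm = "B"),  # RTV 1 -> 50
    make_traj(c(0, 8), c(100, 300), mouse_id = "t2", arm = "B"))  # RTV 3 -> -50
  r <- tgi(dplyr::bind_rows(ctrl, trt), eval_day = 8)
  expect_equal(r$tgi_mean, 0)
  expect_equal(r$tgi_sd, sqrt(5000), tolerance = 1e-12)  # ~70.7
})

test_that("TGI is invariant to a common volume rescaling", {
  coh <- simulate_cohort(seed = 31)
  day <- eval_day_from_control(coh)
  base <- tgi(coh, day)
  scaled <- dplyr::mutate(coh, volume_mm3 = volume_mm3 * 3.7)
  expect_equal(tgi(scaled, day), base)
})

test_that("evaluation day is the first control endpoint with a study-end fallback", {
  ctrl <- dplyr::bind_rows(
    make_traj(0:12, c(rep(500, 8), rep(1100, 5)), mouse_id = "c1"),
    make_traj(0:12, seq(100, 700, by = 50), mouse_id = "c2"))
  expect_equal(eval_day_from_control(ctrl), 8)

  quiet <- make_traj(0:70, rep(200, 71), mouse_id = "c1")
  expect_warning(d <- eval_day_from_control(quiet), "study end")
  expect_equal(d, 70)

  two <- dplyr::bind_rows(
    make_traj(c(0, 10), c(100, 1200), mouse_id = "c1"),
    make_traj(c(0, 8), c(100, 1500), mouse_id = "c2"))
  expect_equal(eval_day_from_control(two), 8)
})

test_that("TGD crossing uses log-linear interpolation with exact hits honoured", {
  expect_equal(tgd(make_traj(c(0, 4), c(100, 200)), folds = 2)$tgd_days, 4)
  expect_equal(tgd(make_traj(c(0, 4), c(100, 400)), folds = 2)$tgd_days, 2)
  expect_equal(tgd(make_traj(c(0, 4), c(100, 400)), folds = 2,
                   interpolation = "linear")$tgd_days, 4 / 3)
  reg <- tgd(make_traj(c(0, 5, 10), c(100, 60, 20)), folds = 2)
  expect_false(reg$reached)
  expect_true(is.na(reg$tgd_days))
})

test_that("TGD is monotone in the fold across simulated trajectories", {
  coh <- simulate_cohort(seed = 17)
  wide <- tgd(coh) |>
    dplyr::filter(reached) |>
    tidyr::pivot_wider(id_cols = mouse_id, names_from = fold,
                       values_from = tgd_days, names_prefix = "f")
  ok25 <- with(wide, is.na(f2) | is.na(f5) | f2 <= f5)
  ok58 <- with(wide, is.na(f5) | is.na(f8) | f5 <= f8)
  expect_true(all(ok25, na.rm = TRUE))
  expect_true(all(ok58, na.rm = TRUE))
})

test_that("TGDI is the treated/control ratio with censored lower bounds flagged", {
  mk_arm <- function(arm, t2) {
    tibble::tibble(mouse_id = paste0(arm, 1:3), arm = arm, fold = 2,
                   tgd_days = t2, reached = !is.na(t2))
  }
  tbl <- dplyr::bind_rows(mk_arm("A", c(8, 8, 8)), mk_arm("B", c(16, 16, 16)))
  r <- tgdi(tbl, control_arm = "A", study_end = 70)
  expect_equal(r$tgdi[r$arm == "A"], 1)
  expect_equal(r$tgdi[r$arm == "B"], 2)
  expect_false(any(r$lower_bound))

  cens <- dplyr::bind_rows(mk_arm("A", c(8, 8, 8)),
                           mk_arm("D", c(NA, NA, NA)))
  r2 <- tgdi(cens, control_arm = "A", study_end = 70)
  expect_equal(r2$tgdi[r2$arm == "D"], 70 / 8)
  expect_true(r2$lower_bound[r2$arm == "D"])
  expect_equal(r2$n_not_reached[r2$arm == "D"], 3L)
})

test_that("endpoint criteria fire in the documented priority order", {
  # (i) volume alone
  v <- make_traj(0:12, c(rep(500, 12), 1100))
  ep <- endpoint_day(v)
  expect_equal(ep$endpoint_day, 12)
  expect_equal(ep$reason, "volume")

  # (ii) body-weight loss alone
  bw <- make_traj(0:9, rep(100, 10), bw = c(rep(22, 9), 22 * 0.84))
  ep2 <- endpoint_day(bw)
  expect_equal(ep2$endpoint_day, 9)
  expect_equal(ep2$reason, "body_weight")

  # (iii) combined moderate volume + moderate weight loss
  combo <- make_traj(0:9, c(rep(500, 9), 850),
                     bw = c(rep(22, 9), 22 * 0.89))
  ep3 <- endpoint_day(combo)
  expect_equal(ep3$endpoint_day, 9)
  expect_equal(ep3$reason, "combination")

  # (iv) ulceration flag
  ul <- make_traj(0:5, rep(300, 6), ulcer = c(rep(FALSE, 5), TRUE))
  ep4 <- endpoint_day(ul)
  expect_equal(ep4$endpoint_day, 5)
  expect_equal(ep4$reason, "ulceration")

  # (v) abnormal behavior flag
  bh <- make_traj(0:3, rep(300, 4), behavior = c(FALSE, FALSE, FALSE, TRUE))
  ep5 <- endpoint_day(bh)
  expect_equal(ep5$endpoint_day, 3)
  expect_equal(ep5$reason, "behavior")

  # volume outranks ulceration when both hold on the same day
  both <- make_traj(0:4, c(rep(200, 4), 1200),
                    ulcer = c(rep(FALSE, 4), TRUE))
  expect_equal(endpoint_day(both)$reason, "volume")

  # nothing fires -> survivor
  ok <- make_traj(0:70, rep(300, 71))
  ep6 <- endpoint_day(ok)
  expect_true(ep6$survived)
  expect_true(is.na(ep6$endpoint_day))
})

test_that("loosening thresholds never gives an earlier endpoint", {
  set.seed(42)
  for (s in 1:20) {
    coh <- simulate_cohort(list(A = arm_params("A", n_mice = 4)), seed = s)
    strict <- endpoint_day(coh, endpoint_rule())
    loose <- endpoint_day(coh, endpoint_rule(volume_limit = 1500,
                                             bw_loss_limit = 0.25,
                                             combo_volume = 1200,
                                             combo_bw_loss = 0.20))
    both <- dplyr::inner_join(strict, loose, by = "mouse_id",
                              suffix = c("_s", "_l"))
    ok <- with(both, is.na(endpoint_day_l) | endpoint_day_l >= endpoint_day_s)
    expect_true(all(ok, na.rm = TRUE))
  }
})

test_that("survival records classify endpoints as events and survivors as censored", {
  traj <- dplyr::bind_rows(
    make_traj(0:12, c(rep(500, 12), 1100), mouse_id = "m1"),
    make_traj(0:70, rep(300, 71), mouse_id = "m2"))
  rec <- survival_records(traj, study_end = 70)
  expect_equal(rec$time_days[rec$mouse_id == "m1"], 12)
  expect_true(rec$event[rec$mouse_id == "m1"])
  expect_equal(rec$time_days[rec$mouse_id == "m2"], 70)
  expect_false(rec$event[rec$mouse_id == "m2"])
})
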
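#' Humane endpoint rule
#'
#' Composite euthanasia criteria, checked in this fixed order:
#' (i) tumor volume >= `volume_limit`; (ii) body-weight loss >=
#' `bw_loss_limit` relative to day 0; (iii) tumor volume >= `combo_volume`
#' together with body-weight loss >= `combo_bw_loss`; (iv) tumor ulceration;
#' (v) abnormal behavior. Defaults follow the standard preclinical limits of
#' 1000 mm3, 15%, and 800 mm3 with 10%.
#'
#' @param volume_limit Tumor volume limit, mm3.
#' @param bw_loss_limit Fractional body-weight loss limit (0.15 = 15%).
#' @param combo_volume,combo_bw_loss Combined-criterion thresholds; must not
#'   exceed the single-criterion thresholds.
#' @param use_ulceration,use_behavior Whether the flag criteria apply.
#' @return An object of class `endpoint_rule`.
#' @export
endpoint_rule <- function(volume_limit = 1000, bw_loss_limit = 0.15,
                          combo_volume = 800, combo_bw_loss = 0.10,
                          use_ulceration = TRUE, use_behavior = TRUE) {
  if (any(c(volume_limit, bw_loss_limit, combo_volume, combo_bw_loss) <= 0)) {
    rlang::abort("All thresholds must be positive.")
  }
  if (combo_volume > volume_limit || combo_bw_loss > bw_loss_limit) {
    rlang::abort("Combined thresholds must not exceed the single-criterion ones.")
  }
  structure(as.list(environment()), class = "endpoint_rule")
}

validate_trajectories <- function(traj) {
  needed <- c("mouse_id", "day", "volume_mm3")
  missing <- setdiff(needed, names(traj))
  if (length(missing)) {
    rlang::abort(paste0("Trajectory table lacks column(s): ",
                        paste(missing, collapse = ", ")))
  }
  has_day0 <- traj |>
    dplyr::group_by(.data$mouse_id) |>
    dplyr::summarise(ok = any(.data$day == 0), .groups = "drop")
  if (!all(has_day0$ok)) {
    rlang::abort("Every mouse needs a day-0 measurement.")
  }
  invisible(traj)
}

#' Relative tumor volume
#'
#' Adds an `rtv` column, V(t) / V(0) per mouse; RTV at day 0 is 1 by
#' construction and a cured (disappeared) tumor has RTV 0.
#'
#' @param traj Trajectory tibble with `mouse_id`, `day`, `volume_mm3`.
#' @return The input with an `rtv` column.
#' @export
#' @examples
#' traj <- tibble::tibble(mouse_id = "m1", day = c(0, 4, 8),
#'                        volume_mm3 = c(100, 200, 400))
#' relative_tumor_volume(traj)
relative_tumor_volume <- function(traj) {
  validate_trajectories(traj)
  out <- traj |>
    dplyr::group_by(.data$mouse_id) |>
    dplyr::mutate(rtv = .data$volume_mm3 / .data$volume_mm3[.data$day == 0][1]) |>
    dplyr::ungroup()
  if (any(!is.finite(out$rtv))) {
    rlang::abort("Zero day-0 volume: RTV undefined for at least one mouse.")
  }
  out
}

# RTV at an arbitrary day, log-linearly interpolated between bracketing
# measurements (exponential growth between calipers); linear where a
# bracketing value is zero. Returns NA for mice off study before `at_day`.
rtv_at_day <- function(traj, at_day, interpolation = c("log-linear", "linear")) {
  interpolation <- match.arg(interpolation)
  relative_tumor_volume(traj) |>
    dplyr::group_by(.data$mouse_id) |>
    dplyr::summarise(
      arm = if ("arm" %in% names(traj)) .data$arm[1] else NA_character_,
      rtv = {
        d <- .data$day; r <- .data$rtv
        if (at_day %in% d) {
          r[d == at_day][1]
        } else if (at_day > max(d) || at_day < min(d)) {
          NA_real_
        } else {
          i <- max(which(d < at_day)); j <- min(which(d > at_day))
          w <- (at_day - d[i]) / (d[j] - d[i])
          if (interpolation == "log-linear" && r[i] > 0 && r[j] > 0) {
            exp((1 - w) * log(r[i]) + w * log(r[j]))
          } else {
            (1 - w) * r[i] + w * r[j]
          }
        }
      },
      .groups = "drop"
    )
}

#' Endpoint day and reason per mouse
#'
#' Applies an [endpoint_rule()] to each trajectory and returns the first day
#' on which any criterion holds, with the reason taken as the first
#' criterion, in the order (i) volume, (ii) body weight, (iii) combination,
#' (iv) ulceration, (v) behavior, that fires on that day. Mice with no
#' criterion met through their last measurement are reported as survivors
#' (`endpoint_day` NA).
#'
#' @param traj Trajectory tibble (`mouse_id`, `arm`, `day`, `volume_mm3`,
#'   `body_weight_g`, optional `ulcer_flag`, `behavior_flag`).
#' @param rule An [endpoint_rule()].
#' @return Tibble with `mouse_id`, `arm`, `endpoint_day`, `reason`,
#'   `survived`, `last_day`.
#' @export
endpoint_day <- function(traj, rule = endpoint_rule()) {
  stopifnot(inherits(rule, "endpoint_rule"))
  validate_trajectories(traj)
  if (!"ulcer_flag" %in% names(traj)) traj$ulcer_flag <- FALSE
  if (!"behavior_flag" %in% names(traj)) traj$behavior_flag <- FALSE
  if (!"body_weight_g" %in% names(traj)) traj$body_weight_g <- NA_real_
  if (!"arm" %in% names(traj)) traj$arm <- NA_character_

  traj |>
    dplyr::group_by(.data$mouse_id) |>
    dplyr::arrange(.data$day, .by_group = TRUE) |>
    dplyr::summarise(
      arm = .data$arm[1],
      last_day = max(.data$day),
      ep = {
        bw0 <- .data$body_weight_g[.data$day == 0][1]
        loss <- if (is.na(bw0)) rep(0, dplyr::n()) else
          pmax(0, (bw0 - .data$body_weight_g) / bw0)
        crit <- cbind(
          volume = .data$volume_mm3 >= rule$volume_limit,
          body_weight = loss >= rule$bw_loss_limit,
          combination = .data$volume_mm3 >= rule$combo_volume &
            loss >= rule$combo_bw_loss,
          ulceration = rule$use_ulceration & .data$ulcer_flag,
          behavior = rule$use_behavior & .data$behavior_flag
        )
        hit <- which(rowSums(crit, na.rm = TRUE) > 0)
        if (length(hit) == 0L) {
          list(day = NA_real_, reason = NA_character_)
        } else {
          i <- hit[1]
          list(day = .data$day[i],
               reason = colnames(crit)[which(crit[i, ])[1]])
        }
      } |> list(),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      endpoint_day = purrr::map_dbl(.data$ep, "day"),
      reason = purrr::map_chr(.data$ep, "reason"),
      survived = is.na(.data$endpoint_day)
    ) |>
    dplyr::select("mouse_id", "arm", "endpoint_day", "reason",
                  "survived", "last_day")
}

#' Evaluation day from the control arm
#'
#' The day the first control mouse reaches the humane endpoint — the
#' conventional day at which tumor growth inhibition is evaluated. Falls
#' back to the study end, with a warning, if no control mouse ever reaches
#' an endpoint.
#'
#' @param traj Trajectory tibble.
#' @param rule An [endpoint_rule()].
#' @param control_arm Label of the control arm (default `"A"`).
#' @param study_end Fallback day (default the cohort's last measured day).
#' @return A single day.
#' @export
eval_day_from_control <- function(traj, rule = endpoint_rule(),
                                  control_arm = "A", study_end = NULL) {
  ctrl <- dplyr::filter(traj, .data$arm == control_arm)
  if (nrow(ctrl) == 0L) rlang::abort("Control arm is empty.")
  if (is.null(study_end)) study_end <- max(traj$day)
  ep <- endpoint_day(ctrl, rule)
  if (all(ep$survived)) {
    rlang::warn("No control mouse reached an endpoint; using study end.")
    return(study_end)
  }
  min(ep$endpoint_day, na.rm = TRUE)
}

#' Tumor growth inhibition
#'
#' TGI for each treated mouse i is `100 - RTV_T[i] / mean(RTV_C) * 100`,
#' where `mean(RTV_C)` is the control arm's mean relative tumor volume at
#' the evaluation day; the arm summary is the mean +/- SD of the per-mouse
#' values. Negative per-mouse values (tumor growing faster than the average
#' control) are retained. Mice without a measurement at the evaluation day
#' (off study earlier) are dropped with a warning.
#'
#' @param traj Trajectory tibble with an `arm` column.
#' @param eval_day Evaluation day, typically [eval_day_from_control()].
#' @param control_arm Control arm label.
#' @param treated_arms Arms to evaluate (default: all non-control arms).
#' @return Tibble with `arm`, `eval_day`, `n`, `tgi_mean`, `tgi_sd`.
#' @export
tgi <- function(traj, eval_day, control_arm = "A", treated_arms = NULL) {
  if (!"arm" %in% names(traj)) rlang::abort("`traj` needs an `arm` column.")
  if (is.null(treated_arms)) {
    treated_arms <- setdiff(unique(traj$arm), control_arm)
  }
  rtv <- rtv_at_day(traj, eval_day)
  ctrl <- dplyr::filter(rtv, .data$arm == control_arm, !is.na(.data$rtv))
  if (nrow(ctrl) == 0L) rlang::abort("No control RTV available at `eval_day`.")
  mean_c <- mean(ctrl$rtv)
  if (mean_c == 0) rlang::abort("Mean control RTV is zero; TGI undefined.")
  treated <- dplyr::filter(rtv, .data$arm %in% treated_arms)
  if (any(is.na(treated$rtv))) {
    rlang::warn("Some treated mice were off study before `eval_day`; dropped.")
  }
  treated |>
    dplyr::filter(!is.na(.data$rtv)) |>
    dplyr::mutate(tgi = 100 - .data$rtv / mean_c * 100) |>
    dplyr::group_by(.data$arm) |>
    dplyr::summarise(
      eval_day = eval_day,
      n = dplyr::n(),
      tgi_mean = mean(.data$tgi),
      tgi_sd = ifelse(dplyr::n() > 1L, stats::sd(.data$tgi), 0),
      .groups = "drop"
    )
}

#' Tumor growth delay
#'
#' Time for each mouse's tumor to reach `fold` times its day-0 volume. The
#' crossing is interpolated between the bracketing measurement days,
#' log-linearly by default (exponential growth between calipers) or
#' linearly. A tumor that never attains the fold before the mouse leaves
#' the study is reported as not reached (`tgd_days` NA, `reached` FALSE) —
#' a value, not an error, since responders are expected never to double.
#'
#' @param traj Trajectory tibble.
#' @param folds Fold thresholds (default `c(2, 5, 8)`).
#' @param interpolation `"log-linear"` (default) or `"linear"`.
#' @return Tibble with `mouse_id`, `arm`, `fold`, `tgd_days`, `reached`.
#' @export
#' @examples
#' traj <- tibble::tibble(mouse_id = "m1", day = c(0, 4),
#'                        volume_mm3 = c(100, 400))
#' tgd(traj, folds = 2)  # one of two doublings in 4 days -> 2 d
tgd <- function(traj, folds = c(2, 5, 8),
                interpolation = c("log-linear", "linear")) {
  interpolation <- match.arg(interpolation)
  rtv <- relative_tumor_volume(traj)
  if (!"arm" %in% names(rtv)) rtv$arm <- NA_character_
  cross_one <- function(d, r, x) {
    idx <- which(r >= x)
    if (length(idx) == 0L) return(NA_real_)
    j <- idx[1]
    if (r[j] == x || j == 1L) return(d[j])
    i <- j - 1L
    if (interpolation == "log-linear" && r[i] > 0) {
      d[i] + (d[j] - d[i]) * (log(x) - log(r[i])) / (log(r[j]) - log(r[i]))
    } else {
      d[i] + (d[j] - d[i]) * (x - r[i]) / (r[j] - r[i])
    }
  }
  nested <- rtv |>
    dplyr::select("mouse_id", "arm", "day", "rtv") |>
    dplyr::arrange(.data$mouse_id, .data$day) |>
    tidyr::nest(data = c("day", "rtv"))
  tidyr::expand_grid(nested, fold = folds) |>
    dplyr::mutate(
      tgd_days = purrr::map2_dbl(.data$data, .data$fold,
                                 ~ cross_one(.x$day, .x$rtv, .y)),
      reached = !is.na(.data$tgd_days)
    ) |>
    dplyr::select("mouse_id", "arm", "fold", "tgd_days", "reached")
}

#' Tumor growth delay index
#'
#' Arm-level TGD (median across mice by default; mice that never reached the
#' fold are assigned the study-end day as a censored lower bound rather than
#' dropped, since dropping responders would bias the index downward) and its
#' ratio over the control arm, `TGDI_x = TGD_x(T) / TGD_x(C)`. Arms whose
#' aggregate rests on censored values are flagged as lower bounds.
#'
#' @param tgd_tbl Output of [tgd()] with an `arm` column.
#' @param control_arm Control arm label.
#' @param study_end Study-end day assigned to not-reached mice.
#' @param aggregate `"median"` (default) or `"mean"`.
#' @return Tibble with `arm`, `fold`, `n`, `n_not_reached`, `tgd_arm_days`,
#'   `tgdi`, `lower_bound`.
#' @export
tgdi <- function(tgd_tbl, control_arm = "A", study_end = 70,
                 aggregate = c("median", "mean")) {
  aggregate <- match.arg(aggregate)
  agg <- if (aggregate == "median") stats::median else mean
  arm_level <- tgd_tbl |>
    dplyr::mutate(tgd_filled = ifelse(.data$reached, .data$tgd_days, study_end)) |>
    dplyr::group_by(.data$arm, .data$fold) |>
    dplyr::summarise(
      n = dplyr::n(),
      n_not_reached = sum(!.data$reached),
      tgd_arm_days = agg(.data$tgd_filled),
      .groups = "drop"
    ) |>
    # the aggregate is a lower bound when censored study-end values carry it:
    # always for the mean, for the median only when it sits on them
    dplyr::mutate(lower_bound = .data$n_not_reached > 0 &
                    (aggregate == "mean" | .data$tgd_arm_days >= study_end))
  ctrl <- arm_level |>
    dplyr::filter(.data$arm == control_arm) |>
    dplyr::select("fold", control_tgd = "tgd_arm_days")
  if (nrow(ctrl) == 0L) rlang::abort("Control arm missing from `tgd_tbl`.")
  if (any(ctrl$control_tgd <= 0)) rlang::abort("Control TGD must be positive.")
  arm_level |>
    dplyr::left_join(ctrl, by = "fold") |>
    dplyr::mutate(tgdi = .data$tgd_arm_days / .data$control_tgd) |>
    dplyr::select("arm", "fold", "n", "n_not_reached", "tgd_arm_days",
                  "tgdi", "lower_bound")
}

#' Survival records from trajectories
#'
#' Converts per-mouse trajectories into right-censored survival records:
#' mice reaching any endpoint are events at their endpoint day; mice alive
#' at the study end are censored there.
#'
#' @param traj Trajectory tibble.
#' @param rule An [endpoint_rule()].
#' @param study_end Censoring day (default the cohort's last measured day).
#' @return Tibble with `mouse_id`, `arm`, `time_days`, `event`.
#' @export
survival_records <- function(traj, rule = endpoint_rule(), study_end = NULL) {
  if (is.null(study_end)) {
    study_end <- attr(traj, "study_end") %||% max(traj$day)
  }
  endpoint_day(traj, rule) |>
    dplyr::mutate(
      time_days = ifelse(.data$survived, study_end, .data$endpoint_day),
      event = !.data$survived
    ) |>
    dplyr::select("mouse_id", "arm", "time_days", "event")
}

#' Plot relative tumor volume trajectories
#'
#' @param traj Trajectory tibble.
#' @return A ggplot object, one panel per arm.
#' @export
plot_rtv <- function(traj) {
  rtv <- relative_tumor_volume(traj)
  ggplot2::ggplot(rtv, ggplot2::aes(x = .data$day, y = .data$rtv,
                                    group = .data$mouse_id)) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::facet_wrap(~arm) +
    ggplot2::labs(x = "Day", y = "Relative tumor volume") +
    ggplot2::theme_minimal()
}
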
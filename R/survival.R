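#' Kaplan-Meier product-limit fit
#'
#' Computes the product-limit estimator S(t) = prod_{t_i <= t} (1 - d_i/n_i)
#' for each arm, with tied events aggregated at their shared time and
#' censored observations reducing the risk set without a step. Written from
#' first principles so the estimator, its median rule and the companion
#' log-rank test share one set of conventions.
#'
#' @param records Tibble with `time_days` (> 0), `event` (logical; `FALSE` =
#'   right-censored) and optionally `arm` (absent = one pooled arm) and
#'   `mouse_id`.
#' @return An object of class `km_fit`: list with `curves` (tibble `arm`,
#'   `time`, `n_risk`, `n_event`, `n_censor`, `survival`) and `records`.
#' @export
#' @examples
#' rec <- tibble::tibble(time_days = c(5, 10, 15),
#'                       event = c(TRUE, FALSE, TRUE))
#' km_fit(rec)$curves
km_fit <- function(records) {
  if (nrow(records) == 0L) rlang::abort("`records` must be non-empty.")
  if (!all(c("time_days", "event") %in% names(records))) {
    rlang::abort("`records` needs columns `time_days` and `event`.")
  }
  if (any(records$time_days <= 0)) rlang::abort("Survival times must be positive.")
  if (!"arm" %in% names(records)) records$arm <- "all"

  one_arm <- function(rec) {
    tab <- rec |>
      dplyr::group_by(time = .data$time_days) |>
      dplyr::summarise(n_event = sum(.data$event),
                       n_censor = sum(!.data$event), .groups = "drop") |>
      dplyr::arrange(.data$time)
    n <- nrow(rec)
    tab$n_risk <- n - dplyr::lag(cumsum(tab$n_event + tab$n_censor),
                                 default = 0)
    tab$survival <- cumprod(1 - tab$n_event / tab$n_risk)
    tab[c("time", "n_risk", "n_event", "n_censor", "survival")]
  }

  curves <- records |>
    dplyr::group_by(.data$arm) |>
    dplyr::group_modify(~ one_arm(.x)) |>
    dplyr::ungroup()
  structure(list(curves = curves, records = tibble::as_tibble(records)),
            class = "km_fit")
}

#' @export
print.km_fit <- function(x, ...) {
  cat("<km_fit> ", dplyr::n_distinct(x$curves$arm), " arm(s), ",
      nrow(x$records), " animals, ", sum(x$records$event), " events\n",
      sep = "")
  print(median_survival(x))
  invisible(x)
}

#' Median survival with study-end censoring semantics
#'
#' The median is the smallest observed time with S(t) <= 0.5. When the curve
#' never drops to 0.5 or below — e.g. when more than half of an arm is still
#' alive at the study end — the median is undetermined and reported as
#' greater than the study end (`median_days` NA, `median_label` `">end"`).
#'
#' @param fit A [km_fit()].
#' @param study_end Study-end day for the sentinel label; defaults to the
#'   largest observed time.
#' @return Tibble with `arm`, `n`, `events`, `median_days`, `median_label`.
#' @export
median_survival <- function(fit, study_end = NULL) {
  stopifnot(inherits(fit, "km_fit"))
  if (is.null(study_end)) study_end <- max(fit$records$time_days)
  counts <- fit$records |>
    dplyr::group_by(.data$arm) |>
    dplyr::summarise(n = dplyr::n(), events = sum(.data$event),
                     .groups = "drop")
  med <- fit$curves |>
    dplyr::group_by(.data$arm) |>
    dplyr::summarise(
      median_days = {
        hit <- .data$time[.data$survival <= 0.5]
        if (length(hit)) min(hit) else NA_real_
      },
      .groups = "drop"
    ) |>
    dplyr::mutate(median_label = ifelse(is.na(.data$median_days),
                                        paste0(">", format(study_end)),
                                        format(.data$median_days)))
  dplyr::left_join(counts, med, by = "arm")
}

#' Two-group log-rank (Mantel-Cox) test
#'
#' At each pooled event time the observed number of events in the first arm
#' is compared with its hypergeometric expectation given the risk sets;
#' chi-square = (sum O - sum E)^2 / sum Var on 1 degree of freedom. Tied
#' events use the aggregate-d hypergeometric variance.
#'
#' @param records Survival tibble with `arm`, `time_days`, `event`.
#' @param arm_a,arm_b Arm labels to compare; default the two arms present.
#' @return An object of class `logrank_test`: list with `arms`, `n`,
#'   `observed`, `expected`, `chi_square`, `df`, `p_value`.
#' @export
#' @examples
#' rec <- tibble::tibble(arm = rep(c("A", "B"), each = 3),
#'                       time_days = c(2, 4, 6, 20, 22, 24),
#'                       event = TRUE)
#' logrank(rec)
logrank <- function(records, arm_a = NULL, arm_b = NULL) {
  if (!all(c("arm", "time_days", "event") %in% names(records))) {
    rlang::abort("`records` needs columns `arm`, `time_days`, `event`.")
  }
  arms <- sort(unique(records$arm))
  if (is.null(arm_a) || is.null(arm_b)) {
    if (length(arms) != 2L) {
      rlang::abort("Specify `arm_a` and `arm_b` when more than two arms are present.")
    }
    arm_a <- arms[1]; arm_b <- arms[2]
  }
  rec <- dplyr::filter(records, .data$arm %in% c(arm_a, arm_b))
  if (!any(rec$arm == arm_a) || !any(rec$arm == arm_b)) {
    rlang::abort("Both arms must be non-empty.")
  }
  if (sum(rec$event) == 0L) {
    rlang::warn("No events in either arm; log-rank statistic undefined.")
    out <- list(arms = c(arm_a, arm_b), n = nrow(rec),
                observed = c(0, 0), expected = c(NA_real_, NA_real_),
                chi_square = NA_real_, df = 1L, p_value = NA_real_)
    return(structure(out, class = "logrank_test"))
  }
  event_times <- sort(unique(rec$time_days[rec$event]))
  o_minus_e <- 0; varsum <- 0; obs_a <- 0; exp_a <- 0
  for (t in event_times) {
    at_risk <- rec$time_days >= t
    n1 <- sum(at_risk & rec$arm == arm_a)
    n2 <- sum(at_risk & rec$arm == arm_b)
    nj <- n1 + n2
    d1 <- sum(rec$arm == arm_a & rec$event & rec$time_days == t)
    dj <- sum(rec$event & rec$time_days == t)
    e1 <- dj * n1 / nj
    obs_a <- obs_a + d1
    exp_a <- exp_a + e1
    o_minus_e <- o_minus_e + (d1 - e1)
    if (nj > 1) {
      varsum <- varsum + dj * (n1 / nj) * (n2 / nj) * (nj - dj) / (nj - 1)
    }
  }
  chi <- if (varsum > 0) o_minus_e^2 / varsum else 0
  total_events <- sum(rec$event)
  structure(
    list(arms = c(arm_a, arm_b), n = nrow(rec),
         observed = c(obs_a, total_events - obs_a),
         expected = c(exp_a, total_events - exp_a),
         chi_square = chi, df = 1L,
         p_value = stats::pchisq(chi, df = 1, lower.tail = FALSE)),
    class = "logrank_test"
  )
}

#' @export
print.logrank_test <- function(x, ...) {
  cat("Log-rank (Mantel-Cox) test: ", x$arms[1], " vs ", x$arms[2], "\n",
      sep = "")
  cat("  chi-square = ", format(x$chi_square, digits = 4),
      " (df = 1), p = ", format(x$p_value, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Pairwise log-rank comparisons
#'
#' Applies [logrank()] to every pair of arms. No multiplicity adjustment is
#' made by default (matching the conventional unadjusted pairwise reporting
#' of preclinical survival tables); Holm adjustment is available.
#'
#' @param records Survival tibble with >= 2 arms.
#' @param alpha Significance level (default 0.05).
#' @param p_adjust `"none"` (default) or `"holm"`.
#' @return Tibble with `arm_a`, `arm_b`, `chi_square`, `p_value`, `p_adj`,
#'   `significant`.
#' @export
pairwise_significance <- function(records, alpha = 0.05,
                                  p_adjust = c("none", "holm")) {
  p_adjust <- match.arg(p_adjust)
  arms <- sort(unique(records$arm))
  if (length(arms) < 2L) rlang::abort("Need at least two arms.")
  pairs <- utils::combn(arms, 2, simplify = FALSE)
  out <- purrr::map(pairs, function(p) {
    lr <- logrank(records, p[1], p[2])
    tibble::tibble(arm_a = p[1], arm_b = p[2],
                   chi_square = lr$chi_square, p_value = lr$p_value)
  }) |>
    purrr::list_rbind()
  out$p_adj <- stats::p.adjust(out$p_value, method = p_adjust)
  out$significant <- !is.na(out$p_adj) & out$p_adj < alpha
  out
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.km_fit <- function(x, ...) x$curves

#' @export
glance.km_fit <- function(x, ...) median_survival(x)

#' @export
tidy.logrank_test <- function(x, ...) {
  tibble::tibble(arm = x$arms, observed = x$observed, expected = x$expected)
}

#' @export
glance.logrank_test <- function(x, ...) {
  tibble::tibble(chi_square = x$chi_square, df = x$df, p_value = x$p_value,
                 n = x$n)
}

#' Kaplan-Meier step plot
#'
#' @param object A [km_fit()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.km_fit <- function(object, ...) {
  start <- object$curves |>
    dplyr::distinct(.data$arm) |>
    dplyr::mutate(time = 0, survival = 1)
  dat <- dplyr::bind_rows(
    start,
    dplyr::select(object$curves, "arm", "time", "survival")
  )
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$time, y = .data$survival,
                                    colour = .data$arm)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Day", y = "Survival fraction", colour = "Arm") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
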
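#' Read / write tidy biodistribution tables
#'
#' The tidy biodistribution format has one row per mouse x organ x time point
#' measurement: `mouse_id`, `organ`, `time_h`, `pct_ia_per_g` (percent of the
#' injected activity per gram of tissue), `decay_corrected` (logical) and
#' `blocked` (logical; `TRUE` for animals pre-injected with excess folic acid
#' to saturate folate receptors).
#'
#' @param path File path of a CSV in the tidy biodistribution layout.
#' @return A tibble of biodistribution records.
#' @export
read_biodistribution <- function(path) {
  out <- readr::read_csv(
    path,
    col_types = readr::cols(
      mouse_id = readr::col_character(),
      organ = readr::col_character(),
      time_h = readr::col_double(),
      pct_ia_per_g = readr::col_double(),
      decay_corrected = readr::col_logical(),
      blocked = readr::col_logical()
    )
  )
  validate_biodistribution(out)
  out
}

#' @rdname read_biodistribution
#' @param records A tibble of biodistribution records.
#' @export
write_biodistribution <- function(records, path) {
  validate_biodistribution(records)
  readr::write_csv(records, path)
  invisible(path)
}

validate_biodistribution <- function(records) {
  needed <- c("mouse_id", "organ", "time_h", "pct_ia_per_g",
              "decay_corrected", "blocked")
  missing <- setdiff(needed, names(records))
  if (length(missing)) {
    rlang::abort(paste0("Biodistribution table lacks column(s): ",
                        paste(missing, collapse = ", ")))
  }
  if (any(records$time_h < 0)) rlang::abort("`time_h` must be non-negative.")
  if (any(records$pct_ia_per_g < 0)) {
    rlang::abort("`pct_ia_per_g` must be non-negative.")
  }
  invisible(records)
}

#' Convert between decay-corrected and non-decay-corrected activity
#'
#' Decay-corrected biodistribution values report the biological distribution
#' as if the nuclide did not decay; dosimetry integrates the physically
#' decaying (non-decay-corrected) concentration. `to_non_decay_corrected()`
#' multiplies each decay-corrected value by the physical decay factor at its
#' sampling time and flips the flag; `to_decay_corrected()` is its inverse.
#' The two operations round-trip to machine precision.
#'
#' @param records Biodistribution tibble whose `decay_corrected` flags are all
#'   `TRUE` (for `to_non_decay_corrected`) or all `FALSE` (for the inverse);
#'   mixed flags are an error because silent partial conversion corrupts
#'   downstream integrals.
#' @param nuclide A [nuclide_spec()].
#' @return The converted tibble with flags flipped.
#' @export
#' @examples
#' rec <- tibble::tibble(mouse_id = "m1", organ = "tumor", time_h = 24,
#'                       pct_ia_per_g = 12, decay_corrected = TRUE,
#'                       blocked = FALSE)
#' to_non_decay_corrected(rec, lu177(with_spectrum = FALSE))
to_non_decay_corrected <- function(records, nuclide) {
  validate_biodistribution(records)
  if (!all(records$decay_corrected)) {
    rlang::abort("All records must be decay-corrected (mixed or flipped flags).")
  }
  dplyr::mutate(records,
    pct_ia_per_g = .data$pct_ia_per_g * decay_factor(nuclide, .data$time_h),
    decay_corrected = FALSE
  )
}

#' @rdname to_non_decay_corrected
#' @export
to_decay_corrected <- function(records, nuclide) {
  validate_biodistribution(records)
  if (any(records$decay_corrected)) {
    rlang::abort("All records must be non-decay-corrected (mixed or flipped flags).")
  }
  dplyr::mutate(records,
    pct_ia_per_g = .data$pct_ia_per_g / decay_factor(nuclide, .data$time_h),
    decay_corrected = TRUE
  )
}

#' Summarize biodistribution records by organ and time point
#'
#' Sample mean, sample standard deviation (n - 1 denominator; reported as 0
#' for a single animal) and animal count per organ x time cell, the standard
#' "average +/- SD (n = 3-4)" presentation of biodistribution studies.
#'
#' @param records Biodistribution tibble.
#' @param ... Additional grouping columns (e.g. `blocked`) passed to
#'   [dplyr::group_by()].
#' @return A tibble with columns `organ`, `time_h`, any extra groups,
#'   `mean_pct_ia_per_g`, `sd_pct_ia_per_g`, `n`.
#' @export
summarize_biodistribution <- function(records, ...) {
  validate_biodistribution(records)
  records |>
    dplyr::group_by(.data$organ, .data$time_h, ...) |>
    dplyr::summarise(
      mean_pct_ia_per_g = mean(.data$pct_ia_per_g),
      sd_pct_ia_per_g = ifelse(dplyr::n() > 1L, stats::sd(.data$pct_ia_per_g), 0),
      n = dplyr::n(),
      .groups = "drop"
    )
}

#' Receptor-blocking fraction
#'
#' Ratio of the mean uptake in the blocked arm (excess folic acid
#' pre-injection) to the mean uptake in the unblocked arm for one organ at
#' one time point. A value of 0.35 means blocking reduced uptake to 35% of
#' the unblocked accumulation, i.e. 65% of uptake was receptor-specific.
#'
#' @param blocked_summary,unblocked_summary Summaries from
#'   [summarize_biodistribution()] containing the requested cell.
#' @param organ Organ label.
#' @param time_h Time point in hours.
#' @return A single fraction.
#' @export
blocking_fraction <- function(blocked_summary, unblocked_summary, organ, time_h) {
  pick <- function(s, what) {
    row <- dplyr::filter(s, .data$organ == !!organ, .data$time_h == !!time_h)
    if (nrow(row) != 1L) {
      rlang::abort(paste0("No unique (", organ, ", ", time_h, " h) cell in the ",
                          what, " summary."))
    }
    row$mean_pct_ia_per_g
  }
  blocked <- pick(blocked_summary, "blocked")
  unblocked <- pick(unblocked_summary, "unblocked")
  if (unblocked == 0) rlang::abort("Unblocked mean is zero; fraction undefined.")
  blocked / unblocked
}

#' Plot a biodistribution time course
#'
#' Mean +/- SD uptake over time per organ, on the familiar %IA/g scale.
#'
#' @param summary A tibble from [summarize_biodistribution()].
#' @return A ggplot object.
#' @export
plot_biodistribution <- function(summary) {
  ggplot2::ggplot(summary,
    ggplot2::aes(x = .data$time_h, y = .data$mean_pct_ia_per_g,
                 colour = .data$organ)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = pmax(.data$mean_pct_ia_per_g - .data$sd_pct_ia_per_g, 0),
      ymax = .data$mean_pct_ia_per_g + .data$sd_pct_ia_per_g)) +
    ggplot2::labs(x = "Time post injection (h)", y = "Uptake (%IA/g)",
                  colour = "Organ") +
    ggplot2::theme_minimal()
}
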
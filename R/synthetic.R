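#' Synthetic biodistribution parameters
#'
#' Describes per-organ uptake/clearance kinetics for the synthetic
#' biodistribution generator. The decay-corrected concentration template is
#'
#'   a(t) = A * (1 - exp(-k_up * t)) * exp(-k_bio * t)
#'
#' with amplitude `A` in fraction of injected activity per gram, uptake rate
#' `k_up` (1/h) and biological clearance rate `k_bio` (1/h). In the blocked
#' arm (excess folic acid pre-injection) the template is multiplied by the
#' organ's `blocking_factor`.
#'
#' @param organs Tibble with columns `organ`, `amplitude` (fraction IA/g,
#'   > 0), `uptake_rate` (1/h, >= 0), `clearance_rate` (1/h, >= 0) and
#'   `blocking_factor` (in (0, 1]).
#' @param time_points Sacrifice time points in hours post injection,
#'   strictly increasing and non-negative.
#' @param n_per_timepoint Animals per time point group (each group is
#'   sacrificed, so groups are independent).
#' @param noise_cv Coefficient of variation of multiplicative lognormal
#'   measurement noise (>= 0); 0 gives noise-free templates.
#' @param blocked_time_points Time points at which a blocked group is also
#'   simulated (the blocking comparison is classically done at 4 h).
#' @return An object of class `biodist_params`.
#' @export
biodist_params <- function(organs,
                           time_points = c(1, 4, 24, 48, 120),
                           n_per_timepoint = 4,
                           noise_cv = 0.10,
                           blocked_time_points = 4) {
  needed <- c("organ", "amplitude", "uptake_rate", "clearance_rate",
              "blocking_factor")
  if (!all(needed %in% names(organs))) {
    rlang::abort(paste0("`organs` needs columns: ", paste(needed, collapse = ", ")))
  }
  if (nrow(organs) == 0L) rlang::abort("`organs` must contain at least one organ.")
  if (any(organs$amplitude <= 0)) rlang::abort("Amplitudes must be positive.")
  if (any(organs$uptake_rate < 0) || any(organs$clearance_rate < 0)) {
    rlang::abort("Kinetic rates must be non-negative.")
  }
  if (any(organs$blocking_factor <= 0) || any(organs$blocking_factor > 1)) {
    rlang::abort("`blocking_factor` must be in (0, 1].")
  }
  if (any(time_points < 0) || is.unsorted(time_points, strictly = TRUE)) {
    rlang::abort("`time_points` must be non-negative and strictly increasing.")
  }
  if (noise_cv < 0) rlang::abort("`noise_cv` must be >= 0.")
  if (n_per_timepoint < 1) rlang::abort("`n_per_timepoint` must be >= 1.")
  structure(
    list(organs = tibble::as_tibble(organs),
         time_points = time_points,
         n_per_timepoint = n_per_timepoint,
         noise_cv = noise_cv,
         blocked_time_points = blocked_time_points),
    class = "biodist_params"
  )
}

#' Default synthetic biodistribution parameters
#'
#' Kinetic templates for a folate-radioconjugate biodistribution in a
#' folate-receptor-positive tumor model. Amplitudes are calibrated in closed
#' form so that, decay-corrected, the kidney template reads exactly
#' 18 %IA/g at 4 h and the tumor template peaks at exactly 12 %IA/g (peak
#' between 4 and 24 h); blocking factors are 0.50 (tumor) and 0.35 (kidneys)
#' for receptor-specific uptake, 1 for non-specific organs.
#'
#' @inheritParams biodist_params
#' @return A `biodist_params` object.
#' @export
default_biodist_params <- function(noise_cv = 0.10) {
  # amplitude such that the template attains `value` at time t_ref
  amp_at <- function(value, t_ref, k_up, k_bio) {
    value / ((1 - exp(-k_up * t_ref)) * exp(-k_bio * t_ref))
  }
  # time of the template maximum (d/dt = 0)
  t_peak <- function(k_up, k_bio) log((k_up + k_bio) / k_bio) / k_up
  tum_kup <- 0.5; tum_kbio <- 0.003
  tum_peak <- t_peak(tum_kup, tum_kbio)
  organs <- tibble::tibble(
    organ = c("tumor", "kidneys", "blood", "liver"),
    amplitude = c(
      amp_at(0.12, tum_peak, tum_kup, tum_kbio),
      amp_at(0.18, 4, 2.0, 0.004),
      0.05,
      0.015
    ),
    uptake_rate = c(tum_kup, 2.0, 20, 1.5),
    clearance_rate = c(tum_kbio, 0.004, 0.08, 0.002),
    blocking_factor = c(0.50, 0.35, 1, 1)
  )
  biodist_params(organs, noise_cv = noise_cv)
}

#' Evaluate a kinetic uptake/clearance template
#'
#' @param time_h Hours post injection.
#' @param amplitude Fraction IA/g.
#' @param uptake_rate,clearance_rate Rates in 1/h.
#' @return Decay-corrected concentration in fraction IA/g.
#' @export
kinetic_template <- function(time_h, amplitude, uptake_rate, clearance_rate) {
  amplitude * (1 - exp(-uptake_rate * time_h)) * exp(-clearance_rate * time_h)
}

#' Simulate a biodistribution study
#'
#' Generates one mouse x organ x time point record per replicate, in both
#' decay-corrected and non-decay-corrected form (two rows per measurement,
#' distinguished by the `decay_corrected` flag; the non-corrected value is
#' the corrected one times the physical decay factor). An additional blocked
#' group is simulated at `blocked_time_points` with each organ's template
#' scaled by its blocking factor. Measurement noise is multiplicative
#' lognormal with the configured CV and unit mean, shared between the two
#' correction states of the same physical measurement.
#'
#' @param params A [biodist_params()].
#' @param injected_activity_mbq Injected activity in MBq (> 0); recorded in
#'   the table attributes (%IA/g is already normalised per injected
#'   activity).
#' @param nuclide A [nuclide_spec()]; default [lu177()] without spectrum.
#' @param seed Integer seed; identical (params, seed) give byte-identical
#'   tables.
#' @return A tidy biodistribution tibble (see [read_biodistribution()]).
#' @export
#' @examples
#' bd <- simulate_biodistribution(default_biodist_params(noise_cv = 0),
#'                                injected_activity_mbq = 3, seed = 1)
#' summarize_biodistribution(dplyr::filter(bd, decay_corrected, !blocked))
simulate_biodistribution <- function(params,
                                     injected_activity_mbq = 3,
                                     nuclide = lu177(with_spectrum = FALSE),
                                     seed = 1L) {
  stopifnot(inherits(params, "biodist_params"))
  if (injected_activity_mbq <= 0) {
    rlang::abort("`injected_activity_mbq` must be positive.")
  }
  set.seed(as.integer(seed))
  grid <- tidyr::expand_grid(
    blocked = c(FALSE, TRUE),
    time_h = params$time_points,
    replicate = seq_len(params$n_per_timepoint),
    params$organs
  ) |>
    dplyr::filter(!.data$blocked | .data$time_h %in% params$blocked_time_points)

  cv <- params$noise_cv
  sdlog <- sqrt(log(1 + cv^2))
  noise <- if (cv > 0) {
    stats::rlnorm(nrow(grid), meanlog = -sdlog^2 / 2, sdlog = sdlog)
  } else {
    rep(1, nrow(grid))
  }

  out <- grid |>
    dplyr::mutate(
      mouse_id = paste0(ifelse(.data$blocked, "B", "U"),
                        "t", .data$time_h, "_", .data$replicate),
      true_frac = kinetic_template(.data$time_h, .data$amplitude,
                                   .data$uptake_rate, .data$clearance_rate) *
        ifelse(.data$blocked, .data$blocking_factor, 1),
      pct_ia_per_g = 100 * .data$true_frac * noise
    )

  long <- dplyr::bind_rows(
    dplyr::mutate(out, decay_corrected = TRUE),
    dplyr::mutate(out,
                  decay_corrected = FALSE,
                  pct_ia_per_g = .data$pct_ia_per_g *
                    decay_factor(nuclide, .data$time_h))
  ) |>
    dplyr::select("mouse_id", "organ", "time_h", "pct_ia_per_g",
                  "decay_corrected", "blocked") |>
    dplyr::arrange(.data$decay_corrected, .data$blocked, .data$organ,
                   .data$time_h, .data$mouse_id)
  attr(long, "injected_activity_mbq") <- injected_activity_mbq
  attr(long, "seed") <- as.integer(seed)
  long
}

#' Therapy-arm simulation parameters
#'
#' One study arm of a four-arm combination-therapy design. Tumors grow
#' piecewise-exponentially: volume is held at baseline during
#' `treatment_delay` days of growth arrest, then either grows at the mouse's
#' net exponential rate (non-responders) or regresses exponentially
#' (responders, drawn with probability `regression_prob`). A responding
#' tumor disappears entirely with probability `cure_prob`; non-cured
#' responders plateau at a residual fraction of baseline. Body weight follows
#' a Gaussian random walk and tumor ulceration is a constant per-day hazard
#' while a tumor is present.
#'
#' @param arm_label Arm label, conventionally one of `"A"`-`"D"`.
#' @param n_mice Animals in the arm (>= 1).
#' @param initial_volume_mean,initial_volume_sd Baseline tumor volume
#'   moments, mm3 (lognormal across mice).
#' @param initial_bw_mean,initial_bw_sd Baseline body weight moments, g.
#' @param growth_rate Median net exponential growth rate, 1/day.
#' @param growth_rate_cv Between-mouse lognormal CV of the growth rate.
#' @param treatment_delay Days of growth arrest after treatment start.
#' @param regression_prob Probability a mouse responds (tumor regresses).
#' @param regression_rate Exponential regression rate for responders, 1/day.
#' @param cure_prob Probability a responder's tumor disappears entirely.
#' @param residual_fraction Plateau fraction of baseline volume for
#'   non-cured responders.
#' @param bw_drift_mean,bw_drift_sd Daily body-weight increments, g.
#' @param ulceration_hazard Per-day ulceration probability while the tumor
#'   measures at least `ulcer_volume_threshold`.
#' @param ulcer_volume_threshold Volume (mm3) above which ulceration can
#'   occur; ulceration is a large-tumor phenomenon.
#' @param behavior_hazard Per-day probability of an abnormal-behavior flag.
#' @return An object of class `arm_params`.
#' @export
arm_params <- function(arm_label, n_mice = 11,
                       initial_volume_mean = 110, initial_volume_sd = 51,
                       initial_bw_mean = 22.3, initial_bw_sd = 1.8,
                       growth_rate = 0.19, growth_rate_cv = 0.20,
                       treatment_delay = 0,
                       regression_prob = 0, regression_rate = 0.10,
                       cure_prob = 0, residual_fraction = 0.2,
                       bw_drift_mean = 0.03, bw_drift_sd = 0.15,
                       ulceration_hazard = 0.012,
                       ulcer_volume_threshold = 300,
                       behavior_hazard = 0) {
  probs <- c(regression_prob, cure_prob, ulceration_hazard, behavior_hazard)
  if (any(probs < 0) || any(probs > 1)) {
    rlang::abort("Probabilities must lie in [0, 1].")
  }
  if (n_mice < 1) rlang::abort("`n_mice` must be >= 1.")
  if (initial_volume_mean <= 0) rlang::abort("Initial volumes must be positive.")
  structure(as.list(environment()), class = "arm_params")
}

#' Default four-arm therapy design
#'
#' Arms mirror a vehicle / radioconjugate / checkpoint-antibody / combination
#' design with n = 11 per arm, baseline tumor volumes of 110 +/- 51,
#' 71 +/- 44, 98 +/- 75 and 88 +/- 67 mm3 and body weights near 21-22 g.
#' Growth and response parameters are calibrated so that (qualitatively) the
#' first control endpoint falls near day 8, control median survival is about
#' 12 days, single-agent arms show modest growth delay, and the combination
#' arm responds in roughly 8 of 11 mice with most responders cured, leaving
#' the majority of that arm alive at the day-70 study end.
#'
#' @return Named list of [arm_params()], arms `"A"`-`"D"`.
#' @export
default_arm_design <- function() {
  list(
    A = arm_params("A", initial_volume_mean = 110, initial_volume_sd = 51,
                   initial_bw_mean = 22.3, initial_bw_sd = 1.8),
    B = arm_params("B", initial_volume_mean = 71, initial_volume_sd = 44,
                   initial_bw_mean = 21.3, initial_bw_sd = 1.6,
                   treatment_delay = 5, regression_prob = 0.09,
                   cure_prob = 0.5),
    C = arm_params("C", initial_volume_mean = 98, initial_volume_sd = 75,
                   initial_bw_mean = 21.2, initial_bw_sd = 1.6,
                   treatment_delay = 3.5, regression_prob = 0.18,
                   cure_prob = 0.5),
    D = arm_params("D", initial_volume_mean = 88, initial_volume_sd = 67,
                   initial_bw_mean = 21.4, initial_bw_sd = 1.6,
                   treatment_delay = 4, regression_prob = 8 / 11,
                   cure_prob = 7 / 8, regression_rate = 0.10)
  )
}

# Deterministic per-mouse substream seed: depends only on the master seed,
# the arm label and the mouse index, so adding a mouse or an arm never
# perturbs the streams of existing mice. Kept below 2^31 - 1.
substream_seed <- function(master_seed, arm_label, index) {
  key <- sum(utf8ToInt(as.character(arm_label))) * 1000003
  (as.numeric(master_seed) * 2654435761 + key + index * 97561) %% 2147483647
}

# True (noise-free) tumor volume at day t for one mouse
true_volume <- function(t, v0, growth, delay, responder, cured,
                        regression_rate, residual_fraction,
                        detection_limit = 1) {
  v <- ifelse(t <= delay, v0, {
    dt <- t - delay
    if (responder) {
      if (cured) v0 * exp(-regression_rate * dt)
      else v0 * (residual_fraction + (1 - residual_fraction) *
                   exp(-regression_rate * dt))
    } else {
      v0 * exp(growth * dt)
    }
  })
  # a cured tumor below the caliper detection limit has disappeared
  if (responder && cured) v[v < detection_limit] <- 0
  v
}

#' Simulate a therapy cohort
#'
#' Generates per-mouse tumor-volume (mm3) and body-weight (g) time series
#' with ulceration/behavior event flags for every arm of the design, applies
#' the humane-endpoint rule, and truncates each trajectory at its endpoint
#' day (the endpoint measurement itself is retained, mirroring the final
#' measurement taken at euthanasia). Each mouse draws from its own
#' deterministic random substream.
#'
#' @param design Named list of [arm_params()]; default [default_arm_design()].
#' @param measurement_days Integer days including day 0 (default daily to
#'   the day-70 study end).
#' @param seed Master integer seed.
#' @param rule An [endpoint_rule()] applied during truncation.
#' @param noise_cv CV of multiplicative lognormal caliper noise on measured
#'   volumes (day-0 baseline is measured noise-free; it defines the
#'   enrolment volume).
#' @return A tidy cohort tibble (`mouse_id`, `arm`, `day`, `volume_mm3`,
#'   `body_weight_g`, `ulcer_flag`, `behavior_flag`) with attributes
#'   `design`, `measurement_days`, `seed`, `study_end`.
#' @export
#' @examples
#' coh <- simulate_cohort(seed = 42)
#' dplyr::count(dplyr::distinct(coh, mouse_id, arm), arm)
simulate_cohort <- function(design = default_arm_design(),
                            measurement_days = 0:70,
                            seed = 1L,
                            rule = endpoint_rule(),
                            noise_cv = 0.10) {
  if (length(design) == 0L) rlang::abort("`design` must contain at least one arm.")
  if (!0 %in% measurement_days) {
    rlang::abort("`measurement_days` must include day 0.")
  }
  measurement_days <- sort(unique(measurement_days))
  study_end <- max(measurement_days)

  one_mouse <- function(ap, index) {
    set.seed(substream_seed(seed, ap$arm_label, index))
    # lognormal baseline volume matching the requested moments
    cv0 <- ap$initial_volume_sd / ap$initial_volume_mean
    sdl <- sqrt(log(1 + cv0^2))
    v0 <- stats::rlnorm(1, log(ap$initial_volume_mean) - sdl^2 / 2, sdl)
    bw0 <- max(stats::rnorm(1, ap$initial_bw_mean, ap$initial_bw_sd), 12)
    g <- ap$growth_rate * stats::rlnorm(1, 0, ap$growth_rate_cv)
    responder <- stats::runif(1) < ap$regression_prob
    cured <- responder && stats::runif(1) < ap$cure_prob

    vt <- true_volume(measurement_days, v0, g, ap$treatment_delay,
                      responder, cured, ap$regression_rate,
                      ap$residual_fraction)
    nd <- length(measurement_days)
    if (noise_cv > 0) {
      sdn <- sqrt(log(1 + noise_cv^2))
      noise <- stats::rlnorm(nd, -sdn^2 / 2, sdn)
      noise[1] <- 1
      v_meas <- vt * noise
    } else {
      v_meas <- vt
    }
    bw <- bw0 + cumsum(c(0, stats::rnorm(nd - 1, ap$bw_drift_mean,
                                         ap$bw_drift_sd)))
    bw <- pmax(bw, 10)
    ulcer <- stats::runif(nd) < ap$ulceration_hazard &
      v_meas >= ap$ulcer_volume_threshold
    ulcer[1] <- FALSE
    ulcer <- cumsum(ulcer) > 0  # ulceration persists once present
    behavior <- stats::runif(nd) < ap$behavior_hazard
    tibble::tibble(
      mouse_id = sprintf("%s%02d", ap$arm_label, index),
      arm = ap$arm_label,
      day = measurement_days,
      volume_mm3 = v_meas,
      body_weight_g = bw,
      ulcer_flag = ulcer,
      behavior_flag = behavior
    )
  }

  traj <- purrr::map(design, function(ap) {
    purrr::map(seq_len(ap$n_mice), function(i) one_mouse(ap, i)) |>
      purrr::list_rbind()
  }) |>
    purrr::list_rbind()

  # truncate each mouse at its endpoint day (endpoint measurement retained)
  ep <- endpoint_day(traj, rule)
  traj <- traj |>
    dplyr::left_join(dplyr::select(ep, "mouse_id", "endpoint_day"),
                     by = "mouse_id") |>
    dplyr::filter(is.na(.data$endpoint_day) | .data$day <= .data$endpoint_day) |>
    dplyr::select(-"endpoint_day")

  attr(traj, "design") <- design
  attr(traj, "measurement_days") <- measurement_days
  attr(traj, "seed") <- as.integer(seed)
  attr(traj, "study_end") <- study_end
  traj
}

#' Read / write tidy cohort tables
#'
#' @param path CSV path in the tidy cohort layout (`mouse_id`, `arm`, `day`,
#'   `volume_mm3`, `body_weight_g`, `ulcer_flag`, `behavior_flag`).
#' @return A cohort tibble.
#' @export
read_cohort <- function(path) {
  readr::read_csv(
    path,
    col_types = readr::cols(
      mouse_id = readr::col_character(),
      arm = readr::col_character(),
      day = readr::col_double(),
      volume_mm3 = readr::col_double(),
      body_weight_g = readr::col_double(),
      ulcer_flag = readr::col_logical(),
      behavior_flag = readr::col_logical()
    )
  )
}

#' @rdname read_cohort
#' @param cohort A cohort tibble.
#' @export
write_cohort <- function(cohort, path) {
  readr::write_csv(cohort, path)
  invisible(path)
}
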
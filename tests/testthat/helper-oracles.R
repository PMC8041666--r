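# Shared fixtures and independent oracles, built in code.

# Minimal biodistribution record table
make_records <- function(values, organ = "tumor", time_h = 4,
                         decay_corrected = TRUE, blocked = FALSE) {
  tibble::tibble(
    mouse_id = paste0("m", seq_along(values)),
    organ = organ,
    time_h = time_h,
    pct_ia_per_g = values,
    decay_corrected = decay_corrected,
    blocked = blocked
  )
}

# Single-mouse trajectory
make_traj <- function(days, volumes, bw = NULL, ulcer = FALSE,
                      behavior = FALSE, mouse_id = "m1", arm = "A") {
  tibble::tibble(
    mouse_id = mouse_id, arm = arm, day = days, volume_mm3 = volumes,
    body_weight_g = if (is.null(bw)) rep(22, length(days)) else bw,
    ulcer_flag = rep_len(ulcer, length(days)),
    behavior_flag = rep_len(behavior, length(days))
  )
}

# Brute-force permutation null of the log-rank statistic: shuffles arm
# labels and recomputes the chi-square; returns the tail probability of the
# observed statistic and the Monte Carlo SE of that estimate.
permutation_logrank <- function(records, n_perm = 1e4, seed = 1) {
  set.seed(seed)
  obs <- logrank(records)$chi_square
  stats <- replicate(n_perm, {
    r <- records
    r$arm <- sample(r$arm)
    logrank(r)$chi_square
  })
  p <- mean(stats >= obs - 1e-12)
  list(p = p, se = sqrt(p * (1 - p) / n_perm), observed = obs)
}

# Empirical (no-censoring) survival function oracle
empirical_survival <- function(times, t) {
  vapply(t, function(x) mean(times > x), numeric(1))
}

# Drop simulator bookkeeping attributes so data frames compare on content
strip_attrs <- function(d) {
  keep <- intersect(names(attributes(d)), c("names", "row.names", "class"))
  attributes(d) <- attributes(d)[keep]
  as.data.frame(d)
}
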
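# Paired motor-unit analysis. A lower-threshold "control" unit is paired
# with each higher-threshold "test" unit; delta-F is the control unit's
# smoothed discharge rate at the test unit's recruitment minus at its
# derecruitment (recruitment-derecruitment hysteresis, in pps), averaged per
# test unit over all eligible controls.

#' Enumerate candidate pairs in one contraction with eligibility diagnostics
#'
#' A pair (control, test) is eligible iff
#' (a) the control's recruitment threshold is below the test's;
#' (b) the control is recruited at least `sep_min` s before the test;
#' (c) the control is derecruited after the test;
#' (d) the control's smoothed-rate modulation (max - min) across the test
#'     unit's active window is at least `mod_min` pps;
#' (e) the rate-rate correlation between the two smoothed curves over their
#'     common active interval, resampled on a shared grid, is at least
#'     `r_min`.
#' Ineligible pairs are returned too, with each failing criterion flagged.
#'
#' @param trial_units One contraction's rows of an `mu_units` table
#'   (see [prepare_units()]).
#' @param sep_min,mod_min,r_min Eligibility thresholds; defaults follow
#'   [analysis_config()].
#' @param grid_hz Resampling rate for the rate-rate correlation.
#' @return Tibble with one row per ordered pair: ids, diagnostics
#'   (`crit_a` .. `crit_e`, `rr_corr`, `recruit_sep_s`, `control_mod_pps`)
#'   and `eligible`.
#' @export
eligible_pairs <- function(trial_units, sep_min = 1.0, mod_min = 0.5,
                           r_min = 0.7, grid_hz = 100) {
  n <- nrow(trial_units)
  if (n < 2) {
    return(tibble::tibble(control_id = character(), test_id = character(),
                          crit_a = logical(), crit_b = logical(),
                          crit_c = logical(), crit_d = logical(),
                          crit_e = logical(), rr_corr = numeric(),
                          recruit_sep_s = numeric(),
                          control_mod_pps = numeric(), eligible = logical()))
  }
  u <- trial_units
  grid <- expand.grid(ci = seq_len(n), ti = seq_len(n))
  grid <- grid[grid$ci != grid$ti, ]
  m <- nrow(grid)
  ci <- grid$ci; ti <- grid$ti
  crit_a <- u$rt_pct[ci] < u$rt_pct[ti]
  sep <- u$t_recruit[ti] - u$t_recruit[ci]
  crit_b <- sep >= sep_min
  crit_c <- u$t_derecruit[ci] > u$t_derecruit[ti]
  mod <- rr <- rep(NA_real_, m)
  for (k in seq_len(m)) {
    c_sm <- u$smoothed[[ci[k]]]
    # control modulation over the test unit's active window
    win_lo <- u$t_recruit[ti[k]]; win_hi <- u$t_derecruit[ti[k]]
    cw <- c_sm$rate[c_sm$time >= win_lo & c_sm$time <= win_hi]
    if (length(cw) > 1) mod[k] <- max(cw) - min(cw)
    # rate-rate correlation over the common active interval
    lo <- max(u$t_recruit[ci[k]], win_lo)
    hi <- min(u$t_derecruit[ci[k]], win_hi)
    if (hi - lo > 2 / grid_hz) {
      t_sm <- u$smoothed[[ti[k]]]
      g <- seq(lo, hi, by = 1 / grid_hz)
      rc <- approx(c_sm$time, c_sm$rate, xout = g, rule = 1)$y
      rt <- approx(t_sm$time, t_sm$rate, xout = g, rule = 1)$y
      ok <- !is.na(rc) & !is.na(rt)
      if (sum(ok) > 2 && sd(rc[ok]) > 0 && sd(rt[ok]) > 0) {
        rr[k] <- cor(rc[ok], rt[ok])
      }
    }
  }
  crit_d <- !is.na(mod) & mod >= mod_min
  crit_e <- !is.na(rr) & rr >= r_min
  tibble::tibble(
    control_id = u$unit_id[ci], test_id = u$unit_id[ti],
    crit_a = crit_a, crit_b = crit_b, crit_c = crit_c,
    crit_d = crit_d, crit_e = crit_e,
    rr_corr = rr, recruit_sep_s = sep, control_mod_pps = mod,
    eligible = crit_a & crit_b & crit_c & crit_d & crit_e
  )
}

#' Delta-F for a single eligible pair
#'
#' The control unit's smoothed discharge rate at the test unit's recruitment
#' time minus at its derecruitment time. Positive under
#' recruitment-derecruitment hysteresis; negative values are retained, not
#' clipped.
#'
#' @param control_smoothed `smoothed_discharge` of the control unit.
#' @param test_events One-row events tibble of the test unit
#'   (see [unit_events()]), or a list with `t_recruit` and `t_derecruit`.
#' @return Delta-F in pps, or `NA` when the control curve is undefined at
#'   either time.
#' @export
pair_deltaf <- function(control_smoothed, test_events) {
  r <- rate_at(control_smoothed,
               c(test_events$t_recruit, test_events$t_derecruit))
  if (any(is.na(r))) return(NA_real_)
  r[1] - r[2]
}

#' Per-test-unit delta-F: mean over eligible controls
#'
#' @param pair_results Pair table for one contraction, with `test_id`,
#'   `eligible` and `delta_f_pps` columns.
#' @return Tibble with `test_id`, `delta_f_pps` (mean across eligible
#'   controls) and `n_controls`; test units with no eligible control are
#'   omitted (they keep their other metrics but carry no delta-F).
#' @export
unit_deltaf <- function(pair_results) {
  pair_results |>
    dplyr::filter(.data$eligible, !is.na(.data$delta_f_pps)) |>
    dplyr::group_by(test_id = .data$test_id) |>
    dplyr::summarise(delta_f_pps = mean(.data$delta_f_pps),
                     n_controls = dplyr::n(), .groups = "drop")
}

#' Delta-F table for a whole dataset
#'
#' Runs the paired motor-unit analysis per contraction: eligibility screening
#' of every ordered pair, per-pair delta-F, then averaging across eligible
#' controls per test unit. Units tracked across trials of the same intensity
#' have their per-contraction delta-F values averaged per unit-intensity.
#'
#' @param units An `mu_units` table ([prepare_units()]) or an `mu_dataset`.
#' @param config An [analysis_config()].
#' @return A list-free tibble, one row per test unit per intensity:
#'   `participant_id, group, sex, intensity, unit_id, rt_pct, bin,
#'   delta_f_pps, n_controls`. The full per-pair diagnostics table is
#'   attached as attribute `pairs`.
#' @export
compute_deltaf <- function(units, config = analysis_config()) {
  if (inherits(units, "mu_dataset")) units <- prepare_units(units, config)
  by_trial <- units |>
    dplyr::group_by(.data$participant_id, .data$group, .data$sex,
                    .data$intensity, .data$trial) |>
    dplyr::group_split()
  pair_tables <- purrr::map(by_trial, function(tu) {
    pr <- eligible_pairs(tu, sep_min = config$sep_min,
                         mod_min = config$mod_min, r_min = config$r_min,
                         grid_hz = config$grid_hz)
    if (nrow(pr) == 0) return(NULL)
    dfv <- rep(NA_real_, nrow(pr))
    idx <- which(pr$eligible)
    for (k in idx) {
      ci <- match(pr$control_id[k], tu$unit_id)
      ti <- match(pr$test_id[k], tu$unit_id)
      dfv[k] <- pair_deltaf(tu$smoothed[[ci]], tu[ti, ])
    }
    pr$delta_f_pps <- dfv
    pr |>
      dplyr::mutate(participant_id = tu$participant_id[1],
                    group = tu$group[1], sex = tu$sex[1],
                    intensity = tu$intensity[1], trial = tu$trial[1],
                    .before = 1)
  })
  pairs <- dplyr::bind_rows(pair_tables)
  if (nrow(pairs) == 0) {
    out <- tibble::tibble(participant_id = character(), group = character(),
                          sex = character(), intensity = numeric(),
                          unit_id = character(), rt_pct = numeric(),
                          bin = factor(), delta_f_pps = numeric(),
                          n_controls = integer())
    attr(out, "pairs") <- pairs
    return(out)
  }
  per_contraction <- pairs |>
    dplyr::filter(.data$eligible, !is.na(.data$delta_f_pps)) |>
    dplyr::group_by(.data$participant_id, .data$group, .data$sex,
                    .data$intensity, .data$trial, unit_id = .data$test_id) |>
    dplyr::summarise(delta_f_pps = mean(.data$delta_f_pps),
                     n_controls = dplyr::n(), .groups = "drop")
  # average per unit-intensity across repeat trials
  out <- per_contraction |>
    dplyr::group_by(.data$participant_id, .data$group, .data$sex,
                    .data$intensity, .data$unit_id) |>
    dplyr::summarise(delta_f_pps = mean(.data$delta_f_pps),
                     n_controls = as.integer(round(mean(.data$n_controls))),
                     .groups = "drop") |>
    dplyr::left_join(
      units |>
        dplyr::group_by(.data$participant_id, .data$intensity,
                        .data$unit_id) |>
        dplyr::summarise(rt_pct = mean(.data$rt_pct), .groups = "drop"),
      by = c("participant_id", "intensity", "unit_id")
    ) |>
    dplyr::mutate(bin = assign_rt_bin(.data$rt_pct, config$bin_edges)) |>
    dplyr::relocate("rt_pct", "bin", .before = "delta_f_pps")
  attr(out, "pairs") <- pairs
  out
}
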
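# Per-unit discharge metrics: instantaneous rates from inter-spike
# intervals, continuous smoothed discharge-rate curves by support vector
# regression, recruitment/derecruitment events and threshold binning.

#' Instantaneous discharge rates from spike times
#'
#' Rate for each closed inter-spike interval: the rate point at spike k
#' (k >= 2) is `1 / (t_k - t_{k-1})`, placed at the second spike of the
#' interval (the rate becomes defined when the interval closes). A train with
#' n spikes yields n - 1 rate points.
#'
#' @param spike_times Strictly increasing spike times (s).
#' @return Tibble with `time` (s) and `rate` (pps).
#' @export
#' @examples
#' instantaneous_rates(c(0, 0.1, 0.2)) # two 10-pps points
instantaneous_rates <- function(spike_times) {
  if (length(spike_times) < 2) {
    abort("at least 2 spikes are required to define a rate.")
  }
  if (is.unsorted(spike_times, strictly = TRUE)) {
    abort("spike times must be strictly increasing.")
  }
  tibble::tibble(
    time = spike_times[-1],
    rate = 1 / diff(spike_times)
  )
}

#' Smooth discharge rates by support vector regression
#'
#' Fits an RBF-kernel epsilon-SVR to the instantaneous rate points and
#' evaluates it on a uniform grid spanning the unit's active interval (first
#' to last spike). No extrapolation is performed beyond that interval. The
#' kernel width defaults to the median pairwise distance of the rate-point
#' times, making the smoother invariant to time-origin shifts.
#'
#' @param times,rates Rate-point times (s) and rates (pps), e.g. from
#'   [instantaneous_rates()]. At least 4 points are required.
#' @param cost,epsilon,gamma SVR hyperparameters; `gamma = NULL` uses
#'   `1 / (2 * median(dist(times))^2)`.
#' @param grid_hz Evaluation-grid rate (Hz).
#' @param t_range Active interval to evaluate over; defaults to
#'   `range(times)`. Supply `c(first_spike, last_spike)` to cover the full
#'   train.
#' @return A tibble of class `smoothed_discharge` with `time` and `rate`,
#'   carrying the fit parameters as attributes.
#' @export
smooth_discharge <- function(times, rates, cost = 50, epsilon = 0.05,
                             gamma = NULL, grid_hz = 100, t_range = NULL) {
  stopifnot(length(times) == length(rates))
  if (length(times) < 4) {
    abort("at least 4 rate points are required for smoothing.")
  }
  t_range <- t_range %||% range(times)
  grid <- seq(t_range[1], t_range[2], by = 1 / grid_hz)
  if (tail(grid, 1) < t_range[2]) grid <- c(grid, t_range[2])
  if (sd(rates) == 0) {
    # degenerate: constant input, constant curve
    out <- tibble::tibble(time = grid, rate = rates[1])
    return(new_smoothed(out, t_range, list(constant = TRUE)))
  }
  if (is.null(gamma)) {
    # half the median pairwise distance: narrow enough to track the rise and
    # fall of a ramp contraction, wide enough to average over ISI jitter
    sigma <- median(dist(times)) / 2
    if (sigma <= 0) sigma <- diff(range(times)) / 4
    gamma <- 1 / (2 * sigma^2)
  }
  fit <- e1071::svm(x = matrix(times, ncol = 1), y = rates,
                    type = "eps-regression", kernel = "radial",
                    cost = cost, epsilon = epsilon, gamma = gamma,
                    scale = FALSE)
  out <- tibble::tibble(
    time = grid,
    rate = as.numeric(predict(fit, matrix(grid, ncol = 1)))
  )
  new_smoothed(out, t_range,
               list(cost = cost, epsilon = epsilon, gamma = gamma))
}

new_smoothed <- function(tbl, t_range, params) {
  structure(tbl, t_range = t_range, svr_params = params,
            class = c("smoothed_discharge", class(tbl)))
}

#' Evaluate a smoothed discharge curve at arbitrary times
#'
#' Linear interpolation on the evaluation grid; returns `NA` outside the
#' active interval (no extrapolation).
#'
#' @param smoothed A `smoothed_discharge` object.
#' @param t Times (s).
#' @return Rates (pps).
#' @export
rate_at <- function(smoothed, t) {
  stopifnot(inherits(smoothed, "smoothed_discharge"))
  approx(smoothed$time, smoothed$rate, xout = t, rule = 1)$y
}

#' Recruitment/derecruitment events and peak discharge rate
#'
#' Recruitment (derecruitment) time is the first (last) spike; the
#' corresponding thresholds are the torque at those times expressed as %MVT,
#' read off the (filtered) torque trace by linear interpolation. Peak
#' discharge rate is the maximum of the smoothed curve.
#'
#' @param spike_times Strictly increasing spike times (s).
#' @param smoothed A `smoothed_discharge` for this unit.
#' @param torque_trace Tibble with `time_s`, `torque_nm` covering the spike
#'   interval.
#' @param mvt_nm Maximal voluntary torque (N.m).
#' @return One-row tibble: `t_recruit`, `t_derecruit`, `rt_pct`,
#'   `derecruit_pct`, `peak_dr_pps`, `t_peak_dr`.
#' @export
unit_events <- function(spike_times, smoothed, torque_trace, mvt_nm) {
  t_rec <- spike_times[1]
  t_der <- spike_times[length(spike_times)]
  tr <- range(torque_trace$time_s)
  if (t_rec < tr[1] || t_der > tr[2]) {
    abort("torque trace does not cover the unit's spike interval.")
  }
  torque_at <- function(t) {
    approx(torque_trace$time_s, torque_trace$torque_nm, xout = t,
           rule = 1)$y
  }
  i_peak <- which.max(smoothed$rate)
  tibble::tibble(
    t_recruit = t_rec,
    t_derecruit = t_der,
    rt_pct = torque_at(t_rec) / mvt_nm * 100,
    derecruit_pct = torque_at(t_der) / mvt_nm * 100,
    peak_dr_pps = smoothed$rate[i_peak],
    t_peak_dr = smoothed$time[i_peak]
  )
}

#' Assign recruitment-threshold bins
#'
#' Bins are half-open on the left: (0, 20] maps to `rt0-20`, (20, 40] to
#' `rt20-40`, (40, 60] to `rt40-60`. Thresholds above the last edge fall
#' outside the binned analyses and return `NA` (flagged, not an error);
#' negative thresholds are a validation error.
#'
#' @param rt_pct Recruitment thresholds (%MVT).
#' @param edges Bin edges, strictly increasing (default `c(0, 20, 40, 60)`).
#' @return Factor of bin labels with `NA` for thresholds above the ceiling.
#' @export
#' @examples
#' assign_rt_bin(c(10, 20, 20.5, 40.5, 61))
assign_rt_bin <- function(rt_pct, edges = c(0, 20, 40, 60)) {
  if (any(rt_pct < 0, na.rm = TRUE)) {
    abort("negative recruitment threshold encountered.")
  }
  labs <- paste0("rt", head(edges, -1), "-", tail(edges, -1))
  cut(rt_pct, breaks = edges, labels = labs, include.lowest = FALSE,
      right = TRUE)
}

# Prepare per-unit curves and events for every spike train in a dataset.
# Returns a nested tibble (class mu_units): one row per
# participant x intensity x trial x unit, with list-columns holding the
# spike times and the smoothed curve, and unnested event metrics.
#' Smooth every unit in a dataset and extract its events
#'
#' Workhorse used by [compute_unit_metrics()], [compute_deltaf()] and
#' [compute_brace()]: low-pass filters each trial's torque trace, smooths
#' each unit's instantaneous rates and extracts recruitment, derecruitment
#' and peak-discharge events. Units with fewer than 4 rate points are flagged
#' unsmoothable and dropped (counted in the `n_unsmoothable` attribute).
#'
#' @param dataset An `mu_dataset` (see [read_mu_dataset()]).
#' @param config An [analysis_config()].
#' @return A nested tibble of class `mu_units`, one row per spike train, with
#'   list-columns `spike_times` and `smoothed` plus event columns.
#' @export
prepare_units <- function(dataset, config = analysis_config()) {
  stopifnot(inherits(dataset, "mu_dataset"))
  torque_f <- lowpass_torque(dataset$torque,
                             cutoff_hz = config$torque_cutoff_hz)
  torque_by_trial <- torque_f |>
    dplyr::group_by(.data$participant_id, .data$intensity, .data$trial) |>
    tidyr::nest(.key = "torque") |>
    dplyr::ungroup()

  nested <- dataset$spikes |>
    dplyr::group_by(.data$participant_id, .data$group, .data$sex,
                    .data$intensity, .data$trial, .data$unit_id,
                    .data$pnr_db) |>
    dplyr::summarise(spike_times = list(sort(.data$spike_time_s)),
                     n_spikes = dplyr::n(), .groups = "drop") |>
    dplyr::left_join(torque_by_trial,
                     by = c("participant_id", "intensity", "trial"))

  n_unsmoothable <- sum(nested$n_spikes < 5)
  nested <- nested |> dplyr::filter(.data$n_spikes >= 5)

  rows <- purrr::pmap(
    list(nested$spike_times, nested$torque),
    function(st, tq) {
      ir <- instantaneous_rates(st)
      # rate points are re-centred on their interval midpoints before
      # smoothing: a rate computed over (t_{k-1}, t_k] estimates the rate at
      # the middle of that interval, and right-aligned placement would lag
      # the curve by half an ISI, biasing delta-F downward
      t_mid <- ir$time - diff(st) / 2
      sm <- smooth_discharge(t_mid, ir$rate, cost = config$svr_cost,
                             epsilon = config$svr_epsilon,
                             gamma = config$svr_gamma,
                             grid_hz = config$grid_hz,
                             t_range = range(st))
      ev <- unit_events(st, sm, tq, tq$mvt_nm[1])
      list(smoothed = sm, events = ev)
    }
  )
  out <- nested |>
    dplyr::mutate(smoothed = purrr::map(rows, "smoothed")) |>
    dplyr::bind_cols(purrr::map_dfr(rows, "events")) |>
    dplyr::mutate(bin = assign_rt_bin(.data$rt_pct, config$bin_edges))
  attr(out, "n_unsmoothable") <- n_unsmoothable
  class(out) <- c("mu_units", class(out))
  out
}

#' Per-unit discharge metrics table
#'
#' Flat table of per-unit metrics: recruitment threshold (%MVT), bin, peak
#' discharge rate and spike count, one row per unit per trial.
#'
#' @param units An `mu_units` table from [prepare_units()], or an
#'   `mu_dataset` (prepared on the fly).
#' @param config An [analysis_config()] (used when preparing a dataset).
#' @return A tibble.
#' @export
compute_unit_metrics <- function(units, config = analysis_config()) {
  if (inherits(units, "mu_dataset")) units <- prepare_units(units, config)
  units |>
    dplyr::select("participant_id", "group", "sex", "intensity", "trial",
                  "unit_id", "pnr_db", "n_spikes", "rt_pct",
                  "derecruit_pct", "bin", "peak_dr_pps") |>
    tibble::as_tibble()
}
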
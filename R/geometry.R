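# Brace height: the maximal orthogonal deviation of the ascending
# discharge-rate-versus-torque trajectory from the straight line joining the
# recruitment point to the peak-discharge point, normalized to the
# hypotenuse of the right triangle formed by those two points. Torque and
# rate are first rescaled to [0, 1] over the endpoint spans so that
# "orthogonal" is well defined across units with different scales; in that
# frame the reference line runs (0,0) -> (1,1) and the hypotenuse has length
# sqrt(2).

#' Ascending discharge-rate-versus-torque trajectory
#'
#' Re-parameterizes a unit's smoothed discharge rate against torque (%MVT)
#' over the ascending phase, from recruitment to the peak-discharge point.
#' If the peak discharge occurs after the torque peak of the ramp, the
#' trajectory is truncated at the torque peak and flagged. Non-monotone
#' torque on the ascent (beyond tolerance) is flagged and replaced by its
#' monotone (running-maximum) envelope.
#'
#' @param smoothed A `smoothed_discharge` object.
#' @param torque_trace Tibble with `time_s`, `torque_nm` (filtered).
#' @param events One-row events tibble from [unit_events()].
#' @param mvt_nm Maximal voluntary torque (N.m).
#' @param monotone_tol Tolerated torque back-tracking on the ascent, as a
#'   fraction of the torque span (default 0.02).
#' @return Tibble of class `ascending_trajectory` with `torque_pct` and
#'   `rate`, plus attributes `endpoints` (recruitment and peak points) and
#'   `flags`.
#' @export
ascending_trajectory <- function(smoothed, torque_trace, events, mvt_nm,
                                 monotone_tol = 0.02) {
  flags <- character(0)
  t_peak_torque <- torque_trace$time_s[which.max(torque_trace$torque_nm)]
  t_end <- events$t_peak_dr
  if (t_end > t_peak_torque) {
    t_end <- t_peak_torque
    flags <- c(flags, "peak discharge after torque peak; truncated")
  }
  idx <- smoothed$time >= events$t_recruit & smoothed$time <= t_end
  if (sum(idx) < 3) {
    out <- tibble::tibble(torque_pct = numeric(), rate = numeric())
    return(structure(out, endpoints = NULL,
                     flags = c(flags, "degenerate zero-length trajectory"),
                     class = c("ascending_trajectory", class(out))))
  }
  tt <- smoothed$time[idx]
  rate <- smoothed$rate[idx]
  torque_pct <- approx(torque_trace$time_s, torque_trace$torque_nm,
                       xout = tt, rule = 2)$y / mvt_nm * 100
  span <- diff(range(torque_pct))
  if (span > 0 && any(diff(torque_pct) < -monotone_tol * span)) {
    flags <- c(flags, "non-monotone torque on ascent; monotone envelope used")
  }
  torque_pct <- cummax(torque_pct)
  out <- tibble::tibble(torque_pct = torque_pct, rate = rate)
  endpoints <- list(
    recruit = c(torque = torque_pct[1], rate = rate[1]),
    peak = c(torque = torque_pct[length(torque_pct)],
             rate = rate[length(rate)])
  )
  structure(out, endpoints = endpoints, flags = flags,
            class = c("ascending_trajectory", class(out)))
}

#' Brace height of an ascending trajectory
#'
#' Both axes are rescaled to [0, 1] over the span between the recruitment and
#' peak-discharge endpoints; the reference line is then y = x and the
#' right-triangle hypotenuse has length sqrt(2). The brace point is the
#' trajectory point of maximal absolute perpendicular deviation from the
#' line; brace height is that deviation expressed as a percentage of the
#' hypotenuse (%rTri), signed positive for deviations above the line
#' (discharge accelerating faster than linearly). Exclusion flags (applied by
#' [brace_exclusions()]) cover: degenerate endpoints, values above 100 %rTri,
#' below-line maxima, and a negative slope of the segment from the
#' recruitment point to the brace point in the normalized frame.
#'
#' @param trajectory An `ascending_trajectory`.
#' @return One-row tibble: `brace_pct_rtri` (signed), `brace_torque_pct`,
#'   `brace_rate`, `slope_to_brace`, `excluded`, `reason`.
#' @export
brace_height <- function(trajectory) {
  flags <- attr(trajectory, "flags") %||% character(0)
  if (nrow(trajectory) < 3 ||
      "degenerate zero-length trajectory" %in% flags) {
    return(brace_row(NA, NA, NA, NA, TRUE, "degenerate trajectory"))
  }
  x0 <- trajectory$torque_pct[1]
  x1 <- trajectory$torque_pct[nrow(trajectory)]
  y0 <- trajectory$rate[1]
  y1 <- trajectory$rate[nrow(trajectory)]
  if (x1 - x0 <= 0 || y1 - y0 == 0) {
    return(brace_row(NA, NA, NA, NA, TRUE, "degenerate endpoints"))
  }
  x <- (trajectory$torque_pct - x0) / (x1 - x0)
  y <- (trajectory$rate - y0) / (y1 - y0)
  dev <- (y - x) / sqrt(2)          # signed perpendicular distance to y = x
  i <- which.max(abs(dev))
  pct <- 100 * dev[i] / sqrt(2)     # % of the sqrt(2) hypotenuse
  slope <- if (x[i] > 0) y[i] / x[i] else Inf * sign(y[i])
  excluded <- FALSE; reason <- NA_character_
  if (pct < 0) {
    excluded <- TRUE; reason <- "below-line maximum deviation"
    if (slope < 0) reason <- "negative recruitment-to-brace slope"
  } else if (pct > 100) {
    excluded <- TRUE; reason <- "brace height exceeds 100 %rTri"
  } else if (slope < 0) {
    excluded <- TRUE; reason <- "negative recruitment-to-brace slope"
  }
  brace_row(pct, trajectory$torque_pct[i], trajectory$rate[i], slope,
            excluded, reason)
}

brace_row <- function(pct, bx, by, slope, excluded, reason) {
  tibble::tibble(brace_pct_rtri = as.numeric(pct),
                 brace_torque_pct = as.numeric(bx),
                 brace_rate = as.numeric(by),
                 slope_to_brace = as.numeric(slope),
                 excluded = excluded, reason = reason)
}

#' Apply brace-height exclusion rules
#'
#' Deterministic counterpart of the manual review step: drops units whose
#' brace height exceeds 100 %rTri, whose maximal deviation lies below the
#' reference line, or whose recruitment-to-brace-point slope is negative.
#' Reasons are tallied in the `exclusion_counts` attribute.
#'
#' @param results Brace-height table (e.g. from [compute_brace()]).
#' @return Filtered tibble of retained units.
#' @export
brace_exclusions <- function(results) {
  counts <- results |>
    dplyr::filter(.data$excluded) |>
    dplyr::count(.data$reason, name = "n")
  out <- results |> dplyr::filter(!.data$excluded)
  attr(out, "exclusion_counts") <- counts
  out
}

#' Brace-height table for a whole dataset
#'
#' Computes the ascending trajectory and brace height of every smoothed unit.
#' Exclusion flags are carried in the table; apply [brace_exclusions()] to
#' drop them.
#'
#' @param units An `mu_units` table ([prepare_units()]) or an `mu_dataset`.
#' @param config An [analysis_config()].
#' @return Tibble, one row per unit per trial, with recruitment threshold,
#'   bin and brace-height columns.
#' @export
compute_brace <- function(units, config = analysis_config()) {
  if (inherits(units, "mu_dataset")) units <- prepare_units(units, config)
  res <- purrr::pmap_dfr(
    list(units$smoothed, units$torque,
         purrr::map(seq_len(nrow(units)), function(i) units[i, ])),
    function(sm, tq, row) {
      traj <- ascending_trajectory(sm, tq, row, tq$mvt_nm[1])
      brace_height(traj)
    }
  )
  dplyr::bind_cols(
    units |>
      dplyr::select("participant_id", "group", "sex", "intensity", "trial",
                    "unit_id", "rt_pct", "bin") |>
      tibble::as_tibble(),
    res
  )
}
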
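#' Analysis configuration
#'
#' Bundles every tunable parameter of the pipeline in one object so that a run
#' is fully described by its config plus its seed. Defaults follow the
#' conventions of the paired motor-unit literature: decomposition quality is
#' gated at a pulse-to-noise ratio of 30 dB, recruitment-threshold bins span
#' 0-60 %MVT in 20 % steps, and bootstrap contrasts use 2000 resamples.
#'
#' @param pnr_min Minimum pulse-to-noise ratio (dB) for a unit to enter the
#'   analysis. Units below the threshold are dropped and counted.
#' @param torque_cutoff_hz Low-pass cutoff (Hz) for the torque trace,
#'   applied as a zero-phase 2nd-order Butterworth filter.
#' @param svr_cost,svr_epsilon Support-vector-regression hyperparameters used
#'   to smooth instantaneous discharge rates: box constraint `C` and
#'   epsilon-insensitive tube half-width (pps).
#' @param svr_gamma RBF kernel gamma. `NULL` (default) tunes it per unit from
#'   the median pairwise spike-time distance.
#' @param grid_hz Evaluation-grid rate (Hz) for smoothed discharge curves.
#' @param sep_min Minimum recruitment separation (s): the control unit must be
#'   recruited at least this long before the test unit.
#' @param mod_min Minimum control-unit discharge-rate modulation (pps) across
#'   the test unit's active window.
#' @param r_min Minimum rate-rate correlation between control and test
#'   smoothed curves over their common active interval.
#' @param bin_edges Recruitment-threshold bin edges (%MVT), strictly
#'   increasing. Units recruited above the last edge are excluded from binned
#'   analyses.
#' @param bootstrap_B Number of bootstrap resamples for group contrasts.
#' @param robust_tuning Huber tuning constant for the M-estimation loop.
#' @param robust_tol Convergence tolerance on fixed-effect coefficients.
#' @param robust_maxit Maximum IRLS iterations.
#' @param include_age Include participant age as a fixed covariate in the
#'   group models (sensitivity analysis; off by default).
#' @param seed Master seed; all randomness in a pipeline run derives from it.
#'
#' @return A list of class `picdf_config`.
#' @export
#' @examples
#' cfg <- analysis_config(pnr_min = 30)
#' cfg$bin_edges
analysis_config <- function(pnr_min = 30,
                            torque_cutoff_hz = 15,
                            svr_cost = 50,
                            svr_epsilon = 0.05,
                            svr_gamma = NULL,
                            grid_hz = 100,
                            sep_min = 1.0,
                            mod_min = 0.5,
                            r_min = 0.7,
                            bin_edges = c(0, 20, 40, 60),
                            bootstrap_B = 2000,
                            robust_tuning = 1.345,
                            robust_tol = 1e-8,
                            robust_maxit = 100,
                            include_age = FALSE,
                            seed = 1L) {
  if (pnr_min < 0) abort("`pnr_min` must be >= 0 dB.")
  if (any(diff(bin_edges) <= 0)) abort("`bin_edges` must be strictly increasing.")
  if (bootstrap_B < 1) abort("`bootstrap_B` must be a positive integer.")
  structure(
    list(
      pnr_min = pnr_min,
      torque_cutoff_hz = torque_cutoff_hz,
      svr_cost = svr_cost,
      svr_epsilon = svr_epsilon,
      svr_gamma = svr_gamma,
      grid_hz = grid_hz,
      sep_min = sep_min,
      mod_min = mod_min,
      r_min = r_min,
      bin_edges = bin_edges,
      bootstrap_B = as.integer(bootstrap_B),
      robust_tuning = robust_tuning,
      robust_tol = robust_tol,
      robust_maxit = as.integer(robust_maxit),
      include_age = include_age,
      seed = as.integer(seed)
    ),
    class = "picdf_config"
  )
}

#' @export
print.picdf_config <- function(x, ...) {
  cat("<picdf analysis config>\n")
  cat("  PNR filter:      >=", x$pnr_min, "dB\n")
  cat("  Torque low-pass: ", x$torque_cutoff_hz, "Hz (zero-phase Butterworth)\n")
  cat("  SVR:             C =", x$svr_cost, ", epsilon =", x$svr_epsilon,
      ", gamma =", if (is.null(x$svr_gamma)) "per-unit" else x$svr_gamma, "\n")
  cat("  Pairing:         sep >=", x$sep_min, "s, modulation >=", x$mod_min,
      "pps, r >=", x$r_min, "\n")
  cat("  RT bins (%MVT):  ", paste(x$bin_edges, collapse = " / "), "\n")
  cat("  Bootstrap:       B =", x$bootstrap_B, ", seed =", x$seed, "\n")
  invisible(x)
}
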
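# Motoneuron-pool simulator with injected, analytically known discharge
# hysteresis. The model is deliberately the simplest one with a closed-form
# delta-F oracle: a common drive D(t) (%MVT) tracks the triangular torque
# target; unit i starts firing when D reaches its recruitment threshold
# theta_i, after which its effective threshold drops by dtheta_i (the
# PIC-like hysteresis); its instantaneous rate is
#   r_i(t) = min(rate_min + gain_i * (D(t) - (theta_i - dtheta_i)), rate_sat)
# and it stops firing when D falls below theta_i - dtheta_i.

#' Motoneuron pool parameters
#'
#' Defines the simulated pool: recruitment-threshold distribution, rate model,
#' hysteresis magnitude, inter-spike-interval noise and decomposition yield.
#' Thresholds are exponential-spaced over (1, peak drive - 2) %MVT so that
#' low-threshold units are dense and high-threshold units sparse, as in real
#' pools.
#'
#' @param n_units Pool size per trial (before yield thinning).
#' @param rate_min Discharge rate at the effective threshold (pps).
#' @param rate_sat Saturation rate (pps).
#' @param gain Mean rate gain (pps per %MVT of drive above the effective
#'   threshold); per-unit gains jitter +/-15 % around this.
#' @param dtheta_mean Mean hysteresis (%MVT drop of the effective threshold
#'   after recruitment). Scaled per group and intensity by the group profile.
#' @param dtheta_cv Coefficient of variation of per-unit hysteresis.
#' @param isi_cv Coefficient of variation of multiplicative (log-normal)
#'   inter-spike-interval jitter; 0 gives deterministic spike trains.
#' @param pnr_mean,pnr_sd Pulse-to-noise ratio distribution (dB) assigned to
#'   decomposed units.
#' @param yield_base,yield_slope Decomposition-yield model: a unit with
#'   threshold `theta` on a ramp peaking at `peak` %MVT is decomposed with
#'   probability `clamp(yield_base - yield_slope * theta/peak, 0.15, 0.95)`,
#'   giving the 10-30 units per trial typical of HD-EMG decomposition.
#' @param torque_noise_sd Additive white noise on the emitted torque trace
#'   (N.m); 0 by default.
#' @param torque_fs Torque sampling rate (Hz).
#' @return A list of class `pool_params`.
#' @export
pool_params <- function(n_units = 40,
                        rate_min = 7,
                        rate_sat = 22,
                        gain = 0.25,
                        dtheta_mean = 6,
                        dtheta_cv = 0.25,
                        isi_cv = 0.1,
                        pnr_mean = 35,
                        pnr_sd = 3.5,
                        yield_base = 0.85,
                        yield_slope = 0.6,
                        torque_noise_sd = 0,
                        torque_fs = 100) {
  stopifnot(n_units >= 1, rate_min > 0, rate_sat >= rate_min, gain > 0,
            dtheta_mean >= 0, isi_cv >= 0)
  structure(as.list(environment()), class = "pool_params")
}

#' Group hysteresis profiles
#'
#' Maps each cohort group to a hysteresis base level and per-intensity scaling
#' of the injected hysteresis. The sarcopenic profile is flat across
#' intensities (no capacity to upregulate PIC-like hysteresis with effort);
#' controls scale moderately and athletes most steeply, so higher-intensity
#' ramps carry larger hysteresis for those groups.
#'
#' @return Tibble with columns `group`, `dtheta_base` (%MVT) and `mult_i20`,
#'   `mult_i40`, `mult_i60` multipliers.
#' @export
group_profiles <- function() {
  tibble::tribble(
    ~group,       ~dtheta_base, ~mult_i20, ~mult_i40, ~mult_i60,
    "sarcopenic", 4.5,          1.0,       1.0,       1.0,
    "control",    6.5,          1.0,       1.25,      1.5,
    "athlete",    7.5,          1.0,       1.4,       1.8
  )
}

# drive (%MVT) of the triangular ramp at time t: 10 s up, 10 s down
ramp_drive <- function(t, intensity) {
  peak <- intensity * 100
  rate <- peak / 10
  ifelse(t <= 10, rate * t, pmax(0, rate * (20 - t)))
}

# unit rate as a function of drive, given effective threshold
unit_rate_at_drive <- function(drive, theta_eff, gain, rate_min, rate_sat) {
  ifelse(drive >= theta_eff,
         pmin(rate_min + gain * (drive - theta_eff), rate_sat),
         NA_real_)
}

#' Analytic delta-F oracle for a simulated pair
#'
#' Closed-form value of the quantity the paired motor-unit estimator targets:
#' the control unit's model discharge rate at the drive level where the test
#' unit recruits (`theta_t`) minus its rate at the level where the test unit
#' derecruits (`theta_t - dtheta_t`). With neither rate saturated this equals
#' `gain_c * dtheta_t`; a control saturated across the whole window gives 0.
#'
#' @param control List (or one-row data frame) with `theta`, `dtheta`,
#'   `gain`, `rate_min`, `rate_sat` for the control unit.
#' @param test List with `theta` and `dtheta` for the test unit.
#' @return Delta-F in pps, or `NA` (with attribute `reason`) when the control
#'   is not active across the test unit's full window.
#' @export
#' @examples
#' analytic_deltaf(
#'   control = list(theta = 5, dtheta = 0, gain = 0.5, rate_min = 5, rate_sat = 30),
#'   test = list(theta = 15, dtheta = 4)
#' ) # 2.0
analytic_deltaf <- function(control, test) {
  theta_eff_c <- control$theta - control$dtheta
  d_rec <- test$theta                 # drive at test recruitment (ascending)
  d_der <- test$theta - test$dtheta   # drive at test derecruitment (descending)
  if (d_der < theta_eff_c || d_rec < control$theta) {
    out <- NA_real_
    attr(out, "reason") <- "control not active across test window"
    return(out)
  }
  r_rec <- unit_rate_at_drive(d_rec, theta_eff_c, control$gain,
                              control$rate_min, control$rate_sat)
  r_der <- unit_rate_at_drive(d_der, theta_eff_c, control$gain,
                              control$rate_min, control$rate_sat)
  r_rec - r_der
}

# draw per-unit pool realisation (thresholds, gains, hysteresis, pnr, yield)
draw_units <- function(params, intensity, dtheta_scale) {
  peak <- intensity * 100
  n <- params$n_units
  # exponential spacing: dense at low thresholds
  q <- (seq_len(n) - 0.5) / n
  theta <- 1 + (peak - 3) * (exp(2.5 * q) - 1) / (exp(2.5) - 1)
  gain <- params$gain * runif(n, 0.85, 1.15)
  dtheta_target <- params$dtheta_mean * dtheta_scale
  dtheta <- if (dtheta_target > 0) {
    cv <- params$dtheta_cv
    sdl <- sqrt(log(1 + cv^2))
    dtheta_target * rlnorm(n, -sdl^2 / 2, sdl)
  } else {
    rep(0, n)
  }
  dtheta <- pmin(dtheta, theta - 0.5)  # unit must derecruit before ramp end
  dtheta <- pmax(dtheta, 0)
  pnr <- rnorm(n, params$pnr_mean, params$pnr_sd)
  p_yield <- pmin(pmax(params$yield_base - params$yield_slope * theta / peak,
                       0.15), 0.95)
  decomposed <- runif(n) < p_yield
  tibble::tibble(
    unit_id = sprintf("mu%02d", seq_len(n)),
    theta = theta, dtheta = dtheta, gain = gain,
    rate_min = params$rate_min, rate_sat = params$rate_sat,
    pnr_db = round(pnr, 1), decomposed = decomposed
  )
}

# spike times for one unit on one ramp by integrating its rate model
draw_spikes <- function(theta, dtheta, gain, rate_min, rate_sat,
                        intensity, isi_cv, dt = 1e-3) {
  peak <- intensity * 100
  ramp <- peak / 10
  theta_eff <- theta - dtheta
  if (theta >= peak) return(numeric(0))
  t_on <- theta / ramp
  t_off <- 20 - max(theta_eff, 0) / ramp
  tt <- seq(t_on, t_off, by = dt)
  r <- pmin(rate_min + gain * (ramp_drive(tt, intensity) - theta_eff), rate_sat)
  cum <- c(0, cumsum((r[-1] + r[-length(r)]) / 2 * dt))
  spikes <- numeric(floor(max(cum)) + 1L)
  spikes[1] <- t_on
  k <- 1L
  target <- 0
  repeat {
    eps <- if (isi_cv > 0) {
      sdl <- sqrt(log(1 + isi_cv^2))
      rlnorm(1, -sdl^2 / 2, sdl)
    } else 1
    target <- target + eps
    if (target > cum[length(cum)]) break
    k <- k + 1L
    if (k > length(spikes)) spikes <- c(spikes, numeric(16L))
    spikes[k] <- approx(cum, tt, xout = target, ties = "ordered")$y
  }
  spikes[seq_len(k)]
}

#' Simulate one ramped contraction trial
#'
#' Generates the torque trace, decomposed spike trains and per-unit ground
#' truth for a single triangular ramp (10 s up, 10 s down) at the requested
#' intensity, with hysteresis scaled by `dtheta_scale`.
#'
#' @param intensity Peak ramp target as a fraction of MVT (0.2, 0.4 or 0.6).
#' @param params A [pool_params()] object.
#' @param dtheta_scale Multiplier applied to `params$dtheta_mean`
#'   (group/intensity profile hook).
#' @param mvt_nm Maximal voluntary torque in N.m (scales the torque trace).
#' @param seed Integer seed; the trial is fully reproducible given it.
#' @param keep_all Keep units that failed yield thinning (for oracle studies).
#' @return List with `torque` (tibble: time_s, torque_nm, mvt_nm), `spikes`
#'   (tibble: unit_id, spike_time_s, pnr_db) and `truth` (tibble of per-unit
#'   model parameters and analytic recruit/derecruit torques, %MVT).
#' @export
simulate_trial <- function(intensity, params = pool_params(),
                           dtheta_scale = 1, mvt_nm = 30, seed = 1,
                           keep_all = FALSE) {
  if (!intensity %in% c(0.2, 0.4, 0.6)) {
    abort("intensity must be one of 0.2, 0.4, 0.6.")
  }
  set.seed(as.integer(seed))
  units <- draw_units(params, intensity, dtheta_scale)

  tt <- seq(0, 20, by = 1 / params$torque_fs)
  torque <- tibble::tibble(
    time_s = tt,
    torque_nm = ramp_drive(tt, intensity) / 100 * mvt_nm +
      (if (params$torque_noise_sd > 0)
        rnorm(length(tt), 0, params$torque_noise_sd) else 0),
    mvt_nm = mvt_nm
  )

  use <- if (keep_all) units else units[units$decomposed, ]
  if (nrow(use) == 0 || all(use$theta >= intensity * 100)) {
    warn("no unit recruited at the requested intensity; empty spike set.")
  }
  spikes <- purrr::pmap_dfr(
    use[, c("unit_id", "theta", "dtheta", "gain", "rate_min", "rate_sat",
            "pnr_db")],
    function(unit_id, theta, dtheta, gain, rate_min, rate_sat, pnr_db) {
      st <- draw_spikes(theta, dtheta, gain, rate_min, rate_sat,
                        intensity, params$isi_cv)
      if (length(st) < 2) return(NULL)
      tibble::tibble(unit_id = unit_id, spike_time_s = st, pnr_db = pnr_db)
    }
  )
  truth <- units |>
    dplyr::mutate(
      recruit_pct = .data$theta,
      derecruit_pct = .data$theta - .data$dtheta,
      t_on = .data$theta / (intensity * 10),
      t_off = 20 - pmax(.data$theta - .data$dtheta, 0) / (intensity * 10),
      intensity = intensity
    )
  list(torque = torque, spikes = spikes, truth = truth)
}

#' Analytic delta-F oracle table for a simulated trial
#'
#' Enumerates all ordered (control, test) pairs of a trial's ground-truth
#' units and evaluates [analytic_deltaf()] for each, flagging pairs where the
#' control is not active across the test window.
#'
#' @param truth Ground-truth tibble from [simulate_trial()].
#' @param decomposed_only Restrict to units that passed yield thinning.
#' @return Tibble with `control_id`, `test_id`, `deltaf_true`, `eligible_true`.
#' @export
oracle_pairs <- function(truth, decomposed_only = TRUE) {
  u <- if (decomposed_only && "decomposed" %in% names(truth)) {
    truth[truth$decomposed, ]
  } else truth
  if (nrow(u) < 2) {
    return(tibble::tibble(control_id = character(), test_id = character(),
                          deltaf_true = numeric(), eligible_true = logical()))
  }
  grid <- tidyr::expand_grid(ci = seq_len(nrow(u)), ti = seq_len(nrow(u))) |>
    dplyr::filter(u$theta[.data$ci] < u$theta[.data$ti])
  purrr::map2_dfr(grid$ci, grid$ti, function(ci, ti) {
    df <- analytic_deltaf(as.list(u[ci, ]), as.list(u[ti, ]))
    tibble::tibble(
      control_id = u$unit_id[ci], test_id = u$unit_id[ti],
      deltaf_true = as.numeric(df), eligible_true = !is.na(df)
    )
  })
}

#' Simulate a cohort of participants
#'
#' Builds a full synthetic dataset in the package's interchange format:
#' every participant performs triangular ramps at 20/40/60 %MVT, with
#' group-dependent hysteresis profiles (flat across intensities for the
#' sarcopenic profile; intensity-scaling for controls and, steeper, athletes)
#' and group-typical strength/function covariates. Per-participant seeds are
#' derived deterministically from the master seed, so identical calls yield
#' byte-identical files.
#'
#' @param group_sizes Named integer vector: participants per group; defaults
#'   reflect a typical ageing-cohort design (12 sarcopenic / 23 controls /
#'   21 athletes).
#' @param params A [pool_params()] object.
#' @param profiles Group hysteresis profiles, see [group_profiles()].
#' @param intensities Ramp intensities (fractions of MVT).
#' @param trials_per_intensity Trials per intensity (default 1).
#' @param deltaf_shift Optional named numeric: additive shift of
#'   `dtheta_base` per group, e.g. to generate null cohorts
#'   (`deltaf_shift = NULL` keeps profile defaults).
#' @param seed Master seed.
#' @return An `mu_dataset` with a `ground_truth` attribute (per-unit truth
#'   for every trial).
#' @export
simulate_cohort <- function(group_sizes = c(sarcopenic = 12, control = 23,
                                            athlete = 21),
                            params = pool_params(),
                            profiles = group_profiles(),
                            intensities = c(0.2, 0.4, 0.6),
                            trials_per_intensity = 1,
                            deltaf_shift = NULL,
                            seed = 1) {
  stopifnot(!is.null(names(group_sizes)),
            all(names(group_sizes) %in% profiles$group))
  set.seed(as.integer(seed))
  # participant-level covariates, group-typical for ageing cohorts
  cov_means <- tibble::tribble(
    ~group,       ~handgrip_kg, ~ugs_ms, ~fgs_ms, ~tug_s, ~fsst_s, ~ststs_s,
    ~ststs_w_kg,  ~peak_torque_nm, ~body_mass_kg, ~age_y,
    "sarcopenic", 22.9, 0.77, 1.04, 12.2, 12.6, 17.0, 1.9, 11.4, 69.4, 79.9,
    "control",    32.5, 1.38, 1.93, 6.7, 8.8, 11.1, 3.0, 26.2, 71.6, 74.5,
    "athlete",    34.6, 1.38, 2.15, 5.8, 7.3, 9.4, 3.7, 25.6, 64.4, 69.8
  )
  parts <- purrr::imap_dfr(group_sizes, function(n, g) {
    m <- cov_means[cov_means$group == g, ]
    tibble::tibble(
      participant_id = sprintf("%s%02d", substr(g, 1, 1), seq_len(n)),
      group = g,
      sex = rep(c("female", "male"), length.out = n),
      body_mass_kg = pmax(rnorm(n, m$body_mass_kg, 8), 40),
      handgrip_kg = pmax(rnorm(n, m$handgrip_kg, 4), 5),
      ugs_ms = pmax(rnorm(n, m$ugs_ms, 0.12), 0.3),
      fgs_ms = pmax(rnorm(n, m$fgs_ms, 0.18), 0.4),
      tug_s = pmax(rnorm(n, m$tug_s, 1.2), 3),
      fsst_s = pmax(rnorm(n, m$fsst_s, 1.2), 3),
      ststs_s = pmax(rnorm(n, m$ststs_s, 1.5), 4),
      ststs_w_kg = pmax(rnorm(n, m$ststs_w_kg, 0.4), 0.5),
      peak_torque_nm = pmax(rnorm(n, m$peak_torque_nm, 4), 4),
      age_y = pmax(rnorm(n, m$age_y, 4), 65)
    )
  })
  # sex effect on handgrip for realism
  parts$handgrip_kg <- parts$handgrip_kg +
    ifelse(parts$sex == "male", 6, -6) * 0.5

  mult_col <- function(intensity) paste0("mult_i", intensity * 100)
  part_seeds <- sample.int(2^30, nrow(parts))

  all_spikes <- list(); all_torque <- list(); all_truth <- list()
  for (i in seq_len(nrow(parts))) {
    p <- parts[i, ]
    prof <- profiles[profiles$group == p$group, ]
    base <- prof$dtheta_base +
      (if (!is.null(deltaf_shift)) deltaf_shift[[p$group]] %||% 0 else 0)
    mvt <- max(p$peak_torque_nm, 5)
    for (int in intensities) {
      for (tr in seq_len(trials_per_intensity)) {
        sc <- base * prof[[mult_col(int)]] / params$dtheta_mean
        trial_seed <- (part_seeds[i] + round(int * 1000) * 7 + tr * 13) %% 2^31
        sim <- simulate_trial(int, params, dtheta_scale = sc, mvt_nm = mvt,
                              seed = trial_seed)
        if (nrow(sim$spikes) > 0) {
          all_spikes[[length(all_spikes) + 1]] <- sim$spikes |>
            dplyr::mutate(participant_id = p$participant_id, group = p$group,
                          sex = p$sex, intensity = int, trial = tr,
                          .before = 1)
        }
        all_torque[[length(all_torque) + 1]] <- sim$torque |>
          dplyr::mutate(participant_id = p$participant_id, intensity = int,
                        trial = tr, .before = 1)
        all_truth[[length(all_truth) + 1]] <- sim$truth |>
          dplyr::mutate(participant_id = p$participant_id, group = p$group,
                        trial = tr, .before = 1)
      }
    }
  }
  ds <- read_mu_dataset(dplyr::bind_rows(all_spikes),
                        dplyr::bind_rows(all_torque), parts)
  attr(ds, "ground_truth") <- dplyr::bind_rows(all_truth)
  attr(ds, "sim_params") <- list(params = params, profiles = profiles,
                                 group_sizes = group_sizes, seed = seed)
  ds
}
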
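# Shared fixtures, all generated in code.

# wrap one simulate_trial() result as a single-participant mu_dataset
trial_as_dataset <- function(sim, participant_id = "p1", group = "control",
                             sex = "female", intensity = 0.2) {
  suppressMessages(read_mu_dataset(
    dplyr::mutate(sim$spikes, participant_id = participant_id, group = group,
                  sex = sex, intensity = intensity, trial = 1L, .before = 1),
    dplyr::mutate(sim$torque, participant_id = participant_id,
                  intensity = intensity, trial = 1L, .before = 1),
    tibble::tibble(participant_id = participant_id, group = group, sex = sex,
                   body_mass_kg = 70)
  ))
}

# minimal hand-built 3-table dataset: 2 units on one i20 trial
tiny_dataset <- function(spike_shift = 0) {
  tt <- seq(0, 20, by = 0.01)
  torque <- tibble::tibble(
    participant_id = "p1", intensity = 0.2, trial = 1L, time_s = tt,
    torque_nm = ifelse(tt <= 10, 2 * tt, 2 * (20 - tt)) / 100 * 30,
    mvt_nm = 30
  )
  st1 <- seq(2, 18, by = 0.125)
  st2 <- seq(5, 15, by = 0.1)
  spikes <- dplyr::bind_rows(
    tibble::tibble(unit_id = "u1", spike_time_s = st1 + spike_shift),
    tibble::tibble(unit_id = "u2", spike_time_s = st2 + spike_shift)
  ) |>
    dplyr::mutate(participant_id = "p1", group = "control", sex = "female",
                  intensity = 0.2, trial = 1L, pnr_db = 35, .before = 1)
  participants <- tibble::tibble(participant_id = "p1", group = "control",
                                 sex = "female", body_mass_kg = 70)
  suppressMessages(read_mu_dataset(spikes, torque, participants))
}

# synthetic smoothed_discharge built from an exact rate function
synthetic_smoothed <- function(t0, t1, rate_fn, grid_hz = 100) {
  grid <- seq(t0, t1, by = 1 / grid_hz)
  if (utils::tail(grid, 1) < t1) grid <- c(grid, t1)
  structure(tibble::tibble(time = grid, rate = rate_fn(grid)),
            t_range = c(t0, t1), svr_params = list(synthetic = TRUE),
            class = c("smoothed_discharge", "tbl_df", "tbl", "data.frame"))
}

# raw trajectory constructor for brace-height tests
make_trajectory <- function(torque_pct, rate) {
  structure(tibble::tibble(torque_pct = torque_pct, rate = rate),
            class = c("ascending_trajectory", "tbl_df", "tbl", "data.frame"))
}

# independent brute-force brace-height oracle: exact point-to-segment
# distances on the normalized frame, max over all points (signed)
brute_brace <- function(tr) {
  x0 <- tr$torque_pct[1]; x1 <- utils::tail(tr$torque_pct, 1)
  y0 <- tr$rate[1]; y1 <- utils::tail(tr$rate, 1)
  xs <- (tr$torque_pct - x0) / (x1 - x0)
  ys <- (tr$rate - y0) / (y1 - y0)
  d <- (ys - xs) / sqrt(2)
  i <- which.max(abs(d))
  d[i] / sqrt(2) * 100
}

# direct generative model for unit-level delta-F tables (stats-module tests):
# participant random intercepts + optional group/intensity effects
synth_deltaf_table <- function(n_per_group = 8, units_per_cell = 15,
                               group_effects = c(sarcopenic = 0, control = 0,
                                                 athlete = 0),
                               intensity_slope = 0, sd_participant = 0.5,
                               sd_unit = 0.8, seed = 1) {
  set.seed(seed)
  purrr::imap_dfr(group_effects, function(eff, g) {
    purrr::map_dfr(seq_len(n_per_group), function(i) {
      pid <- paste0(g, i)
      b <- rnorm(1, 0, sd_participant)
      sex <- sample(c("female", "male"), 1)
      purrr::map_dfr(c(0.2, 0.4, 0.6), function(int) {
        tibble::tibble(
          participant_id = pid, group = g, sex = sex, intensity = int,
          unit_id = paste0("u", seq_len(units_per_cell)),
          delta_f_pps = 3 + eff + intensity_slope * (int - 0.2) / 0.4 + b +
            rnorm(units_per_cell, 0, sd_unit)
        )
      })
    })
  })
}
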
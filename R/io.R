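# Tidy long-format interchange for decomposed motor-unit data. Three tables:
# one row per spike, one row per torque sample, one row per participant.

SPIKE_COLS <- c("participant_id", "group", "sex", "intensity", "trial",
                "unit_id", "spike_time_s", "pnr_db")
TORQUE_COLS <- c("participant_id", "intensity", "trial", "time_s",
                 "torque_nm", "mvt_nm")
PART_COLS <- c("participant_id", "group", "sex", "body_mass_kg")

#' Assemble and validate a motor-unit dataset
#'
#' Reads (or accepts in-memory) the three tidy tables the pipeline consumes --
#' per-spike, per-torque-sample, and per-participant -- checks the schema,
#' resolves cross-references, and applies record-level validation: spike times
#' must be strictly increasing and fall inside the torque trace of their
#' trial. Units failing record-level validation are removed and reported in
#' the `problems` attribute; schema or referential-integrity failures are
#' errors.
#'
#' @param spikes Path to a spikes CSV or a data frame with columns
#'   `participant_id, group, sex, intensity, trial, unit_id, spike_time_s,
#'   pnr_db`.
#' @param torque Path or data frame with columns `participant_id, intensity,
#'   trial, time_s, torque_nm, mvt_nm`.
#' @param participants Path or data frame with columns `participant_id,
#'   group, sex, body_mass_kg` plus optional function measures
#'   (`handgrip_kg, ugs_ms, fgs_ms, tug_s, fsst_s, ststs_s, ststs_w_kg,
#'   peak_torque_nm`, `age_y`).
#'
#' @return A list of class `mu_dataset` with elements `spikes`, `torque`,
#'   `participants` (tibbles) and attribute `problems` (tibble of removed
#'   units with reasons).
#' @export
read_mu_dataset <- function(spikes, torque, participants) {
  spikes <- as_table(spikes, "spikes")
  torque <- as_table(torque, "torque")
  participants <- as_table(participants, "participants")

  check_columns(spikes, SPIKE_COLS, "spikes")
  check_columns(torque, TORQUE_COLS, "torque")
  check_columns(participants, PART_COLS, "participants")

  if (any(!is.finite(torque$torque_nm))) {
    abort("torque: non-finite torque samples present.")
  }
  if (any(torque$mvt_nm <= 0)) abort("torque: `mvt_nm` must be > 0.")
  bad_int <- setdiff(unique(spikes$intensity), c(0.2, 0.4, 0.6))
  if (length(bad_int) > 0) {
    abort(paste0("spikes: intensity must be one of 0.2/0.4/0.6, found: ",
                 paste(bad_int, collapse = ", ")))
  }
  if (any(participants$body_mass_kg <= 0, na.rm = TRUE)) {
    abort("participants: `body_mass_kg` must be > 0.")
  }

  # referential integrity
  dangling_p <- setdiff(unique(spikes$participant_id),
                        participants$participant_id)
  if (length(dangling_p) > 0) {
    abort(paste0("integrity: spikes reference unknown participants: ",
                 paste(dangling_p, collapse = ", ")))
  }
  trial_keys <- function(d) paste(d$participant_id, d$intensity, d$trial)
  dangling_t <- setdiff(unique(trial_keys(spikes)), unique(trial_keys(torque)))
  if (length(dangling_t) > 0) {
    abort(paste0("integrity: spike trains reference trials with no torque ",
                 "trace: ", paste(dangling_t, collapse = "; ")))
  }

  # record-level validation, per unit per trial
  bounds <- torque |>
    dplyr::group_by(.data$participant_id, .data$intensity, .data$trial) |>
    dplyr::summarise(t_min = min(.data$time_s), t_max = max(.data$time_s),
                     .groups = "drop")
  checked <- spikes |>
    dplyr::group_by(.data$participant_id, .data$intensity, .data$trial,
                    .data$unit_id) |>
    dplyr::summarise(
      n_spikes = dplyr::n(),
      monotone = !is.unsorted(.data$spike_time_s, strictly = TRUE),
      lo = min(.data$spike_time_s), hi = max(.data$spike_time_s),
      .groups = "drop"
    ) |>
    dplyr::left_join(bounds,
                     by = c("participant_id", "intensity", "trial")) |>
    dplyr::mutate(
      reason = dplyr::case_when(
        .data$n_spikes < 2 ~ "fewer than 2 spikes",
        !.data$monotone ~ "spike times not strictly increasing",
        .data$lo < .data$t_min | .data$hi > .data$t_max ~
          "spike time outside trial bounds",
        TRUE ~ NA_character_
      )
    )
  problems <- checked |>
    dplyr::filter(!is.na(.data$reason)) |>
    dplyr::select("participant_id", "intensity", "trial", "unit_id", "reason")
  if (nrow(problems) > 0) {
    spikes <- spikes |>
      dplyr::anti_join(problems,
                       by = c("participant_id", "intensity", "trial", "unit_id"))
    inform(paste0(nrow(problems), " unit(s) removed by record-level validation."))
  }

  structure(
    list(spikes = spikes, torque = torque, participants = participants),
    problems = problems,
    class = "mu_dataset"
  )
}

as_table <- function(x, what) {
  if (is.character(x) && length(x) == 1) {
    if (!file.exists(x)) abort(paste0(what, ": file not found: ", x))
    x <- readr::read_csv(x, show_col_types = FALSE, progress = FALSE)
  }
  if (!is.data.frame(x)) abort(paste0(what, " must be a path or data frame."))
  tibble::as_tibble(x)
}

check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(paste0("schema: ", what, " is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  invisible(df)
}

#' Write a motor-unit dataset to a directory of CSV files
#'
#' Inverse of [read_mu_dataset()]: emits `spikes.csv`, `torque.csv`,
#' `participants.csv` (and `ground_truth.csv` when the dataset carries
#' simulator ground truth). Round-trips losslessly.
#'
#' @param dataset An `mu_dataset`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_mu_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "mu_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(dataset$spikes, file.path(dir, "spikes.csv"))
  readr::write_csv(dataset$torque, file.path(dir, "torque.csv"))
  readr::write_csv(dataset$participants, file.path(dir, "participants.csv"))
  gt <- attr(dataset, "ground_truth")
  if (!is.null(gt)) readr::write_csv(gt, file.path(dir, "ground_truth.csv"))
  invisible(dir)
}

#' @export
print.mu_dataset <- function(x, ...) {
  n_units <- nrow(dplyr::distinct(x$spikes, .data$participant_id,
                                  .data$intensity, .data$trial, .data$unit_id))
  cat("<mu_dataset>\n")
  cat("  participants:", nrow(x$participants), "\n")
  cat("  trials:      ",
      nrow(dplyr::distinct(x$torque, .data$participant_id, .data$intensity,
                           .data$trial)), "\n")
  cat("  spike trains:", n_units, " (", nrow(x$spikes), "spikes )\n")
  pr <- attr(x, "problems")
  if (!is.null(pr) && nrow(pr) > 0) cat("  removed by validation:", nrow(pr), "\n")
  invisible(x)
}

#' Filter spike trains by pulse-to-noise ratio
#'
#' Retains units whose decomposition quality (PNR) meets the threshold;
#' the comparison is inclusive (`pnr >= pnr_min`), so a unit at exactly the
#' threshold is kept. The number of removed units is recorded in the
#' `n_removed` attribute and reported via a message.
#'
#' @param dataset An `mu_dataset`, or a spikes tibble with a `pnr_db` column.
#' @param pnr_min Threshold in dB (default 30).
#' @return Filtered object of the same type.
#' @export
filter_pnr <- function(dataset, pnr_min = 30) {
  spikes <- if (inherits(dataset, "mu_dataset")) dataset$spikes else dataset
  if (!"pnr_db" %in% names(spikes)) abort("no `pnr_db` column present.")
  if (any(is.na(spikes$pnr_db))) {
    abort("PNR missing for some spike trains; every unit must carry a PNR.")
  }
  keys <- c("participant_id", "intensity", "trial", "unit_id")
  keys <- intersect(keys, names(spikes))
  units <- dplyr::distinct(spikes, dplyr::across(dplyr::all_of(c(keys, "pnr_db"))))
  keep <- units |> dplyr::filter(.data$pnr_db >= pnr_min)
  n_removed <- nrow(units) - nrow(keep)
  out_spikes <- spikes |>
    dplyr::semi_join(keep, by = c(keys, "pnr_db"))
  if (n_removed > 0) {
    inform(paste0(n_removed, " unit(s) below ", pnr_min, " dB PNR removed."))
  }
  if (inherits(dataset, "mu_dataset")) {
    dataset$spikes <- out_spikes
    attr(dataset, "n_removed_pnr") <- n_removed
    dataset
  } else {
    attr(out_spikes, "n_removed_pnr") <- n_removed
    out_spikes
  }
}

#' Zero-phase low-pass filter for torque traces
#'
#' Applies a 2nd-order Butterworth filter forwards and backwards
#' (zero net phase shift) to the torque signal, as is conventional for
#' dynamometer signals prior to conversion into torque values. Length and
#' sampling are preserved.
#'
#' @param trace A tibble with `time_s` and `torque_nm` columns (uniformly
#'   sampled; may contain several trials if grouped beforehand), or a numeric
#'   vector.
#' @param cutoff_hz Cutoff frequency in Hz (must be below Nyquist).
#' @param fs Sampling rate in Hz; inferred from `time_s` when `NULL`.
#' @return Object of the same shape with filtered torque.
#' @export
lowpass_torque <- function(trace, cutoff_hz = 15, fs = NULL) {
  if (is.numeric(trace) && is.null(dim(trace))) {
    if (is.null(fs)) abort("`fs` is required for a bare numeric trace.")
    return(lowpass_vec(trace, cutoff_hz, fs))
  }
  stopifnot(is.data.frame(trace))
  check_columns(trace, c("time_s", "torque_nm"), "torque trace")
  keys <- intersect(c("participant_id", "intensity", "trial"), names(trace))
  trace |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::group_modify(function(d, ...) {
      f <- fs %||% (1 / median(diff(d$time_s)))
      d$torque_nm <- lowpass_vec(d$torque_nm, cutoff_hz, f)
      d
    }) |>
    dplyr::ungroup()
}

lowpass_vec <- function(x, cutoff_hz, fs) {
  if (cutoff_hz >= fs / 2) {
    abort(paste0("cutoff (", cutoff_hz, " Hz) must be below Nyquist (",
                 fs / 2, " Hz)."))
  }
  bf <- signal::butter(2, cutoff_hz / (fs / 2), type = "low")
  # odd (point-reflected) end padding so the forward-backward pass carries no
  # startup transient at the trace edges
  n <- length(x)
  npad <- min(n - 1, ceiling(6 * fs / cutoff_hz))
  xp <- c(2 * x[1] - x[(npad + 1):2], x, 2 * x[n] - x[(n - 1):(n - npad)])
  y <- as.numeric(signal::filtfilt(bf, xp))
  y[(npad + 1):(npad + n)]
}
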
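# Delta-F versus strength/power/function association models, and the SDOC
# sarcopenia classifier.

#' Robust association model between delta-F and a function measure
#'
#' Fits `delta_f ~ measure * sex * intensity (+ body_mass) +
#' (1 | participant_id)` by Huber M-estimation, with motor units nested
#' within participants. Reports the per-stratum slope of delta-F on the
#' measure (one slope per sex x intensity cell, with Wald 95% CI) and
#' predictive R-squared values computed as the squared correlation between
#' observed and model-predicted outcomes: marginal (`r2m`, fixed effects
#' only) and conditional (`r2c`, fixed plus random effects).
#'
#' @param data Unit-level delta-F tibble joined to participant measures;
#'   needs `delta_f_pps`, `sex`, `intensity`, `participant_id` and the
#'   measure column.
#' @param measure Predictor column name (e.g. `"ugs_ms"`).
#' @param adjust_body_mass Add `body_mass_kg` as a covariate (used for peak
#'   torque).
#' @param config An [analysis_config()].
#' @return Object of class `picdf_assoc`: `slopes` tibble (sex, intensity,
#'   slope, conf.low, conf.high), `r2m`, `r2c`, the `rlmm` object and
#'   metadata.
#' @export
fit_association_model <- function(data, measure, adjust_body_mass = FALSE,
                                  config = analysis_config()) {
  if (!measure %in% names(data)) {
    abort(paste0("measure column `", measure, "` not found."))
  }
  n_all <- dplyr::n_distinct(data$participant_id)
  d <- data |>
    dplyr::filter(!is.na(.data$delta_f_pps), !is.na(.data[[measure]]))
  n_ok <- dplyr::n_distinct(d$participant_id)
  if (n_ok < 0.8 * n_all) {
    abort(paste0("measure `", measure, "` present for fewer than 80% of ",
                 "participants (", n_ok, "/", n_all, ")."))
  }
  if (sd(d[[measure]]) == 0) {
    abort(paste0("rank deficiency: measure `", measure, "` is constant."))
  }
  d <- d |>
    dplyr::mutate(
      .outcome = .data$delta_f_pps,
      .x = .data[[measure]],
      sex = factor(as.character(.data$sex)),
      intensity = factor(intensity_label(.data$intensity),
                         levels = c("i20", "i40", "i60"))
    ) |>
    dplyr::mutate(intensity = droplevels(.data$intensity))
  rhs <- ".x * sex * intensity"
  if (adjust_body_mass) {
    if (!"body_mass_kg" %in% names(d)) {
      abort("`body_mass_kg` required when adjust_body_mass = TRUE.")
    }
    rhs <- paste(rhs, "+ body_mass_kg")
  }
  fml <- as.formula(paste(".outcome ~", rhs, "+ (1 | participant_id)"))
  obj <- rlmm(fml, d, tuning = config$robust_tuning,
              tol = config$robust_tol, maxit = config$robust_maxit)
  fit <- obj$fit
  beta <- lme4::fixef(fit)
  V <- as.matrix(vcov(fit))

  # per-stratum slope = d(outcome)/d(.x) in each sex x intensity cell:
  # difference of the fixed-effect design rows at .x = 1 and .x = 0.
  X_terms <- terms(fit)
  strata <- expand.grid(sex = levels(d$sex), intensity = levels(d$intensity),
                        stringsAsFactors = FALSE)
  slopes <- purrr::map_dfr(seq_len(nrow(strata)), function(i) {
    base <- data.frame(sex = factor(strata$sex[i], levels(d$sex)),
                       intensity = factor(strata$intensity[i],
                                          levels(d$intensity)))
    if (adjust_body_mass) base$body_mass_kg <- mean(d$body_mass_kg)
    d1 <- base; d1$.x <- 1
    d0 <- base; d0$.x <- 0
    x <- (model.matrix(delete.response(X_terms), d1) -
            model.matrix(delete.response(X_terms), d0))[1, names(beta)]
    est <- sum(x * beta)
    se <- sqrt(drop(t(x) %*% V %*% x))
    tibble::tibble(sex = strata$sex[i], intensity = strata$intensity[i],
                   slope = est, std.error = se,
                   conf.low = est - 1.96 * se, conf.high = est + 1.96 * se)
  })

  y <- d$.outcome
  pred_fixed <- drop(model.matrix(delete.response(X_terms),
                                  obj$data)[, names(beta)] %*% beta)
  pred_cond <- fitted(fit)
  r2m <- cor(y, pred_fixed)^2
  r2c <- cor(y, pred_cond)^2
  structure(
    list(slopes = slopes, r2m = r2m, r2c = r2c, measure = measure,
         adjust_body_mass = adjust_body_mass, rlmm = obj,
         coefs = rlmm_coefs(obj), nobs = nrow(d), n_participants = n_ok),
    class = "picdf_assoc"
  )
}

#' @export
print.picdf_assoc <- function(x, ...) {
  cat("<picdf delta-F association model>\n")
  cat("  measure:", x$measure,
      if (x$adjust_body_mass) "(adjusted for body mass)\n" else "\n")
  cat(sprintf("  R2m = %.3f  R2c = %.3f   (%d units, %d participants)\n",
              x$r2m, x$r2c, x$nobs, x$n_participants))
  cat("\nSlopes per sex x intensity:\n")
  print(as.data.frame(x$slopes), digits = 3, row.names = FALSE)
  invisible(x)
}

#' SDOC sarcopenia classifier
#'
#' Applies the Sarcopenia Definitions and Outcomes Consortium cut-offs:
#' sarcopenic iff handgrip strength is below the sex-specific cut-off
#' (20 kg for females, 35.5 kg for males) AND usual gait speed is below
#' 0.8 m/s. Both criteria are required; a missing input yields `NA` with a
#' warning.
#'
#' @param sex `"female"`/`"male"` (vectorized).
#' @param handgrip_kg Handgrip strength (kg).
#' @param ugs_ms Usual gait speed (m/s).
#' @return Character vector: `"sarcopenic"` / `"not sarcopenic"`, `NA` for
#'   indeterminate rows.
#' @export
#' @examples
#' sdoc_classify("female", 18, 0.7)  # sarcopenic
#' sdoc_classify("male", 36, 0.7)    # not sarcopenic
sdoc_classify <- function(sex, handgrip_kg, ugs_ms) {
  sex <- tolower(as.character(sex))
  if (!all(sex %in% c("female", "male") | is.na(sex))) {
    abort("sex must be 'female' or 'male'.")
  }
  cut_grip <- ifelse(sex == "female", 20, 35.5)
  low_grip <- handgrip_kg < cut_grip
  slow <- ugs_ms < 0.8
  out <- ifelse(low_grip & slow, "sarcopenic", "not sarcopenic")
  miss <- is.na(sex) | is.na(handgrip_kg) | is.na(ugs_ms)
  if (any(miss)) {
    warn("missing input(s): classification indeterminate for some rows.")
    out[miss] <- NA_character_
  }
  out
}
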
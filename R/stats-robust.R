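# Robust (Huber M-estimation) linear mixed-effects models by iteratively
# reweighted lme4 fits, with estimated marginal means at balanced factor
# weights and Wald contrasts. Used for the per-bin group x intensity models
# and the delta-F association models.

huber_weights <- function(r, s, k) {
  u <- abs(r) / max(s, .Machine$double.eps)
  ifelse(u <= k, 1, k / u)
}

# Huber IRLS around lme4::lmer. Returns the final lmer fit plus trace info.
rlmm <- function(formula, data, tuning = 1.345, tol = 1e-8, maxit = 100,
                 weights_start = NULL) {
  data <- as.data.frame(data)
  w <- weights_start %||% rep(1, nrow(data))
  beta_old <- NULL
  ctrl <- lme4::lmerControl(calc.derivs = FALSE,
                            check.conv.singular = "ignore")
  fit <- NULL
  it <- 0
  converged <- FALSE
  repeat {
    it <- it + 1
    data$`..w` <- w
    fit <- suppressMessages(
      lme4::lmer(formula, data = data, weights = `..w`, REML = TRUE,
                 control = ctrl)
    )
    beta <- lme4::fixef(fit)
    if (!is.null(beta_old) &&
        max(abs(beta - beta_old)) < tol * (1 + max(abs(beta)))) {
      converged <- TRUE
      break
    }
    if (it >= maxit) break
    beta_old <- beta
    r <- resid(fit)
    s <- mad(r, center = 0)
    if (s <= 0) { converged <- TRUE; break }
    w <- huber_weights(r, s, tuning)
  }
  structure(list(fit = fit, weights = w, iterations = it,
                 converged = converged, tuning = tuning,
                 formula = formula, data = data),
            class = "picdf_rlmm")
}

# Fixed-effect table with Wald 95% CIs and t values.
rlmm_coefs <- function(obj) {
  fit <- obj$fit
  beta <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(vcov(fit))))
  tibble::tibble(
    term = names(beta), estimate = as.numeric(beta), std.error = se,
    statistic = as.numeric(beta) / se,
    conf.low = as.numeric(beta) - 1.96 * se,
    conf.high = as.numeric(beta) + 1.96 * se
  )
}

# Estimated marginal means over a factor grid, averaging the remaining
# model factors (sex) with balanced 50/50 weights.
rlmm_emm <- function(obj, spec = c("group", "intensity")) {
  fit <- obj$fit
  data <- obj$data
  X_terms <- terms(fit)
  grid <- expand.grid(lapply(spec, function(v) levels(data[[v]])),
                      stringsAsFactors = FALSE)
  names(grid) <- spec
  sexes <- levels(data$sex)
  beta <- lme4::fixef(fit)
  V <- as.matrix(vcov(fit))
  rows <- purrr::map(seq_len(nrow(grid)), function(i) {
    newd <- purrr::map_dfr(sexes, function(sx) {
      d <- grid[i, , drop = FALSE]
      d$sex <- sx
      d
    })
    # carry any numeric covariates at their mean
    num_covs <- setdiff(all.vars(obj$formula)[-1],
                        c(spec, "sex", names(lme4::ranef(fit))))
    for (v in num_covs) {
      if (v %in% names(data) && is.numeric(data[[v]])) {
        newd[[v]] <- mean(data[[v]], na.rm = TRUE)
      }
    }
    for (v in c(spec, "sex")) newd[[v]] <- factor(newd[[v]],
                                                  levels = levels(data[[v]]))
    mm <- model.matrix(delete.response(X_terms), newd)
    x <- colMeans(mm)[names(beta)]
    est <- sum(x * beta)
    se <- sqrt(drop(t(x) %*% V %*% x))
    c(emmean = est, se = se)
  })
  out <- dplyr::bind_cols(tibble::as_tibble(grid),
                          purrr::map_dfr(rows, ~tibble::tibble(
                            emmean = .x[["emmean"]], se = .x[["se"]])))
  out$conf.low <- out$emmean - 1.96 * out$se
  out$conf.high <- out$emmean + 1.96 * out$se
  out
}

#' Robust mixed-effects group model for one recruitment-threshold bin
#'
#' Fits `outcome ~ group * intensity + sex + (1 | participant_id)` by Huber
#' M-estimation (iteratively reweighted [lme4::lmer()] fits), with motor
#' units nested within participants via the random intercept. Returns fixed
#' effects with Wald 95% CIs and t values, and estimated marginal means per
#' group x intensity with sex averaged at balanced (50/50) weights.
#'
#' @param data Unit-level tibble for one bin with columns `group` (factor or
#'   character: sarcopenic/control/athlete), `intensity` (0.2/0.4/0.6 or
#'   i20/i40/i60), `sex`, `participant_id` and the outcome.
#' @param outcome Outcome column name (default `delta_f_pps`).
#' @param bin Optional bin label stored on the result.
#' @param config An [analysis_config()] supplying the Huber tuning constant,
#'   tolerance, iteration cap and the `include_age` switch.
#' @return Object of class `picdf_binfit` with elements `coefs`, `emm`,
#'   `contrasts` (Wald), the underlying `rlmm` object and metadata.
#' @export
fit_bin_model <- function(data, outcome = "delta_f_pps", bin = NULL,
                          config = analysis_config()) {
  data <- prep_model_data(data, outcome)
  if (dplyr::n_distinct(data$group) < 2) {
    abort("at least 2 groups are required.")
  }
  pp_per_group <- data |>
    dplyr::distinct(.data$group, .data$participant_id) |>
    dplyr::count(.data$group)
  if (any(pp_per_group$n < 2)) {
    abort("convergence: at least 2 participants per group are required.")
  }
  if (var(data$.outcome) == 0) {
    return(degenerate_binfit(data, outcome, bin))
  }
  rhs <- bin_rhs(data, config$include_age)
  fml <- as.formula(paste(".outcome ~", rhs, "+ (1 | participant_id)"))
  obj <- rlmm(fml, data, tuning = config$robust_tuning,
              tol = config$robust_tol, maxit = config$robust_maxit)
  emm <- rlmm_emm(obj)
  structure(
    list(coefs = rlmm_coefs(obj), emm = emm,
         contrasts = emm_wald_contrasts(obj, emm),
         rlmm = obj, outcome = outcome, bin = bin,
         nobs = nrow(data),
         n_participants = dplyr::n_distinct(data$participant_id)),
    class = "picdf_binfit"
  )
}

# model terms that are estimable on this data: interaction only when both
# factors vary, sex adjustment only when both sexes are present
bin_rhs <- function(data, include_age = FALSE) {
  rhs <- if (nlevels(droplevels(data$intensity)) >= 2) {
    "group * intensity"
  } else "group"
  if (nlevels(droplevels(data$sex)) >= 2) rhs <- paste(rhs, "+ sex")
  if (isTRUE(include_age) && "age_y" %in% names(data)) {
    rhs <- paste(rhs, "+ age_y")
  }
  rhs
}

# all-equal outcome: every non-intercept effect is exactly 0
degenerate_binfit <- function(data, outcome, bin) {
  val <- data$.outcome[1]
  rhs <- bin_rhs(data)
  mm <- model.matrix(as.formula(paste("~", rhs)), data)
  coefs <- tibble::tibble(
    term = colnames(mm),
    estimate = c(val, rep(0, ncol(mm) - 1)),
    std.error = 0, statistic = NA_real_,
    conf.low = c(val, rep(0, ncol(mm) - 1)),
    conf.high = c(val, rep(0, ncol(mm) - 1))
  )
  grid <- expand.grid(group = levels(data$group),
                      intensity = levels(droplevels(data$intensity)),
                      stringsAsFactors = FALSE)
  emm <- tibble::as_tibble(grid)
  emm$emmean <- val; emm$se <- 0; emm$conf.low <- val; emm$conf.high <- val
  gl <- levels(data$group); il <- levels(droplevels(data$intensity))
  ctr <- dplyr::bind_rows(
    tidyr::expand_grid(type = "group", at = il,
                       contrast = apply(utils::combn(gl, 2), 2,
                                        function(p) paste(p[2], "-", p[1]))),
    if (length(il) >= 2) {
      tidyr::expand_grid(type = "intensity", at = gl,
                         contrast = apply(utils::combn(il, 2), 2,
                                          function(p) paste(p[2], "-", p[1])))
    }
  )
  ctr$estimate <- 0; ctr$se <- 0; ctr$conf.low <- 0; ctr$conf.high <- 0
  structure(
    list(coefs = coefs, emm = emm, contrasts = ctr,
         rlmm = list(fit = NULL, weights = rep(1, nrow(data)),
                     iterations = 0L, converged = TRUE),
         outcome = outcome, bin = bin, nobs = nrow(data),
         n_participants = dplyr::n_distinct(data$participant_id)),
    class = "picdf_binfit"
  )
}

prep_model_data <- function(data, outcome) {
  if (!outcome %in% names(data)) {
    abort(paste0("outcome column `", outcome, "` not found."))
  }
  data <- data |>
    dplyr::filter(!is.na(.data[[outcome]])) |>
    dplyr::mutate(
      .outcome = .data[[outcome]],
      group = factor(as.character(.data$group),
                     levels = intersect(c("sarcopenic", "control", "athlete"),
                                        unique(as.character(.data$group)))),
      intensity = factor(intensity_label(.data$intensity),
                         levels = c("i20", "i40", "i60")),
      sex = factor(as.character(.data$sex))
    ) |>
    dplyr::mutate(intensity = droplevels(.data$intensity))
  data
}

intensity_label <- function(x) {
  if (is.numeric(x)) paste0("i", round(x * 100)) else as.character(x)
}

# All pairwise group differences per intensity and pairwise intensity
# differences per group, on the EMM scale, with Wald CIs via the fixed-effect
# covariance.
emm_wald_contrasts <- function(obj, emm) {
  fit <- obj$fit
  data <- obj$data
  beta <- lme4::fixef(fit)
  V <- as.matrix(vcov(fit))
  X_terms <- terms(fit)
  xrow <- function(g, i) {
    newd <- data.frame(group = factor(g, levels(data$group)),
                       intensity = factor(i, levels(data$intensity)),
                       sex = factor(levels(data$sex),
                                    levels = levels(data$sex)))
    num_covs <- setdiff(all.vars(obj$formula)[-1],
                        c("group", "intensity", "sex", "participant_id"))
    for (v in num_covs) {
      if (v %in% names(data) && is.numeric(data[[v]])) {
        newd[[v]] <- mean(data[[v]], na.rm = TRUE)
      }
    }
    colMeans(model.matrix(delete.response(X_terms), newd))[names(beta)]
  }
  rows <- list()
  gl <- levels(data$group); il <- levels(data$intensity)
  for (i in il) {
    for (a in seq_along(gl)) for (b in seq_along(gl)) {
      if (a >= b) next
      x <- xrow(gl[b], i) - xrow(gl[a], i)
      rows[[length(rows) + 1]] <- tibble::tibble(
        type = "group", at = i,
        contrast = paste(gl[b], "-", gl[a]),
        estimate = sum(x * beta),
        se = sqrt(drop(t(x) %*% V %*% x))
      )
    }
  }
  for (g in gl) {
    for (a in seq_along(il)) for (b in seq_along(il)) {
      if (a >= b) next
      x <- xrow(g, il[b]) - xrow(g, il[a])
      rows[[length(rows) + 1]] <- tibble::tibble(
        type = "intensity", at = g,
        contrast = paste(il[b], "-", il[a]),
        estimate = sum(x * beta),
        se = sqrt(drop(t(x) %*% V %*% x))
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  out$conf.low <- out$estimate - 1.96 * out$se
  out$conf.high <- out$estimate + 1.96 * out$se
  out
}

#' @export
print.picdf_binfit <- function(x, ...) {
  cat("<picdf robust mixed-effects bin model>\n")
  if (!is.null(x$bin)) cat("  bin:", as.character(x$bin), "\n")
  cat("  outcome:", x$outcome, " (", x$nobs, "units,",
      x$n_participants, "participants )\n")
  cat("  IRLS iterations:", x$rlmm$iterations,
      if (x$rlmm$converged) "(converged)\n" else "(NOT converged)\n")
  cat("\nEstimated marginal means:\n")
  print(as.data.frame(x$emm), digits = 3, row.names = FALSE)
  invisible(x)
}

#' Difference and percent difference between two estimated marginal means
#'
#' `difference = a - b`; `percent = (a - b) / b * 100`, i.e. the subtrahend
#' (second) mean is the denominator, which is the conventional
#' "relative to the comparison group" reading. `percent_of_minuend` gives the
#' alternative convention `(a - b) / a * 100`.
#'
#' @param a,b Estimated marginal means on the same scale (`b` is the
#'   comparison/subtrahend group).
#' @return One-row tibble: `difference`, `percent`, `percent_of_minuend`.
#'   With `b = 0` the percent is `NA` and a warning is raised.
#' @export
#' @examples
#' emm_difference(5.14, 4.28) # difference 0.86, percent ~20
emm_difference <- function(a, b) {
  stopifnot(is.numeric(a), is.numeric(b), length(a) == length(b))
  pct <- ifelse(b == 0, NA_real_, (a - b) / b * 100)
  if (any(b == 0)) warn("percent difference undefined for zero denominator.")
  pct_min <- ifelse(a == 0, NA_real_, (a - b) / a * 100)
  tibble::tibble(difference = a - b, percent = pct,
                 percent_of_minuend = pct_min)
}
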
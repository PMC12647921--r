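test_that("marginal-mean differences reproduce printed-precision arithmetic", {
  d <- emm_difference(5.14, 4.28)
  expect_equal(d$difference, 0.86, tolerance = 1e-9)
  expect_equal(round(d$percent), 20)
  d2 <- emm_difference(2.89, 5.14)
  expect_equal(d2$difference, -2.25, tolerance = 1e-9)
  expect_equal(emm_difference(3.3, 3.3)$difference, 0)
  expect_warning(out <- emm_difference(2, 0), "zero denominator")
  expect_true(is.na(out$percent))
  # both denominator conventions are exposed
  expect_equal(d$percent_of_minuend, 0.86 / 5.14 * 100, tolerance = 1e-9)
})

test_that("SDOC classifier implements the sex-specific cut-offs", {
  expect_equal(sdoc_classify("female", 18, 0.7), "sarcopenic")
  expect_equal(sdoc_classify("male", 36, 0.7), "not sarcopenic")
  expect_equal(sdoc_classify("female", 18, 0.9), "not sarcopenic")
  # boundary: cut-offs are strict inequalities
  expect_equal(sdoc_classify("female", 20, 0.7), "not sarcopenic")
  expect_equal(sdoc_classify("male", 35.4, 0.79), "sarcopenic")
  # vectorized + missing input flagged
  expect_warning(
    out <- sdoc_classify(c("female", "male"), c(18, NA), c(0.7, 0.7)),
    "indeterminate")
  expect_equal(out, c("sarcopenic", NA))
  expect_error(sdoc_classify("other", 20, 1), "sex")
})

test_that("robust bin model recovers a known group shift", {
  d <- synth_deltaf_table(n_per_group = 8,
                          group_effects = c(sarcopenic = -1, control = 0,
                                            athlete = 0),
                          sd_participant = 0.4, seed = 3)
  fit <- fit_bin_model(d, config = analysis_config(robust_tol = 1e-6))
  ctr <- fit$contrasts
  sc <- ctr[ctr$type == "group" & ctr$contrast == "control - sarcopenic", ]
  expect_equal(mean(sc$estimate), 1, tolerance = 0.35)
  expect_true(all(sc$conf.low > 0))
  # degenerate outcome: all equal -> all non-intercept coefficients 0
  d0 <- d
  d0$delta_f_pps <- 4
  fit0 <- fit_bin_model(d0)
  non_int <- fit0$coefs[fit0$coefs$term != "(Intercept)", ]
  expect_lt(max(abs(non_int$estimate)), 1e-8)
  # guard rails
  expect_error(fit_bin_model(d[d$group == "control", ]), "2 groups")
  d1 <- d[d$group != "sarcopenic" |
            d$participant_id == "sarcopenic1", ]
  expect_error(fit_bin_model(d1), "participants per group")
})

test_that("tidy/glance expose the fitted objects as tibbles", {
  d <- synth_deltaf_table(n_per_group = 6, seed = 5)
  fit <- fit_bin_model(d, config = analysis_config(robust_tol = 1e-6))
  expect_s3_class(tidy(fit), "tbl_df")
  expect_true(all(c("term", "estimate", "conf.low", "conf.high",
                    "statistic") %in% names(tidy(fit))))
  expect_equal(nrow(tidy(fit, "emmeans")), 9)
  expect_true(glance(fit)$converged)
})

test_that("cluster bootstrap contrasts are reproducible and cover truth", {
  d <- synth_deltaf_table(n_per_group = 6,
                          group_effects = c(control = 0, athlete = 1),
                          sd_participant = 0.3, seed = 11)
  cfg <- analysis_config(robust_tol = 1e-6)
  b1 <- bootstrap_contrasts(d, B = 200, seed = 5, config = cfg)
  b2 <- bootstrap_contrasts(d, B = 200, seed = 5, config = cfg)
  expect_identical(b1$conf.low, b2$conf.low)   # bit-for-bit under fixed seed
  expect_identical(b1$conf.high, b2$conf.high)
  ac <- b1[b1$type == "group" & b1$contrast == "athlete - control", ]
  # known location shift of 1.0 recovered within Monte-Carlo error
  expect_equal(mean(ac$estimate), 1, tolerance = 0.35)
  expect_true(all(ac$conf.low <= 1 & ac$conf.high >= 1))
  expect_error(bootstrap_contrasts(d, B = 50), "at least 200")
})

test_that("bootstrap interval covers 0 for identical groups", {
  d <- synth_deltaf_table(n_per_group = 6,
                          group_effects = c(control = 0, athlete = 0),
                          seed = 13)
  b <- bootstrap_contrasts(d, B = 200, seed = 2,
                           config = analysis_config(robust_tol = 1e-6))
  ac <- b[b$type == "group", ]
  expect_true(all(ac$conf.low <= 0 & ac$conf.high >= 0))
})

test_that("association model separates fixed-effect and random-effect fits", {
  cfg <- analysis_config(robust_tol = 1e-6)
  set.seed(21)
  # outcome a pure function of the predictor: R2m ~ R2c, both high
  base <- synth_deltaf_table(n_per_group = 8, sd_participant = 0,
                             sd_unit = 0.01, seed = 21)
  meas <- tibble::tibble(participant_id = unique(base$participant_id),
                         ugs_ms = runif(length(unique(base$participant_id)),
                                        0.6, 1.6))
  d <- dplyr::left_join(base, meas, by = "participant_id")
  d$delta_f_pps <- 1 + 2 * d$ugs_ms + rnorm(nrow(d), 0, 0.05)
  fit <- fit_association_model(d, "ugs_ms", config = cfg)
  expect_equal(fit$r2m, fit$r2c, tolerance = 0.02)
  expect_gt(fit$r2m, 0.9)
  expect_equal(mean(fit$slopes$slope), 2, tolerance = 0.1)
  # outcome independent of the predictor, strong participant intercepts:
  # R2m ~ 0, R2c large
  d2 <- dplyr::left_join(
    synth_deltaf_table(n_per_group = 8, sd_participant = 2, sd_unit = 0.3,
                       seed = 22),
    meas, by = "participant_id")
  fit2 <- fit_association_model(d2, "ugs_ms", config = cfg)
  expect_lt(fit2$r2m, 0.2)
  expect_gt(fit2$r2c, 0.7)
  # nesting property on both fits
  expect_gte(fit$r2c, fit$r2m - 1e-6)
  expect_gte(fit2$r2c, fit2$r2m)
  expect_true(all(c(fit$r2m, fit$r2c, fit2$r2m, fit2$r2c) >= 0))
  expect_true(all(c(fit$r2m, fit$r2c, fit2$r2m, fit2$r2c) <= 1))
  # constant predictor -> rank-deficiency error
  d3 <- d
  d3$ugs_ms <- 1
  expect_error(fit_association_model(d3, "ugs_ms"), "constant")
  # missing for too many participants -> error
  d4 <- d
  d4$ugs_ms[d4$participant_id %in% unique(d4$participant_id)[1:8]] <- NA
  expect_error(fit_association_model(d4, "ugs_ms"), "80%")
})

test_that("body-mass adjustment enters the peak-torque association model", {
  set.seed(31)
  base <- synth_deltaf_table(n_per_group = 8, seed = 31)
  ids <- unique(base$participant_id)
  meas <- tibble::tibble(participant_id = ids,
                         peak_torque_nm = runif(length(ids), 10, 30),
                         body_mass_kg = runif(length(ids), 55, 90))
  d <- dplyr::left_join(base, meas, by = "participant_id")
  fit <- fit_association_model(d, "peak_torque_nm", adjust_body_mass = TRUE,
                               config = analysis_config(robust_tol = 1e-6))
  expect_true("body_mass_kg" %in% fit$coefs$term)
  expect_equal(nrow(fit$slopes), 6)   # 2 sexes x 3 intensities
})
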
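test_that("no injected hysteresis means symmetric recruit/derecruit torques", {
  p <- pool_params(isi_cv = 0, dtheta_mean = 0)
  sim <- simulate_trial(0.2, p, seed = 1, keep_all = TRUE)
  expect_equal(sim$truth$derecruit_pct, sim$truth$recruit_pct)
  # observed spike trains are time-symmetric about the ramp apex (10 s)
  by_unit <- split(sim$spikes$spike_time_s, sim$spikes$unit_id)
  asym <- vapply(by_unit, function(st) abs((st[1] + max(st)) / 2 - 10),
                 numeric(1))
  expect_lt(max(asym), 0.2)
})

test_that("first spike lands where the ramp crosses the threshold", {
  p <- pool_params(isi_cv = 0)
  sim <- simulate_trial(0.2, p, seed = 3, keep_all = TRUE)
  tr <- sim$truth
  for (uid in unique(sim$spikes$unit_id)) {
    st <- sim$spikes$spike_time_s[sim$spikes$unit_id == uid]
    i <- match(uid, tr$unit_id)
    expect_equal(st[1], tr$theta[i] / 2, tolerance = 1e-6)
  }
  # the worked case: theta = 10 %MVT on an i20 ramp (2 %MVT/s) -> 5.0 s
  u <- tr[which.min(abs(tr$theta - 10)), ]
  st <- sim$spikes$spike_time_s[sim$spikes$unit_id == u$unit_id]
  expect_equal(st[1], u$theta / 2, tolerance = 1e-6)
})

test_that("analytic delta-F oracle matches its closed forms", {
  ctl <- list(theta = 5, dtheta = 0, gain = 0.5, rate_min = 5, rate_sat = 30)
  # no test hysteresis -> 0
  expect_equal(analytic_deltaf(ctl, list(theta = 15, dtheta = 0)), 0)
  # unsaturated: gain_c * dtheta_t
  expect_equal(analytic_deltaf(ctl, list(theta = 15, dtheta = 4)), 2.0)
  # control saturated across the whole test window -> 0
  ctl_sat <- list(theta = 1, dtheta = 0, gain = 2, rate_min = 5, rate_sat = 8)
  expect_equal(analytic_deltaf(ctl_sat, list(theta = 15, dtheta = 4)), 0)
  # control not active across the test window -> NA, flagged
  ctl_late <- list(theta = 14, dtheta = 0, gain = 0.5, rate_min = 5,
                   rate_sat = 30)
  out <- analytic_deltaf(ctl_late, list(theta = 15, dtheta = 4))
  expect_true(is.na(out))
  expect_match(attr(out, "reason"), "not active")
  # brute-force check of the oracle from the rate model itself
  rate <- function(D) pmin(5 + 0.5 * (D - 5), 30)
  expect_equal(analytic_deltaf(ctl, list(theta = 15, dtheta = 4)),
               rate(15) - rate(11))
})

test_that("analytic delta-F increases strictly over a hysteresis sweep", {
  ctl <- list(theta = 5, dtheta = 2, gain = 0.4, rate_min = 6, rate_sat = 30)
  vals <- vapply(0:6, function(dt) {
    analytic_deltaf(ctl, list(theta = 15, dtheta = dt))
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("simulation is deterministic under a fixed seed", {
  ds1 <- simulate_cohort(group_sizes = c(control = 2), intensities = 0.2,
                         seed = 8)
  ds2 <- simulate_cohort(group_sizes = c(control = 2), intensities = 0.2,
                         seed = 8)
  expect_identical(as.data.frame(ds1$spikes), as.data.frame(ds2$spikes))
  expect_identical(as.data.frame(ds1$torque), as.data.frame(ds2$torque))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_mu_dataset(ds1, d1); write_mu_dataset(ds2, d2)
  for (f in c("spikes.csv", "torque.csv", "participants.csv")) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
})

test_that("units recruit in threshold order on the ascending ramp", {
  p <- pool_params(isi_cv = 0.1)
  sim <- simulate_trial(0.4, p, seed = 12, keep_all = TRUE)
  first_spike <- vapply(split(sim$spikes$spike_time_s, sim$spikes$unit_id),
                        min, numeric(1))
  tr <- sim$truth[match(names(first_spike), sim$truth$unit_id), ]
  expect_equal(order(first_spike), order(tr$theta))
})

test_that("group profiles shape the ground-truth delta-F pattern", {
  prof <- group_profiles()
  mean_oracle <- function(g, int, seed) {
    row <- prof[prof$group == g, ]
    mult <- row[[paste0("mult_i", int * 100)]]
    p <- pool_params(isi_cv = 0)
    sim <- simulate_trial(int, p,
                          dtheta_scale = row$dtheta_base * mult / p$dtheta_mean,
                          seed = seed, keep_all = TRUE)
    or <- oracle_pairs(sim$truth, decomposed_only = FALSE)
    mean(or$deltaf_true[or$eligible_true])
  }
  # sarcopenic: flat across intensities (by construction)
  s <- vapply(c(0.2, 0.4, 0.6), function(i) mean_oracle("sarcopenic", i, 21),
              numeric(1))
  expect_lt(max(s) - min(s), 0.35 * mean(s))
  # athlete > control at i60
  expect_gt(mean_oracle("athlete", 0.6, 22), mean_oracle("control", 0.6, 22))
})

test_that("a pool with no recruitable unit warns and returns no spikes", {
  p <- pool_params(n_units = 3)
  expect_warning(
    sim <- simulate_trial(0.2, pool_params(n_units = 2, yield_base = -1),
                          seed = 1),
    "no unit recruited"
  )
  expect_equal(nrow(sim$spikes), 0)
})
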
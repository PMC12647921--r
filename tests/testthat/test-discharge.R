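test_that("instantaneous rates are reciprocal inter-spike intervals", {
  r <- instantaneous_rates(c(0, 0.1, 0.2))
  expect_equal(r$rate, c(10, 10))
  expect_equal(r$time, c(0.1, 0.2))
  expect_equal(instantaneous_rates(c(0, 0.5))$rate, 2)
  expect_error(instantaneous_rates(1.5), "at least 2")
  expect_error(instantaneous_rates(c(1, 1, 2)), "strictly increasing")
  # noise-free simulator unit: rates within 1% of the model rate at interval
  # midpoints
  p <- pool_params(isi_cv = 0)
  sim <- simulate_trial(0.2, p, seed = 3, keep_all = TRUE)
  tr <- sim$truth
  uid <- tr$unit_id[which.min(abs(tr$theta - 8))]
  st <- sim$spikes$spike_time_s[sim$spikes$unit_id == uid]
  ir <- instantaneous_rates(st)
  i <- match(uid, tr$unit_id)
  mid <- ir$time - diff(st) / 2
  drive <- ifelse(mid <= 10, 2 * mid, 2 * (20 - mid))
  model <- pmin(p$rate_min + tr$gain[i] *
                  (drive - (tr$theta[i] - tr$dtheta[i])), p$rate_sat)
  expect_lt(max(abs(ir$rate - model) / model), 0.01)
})

test_that("SVR smoothing: constant in, constant out; linear tracked closely", {
  tt <- seq(0, 12, by = 0.1)
  sm <- smooth_discharge(tt, rep(10, length(tt)))
  expect_equal(unique(sm$rate), 10)
  # noiseless linear ramp of rates stays within 0.2 pps of the line
  rr <- 7 + 0.5 * tt
  sm2 <- smooth_discharge(tt, rr)
  expect_lt(max(abs(rate_at(sm2, sm2$time) - (7 + 0.5 * sm2$time))), 0.2)
  expect_error(smooth_discharge(1:3, 1:3), "at least 4")
})

test_that("smoothing a noisy simulator unit stays near the model rate", {
  p <- pool_params(isi_cv = 0.1)
  sim <- simulate_trial(0.2, p, seed = 42, keep_all = TRUE)
  tr <- sim$truth
  counts <- table(sim$spikes$unit_id)
  uid <- names(which.max(counts))
  st <- sim$spikes$spike_time_s[sim$spikes$unit_id == uid]
  ir <- instantaneous_rates(st)
  sm <- smooth_discharge(ir$time - diff(st) / 2, ir$rate,
                         t_range = range(st))
  i <- match(uid, tr$unit_id)
  g <- seq(min(st), max(st), by = 0.05)
  drive <- ifelse(g <= 10, 2 * g, 2 * (20 - g))
  model <- pmin(p$rate_min + tr$gain[i] *
                  (drive - (tr$theta[i] - tr$dtheta[i])), p$rate_sat)
  rmse <- sqrt(mean((rate_at(sm, g) - model)^2))
  expect_lt(rmse, 0.5)
})

test_that("smoothed curve is invariant to time-origin shifts", {
  tt <- seq(0, 10, by = 0.11)
  rr <- 8 + 3 * sin(tt / 2)
  sm0 <- smooth_discharge(tt, rr)
  sm1 <- smooth_discharge(tt + 137.5, rr)
  expect_equal(sm1$rate, sm0$rate, tolerance = 1e-8)
  # and no extrapolation beyond the active interval
  expect_true(is.na(rate_at(sm0, -1)))
  expect_true(is.na(rate_at(sm0, 11)))
})

test_that("unit events read thresholds off the ramp and peak off the curve", {
  ds <- tiny_dataset()
  tq <- ds$torque
  # first spike at 5.0 s on an i20 ramp -> recruitment threshold 10 %MVT
  st <- seq(5, 15, by = 0.1)
  sm <- synthetic_smoothed(5, 15, function(t) rep(10, length(t)))
  ev <- unit_events(st, sm, tq, mvt_nm = 30)
  expect_equal(ev$rt_pct, 10, tolerance = 1e-6)
  expect_equal(ev$derecruit_pct, 10, tolerance = 1e-6)
  expect_equal(ev$peak_dr_pps, 10)   # constant curve -> peak 10
  expect_error(unit_events(c(-1, 5), sm, tq, 30), "cover")
  # simulator unit with known threshold recovered within 0.5 %MVT
  p <- pool_params(isi_cv = 0)
  sim <- simulate_trial(0.2, p, seed = 6, keep_all = TRUE)
  dsim <- trial_as_dataset(sim)
  units <- prepare_units(dsim)
  tr <- sim$truth[match(units$unit_id, sim$truth$unit_id), ]
  expect_lt(max(abs(units$rt_pct - tr$theta)), 0.5)
})

test_that("recruitment-threshold bins partition (0, 60] as specified", {
  expect_equal(as.character(assign_rt_bin(10)), "rt0-20")
  expect_equal(as.character(assign_rt_bin(20.0)), "rt0-20")  # <= 20
  expect_equal(as.character(assign_rt_bin(20.5)), "rt20-40") # > 20
  expect_equal(as.character(assign_rt_bin(40.5)), "rt40-60") # > 40, <= 60
  expect_true(is.na(assign_rt_bin(61)))                      # above ceiling
  expect_error(assign_rt_bin(-2), "negative")
  # partition property: every threshold in (0, 60] maps to exactly one bin
  set.seed(5)
  x <- runif(500, 0.001, 60)
  b <- assign_rt_bin(x)
  expect_false(any(is.na(b)))
  expect_equal(as.integer(b), findInterval(x, c(0, 20, 40, 60),
                                           left.open = TRUE))
})

test_that("peak of the smoothed curve does not overshoot the rate points", {
  p <- pool_params(isi_cv = 0.1)
  sim <- simulate_trial(0.2, p, seed = 31)
  dsim <- trial_as_dataset(sim)
  units <- prepare_units(dsim)
  max_inst <- vapply(units$spike_times, function(st) max(1 / diff(st)),
                     numeric(1))
  expect_true(all(units$peak_dr_pps <= max_inst + 1.0))
})
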
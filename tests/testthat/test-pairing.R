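# helper: build an mu_units-like table from synthetic curves
fake_units <- function(...) {
  rows <- list(...)
  tibble::tibble(
    unit_id = vapply(rows, `[[`, character(1), "id"),
    rt_pct = vapply(rows, `[[`, numeric(1), "rt"),
    t_recruit = vapply(rows, function(r) attr(r$sm, "t_range")[1], numeric(1)),
    t_derecruit = vapply(rows, function(r) attr(r$sm, "t_range")[2], numeric(1)),
    smoothed = lapply(rows, `[[`, "sm")
  )
}

test_that("eligibility criteria flag the failing condition", {
  ramp <- function(a, b) function(t) a + b * (t - min(t))
  # control recruited after test -> criterion (b) fails
  u <- fake_units(
    list(id = "c", rt = 5,
         sm = synthetic_smoothed(6, 18, function(t) 8 + 0.5 * sin(t))),
    list(id = "t", rt = 12,
         sm = synthetic_smoothed(5.5, 15, function(t) 7 + 0.5 * sin(t)))
  )
  pr <- eligible_pairs(u)
  row <- pr[pr$control_id == "c" & pr$test_id == "t", ]
  expect_false(row$eligible)
  expect_false(row$crit_b)
  # control derecruited before the test unit -> criterion (c) fails
  u2 <- fake_units(
    list(id = "c", rt = 5,
         sm = synthetic_smoothed(2, 14, function(t) 8 + sin(t / 2))),
    list(id = "t", rt = 12,
         sm = synthetic_smoothed(5, 15, function(t) 7 + sin(t / 2)))
  )
  pr2 <- eligible_pairs(u2)
  row2 <- pr2[pr2$control_id == "c" & pr2$test_id == "t", ]
  expect_false(row2$eligible)
  expect_false(row2$crit_c)
  # flat control -> modulation criterion (d) fails
  u3 <- fake_units(
    list(id = "c", rt = 5,
         sm = synthetic_smoothed(2, 18, function(t) rep(9, length(t)))),
    list(id = "t", rt = 12,
         sm = synthetic_smoothed(5, 15, function(t) 7 + sin(t / 2)))
  )
  pr3 <- eligible_pairs(u3)
  row3 <- pr3[pr3$control_id == "c" & pr3$test_id == "t", ]
  expect_false(row3$crit_d)
})

test_that("eligibility matches a brute-force enumeration on simulated data", {
  p <- pool_params(isi_cv = 0.1)
  sim <- simulate_trial(0.2, p, seed = 14)
  ds <- trial_as_dataset(sim)
  units <- prepare_units(ds)
  cfg <- analysis_config()
  pr <- eligible_pairs(units, cfg$sep_min, cfg$mod_min, cfg$r_min)
  # independent re-derivation of all five criteria
  for (k in sample.int(nrow(pr), min(nrow(pr), 120))) {
    ci <- match(pr$control_id[k], units$unit_id)
    ti <- match(pr$test_id[k], units$unit_id)
    c_sm <- units$smoothed[[ci]]; t_sm <- units$smoothed[[ti]]
    a <- units$rt_pct[ci] < units$rt_pct[ti]
    b <- units$t_recruit[ti] - units$t_recruit[ci] >= cfg$sep_min
    cc <- units$t_derecruit[ci] > units$t_derecruit[ti]
    w <- c_sm$rate[c_sm$time >= units$t_recruit[ti] &
                     c_sm$time <= units$t_derecruit[ti]]
    d <- length(w) > 1 && (max(w) - min(w)) >= cfg$mod_min
    lo <- max(units$t_recruit[ci], units$t_recruit[ti])
    hi <- min(units$t_derecruit[ci], units$t_derecruit[ti])
    e <- FALSE
    if (hi > lo) {
      g <- seq(lo, hi, by = 0.01)
      r <- cor(rate_at(c_sm, g), rate_at(t_sm, g), use = "complete.obs")
      e <- !is.na(r) && r >= cfg$r_min
    }
    expect_equal(pr$eligible[k], a && b && cc && d && e)
  }
  # antisymmetry: (c, t) eligible implies (t, c) ineligible via criterion (a)
  el <- pr[pr$eligible, ]
  for (k in seq_len(nrow(el))) {
    rev <- pr[pr$control_id == el$test_id[k] & pr$test_id == el$control_id[k], ]
    expect_false(rev$eligible)
    expect_false(rev$crit_a)
  }
})

test_that("pair delta-F is the control-rate drop over the test window", {
  # constant control curve -> 0
  cs <- synthetic_smoothed(0, 20, function(t) rep(11, length(t)))
  ev <- tibble::tibble(t_recruit = 6, t_derecruit = 14)
  expect_equal(pair_deltaf(cs, ev), 0)
  # 12 pps at recruitment, 9 at derecruitment -> 3
  cs2 <- synthetic_smoothed(0, 20, function(t) 12 - 3 * (t - 6) / 8)
  expect_equal(pair_deltaf(cs2, ev), 3, tolerance = 1e-9)
  # control curve undefined at a test time -> NA
  cs3 <- synthetic_smoothed(7, 20, function(t) rep(10, length(t)))
  expect_true(is.na(pair_deltaf(cs3, ev)))
})

test_that("per-unit delta-F averages eligible controls", {
  pr <- tibble::tibble(test_id = c("t1", "t1", "t2", "t3"),
                       eligible = c(TRUE, TRUE, TRUE, FALSE),
                       delta_f_pps = c(2, 4, 2.5, 9))
  out <- unit_deltaf(pr)
  expect_equal(out$delta_f_pps[out$test_id == "t1"], 3)
  expect_equal(out$n_controls[out$test_id == "t1"], 2L)
  expect_equal(out$delta_f_pps[out$test_id == "t2"], 2.5)
  expect_false("t3" %in% out$test_id)  # no eligible pair -> no delta-F
})

test_that("dataset-level delta-F equals brute-force recomputation", {
  p <- pool_params(isi_cv = 0.1)
  ds <- simulate_cohort(group_sizes = c(control = 2), intensities = 0.2,
                        seed = 17)
  df <- compute_deltaf(ds)
  pairs <- attr(df, "pairs")
  brute <- pairs[pairs$eligible & !is.na(pairs$delta_f_pps), ]
  brute_means <- tapply(brute$delta_f_pps,
                        paste(brute$participant_id, brute$test_id),
                        mean)
  got <- setNames(df$delta_f_pps, paste(df$participant_id, df$unit_id))
  expect_equal(sort(names(got)), sort(names(brute_means)))
  expect_equal(got[names(brute_means)], brute_means, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("estimated pair delta-F tracks the analytic oracle", {
  # noise-free: every matched eligible pair within 0.2 pps of the oracle
  ds <- simulate_cohort(group_sizes = c(control = 2),
                        params = pool_params(isi_cv = 0),
                        intensities = 0.2, seed = 11)
  df <- compute_deltaf(ds)
  pairs <- attr(df, "pairs")
  pairs <- pairs[pairs$eligible, ]
  gt <- attr(ds, "ground_truth")
  or <- dplyr::bind_rows(lapply(split(gt, gt$participant_id), function(g) {
    dplyr::mutate(oracle_pairs(g), participant_id = g$participant_id[1])
  }))
  m <- dplyr::inner_join(pairs, or[or$eligible_true, ],
                         by = c("participant_id", "control_id", "test_id"))
  expect_gt(nrow(m), 100)
  expect_lt(max(abs(m$delta_f_pps - m$deltaf_true)), 0.2)
})
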
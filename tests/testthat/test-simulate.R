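test_that("dynamics honor fixed points, identity and dose arithmetic", {
  cfg <- sim_config("K", reversion_rate = 0.5, illness_drift = -0.25)
  cat_k <- action_catalog("K")
  none <- which(cat_k$route == "NONE")
  attractor <- cfg$setpoint + cfg$illness_drift
  expect_equal(step_dynamics(attractor, none, cfg, noise = 0), attractor)

  cfg0 <- sim_config("K", reversion_rate = 0)
  expect_equal(step_dynamics(3.1, none, cfg0, noise = 0), 3.1)

  cfg2 <- sim_config("K", reversion_rate = 0, po_effect_per_unit = 0.2)
  po2 <- which(cat_k$route == "PO" & cat_k$po_level == 2L)
  expect_equal(step_dynamics(3.0, po2, cfg2, noise = 0), 3.4)

  expect_error(step_dynamics(NaN, none, cfg), "finite")
  expect_error(step_dynamics(3, none, cfg, noise = Inf), "finite")
})

test_that("behavior policy branches are exact at probability 0 and 1", {
  cat_k <- action_catalog("K")
  b0 <- behavior_config(replete_threshold = 3.5, over_replete_prob = 0)
  set.seed(1)
  expect_identical(cat_k$route[behavior_action(4.5, b0, cat_k)], "NONE")

  b1 <- behavior_config(replete_threshold = 3.5, over_replete_prob = 1,
                        iv_prob_given_replete = 1)
  for (lev in c(2.8, 4.0, 5.5)) {
    expect_identical(cat_k$route[behavior_action(lev, b1, cat_k)], "IV")
  }
  expect_error(behavior_action(4, b0, cat_k[0, ]), "NONE")
})

test_that("over-repletion frequency matches its configured probability", {
  cat_k <- action_catalog("K")
  b <- behavior_config(replete_threshold = 3.5, over_replete_prob = 0.3)
  set.seed(99)
  acts <- replicate(10000, behavior_action(4.2, b, cat_k))
  frac <- mean(cat_k$route[acts] != "NONE")
  expect_lt(abs(frac - 0.3), 0.02)
})

test_that("simulated cohorts are byte-identical under a fixed seed", {
  cfg <- sim_config("K", n_visits = 5, rng_seed = 123)
  t1 <- simulate_cohort(cfg)
  t2 <- simulate_cohort(cfg)
  expect_identical(t1$static, t2$static)
  expect_identical(t1$observations, t2$observations)
  expect_identical(t1$medications, t2$medications)
  d1 <- tempfile(); d2 <- tempfile()
  write_ehr(t1, d1); write_ehr(t2, d2)
  for (f in c("static.csv", "observations.csv", "medications.csv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  expect_error(sim_config("K", horizon_hours = 18), "24")
})

test_that("measurement_prob = 1 puts an electrolyte lab in every bin", {
  cfg <- sim_config("K", n_visits = 4, measurement_prob = 1, rng_seed = 5)
  tabs <- simulate_cohort(cfg)
  for (vid in tabs$static$visit_id) {
    o <- tabs$observations
    o <- o[o$visit_id == vid & o$variable == "K", ]
    n_bins <- tabs$static$los_hours[tabs$static$visit_id == vid] / 6
    expect_setequal(unique(floor(o$time_hours / 6)), seq_len(n_bins) - 1L)
  }
})

test_that("stronger illness drift yields more below-range measurements", {
  b_none <- behavior_config(replete_threshold = 0, over_replete_prob = 0)
  cfg_sick <- sim_config("K", n_visits = 60, illness_drift = -0.4,
                         rng_seed = 11)
  cfg_well <- sim_config("K", n_visits = 60, illness_drift = 0, rng_seed = 11)
  frac_below <- function(cfg) {
    o <- simulate_cohort(cfg, b_none)$observations
    k <- o[o$variable == "K", "value"]
    mean(k < cfg$reference_range[1L])
  }
  expect_gt(frac_below(cfg_sick), frac_below(cfg_well))
})

test_that("untreated noiseless levels converge monotonically to the attractor", {
  cfg <- sim_config("K", noise_sd = 0)
  cat_k <- action_catalog("K")
  none <- which(cat_k$route == "NONE")
  attractor <- cfg$setpoint + cfg$illness_drift
  lev <- 2.5
  gaps <- numeric(20)
  for (t in 1:20) {
    gaps[t] <- attractor - lev
    lev <- step_dynamics(lev, none, cfg, noise = 0)
  }
  expect_true(all(diff(gaps) < 0))        # gap shrinks
  expect_true(all(gaps > 0))              # never overshoots
})

test_that("regression on no-action transitions recovers the reversion rate", {
  cfg <- sim_config("K", n_visits = 900, rng_seed = 21)
  b_none <- behavior_config(replete_threshold = 0, over_replete_prob = 0)
  log <- attr(simulate_cohort(cfg, b_none), "log")
  gap <- (cfg$setpoint + cfg$illness_drift) - log$level
  dl <- log$next_level - log$level
  est <- stats::coef(stats::lm(dl ~ gap - 1))[[1]]
  expect_gt(length(gap), 5000)
  expect_lt(abs(est - cfg$reversion_rate), 0.05)
})
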
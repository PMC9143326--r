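test_that("frequency analysis is exact at the identity and boundary policies", {
  imp <- make_imputed(n_visits = 20, rng_seed = 19)
  tr <- build_transitions(imp, mdp_spec("K"))
  K <- nrow(tr$spec$catalog)

  # policy that replays the logged actions -> 0% change, identical histograms
  fr <- frequency_analysis(tr, function(states) tr$action)
  expect_equal(fr$repletion_change_pct, 0)
  expect_identical(fr$counts$historical, fr$counts$policy)
  expect_identical(fr$po_levels$historical, fr$po_levels$policy)

  # never-repleting policy -> -100%
  none <- which(tr$spec$catalog$route == "NONE")
  fr2 <- frequency_analysis(tr, function(states) rep(none, nrow(states)))
  expect_equal(fr2$repletion_change_pct, -100)

  # counts conserve the number of test states in both columns
  expect_identical(sum(fr2$counts$historical), fr2$n_states)
  expect_identical(sum(fr2$counts$policy), fr2$n_states)
  # route-mix shares sum to one
  expect_equal(colSums(fr2$route_mix[, c("historical", "policy")]),
               c(historical = 1, policy = 1))

  # zero historical repletions -> undefined percent change
  tr0 <- tr
  tr0$action <- rep(none, length(tr0$action))
  fr3 <- frequency_analysis(tr0, function(states) rep(none, nrow(states)))
  expect_true(is.na(fr3$repletion_change_pct))
})

test_that("pre/post distributions respect the observed mask and range logic", {
  rng <- c(3.5, 5.0)
  # one repletion at a measured below-range level; next measurement in range
  meds <- data.frame(visit_id = "V1", start_hours = 13, end_hours = 15,
                     drug = "K-IV", dose = 20, route = "IV")
  v <- fixture_visit(times = c(2, 13.5, 21), values = c(3.8, 3.1, 4.0),
                     los = 30, meds = meds)
  binned <- impute_cohort(bin_visits(as_cohort(v)))
  pp <- pre_post_distribution(binned, "K", rng)
  expect_identical(pp$n_events, 1L)
  expect_equal(pp$pre, 3.1)
  expect_equal(pp$post, 4.0)
  expect_equal(pp$frac_within_or_above, 0)
  expect_equal(pp$frac_below, 1)

  # all repletions initiated above range -> above fraction 1
  meds2 <- data.frame(visit_id = "V1", start_hours = c(1, 13), end_hours = c(3, 15),
                      drug = "K-IV", dose = 20, route = "IV")
  v2 <- fixture_visit(times = c(0.5, 12.5, 20), values = c(5.6, 5.8, 5.1),
                      los = 30, meds = meds2)
  pp2 <- pre_post_distribution(impute_cohort(bin_visits(as_cohort(v2))), "K", rng)
  expect_equal(pp2$frac_above, 1)
  expect_equal(pp2$frac_within_or_above, 1)
  # complementary fractions partition the events
  expect_equal(pp2$frac_within_or_above + pp2$frac_below, 1)

  # imputed (non-measured) cells never provide the pre or post value:
  # the only measurement after infusion end is at hour 21, despite the
  # imputed cells in between
  expect_equal(pp$post, 4.0)
})

test_that("simulated over-repletion shows up in the within-or-above fraction", {
  bcfg <- behavior_config(over_replete_prob = 0.3)
  cfg <- sim_config("K", n_visits = 250, measurement_prob = 1, rng_seed = 23)
  imp <- make_imputed(cfg = cfg, bcfg = bcfg)
  pp <- pre_post_distribution(imp, "K", cfg$reference_range)
  # expectation computed from the simulator's own event log
  log <- attr(simulate_cohort(cfg, bcfg), "log")
  cat_k <- action_catalog("K")
  rep_evt <- cat_k$route[log$action] != "NONE"
  expected <- mean(log$level[rep_evt] >= cfg$reference_range[1L])
  expect_lt(abs(pp$frac_within_or_above - expected), 0.03)
})

test_that("trajectory overlays align actions, levels and infusion spans", {
  spec <- mdp_spec("K")
  # no repletions anywhere and a never-repleting policy -> empty action columns
  v0 <- fixture_visit(times = c(1, 7, 13), values = c(4, 4.1, 4.2), los = 18)
  bv0 <- impute_cohort(bin_visits(as_cohort(v0)))[[1L]]
  none <- which(spec$catalog$route == "NONE")
  ov0 <- trajectory_overlay(bv0, function(states) rep(none, nrow(states)), spec)
  expect_true(all(ov0$historical_action == ""))
  expect_true(all(ov0$policy_action == ""))

  # historical IV K 40 mEq / 2 h starting in bin 3 spans hours 18-20
  meds <- data.frame(visit_id = "V1", start_hours = 18.5, end_hours = 20.5,
                     drug = "K-IV", dose = 40, route = "IV")
  v <- fixture_visit(times = c(1, 7, 13, 19, 25), values = c(4, 4, 4, 3.2, 3.9),
                     los = 30, meds = meds)
  bv <- impute_cohort(bin_visits(as_cohort(v)))[[1L]]
  ov <- trajectory_overlay(bv, function(states) rep(none, nrow(states)), spec)
  expect_identical(ov$historical_action[4L], "IV5")
  expect_equal(ov$hist_iv_start[4L], 18)
  expect_equal(ov$hist_iv_end[4L], 20)
  expect_true(all(is.na(ov$hist_iv_start[-4L])))
  # measured levels pass through; nothing imputed here
  expect_equal(ov$measured_level, c(4, 4, 4, 3.2, 3.9))
})

test_that("a policy that treats hypokalemia acts within the deficient episode", {
  # strongly deficient visit; a threshold policy on the current level
  meds <- NULL
  v <- fixture_visit(times = c(1, 7, 13, 19), values = c(2.9, 3.0, 3.1, 3.2),
                     los = 24)
  bv <- impute_cohort(bin_visits(as_cohort(v)))[[1L]]
  spec <- mdp_spec("K")
  po3 <- which(spec$catalog$route == "PO" & spec$catalog$po_level == 3L)
  none <- which(spec$catalog$route == "NONE")
  thresh_pol <- function(states) {
    ifelse(states[, "K"] < 3.5, po3, none)
  }
  ov <- trajectory_overlay(bv, thresh_pol, spec)
  expect_true(all(ov$policy_action == "PO3"))
})
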
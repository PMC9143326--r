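test_that("event costs follow the documented arithmetic", {
  cat_k <- action_catalog("K")
  model <- fixture_cost_model()
  none <- which(cat_k$route == "NONE")
  expect_equal(event_cost(none, model, cat_k)$total, 0)

  # PO1: drug 2.00 + nurse 5 min at 60/h + one lab (10.00 + phlebotomist
  # 5 min at 36/h) = 20.00
  po1 <- which(cat_k$route == "PO" & cat_k$po_level == 1L)
  ec <- event_cost(po1, model, cat_k)
  expect_equal(ec$drug, 2)
  expect_equal(ec$staff, 5 + 3)
  expect_equal(ec$lab, 10)
  expect_equal(ec$total, 20)

  # wages and labs zeroed out leaves the drug cost alone
  m0 <- fixture_cost_model()
  m0$wage_per_hour[] <- 0
  m0$labs_per_repletion <- 0
  expect_equal(event_cost(po1, m0, cat_k)$total, 2)

  # combination actions sum their PO and IV components
  both11 <- which(cat_k$route == "BOTH" & cat_k$po_level == 1L &
                    cat_k$iv_level == 1L)
  iv1 <- which(cat_k$route == "IV" & cat_k$iv_level == 1L)
  eb <- event_cost(both11, model, cat_k)
  expect_equal(eb$drug,
               event_cost(po1, model, cat_k)$drug +
                 event_cost(iv1, model, cat_k)$drug)
  # shared tasks (ordering, labs) are counted once per event
  expect_equal(eb$lab, 10)

  # a dose level without a configured price names the gap
  m_bad <- fixture_cost_model()
  m_bad$iv_drug_cost <- m_bad$iv_drug_cost[1:2]
  iv5 <- which(cat_k$route == "IV" & cat_k$iv_level == 5L)
  expect_error(event_cost(iv5, m_bad, cat_k), "dose level 5")
})

test_that("cohort comparison reproduces hand-computed savings", {
  cat_k <- action_catalog("K")
  model <- fixture_cost_model()
  po1 <- which(cat_k$route == "PO" & cat_k$po_level == 1L)
  iv1 <- which(cat_k$route == "IV" & cat_k$iv_level == 1L)
  none <- which(cat_k$route == "NONE")

  # 2 visits, 4 decision points: historical {IV, PO, NONE, IV},
  # policy {NONE, PO, NONE, NONE}
  hist <- c(iv1, po1, none, iv1)
  pol <- c(none, po1, none, none)
  rep_cost_iv <- event_cost(iv1, model, cat_k)$total
  rep <- cohort_cost_comparison(hist, pol, model, cat_k, n_visits = 2)
  expect_equal(rep$savings, 2 * rep_cost_iv)
  expect_equal(rep$savings_per_visit, rep_cost_iv)
  # itemized components sum exactly to the totals
  expect_equal(colSums(rep$itemized[, c("historical", "policy")]),
               rep$total)

  # identical streams -> zero savings; all-NONE policy refunds everything
  expect_equal(cohort_cost_comparison(hist, hist, model, cat_k, 2)$savings, 0)
  all_none <- rep(none, 4)
  expect_equal(cohort_cost_comparison(hist, all_none, model, cat_k, 2)$savings,
               unname(rep$total["historical"]))
})

test_that("cost is monotone in events and staff costs scale with wages", {
  cat_k <- action_catalog("K")
  model <- fixture_cost_model()
  none <- which(cat_k$route == "NONE")
  set.seed(8)
  stream <- sample(nrow(cat_k), 30, replace = TRUE)
  base <- cohort_cost_comparison(stream, rep(none, 30), model, cat_k, 5)
  # appending any repletion event never decreases the stream total
  for (a in c(2L, 10L, 25L)) {
    more <- cohort_cost_comparison(c(stream, a), rep(none, 31), model, cat_k, 5)
    expect_gte(more$total["historical"], base$total["historical"])
  }
  # doubling all wages doubles exactly the staff component
  m2 <- model
  m2$wage_per_hour <- model$wage_per_hour * 2
  c1 <- cohort_cost_comparison(stream, rep(none, 30), model, cat_k, 5)
  c2 <- cohort_cost_comparison(stream, rep(none, 30), m2, cat_k, 5)
  it1 <- c1$itemized; it2 <- c2$itemized
  expect_equal(it2$historical[it2$component == "staff"],
               2 * it1$historical[it1$component == "staff"])
  expect_equal(it2$historical[it2$component == "drug"],
               it1$historical[it1$component == "drug"])
})
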
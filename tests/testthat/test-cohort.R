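write_fixture_tables <- function(tabs, dir = tempfile()) {
  write_ehr(tabs, dir)
  list(static = file.path(dir, "static.csv"),
       observations = file.path(dir, "observations.csv"),
       medications = file.path(dir, "medications.csv"))
}

test_that("loading round-trips the simulator's tables", {
  tabs <- simulate_cohort(sim_config("K", n_visits = 5, rng_seed = 3))
  p <- write_fixture_tables(tabs)
  visits <- load_ehr(p$static, p$observations, p$medications)
  expect_length(visits, 5L)
  expect_identical(attr(visits, "n_dropped"), 0L)
  expect_setequal(names(visits), tabs$static$visit_id)

  # a non-numeric value is dropped, with the drop counted
  obs <- utils::read.csv(p$observations)
  obs$value <- as.character(obs$value)
  obs$value[1L] <- "error"
  f2 <- tempfile(fileext = ".csv")
  utils::write.csv(obs, f2, row.names = FALSE)
  expect_message(v2 <- load_ehr(p$static, f2, p$medications), "dropped 1")
  expect_identical(attr(v2, "n_dropped"), 1L)

  # an empty medications table is legal
  meds0 <- utils::read.csv(p$medications)[0, ]
  f3 <- tempfile(fileext = ".csv")
  utils::write.csv(meds0, f3, row.names = FALSE)
  v3 <- load_ehr(p$static, p$observations, f3)
  expect_true(all(vapply(v3, function(v) nrow(v$medications) == 0L, logical(1))))

  # missing required column names the column
  bad <- utils::read.csv(p$static)
  bad$age <- NULL
  f4 <- tempfile(fileext = ".csv")
  utils::write.csv(bad, f4, row.names = FALSE)
  expect_error(load_ehr(f4, p$observations, p$medications), "age")
})

test_that("cohort selection keeps exactly the hand-enumerated survivors", {
  visits <- fixture_cohort()
  res <- select_cohort(visits, cohort_filter_spec(target_electrolyte = "K"))
  expect_setequal(names(res$kept), c("F4", "F5"))
  expect_identical(unname(res$exclusions[c("age", "length_of_stay", "kept")]),
                   c(1L, 2L, 2L))
  # first-failed-filter attribution: F1 fails age even though its LOS passes
  expect_identical(unname(res$exclusions[["age"]]), 1L)

  # requiring repletion with no medication rows keeps nothing
  stripped <- lapply(visits, function(v) { v$medications <- v$medications[0, ]; v })
  res2 <- select_cohort(structure(stripped, class = "ehr_cohort"),
                        cohort_filter_spec())
  expect_length(res2$kept, 0L)

  # an all-permissive spec keeps everything
  spec <- cohort_filter_spec(min_age = 0, min_los = 0, max_los = Inf,
                             require_admission_weight = FALSE,
                             require_repletion_event = FALSE)
  expect_length(select_cohort(visits, spec)$kept, 5L)
  # and selection is idempotent
  again <- select_cohort(res$kept, cohort_filter_spec())
  expect_setequal(names(again$kept), names(res$kept))
})

test_that("binning averages survivors, drops outliers, uses half-open bins", {
  v <- fixture_visit(times = c(2, 5), values = c(3.8, 4.0))
  bv <- bin_visit(v)
  expect_equal(unname(bv$features[1L, "K"]), 3.9)
  expect_true(bv$observed[1L, "K"])

  # nonviable outlier discarded before averaging
  v2 <- fixture_visit(times = c(2, 5), values = c(3.8, 40))
  bv2 <- bin_visit(v2, ranges = list(K = c(1, 10)))
  expect_equal(unname(bv2$features[1L, "K"]), 3.8)
  expect_identical(bv2$n_discarded, 1L)

  # half-open convention: an event at exactly hour 6 belongs to bin 1
  v3 <- fixture_visit(times = 6, values = 4.2)
  bv3 <- bin_visit(v3)
  expect_true(is.na(bv3$features[1L, "K"]))
  expect_equal(unname(bv3$features[2L, "K"]), 4.2)

  # medication assigned by start time
  v4 <- fixture_visit(times = 1, values = 4,
                      meds = data.frame(visit_id = "V1", start_hours = 13,
                                        end_hours = 15, drug = "K-IV",
                                        dose = 20, route = "IV"))
  expect_identical(bin_visit(v4)$medications$bin, 2)

  # a 192 h stay yields exactly 32 six-hour bins
  expect_identical(bin_visit(fixture_visit(1, 4, los = 192))$n_bins, 32)
})

test_that("bin counts conserve the number of surviving measurements", {
  tabs <- simulate_cohort(sim_config("K", n_visits = 10, rng_seed = 8))
  p <- write_fixture_tables(tabs)
  visits <- load_ehr(p$static, p$observations, p$medications)
  binned <- bin_visits(visits)
  n_in <- nrow(tabs$observations)
  n_discarded <- sum(vapply(binned, `[[`, integer(1), "n_discarded"))
  # recount survivors independently from the raw table and the bounds
  ranges <- plausibility_ranges()
  n_viable <- 0L
  for (v in visits) {
    o <- v$observations
    for (k in seq_len(nrow(o))) {
      r <- ranges[[o$variable[k]]]
      if (is.null(r) || (o$value[k] >= r[1] && o$value[k] <= r[2])) {
        n_viable <- n_viable + 1L
      }
    }
  }
  expect_identical(n_viable + n_discarded, n_in)
  # every surviving measurement lands in exactly one (bin, variable) cell
  n_cells <- sum(vapply(binned, function(b) sum(b$observed), numeric(1)))
  n_distinct <- 0L
  for (v in visits) {
    o <- v$observations
    keep <- vapply(seq_len(nrow(o)), function(k) {
      r <- ranges[[o$variable[k]]]
      is.null(r) || (o$value[k] >= r[1] && o$value[k] <= r[2])
    }, logical(1))
    o <- o[keep, ]
    n_distinct <- n_distinct +
      nrow(unique(data.frame(floor(o$time_hours / 6), o$variable)))
  }
  expect_equal(n_cells, n_distinct)
})

test_that("imputation follows the capped-LOCF-then-population-mean trace", {
  # K observed in bin 0 only, over a 60 h stay (10 bins); second visit pins
  # the population mean at 5.0
  v1 <- fixture_visit(times = 1, values = 3.0, los = 60)
  v2 <- fixture_visit(times = 1, values = 5.0, los = 6)
  v2$visit_id <- "V2"
  binned <- bin_visits(as_cohort(v1, v2))
  imp <- impute_cohort(binned)
  f <- imp[[1L]]$features[, "K"]
  pop_mean <- mean(c(3.0, 5.0))
  # bins 1..8 are 6-48 h after the observation: carried forward
  expect_equal(unname(f[2:9]), rep(3.0, 8))
  # bin 9 is 54 h later: population mean
  expect_equal(unname(f[10]), pop_mean)
  # the observed cell itself is untouched, as is the mask
  expect_equal(unname(f[1]), 3.0)
  expect_identical(imp[[1L]]$observed, binned[[1L]]$observed)

  # no prior observation in the visit -> population mean from bin 0 onward
  v3 <- fixture_visit(times = 31, values = 4.4, los = 36)
  binned3 <- bin_visits(as_cohort(v3))
  f3 <- impute_cohort(binned3)[[1L]]$features[, "K"]
  expect_equal(unname(f3[1:5]), rep(4.4, 5))

  # fully observed visits are unchanged
  v4 <- fixture_visit(times = c(1, 7), values = c(4, 4.2), los = 12)
  binned4 <- bin_visits(as_cohort(v4))
  expect_identical(impute_cohort(binned4)[[1L]]$features,
                   binned4[[1L]]$features)

  # a variable never observed anywhere is an error naming it
  v5 <- fixture_visit(times = 1, values = 4)
  b5 <- bin_visits(as_cohort(v5), variables = c("K", "Mg"))
  expect_error(impute_cohort(b5), "Mg")
})

test_that("train/test split is visit-level, seeded and exhaustive", {
  ids <- sprintf("V%02d", 1:10)
  sp <- split_cohort(ids, train_fraction = 0.7, rng_seed = 4)
  expect_length(sp$train, 7L)
  expect_length(sp$test, 3L)
  expect_length(intersect(sp$train, sp$test), 0L)
  expect_setequal(c(sp$train, sp$test), ids)
  expect_identical(sp, split_cohort(ids, train_fraction = 0.7, rng_seed = 4))
  # explicit-count splits are supported alongside fractions
  sp2 <- split_cohort(ids, train_count = 4, rng_seed = 4)
  expect_length(sp2$train, 4L)
})
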
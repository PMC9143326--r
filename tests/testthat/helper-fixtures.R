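# Hand-written fixtures shared by the cohort-preprocessing tests.

# five visits exercising the inclusion funnel: ages {17,30,40,50,60},
# stays {100,10,300,100,100} h; only the age-50 and age-60 visits pass
fixture_cohort <- function() {
  ages <- c(17, 30, 40, 50, 60)
  los <- c(100, 10, 300, 100, 100)
  visits <- lapply(1:5, function(i) {
    list(visit_id = paste0("F", i), age = ages[i], sex = "F",
         admit_weight = 70, los_hours = los[i],
         observations = data.frame(
           visit_id = paste0("F", i),
           time_hours = c(2, 5), variable = "K", value = c(3.8, 4.0)),
         medications = data.frame(
           visit_id = paste0("F", i), start_hours = 10, end_hours = 12,
           drug = "K-IV", dose = 20, route = "IV"))
  })
  names(visits) <- paste0("F", 1:5)
  structure(visits, class = "ehr_cohort")
}

# one-visit builder for binning/imputation traces
fixture_visit <- function(times, values, variable = "K", los = 60,
                          meds = NULL) {
  if (is.null(meds)) {
    meds <- data.frame(visit_id = character(0), start_hours = numeric(0),
                       end_hours = numeric(0), drug = character(0),
                       dose = numeric(0), route = character(0))
  }
  list(visit_id = "V1", age = 50, sex = "M", admit_weight = 80,
       los_hours = los,
       observations = data.frame(visit_id = "V1", time_hours = times,
                                 variable = variable, value = values),
       medications = meds)
}

as_cohort <- function(...) structure(list(...), class = "ehr_cohort")

# simulate -> write -> load -> bin -> impute, in one call
make_imputed <- function(n_visits = 4, rng_seed = 7, horizon_hours = 72,
                         cfg = NULL, bcfg = behavior_config()) {
  if (is.null(cfg)) {
    cfg <- sim_config("K", n_visits = n_visits, horizon_hours = horizon_hours,
                      rng_seed = rng_seed)
  }
  tabs <- simulate_cohort(cfg, bcfg)
  d <- tempfile(); write_ehr(tabs, d)
  visits <- load_ehr(file.path(d, "static.csv"),
                     file.path(d, "observations.csv"),
                     file.path(d, "medications.csv"))
  impute_cohort(bin_visits(visits))
}

# documented illustrative cost model used in the finance arithmetic tests:
# only PO administration, lab draw and the panel itself carry cost
fixture_cost_model <- function() {
  cost_model(
    po_drug_cost = c(2, 4, 6),
    iv_drug_cost = c(10, 20, 30, 10, 20, 30),
    lab_test_cost = 10,
    staff_minutes = c(order = 0, prepare = 0, administer_po = 5,
                      administer_iv = 12, monitor_iv = 6, draw_lab = 5),
    wage_per_hour = c(nurse = 60, pharmacist = 80, provider = 120,
                      phlebotomist = 36),
    labs_per_repletion = 1)
}
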
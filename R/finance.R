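#' Repletion cost model
#'
#' A single-rate (non-tiered) price model for one electrolyte's repletion
#' workflow: drug unit costs per route and dose level, a flat lab-panel cost,
#' per-task staff minutes by role, hourly wages, and the number of follow-up
#' lab draws attributed to each repletion event. All monetary outputs of the
#' package are functions of this configuration; the shipped defaults are
#' documented illustrative figures, not reproductions of any institution's
#' prices.
#'
#' Tasks and their roles: \code{order} (provider), \code{prepare}
#' (pharmacist), \code{administer_po} (nurse), \code{administer_iv} (nurse),
#' \code{monitor_iv} (nurse), \code{draw_lab} (phlebotomist).
#'
#' @param po_drug_cost numeric vector, cost per PO dose level.
#' @param iv_drug_cost numeric vector, cost per IV dose level.
#' @param lab_test_cost cost of one electrolyte panel.
#' @param staff_minutes named numeric: minutes per task (names as above).
#' @param wage_per_hour named numeric: hourly wage per role (\code{nurse},
#'   \code{pharmacist}, \code{provider}, \code{phlebotomist}).
#' @param labs_per_repletion follow-up draws attributed to one repletion event.
#' @return list of class \code{"cost_model"}.
#' @export
cost_model <- function(po_drug_cost, iv_drug_cost, lab_test_cost,
                       staff_minutes, wage_per_hour, labs_per_repletion = 1) {
  stopifnot(all(po_drug_cost >= 0), all(iv_drug_cost >= 0),
            lab_test_cost >= 0, all(staff_minutes >= 0),
            all(wage_per_hour >= 0), labs_per_repletion >= 0)
  need_tasks <- c("order", "prepare", "administer_po", "administer_iv",
                  "monitor_iv", "draw_lab")
  need_roles <- c("nurse", "pharmacist", "provider", "phlebotomist")
  stopifnot(all(need_tasks %in% names(staff_minutes)),
            all(need_roles %in% names(wage_per_hour)))
  structure(list(po_drug_cost = po_drug_cost, iv_drug_cost = iv_drug_cost,
                 lab_test_cost = lab_test_cost,
                 staff_minutes = staff_minutes,
                 wage_per_hour = wage_per_hour,
                 labs_per_repletion = labs_per_repletion),
            class = "cost_model")
}

task_role <- c(order = "provider", prepare = "pharmacist",
               administer_po = "nurse", administer_iv = "nurse",
               monitor_iv = "nurse", draw_lab = "phlebotomist")

#' Illustrative default cost model
#'
#' Round-number USD figures of realistic magnitude for a US hospital workflow
#' (single lowest-bracket rate applied uniformly). Every number is a
#' configuration input, not an estimate of any particular institution.
#'
#' @param electrolyte \code{"K"}, \code{"Mg"} or \code{"P"} (sets the drug
#'   price vectors to the catalog's dose-level counts).
#' @return a [cost_model()].
#' @export
default_cost_model <- function(electrolyte = c("K", "Mg", "P")) {
  electrolyte <- match.arg(electrolyte)
  po <- switch(electrolyte, K = c(0.60, 0.90, 1.20),
               Mg = c(0.50, 0.80, 1.10), P = c(0.70, 1.00, 1.30))
  iv <- switch(electrolyte, K = c(8, 12, 16, 8, 12, 16),
               Mg = c(6, 9, 9, 9), P = c(12, 18, 25))
  cost_model(
    po_drug_cost = po, iv_drug_cost = iv, lab_test_cost = 10,
    staff_minutes = c(order = 2, prepare = 5, administer_po = 3,
                      administer_iv = 10, monitor_iv = 5, draw_lab = 5),
    wage_per_hour = c(nurse = 40, pharmacist = 60, provider = 100,
                      phlebotomist = 20),
    labs_per_repletion = 1)
}

staff_cost <- function(model, tasks) {
  mins <- model$staff_minutes[tasks]
  wages <- model$wage_per_hour[task_role[tasks]]
  sum(mins * wages / 60)
}

#' Itemized cost of one repletion event
#'
#' Drug cost for each route component, staff time (ordering and preparation
#' once per event; administration per route component; IV monitoring when an
#' IV component is present), and the attributed follow-up labs (panel price
#' plus the draw's staff time). The NONE action costs exactly zero.
#'
#' @param action catalog index or row.
#' @param model a [cost_model()].
#' @param catalog the electrolyte's [action_catalog()].
#' @return list with \code{drug}, \code{staff}, \code{lab}, \code{total}.
#' @export
event_cost <- function(action, model, catalog) {
  a <- resolve_action(action, catalog)
  if (a$route == "NONE") {
    return(list(drug = 0, staff = 0, lab = 0, total = 0))
  }
  drug <- 0
  tasks <- c("order", "prepare")
  if (a$po_level > 0L) {
    if (a$po_level > length(model$po_drug_cost)) {
      stop("no PO price configured for dose level ", a$po_level)
    }
    drug <- drug + model$po_drug_cost[a$po_level]
    tasks <- c(tasks, "administer_po")
  }
  if (a$iv_level > 0L) {
    if (a$iv_level > length(model$iv_drug_cost)) {
      stop("no IV price configured for dose level ", a$iv_level)
    }
    drug <- drug + model$iv_drug_cost[a$iv_level]
    tasks <- c(tasks, "administer_iv", "monitor_iv")
  }
  staff <- staff_cost(model, tasks) +
    model$labs_per_repletion * staff_cost(model, "draw_lab")
  lab <- model$labs_per_repletion * model$lab_test_cost
  list(drug = drug, staff = staff, lab = lab, total = drug + staff + lab)
}

#' Compare cohort-level repletion expenditure: historical vs. policy
#'
#' Sums [event_cost()] over two action streams recorded at the same decision
#' points and itemizes the difference.
#'
#' @param historical_actions,policy_actions integer catalog indices over the
#'   same states (equal length).
#' @param model a [cost_model()].
#' @param catalog the electrolyte's [action_catalog()].
#' @param n_visits number of hospital visits the streams cover (for the
#'   per-visit savings figure).
#' @return list of class \code{"cost_report"}: \code{total} (historical,
#'   policy), \code{savings}, \code{savings_per_visit}, and an
#'   \code{itemized} data frame (drug/lab/staff by stream).
#' @export
cohort_cost_comparison <- function(historical_actions, policy_actions, model,
                                   catalog, n_visits) {
  stopifnot(length(historical_actions) == length(policy_actions),
            n_visits >= 1)
  K <- nrow(catalog)
  per_action <- lapply(seq_len(K), event_cost, model = model,
                       catalog = catalog)
  comp <- function(actions, field) {
    v <- vapply(per_action, `[[`, numeric(1), field)
    sum(v[actions])
  }
  item <- data.frame(
    component = c("drug", "lab", "staff"),
    historical = c(comp(historical_actions, "drug"),
                   comp(historical_actions, "lab"),
                   comp(historical_actions, "staff")),
    policy = c(comp(policy_actions, "drug"),
               comp(policy_actions, "lab"),
               comp(policy_actions, "staff"))
  )
  tot <- c(historical = sum(item$historical), policy = sum(item$policy))
  structure(list(total = tot,
                 savings = unname(tot["historical"] - tot["policy"]),
                 savings_per_visit =
                   unname(tot["historical"] - tot["policy"]) / n_visits,
                 itemized = item, n_visits = n_visits),
            class = "cost_report")
}

#' @export
print.cost_report <- function(x, ...) {
  cat("Repletion expenditure comparison over", x$n_visits, "visits\n")
  cat(sprintf("  historical total: %.2f\n", x$total["historical"]))
  cat(sprintf("  policy total:     %.2f\n", x$total["policy"]))
  cat(sprintf("  savings:          %.2f (%.2f per visit)\n",
              x$savings, x$savings_per_visit))
  print(x$itemized, row.names = FALSE)
  invisible(x)
}
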
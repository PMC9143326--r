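#' Compare action frequencies: historical behavior vs. a policy
#'
#' State-matched comparison: the policy is queried at every logged test state
#' and its choice is tallied against the historical action taken there. (True
#' counterfactual trajectories are unknowable retrospectively, so frequencies
#' are compared at the states that actually occurred.)
#'
#' @param samples test-set \code{"transition_set"} (historical actions).
#' @param policy a \code{"repletion_policy"} or function.
#' @return list of class \code{"frequency_report"}: per-action \code{counts}
#'   (columns \code{historical}, \code{policy}), \code{repletion_change_pct}
#'   (percent change in total repletion events; \code{NA} when history has
#'   none), \code{route_mix} (shares of NONE/PO/IV/BOTH per stream), and
#'   dose-level histograms.
#' @export
frequency_analysis <- function(samples, policy) {
  catalog <- samples$spec$catalog
  K <- nrow(catalog)
  hist_a <- samples$action
  pol_a <- policy_actions(policy, samples$state)
  counts <- data.frame(
    action = catalog$label,
    route = catalog$route,
    historical = tabulate(hist_a, nbins = K),
    policy = tabulate(pol_a, nbins = K)
  )
  repletes <- function(a) sum(catalog$route[a] != "NONE")
  n_hist <- repletes(hist_a)
  n_pol <- repletes(pol_a)
  change <- if (n_hist == 0L) NA_real_ else (n_pol - n_hist) / n_hist * 100
  route_share <- function(a) {
    tab <- table(factor(catalog$route[a], levels = c("NONE", "PO", "IV", "BOTH")))
    as.numeric(tab) / length(a)
  }
  route_mix <- data.frame(route = c("NONE", "PO", "IV", "BOTH"),
                          historical = route_share(hist_a),
                          policy = route_share(pol_a))
  dose_hist <- function(a, col) {
    lv <- catalog[[col]][a]
    table(factor(lv[lv > 0], levels = seq_len(max(catalog[[col]]))))
  }
  structure(list(counts = counts,
                 n_states = length(hist_a),
                 repletions = c(historical = n_hist, policy = n_pol),
                 repletion_change_pct = change,
                 route_mix = route_mix,
                 po_levels = list(historical = dose_hist(hist_a, "po_level"),
                                  policy = dose_hist(pol_a, "po_level")),
                 iv_levels = list(historical = dose_hist(hist_a, "iv_level"),
                                  policy = dose_hist(pol_a, "iv_level"))),
            class = "frequency_report")
}

#' @export
print.frequency_report <- function(x, ...) {
  cat("Action frequency comparison over", x$n_states, "test states\n")
  cat("  repletion events: historical", x$repletions["historical"],
      "vs policy", x$repletions["policy"], "\n")
  if (is.na(x$repletion_change_pct)) {
    cat("  percent change: undefined (no historical repletions)\n")
  } else {
    cat("  percent change:", sprintf("%+.1f%%", x$repletion_change_pct), "\n")
  }
  cat("  route mix (share of states):\n")
  print(x$route_mix, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Pre- and post-repletion electrolyte level distributions
#'
#' For every historical repletion event of the target electrolyte: the
#' pre-repletion level is the last genuinely measured value (per the observed
#' mask — imputed fill never counts) at or before the repletion bin, and the
#' post-repletion level is the first measured value after the infusion ends.
#' Reports the fractions of events initiated while the level was within or
#' above the reference range, above it, and below it.
#'
#' @param binned an imputed \code{"binned_cohort"}.
#' @param electrolyte target electrolyte label.
#' @param reference_range (low, high).
#' @return list of class \code{"pre_post_report"}: vectors \code{pre} and
#'   \code{post} (NA where no measurement qualifies), \code{n_events},
#'   \code{frac_within_or_above}, \code{frac_above}, \code{frac_below}.
#' @export
pre_post_distribution <- function(binned, electrolyte, reference_range) {
  catalog <- action_catalog(electrolyte)
  drugs <- repletion_drug(electrolyte, c("PO", "IV"))
  pre <- numeric(0); post <- numeric(0)
  for (bv in binned) {
    meds <- bv$medications
    meds <- meds[meds$drug %in% drugs, , drop = FALSE]
    if (nrow(meds) == 0L) next
    lev <- bv$features[, electrolyte]
    obs <- bv$observed[, electrolyte]
    for (k in seq_len(nrow(meds))) {
      b <- meds$bin[k]
      prior <- which(obs & (seq_along(lev) - 1L) <= b)
      pre <- c(pre, if (length(prior)) lev[max(prior)] else NA_real_)
      end_h <- meds$end_hours[k]
      later <- which(obs & ((seq_along(lev) - 1L) * bv$bin_width) > end_h)
      post <- c(post, if (length(later)) lev[min(later)] else NA_real_)
    }
  }
  lo <- reference_range[1L]; hi <- reference_range[2L]
  ok <- !is.na(pre)
  structure(list(pre = pre, post = post, n_events = length(pre),
                 frac_within_or_above = mean(pre[ok] >= lo),
                 frac_above = mean(pre[ok] > hi),
                 frac_below = mean(pre[ok] < lo),
                 reference_range = reference_range,
                 electrolyte = electrolyte),
            class = "pre_post_report")
}

#' @export
print.pre_post_report <- function(x, ...) {
  cat("Pre/post repletion levels (", x$electrolyte, "), ", x$n_events,
      " events\n", sep = "")
  cat(sprintf("  initiated within-or-above range: %.1f%%\n",
              100 * x$frac_within_or_above))
  cat(sprintf("  initiated above range:           %.1f%%\n",
              100 * x$frac_above))
  invisible(x)
}

#' Per-visit trajectory overlay of measured levels and actions
#'
#' Aligns, bin by bin, the measured electrolyte level (NA where only imputed
#' fill exists), the historical action, the policy's recommendation at the
#' same state, and the infusion spans implied by the catalog durations —
#' the table behind a single-visit measured/ordered/recommended panel plot.
#'
#' @param bv one imputed \code{"binned_visit"}.
#' @param policy a \code{"repletion_policy"} or function.
#' @param spec the [mdp_spec()].
#' @return data frame of class \code{"trajectory_overlay"} with one row per
#'   bin: \code{bin}, \code{hours}, \code{measured_level},
#'   \code{historical_action}, \code{policy_action}, and infusion span columns
#'   \code{hist_iv_start/end}, \code{policy_iv_start/end} (NA when no IV
#'   component).
#' @export
trajectory_overlay <- function(bv, policy, spec) {
  sm <- visit_state_matrix(bv, spec)
  catalog <- spec$catalog
  pol_a <- policy_actions(policy, sm$states)
  hist_a <- sm$actions
  hours <- (seq_len(bv$n_bins) - 1L) * bv$bin_width
  span <- function(a) {
    dur <- catalog$iv_duration_h[a]
    start <- ifelse(dur > 0, hours, NA_real_)
    end <- ifelse(dur > 0, hours + dur, NA_real_)
    list(start = start, end = end)
  }
  hs <- span(hist_a); ps <- span(pol_a)
  lev <- bv$features[, spec$electrolyte]
  lev[!bv$observed[, spec$electrolyte]] <- NA_real_
  lab <- function(a) ifelse(catalog$route[a] == "NONE", "", catalog$label[a])
  out <- data.frame(bin = seq_len(bv$n_bins) - 1L, hours = hours,
                    measured_level = lev,
                    historical_action = lab(hist_a),
                    policy_action = lab(pol_a),
                    hist_iv_start = hs$start, hist_iv_end = hs$end,
                    policy_iv_start = ps$start, policy_iv_end = ps$end)
  class(out) <- c("trajectory_overlay", "data.frame")
  out
}

#' Monte-Carlo discounted return of an agent in the simulator
#'
#' Rolls the synthetic dynamics forward and accumulates the discounted
#' four-term penalty reward along each trajectory; the ground-truth check that
#' off-policy value estimates are compared against.
#'
#' @param agent a [behavior_config()] or a policy ([greedy_policy()] /
#'   function).
#' @param cfg a [sim_config()].
#' @param weights a [reward_weights()] vector.
#' @param gamma discount factor.
#' @param n_visits number of rollout trajectories.
#' @param rng_seed seed.
#' @return list with \code{mean} return, per-visit \code{returns}, \code{n}.
#' @export
monte_carlo_return <- function(agent, cfg, weights, gamma = 0.9,
                               n_visits = cfg$n_visits,
                               rng_seed = cfg$rng_seed) {
  tabs <- if (inherits(agent, "behavior_config")) {
    cfg$n_visits <- as.integer(n_visits); cfg$rng_seed <- as.integer(rng_seed)
    simulate_cohort(cfg, agent)
  } else {
    rollout_policy(agent, cfg, n_visits = n_visits, rng_seed = rng_seed)
  }
  log <- attr(tabs, "log")
  phi <- as.matrix(log[, c("phi_iv", "phi_po", "phi_high", "phi_low")])
  r <- -as.numeric(phi %*% as.numeric(weights))
  ret <- tapply(r * gamma^log$bin, log$visit_id, sum)
  list(mean = mean(ret), returns = as.numeric(ret), n = length(ret))
}
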
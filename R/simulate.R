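#' Synthetic ICU cohort simulator configuration
#'
#' Configures the seeded generator that stands in for restricted ICU EHR data.
#' The target electrolyte follows first-order mean-reverting dynamics around
#' \code{setpoint + illness_drift} with additive, immediate dose response and
#' Gaussian innovation noise; a negative \code{illness_drift} pulls the
#' attractor below the reference range and so induces hypo-electrolyte
#' episodes. All other vitals and labs are independent stationary noise around
#' clinically plausible means — nuisance features a policy learner should
#' discover to be irrelevant.
#'
#' Electrolyte-specific defaults (setpoint, drift, noise, dose response,
#' reference range) are chosen so that untreated patients spend a substantial
#' share of their stay below range, a single top-level PO dose restores the
#' level for a few intervals, and IV doses act faster and stronger — the
#' regime in which "replete only when low, prefer PO" is the optimal policy.
#'
#' @param electrolyte \code{"K"}, \code{"Mg"} or \code{"P"}.
#' @param n_visits number of admissions to simulate.
#' @param horizon_hours maximum length of stay (must be >= 24; per-visit stays
#'   are sampled in whole 6 h bins up to this horizon).
#' @param setpoint healthy equilibrium concentration (e.g. mEq/L for K).
#' @param reversion_rate fraction of the gap to the attractor closed per 6 h
#'   interval, in [0, 1].
#' @param illness_drift concentration offset added to the setpoint to form the
#'   attractor; negative values induce deficiency episodes.
#' @param noise_sd SD of the per-interval concentration innovation.
#' @param po_effect_per_unit,iv_effect_per_unit immediate concentration gain
#'   per catalog dose level for oral / intravenous repletion.
#' @param measurement_prob probability that a 6 h bin contains a lab draw of
#'   the target electrolyte.
#' @param missing_prob_vitals probability that a nuisance vital/lab is NOT
#'   recorded in a given bin.
#' @param reference_range length-2 numeric (low, high) target band.
#' @param rng_seed integer seed; identical configurations reproduce identical
#'   cohorts byte for byte.
#' @return list of class \code{"sim_config"}.
#' @export
sim_config <- function(electrolyte = c("K", "Mg", "P"),
                       n_visits = 200L,
                       horizon_hours = 72,
                       setpoint = NULL,
                       reversion_rate = 0.35,
                       illness_drift = NULL,
                       noise_sd = NULL,
                       po_effect_per_unit = NULL,
                       iv_effect_per_unit = NULL,
                       measurement_prob = 0.8,
                       missing_prob_vitals = 0.3,
                       reference_range = NULL,
                       rng_seed = 1L) {
  electrolyte <- match.arg(electrolyte)
  d <- switch(electrolyte,
    K  = list(setpoint = 4.4, drift = -0.25, noise = 0.15, po = 0.15,
              iv = 0.25, range = c(3.5, 5.0)),
    Mg = list(setpoint = 2.15, drift = -0.12, noise = 0.07, po = 0.07,
              iv = 0.12, range = c(1.7, 2.3)),
    P  = list(setpoint = 4.0, drift = -0.30, noise = 0.20, po = 0.25,
              iv = 0.45, range = c(2.5, 4.5))
  )
  cfg <- list(
    electrolyte = electrolyte,
    n_visits = as.integer(n_visits),
    horizon_hours = horizon_hours,
    setpoint = setpoint %||% d$setpoint,
    reversion_rate = reversion_rate,
    illness_drift = illness_drift %||% d$drift,
    noise_sd = noise_sd %||% d$noise,
    po_effect_per_unit = po_effect_per_unit %||% d$po,
    iv_effect_per_unit = iv_effect_per_unit %||% d$iv,
    measurement_prob = measurement_prob,
    missing_prob_vitals = missing_prob_vitals,
    reference_range = reference_range %||% d$range,
    rng_seed = as.integer(rng_seed)
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_sim_config <- function(cfg) {
  stopifnot(
    cfg$n_visits >= 1L,
    is.finite(cfg$horizon_hours),
    cfg$reversion_rate >= 0, cfg$reversion_rate <= 1,
    cfg$measurement_prob >= 0, cfg$measurement_prob <= 1,
    cfg$missing_prob_vitals >= 0, cfg$missing_prob_vitals <= 1,
    length(cfg$reference_range) == 2L,
    cfg$reference_range[1L] < cfg$reference_range[2L]
  )
  if (cfg$horizon_hours < 24) {
    stop("horizon_hours must be >= 24: the cohort filter would reject every visit")
  }
  invisible(cfg)
}

#' Simulated clinician (behavior) policy configuration
#'
#' Emulates a threshold-driven repletion habit: repletion is always ordered
#' when the level is below \code{replete_threshold}, and with probability
#' \code{over_replete_prob} when at or above it — the knob that reproduces the
#' qualitative pattern of historical over-repletion. Route and dose level are
#' then sampled independently of the level.
#'
#' @param replete_threshold concentration below which repletion is certain.
#'   When used through [simulate_cohort()] a \code{NULL} threshold defaults to
#'   slightly below the reference-range low (1.5 noise SDs), so mild
#'   below-range episodes go untreated — the under-treatment half of the
#'   historical pattern.
#' @param over_replete_prob probability of ordering repletion at or above the
#'   threshold.
#' @param iv_prob_given_replete probability the ordered route is IV (otherwise
#'   PO).
#' @param dose_level_probs probability over catalog dose levels, indexed from
#'   level 1; truncated to the chosen route's available levels and
#'   renormalized. Must sum to 1.
#' @param rng_seed optional extra seed mixed into the cohort seed.
#' @return list of class \code{"behavior_config"}.
#' @export
behavior_config <- function(replete_threshold = NULL,
                            over_replete_prob = 0.3,
                            iv_prob_given_replete = 0.5,
                            dose_level_probs = c(0.4, 0.35, 0.25),
                            rng_seed = NULL) {
  stopifnot(
    over_replete_prob >= 0, over_replete_prob <= 1,
    iv_prob_given_replete >= 0, iv_prob_given_replete <= 1,
    all(dose_level_probs >= 0),
    abs(sum(dose_level_probs) - 1) <= 1e-9
  )
  structure(list(replete_threshold = replete_threshold,
                 over_replete_prob = over_replete_prob,
                 iv_prob_given_replete = iv_prob_given_replete,
                 dose_level_probs = dose_level_probs,
                 rng_seed = rng_seed),
            class = "behavior_config")
}

#' One step of the electrolyte dynamics
#'
#' \deqn{L' = L + \rho\,(setpoint + drift - L) + e_{PO}\,po\_level +
#'   e_{IV}\,iv\_level + \epsilon}
#'
#' @param level current concentration (finite scalar).
#' @param action catalog index or row.
#' @param cfg a [sim_config()].
#' @param noise innovation term (pass 0 for the deterministic skeleton).
#' @param catalog the electrolyte's catalog (derived from \code{cfg} by
#'   default).
#' @return next concentration.
#' @export
step_dynamics <- function(level, action, cfg, noise = 0,
                          catalog = action_catalog(cfg$electrolyte)) {
  if (!is.finite(level) || !is.finite(noise)) {
    stop("step_dynamics requires finite `level` and `noise`")
  }
  a <- resolve_action(action, catalog)
  attractor <- cfg$setpoint + cfg$illness_drift
  level + cfg$reversion_rate * (attractor - level) +
    cfg$po_effect_per_unit * a$po_level +
    cfg$iv_effect_per_unit * a$iv_level +
    noise
}

#' Draw one clinician action from the behavior policy
#'
#' Deterministic given the R random number generator state. Below the
#' threshold repletion is certain; at or above it repletion occurs with
#' probability \code{over_replete_prob}. Conditional on repleting, the route is
#' IV with probability \code{iv_prob_given_replete} (PO otherwise) and the dose
#' level is drawn from \code{dose_level_probs} truncated to the route's
#' available levels.
#'
#' @param level current electrolyte level as seen by the clinician.
#' @param bcfg a [behavior_config()] (its \code{replete_threshold} must be
#'   set).
#' @param catalog the electrolyte's [action_catalog()].
#' @return integer catalog index of the chosen action.
#' @export
behavior_action <- function(level, bcfg, catalog) {
  if (nrow(catalog) == 0L || !any(catalog$route == "NONE")) {
    stop("catalog must be non-empty and contain the NONE action")
  }
  thr <- bcfg$replete_threshold
  stopifnot(!is.null(thr))
  replete <- if (level < thr) TRUE else stats::runif(1) < bcfg$over_replete_prob
  if (!replete) return(which(catalog$route == "NONE")[1L])
  iv <- stats::runif(1) < bcfg$iv_prob_given_replete
  route <- if (iv) "IV" else "PO"
  pool <- catalog[catalog$route == route, , drop = FALSE]
  lev_col <- if (iv) pool$iv_level else pool$po_level
  p <- bcfg$dose_level_probs
  n_lev <- max(lev_col)
  p <- if (length(p) >= n_lev) p[seq_len(n_lev)] else c(p, rep(0, n_lev - length(p)))
  if (sum(p) == 0) p <- rep(1, n_lev)
  lev <- sample.int(n_lev, 1L, prob = p / sum(p))
  pool$index[match(lev, lev_col)]
}

# stationary nuisance variables emitted alongside the target electrolyte
nuisance_vars <- function(electrolyte) {
  v <- data.frame(
    name = c("heart_rate", "resp_rate", "temp", "spo2", "bp_sys", "bp_dia",
             "urine_output", "creatinine", "glucose", "hemoglobin", "sodium",
             "chloride", "bun", "wbc", "K", "Mg", "P"),
    mean = c(85, 18, 37, 97, 120, 70, 100, 1.0, 130, 10.5, 139, 103, 20, 9,
             4.0, 2.0, 3.5),
    sd = c(12, 4, 0.5, 2, 15, 10, 40, 0.3, 30, 1.5, 3, 4, 8, 3,
           0.3, 0.15, 0.5)
  )
  v[v$name != electrolyte, , drop = FALSE]
}

with_local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# core trajectory engine shared by simulate_cohort() and rollout_policy().
# `agent` is a function(level, state_row, prev_action) -> catalog index, where
# state_row is a named numeric vector of the full per-bin feature set.
sim_visits <- function(cfg, agent, seed) {
  catalog <- action_catalog(cfg$electrolyte)
  elec <- cfg$electrolyte
  nv <- nuisance_vars(elec)
  max_bins <- max(4L, floor(cfg$horizon_hours / 6))
  min_bins <- max(4L, min(6L, max_bins))
  po_prev_name <- paste0(elec, "_po_prev")
  iv_prev_name <- paste0(elec, "_iv_prev")

  static_l <- vector("list", cfg$n_visits)
  obs_l <- vector("list", cfg$n_visits)
  med_l <- vector("list", cfg$n_visits)
  log_l <- vector("list", cfg$n_visits)

  with_local_seed(seed, {
    for (i in seq_len(cfg$n_visits)) {
      vid <- sprintf("V%05d", i)
      n_bins <- if (max_bins > min_bins) {
        sample(min_bins:max_bins, 1L)
      } else max_bins
      los <- n_bins * 6
      age <- round(stats::runif(1, 20, 90), 1)
      sex <- sample(c("M", "F"), 1L)
      wt <- round(min(max(stats::rnorm(1, 80, 15), 40), 160), 1)
      static_l[[i]] <- data.frame(visit_id = vid, age = age, sex = sex,
                                  admit_weight = wt, los_hours = los)

      # nuisance panel, drawn for every bin (emission decided separately)
      nz <- matrix(stats::rnorm(n_bins * nrow(nv), mean = rep(nv$mean, each = n_bins),
                                sd = rep(nv$sd, each = n_bins)),
                   nrow = n_bins, dimnames = list(NULL, nv$name))
      nz <- round(nz, 2)

      # admissions present with a deficit proportional to illness severity:
      # sicker cohorts both run lower (attractor) and arrive lower
      level <- cfg$setpoint + 6 * cfg$illness_drift +
        stats::rnorm(1, 0, 2 * cfg$noise_sd)
      prev_action <- which(catalog$route == "NONE")[1L]
      actions <- integer(n_bins)
      levels_t <- numeric(n_bins + 1L)
      obs_i <- list(); med_i <- list()

      for (t in seq_len(n_bins)) {
        levels_t[t] <- level
        bin_start <- (t - 1L) * 6
        state_row <- c(age = age, admit_weight = wt,
                       sex_male = as.numeric(sex == "M"),
                       hours_in = bin_start, nz[t, ],
                       stats::setNames(level, elec),
                       stats::setNames(as.numeric(catalog$po_level[prev_action] > 0),
                                       po_prev_name),
                       stats::setNames(as.numeric(catalog$iv_level[prev_action] > 0),
                                       iv_prev_name))
        a <- agent(level, state_row, prev_action)
        actions[t] <- a
        rows <- action_to_rows(a, catalog, start_hours = bin_start + 0.5)
        if (nrow(rows) > 0L) med_i[[length(med_i) + 1L]] <- rows

        # lab draw of the target electrolyte
        if (stats::runif(1) < cfg$measurement_prob) {
          obs_i[[length(obs_i) + 1L]] <- data.frame(
            time_hours = bin_start + stats::runif(1, 0, 5.99),
            variable = elec, value = round(level, 3))
        }
        level <- step_dynamics(level, a, cfg,
                               noise = stats::rnorm(1, 0, cfg$noise_sd),
                               catalog = catalog)
        prev_action <- a
      }
      levels_t[n_bins + 1L] <- level

      # nuisance emissions
      present <- matrix(stats::runif(n_bins * nrow(nv)) >= cfg$missing_prob_vitals,
                        nrow = n_bins)
      if (any(present)) {
        idx <- which(present, arr.ind = TRUE)
        obs_i[[length(obs_i) + 1L]] <- data.frame(
          time_hours = (idx[, 1L] - 1L) * 6 + stats::runif(nrow(idx), 0, 5.99),
          variable = nv$name[idx[, 2L]],
          value = nz[idx])
      }

      obs <- if (length(obs_i)) do.call(rbind, obs_i) else
        data.frame(time_hours = numeric(0), variable = character(0),
                   value = numeric(0))
      obs <- cbind(visit_id = rep(vid, nrow(obs)), obs)
      obs <- obs[order(obs$time_hours, obs$variable), , drop = FALSE]
      obs_l[[i]] <- obs

      meds <- if (length(med_i)) do.call(rbind, med_i) else
        data.frame(start_hours = numeric(0), end_hours = numeric(0),
                   drug = character(0), dose = numeric(0), route = character(0))
      med_l[[i]] <- cbind(visit_id = rep(vid, nrow(meds)), meds)

      phi <- reward_features(catalog$iv_level[actions] > 0,
                             catalog$po_level[actions] > 0,
                             levels_t[-1L], cfg$reference_range)
      log_l[[i]] <- data.frame(visit_id = vid, bin = seq_len(n_bins) - 1L,
                               level = levels_t[-(n_bins + 1L)],
                               next_level = levels_t[-1L],
                               action = actions,
                               phi_iv = phi[, 1L], phi_po = phi[, 2L],
                               phi_high = phi[, 3L], phi_low = phi[, 4L])
    }
  })

  out <- list(static = do.call(rbind, static_l),
              observations = do.call(rbind, obs_l),
              medications = do.call(rbind, med_l))
  rownames(out$static) <- rownames(out$observations) <-
    rownames(out$medications) <- NULL
  attr(out, "log") <- do.call(rbind, log_l)
  attr(out, "config") <- cfg
  class(out) <- "ehr_tables"
  out
}

#' Simulate a synthetic ICU cohort under the clinician behavior policy
#'
#' Produces the three raw long-format EHR tables the preprocessing pipeline
#' consumes: \code{static} (visit_id, age, sex, admit_weight, los_hours),
#' \code{observations} (visit_id, time_hours, variable, value) and
#' \code{medications} (visit_id, start_hours, end_hours, drug, dose, route).
#' Combination orders appear as two medication rows (one PO, one IV) sharing a
#' start time. Output is byte-identical across runs with the same
#' configurations.
#'
#' A per-bin ground-truth trajectory log (true levels, actions, penalty
#' features) is attached as attribute \code{"log"} for simulator-based checks;
#' downstream analysis code never reads it.
#'
#' @param cfg a [sim_config()].
#' @param bcfg a [behavior_config()]; a \code{NULL} \code{replete_threshold}
#'   defaults to 1.5 noise SDs below the reference-range low.
#' @return list of class \code{"ehr_tables"} with the three tables.
#' @export
simulate_cohort <- function(cfg, bcfg = behavior_config()) {
  validate_sim_config(cfg)
  if (is.null(bcfg$replete_threshold)) {
    # clinicians react to frank deficiency a little inside the range boundary,
    # leaving mild below-range episodes untreated (the historical pattern the
    # learned policy is meant to improve on)
    bcfg$replete_threshold <- cfg$reference_range[1L] - 1.5 * cfg$noise_sd
  }
  catalog <- action_catalog(cfg$electrolyte)
  agent <- function(level, state_row, prev_action) {
    behavior_action(level, bcfg, catalog)
  }
  seed <- cfg$rng_seed + (bcfg$rng_seed %||% 0L)
  sim_visits(cfg, agent, seed)
}

#' Simulate a cohort treated by a learned policy
#'
#' Rolls the simulator forward with actions chosen by \code{policy} (e.g. the
#' greedy policy of a fitted Q-function) instead of the clinician behavior
#' model. State features the policy was trained on but that the simulator does
#' not produce are filled with the policy's stored training means.
#'
#' @param policy a policy object from [greedy_policy()] (or any function
#'   mapping a 1-row state data frame to a catalog index).
#' @param cfg a [sim_config()].
#' @param n_visits number of visits (defaults to \code{cfg$n_visits}).
#' @param rng_seed seed (defaults to \code{cfg$rng_seed}).
#' @param explore_prob probability per decision point of replacing the
#'   policy's choice with execution noise: an omitted dose (NONE) half the
#'   time, a uniformly random repletion action otherwise. A deterministic
#'   policy executed with no such noise produces logs with zero action
#'   diversity at each state, and no model-free off-policy estimator is
#'   identified on such logs; a small positive value restores the positivity
#'   (overlap) condition, reflecting the omissions and unprompted orders real
#'   clinician logs contain.
#' @return an \code{"ehr_tables"} object, as [simulate_cohort()].
#' @export
rollout_policy <- function(policy, cfg, n_visits = cfg$n_visits,
                           rng_seed = cfg$rng_seed, explore_prob = 0) {
  cfg$n_visits <- as.integer(n_visits)
  cfg$rng_seed <- as.integer(rng_seed)
  validate_sim_config(cfg)
  stopifnot(explore_prob >= 0, explore_prob <= 1)
  catalog <- action_catalog(cfg$electrolyte)
  none_idx <- which(catalog$route == "NONE")[1L]
  replete_idx <- which(catalog$route != "NONE")
  agent <- function(level, state_row, prev_action) {
    if (explore_prob > 0 && stats::runif(1) < explore_prob) {
      if (stats::runif(1) < 0.5) return(none_idx)
      return(sample(replete_idx, 1L))
    }
    policy_actions(policy, state_row)
  }
  sim_visits(cfg, agent, cfg$rng_seed)
}

#' Write the raw EHR tables to disk
#'
#' Writes \code{static.csv}, \code{observations.csv} and
#' \code{medications.csv} into \code{dir}; the column names are the package's
#' ingestion contract.
#'
#' @param tables an \code{"ehr_tables"} object.
#' @param dir output directory (created if needed).
#' @return invisibly, the three file paths.
#' @export
write_ehr <- function(tables, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("static.csv", "observations.csv", "medications.csv"))
  utils::write.csv(tables$static, paths[1L], row.names = FALSE)
  utils::write.csv(tables$observations, paths[2L], row.names = FALSE)
  utils::write.csv(tables$medications, paths[3L], row.names = FALSE)
  invisible(paths)
}
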
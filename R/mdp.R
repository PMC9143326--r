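#' Clinical state feature list used on the full EHR cohort
#'
#' The 52-feature default state: static attributes, vitals, raw and
#' indicator labs, prior-interval medication classes and procedures relevant to
#' electrolyte homeostasis. The simulator emits only a subset of these;
#' [build_transitions()] derives its feature set from the data unless an
#' explicit list is configured, so both the full EHR feature set and reduced
#' research configurations are supported by the same machinery.
#'
#' @return character vector of feature names.
#' @export
clinical_state_features <- function() {
  c("age", "sex_male", "admit_weight", "floor_icu",
    "heart_rate", "resp_rate", "temp", "spo2", "urine_output",
    "bp_sys", "bp_dia",
    "K", "Mg", "P", "sodium", "chloride", "anion_gap", "creatinine",
    "hemoglobin", "glucose", "bun", "wbc",
    "ca_ionized_ind", "glucose_ind", "cpk_ind", "ldh_ind", "alt_ind",
    "ast_ind", "pth_ind",
    "K_iv_prev", "K_po_prev", "Mg_iv_prev", "Mg_po_prev", "P_iv_prev",
    "P_po_prev", "ca_iv_prev", "ca_po_prev", "loop_diuretic_prev",
    "thiazide_prev", "acetazolamide_prev", "spironolactone_prev",
    "fluids_prev", "vasopressor_prev", "beta_blocker_prev",
    "ca_blocker_prev", "dextrose_prev", "insulin_prev", "kayexalate_prev",
    "tpn_prev", "pn_prev", "po_nutrition_prev",
    "transfusion_prev", "dialysis_prev")
}

#' Markov decision process specification
#'
#' Bundles everything that defines the repletion MDP for one electrolyte: the
#' state feature list, the discrete action catalog, the discount factor, the
#' reference range and the reward weights. The transition law is never modeled
#' explicitly; it is represented by the empirical one-step samples.
#'
#' @param electrolyte \code{"K"}, \code{"Mg"} or \code{"P"}.
#' @param state_features ordered character vector of state features, or
#'   \code{NULL} to derive them from the binned data at transition-building
#'   time.
#' @param gamma discount factor in [0, 1); default 0.9, suited to stays of up
#'   to 32 six-hour decision points.
#' @param reference_range (low, high); defaults per electrolyte: K 3.5-5.0
#'   mEq/L, Mg 1.7-2.3 mg/dL, P 2.5-4.5 mg/dL.
#' @param weights a [reward_weights()] vector; defaults to the electrolyte's
#'   training preset.
#' @param reward_form \code{"indicator"} (default) or \code{"graded"}; see
#'   [reward()].
#' @return list of class \code{"mdp_spec"} (includes the action catalog).
#' @export
mdp_spec <- function(electrolyte = c("K", "Mg", "P"), state_features = NULL,
                     gamma = 0.9, reference_range = NULL, weights = NULL,
                     reward_form = c("indicator", "graded")) {
  electrolyte <- match.arg(electrolyte)
  reward_form <- match.arg(reward_form)
  stopifnot(gamma >= 0, gamma < 1)
  if (!is.null(state_features)) {
    stopifnot(length(state_features) > 0,
              !anyDuplicated(state_features))
  }
  rr <- reference_range %||% switch(electrolyte,
    K = c(3.5, 5.0), Mg = c(1.7, 2.3), P = c(2.5, 4.5))
  stopifnot(length(rr) == 2L, rr[1L] < rr[2L])
  w <- weights %||% weight_presets(electrolyte)$training
  structure(list(electrolyte = electrolyte,
                 state_features = state_features,
                 gamma = gamma,
                 reference_range = rr,
                 weights = w,
                 reward_form = reward_form,
                 catalog = action_catalog(electrolyte)),
            class = "mdp_spec")
}

# assemble the per-bin state matrix for one binned, imputed visit
visit_state_matrix <- function(bv, spec) {
  elec <- spec$electrolyte
  n <- bv$n_bins
  catalog <- spec$catalog
  # historical action per bin
  acts <- vapply(seq_len(n) - 1L, function(b) {
    as.integer(encode_historical_action(
      bv$medications[bv$medications$bin == b, , drop = FALSE], catalog))
  }, integer(1))
  po_prev <- c(0, as.numeric(catalog$po_level[acts[-n]] > 0))
  iv_prev <- c(0, as.numeric(catalog$iv_level[acts[-n]] > 0))
  base <- cbind(age = rep(bv$age, n),
                admit_weight = rep(bv$admit_weight, n),
                sex_male = rep(as.numeric(identical(bv$sex, "M")), n),
                hours_in = (seq_len(n) - 1L) * bv$bin_width)
  m <- cbind(base, bv$features)
  m <- cbind(m, stats::setNames(data.frame(po_prev, iv_prev),
                                paste0(elec, c("_po_prev", "_iv_prev"))))
  m <- as.matrix(m)
  list(states = m, actions = acts)
}

#' Build one-step transition samples from a binned, imputed cohort
#'
#' For every consecutive pair of 6 h bins within a visit, emits one
#' \code{<state, action, reward, next state>} sample: the action is the
#' historical repletion (encoded onto the catalog) ordered in the earlier bin,
#' and the reward's range penalties are evaluated at the later bin's
#' electrolyte level. The final bin of each visit emits a terminal sample
#' (its range penalty evaluated at its own level; no bootstrap target).
#' Visits with fewer than two bins are skipped with a reported count.
#'
#' @param binned a fully imputed \code{"binned_cohort"}.
#' @param spec an [mdp_spec()]; a \code{NULL} \code{state_features} is
#'   resolved to the features present in the data.
#' @return list of class \code{"transition_set"}: matrices \code{state} and
#'   \code{next_state} (terminal rows zeroed), integer vectors \code{action}
#'   and \code{next_action} (NA at terminals), numeric \code{reward}, matrix
#'   \code{phi} (n x 4 penalty features), logical \code{terminal},
#'   \code{visit_id}, \code{bin}, and the resolved \code{spec}.
#' @export
build_transitions <- function(binned, spec) {
  elec <- spec$electrolyte
  if (!elec %in% attr(binned, "variables")) {
    stop("binned cohort has no '", elec, "' feature")
  }
  skipped <- 0L
  per_visit <- list()
  for (bv in binned) {
    if (bv$n_bins < 2L) { skipped <- skipped + 1L; next }
    if (anyNA(bv$features)) {
      stop("visit ", bv$visit_id, " contains missing cells; impute first")
    }
    sm <- visit_state_matrix(bv, spec)
    n <- bv$n_bins
    catalog <- spec$catalog
    a <- sm$actions
    lev <- bv$features[, elec]
    next_lev <- c(lev[-1L], lev[n])  # terminal row penalized at its own level
    phi <- reward_features(catalog$iv_level[a] > 0, catalog$po_level[a] > 0,
                           next_lev, spec$reference_range, spec$reward_form)
    r <- -as.numeric(phi %*% as.numeric(spec$weights))
    per_visit[[length(per_visit) + 1L]] <- list(
      state = sm$states,
      next_state = rbind(sm$states[-1L, , drop = FALSE],
                         matrix(0, 1L, ncol(sm$states))),
      action = a,
      next_action = c(a[-1L], NA_integer_),
      reward = r,
      phi = phi,
      terminal = c(rep(FALSE, n - 1L), TRUE),
      visit_id = rep(bv$visit_id, n),
      bin = seq_len(n) - 1L
    )
  }
  if (!length(per_visit)) stop("no visits with >= 2 bins")
  if (skipped > 0L) message("build_transitions: skipped ", skipped,
                            " visit(s) with < 2 bins")
  cat_all <- function(fld) {
    x <- lapply(per_visit, `[[`, fld)
    if (is.matrix(x[[1L]])) do.call(rbind, x) else do.call(c, x)
  }
  out <- list(state = cat_all("state"), next_state = cat_all("next_state"),
              action = cat_all("action"), next_action = cat_all("next_action"),
              reward = cat_all("reward"), phi = cat_all("phi"),
              terminal = cat_all("terminal"), visit_id = cat_all("visit_id"),
              bin = cat_all("bin"))
  if (is.null(spec$state_features)) {
    spec$state_features <- colnames(out$state)
  } else {
    miss <- setdiff(spec$state_features, colnames(out$state))
    if (length(miss)) stop("state features absent from data: ",
                           paste(miss, collapse = ", "))
    out$state <- out$state[, spec$state_features, drop = FALSE]
    out$next_state <- out$next_state[, spec$state_features, drop = FALSE]
  }
  out$spec <- spec
  out$n_skipped <- skipped
  class(out) <- "transition_set"
  out
}

#' @export
print.transition_set <- function(x, ...) {
  cat("Transition set:", length(x$reward), "samples (",
      sum(x$terminal), "terminal ) over",
      length(unique(x$visit_id)), "visits;",
      ncol(x$state), "state features;",
      nrow(x$spec$catalog), "actions; gamma =", x$spec$gamma, "\n")
  invisible(x)
}

#' Subset a transition set by visit
#'
#' @param samples a \code{"transition_set"}.
#' @param visit_ids visits to keep.
#' @return a \code{"transition_set"} restricted to those visits.
#' @export
subset_transitions <- function(samples, visit_ids) {
  keep <- samples$visit_id %in% visit_ids
  out <- samples
  for (f in c("action", "next_action", "reward", "terminal", "visit_id", "bin")) {
    out[[f]] <- samples[[f]][keep]
  }
  out$state <- samples$state[keep, , drop = FALSE]
  out$next_state <- samples$next_state[keep, , drop = FALSE]
  out$phi <- samples$phi[keep, , drop = FALSE]
  out
}

#' Write / read a transition set as a flat CSV
#'
#' One row per sample: identifiers, action index, reward, the four penalty
#' features, then state and next-state feature columns.
#'
#' @param samples a \code{"transition_set"}.
#' @param path CSV path.
#' @return \code{write_transitions} returns the path invisibly.
#' @export
write_transitions <- function(samples, path) {
  df <- data.frame(visit_id = samples$visit_id, bin = samples$bin,
                   action = samples$action, next_action = samples$next_action,
                   reward = samples$reward, terminal = samples$terminal)
  colnames(samples$phi) <- paste0("phi_", c("iv", "po", "high", "low"))
  df <- cbind(df, samples$phi,
              stats::setNames(as.data.frame(samples$state),
                              paste0("s_", colnames(samples$state))),
              stats::setNames(as.data.frame(samples$next_state),
                              paste0("sp_", colnames(samples$next_state))))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
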
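#' Discounted feature expectations of the logged behavior
#'
#' The 4-vector \eqn{\mu = E[\sum_t \gamma^t \phi_t]} of discounted penalty
#' features (IV cost, PO cost, above-range, below-range), averaged over visits.
#' This is the quantity the inverse-RL loop matches.
#'
#' @param samples a \code{"transition_set"} (its \code{phi} matrix is used).
#' @param gamma discount factor; defaults to the sample set's.
#' @return list of class \code{"feature_expectation"} with \code{mu} (named
#'   4-vector), \code{gamma}, \code{n_visits}.
#' @export
behavior_feature_expectations <- function(samples, gamma = samples$spec$gamma) {
  if (length(samples$reward) == 0L) stop("empty sample set")
  vids <- unique(samples$visit_id)
  mu <- c(iv = 0, po = 0, high = 0, low = 0)
  for (v in vids) {
    sel <- which(samples$visit_id == v)
    sel <- sel[order(samples$bin[sel])]
    disc <- gamma^(seq_along(sel) - 1L)
    mu <- mu + as.numeric(disc %*% samples$phi[sel, , drop = FALSE])
  }
  structure(list(mu = mu / length(vids), gamma = gamma,
                 n_visits = length(vids)),
            class = "feature_expectation")
}

# discounted feature expectations of a candidate policy, estimated model-free:
# one FQE per penalty component (accumulating +phi_j), read off at initial
# states under the policy's own action
policy_feature_expectations <- function(policy, samples, n_iterations,
                                        regressor, rng_seed) {
  mu <- numeric(4L)
  for (j in 1:4) {
    f <- fqe(policy, samples, n_iterations = n_iterations,
             regressor = regressor, rng_seed = rng_seed,
             reward = samples$phi[, j])
    mu[j] <- policy_value(f, samples, at = "initial")$mean
  }
  names(mu) <- c("iv", "po", "high", "low")
  mu
}

# direction w (||w||_2 <= 1) maximizing the smallest margin
# min_j w . (mu_E - mu_j). Dual: w is the unit vector along the minimum-norm
# point of the convex hull of {mu_E - mu_j}, found by Frank-Wolfe with exact
# line search (Gilbert's algorithm); deterministic.
max_margin_direction <- function(mu_E, candidates) {
  D <- t(vapply(candidates, function(m) mu_E - m, numeric(4L)))
  if (max(abs(D)) < 1e-12) return(numeric(4L))
  p <- D[1L, ]
  for (it in seq_len(500L)) {
    scores <- as.numeric(D %*% p)
    j <- which.min(scores)
    # stationarity: the worst vertex is no better than the current point
    if (scores[j] >= sum(p * p) - 1e-12) break
    d <- D[j, ] - p
    lam <- min(max(-sum(p * d) / sum(d * d), 0), 1)
    p <- p + lam * d
    if (sum(p * p) < 1e-18) break  # hull contains the origin: no margin
  }
  n <- sqrt(sum(p^2))
  if (n < 1e-9) return(numeric(4L))
  p / n
}

#' Estimate reward weights from observed behavior (inverse RL)
#'
#' Apprenticeship learning by discounted feature-expectation matching over the
#' four penalty features, with the max-margin weight update: starting from a
#' non-repleting reference policy, each outer step proposes the weight
#' direction under which the observed behavior dominates every candidate
#' policy found so far by the largest margin, solves the induced MDP with
#' [fqi()], and estimates the new policy's discounted feature expectations by
#' per-component fitted-Q evaluation on held-out visits. It stops when a
#' candidate's Euclidean feature-matching error drops below \code{tol} or
#' after \code{max_outer_iters} proposals; the final max-margin direction is
#' reported, L1-normalized. Signs are unconstrained, so small negative cost
#' weights — as estimated for historical clinician behavior — are
#' representable.
#'
#' @param samples behavior transition samples for one electrolyte sub-cohort.
#' @param fqi_iterations,fqe_iterations inner-loop regression sweeps.
#' @param regressor a [regressor_spec()] shared by the inner FQI/FQE fits.
#' @param max_outer_iters proposal budget.
#' @param tol stopping tolerance on the matching error.
#' @param holdout_fraction share of visits reserved for the feature-expectation
#'   estimates (the rest train the inner FQI).
#' @param rng_seed integer seed (drives the holdout split and the regressors).
#' @return list of class \code{"irl_fit"}: \code{weights} (unit L1 norm),
#'   \code{raw_weights}, \code{matching_error} (best achieved),
#'   \code{error_trajectory}, \code{best_so_far} (cumulative minima),
#'   \code{converged}, \code{degenerate} (TRUE when the behavior features
#'   carry no signal), \code{mu_behavior}.
#' @export
irl_weights <- function(samples, fqi_iterations = 8L, fqe_iterations = 8L,
                        regressor = regressor_spec("xgboost", nrounds = 40L,
                                                   max_depth = 4L),
                        max_outer_iters = 8L, tol = 0.05,
                        holdout_fraction = 0.35, rng_seed = 1L) {
  if (length(samples$reward) == 0L) stop("empty sample set")
  sp <- split_cohort(unique(samples$visit_id),
                     train_fraction = 1 - holdout_fraction,
                     rng_seed = rng_seed)
  train <- subset_transitions(samples, sp$train)
  held <- subset_transitions(samples, sp$test)

  mu_E_phi <- behavior_feature_expectations(held)$mu
  degenerate <- sqrt(sum(mu_E_phi^2)) < 1e-8
  if (degenerate) {
    warning("behavior feature expectations are (near) zero: ",
            "reward weights are unidentifiable from this behavior")
  }
  # work in psi = -phi space, where the expert MAXIMIZES w . mu_psi
  mu_E <- -mu_E_phi

  pfe <- function(policy) {
    -policy_feature_expectations(policy, held, fqe_iterations, regressor,
                                 rng_seed)
  }
  # reference policy: never replete
  none_idx <- which(samples$spec$catalog$route == "NONE")[1L]
  p0 <- function(states) rep(none_idx, nrow(states))

  # Max-margin feature matching: at every outer step, propose the weight
  # direction under which the behavior's feature expectations dominate every
  # candidate policy found so far by the largest margin, solve the induced
  # MDP, and add the new policy's feature expectations to the candidate set.
  # As candidates accumulate, the only surviving direction is one that
  # rationalizes the behavior. The residual mixture direction is never
  # reported: once the candidate mixture matches the behavior it is pure
  # estimation noise.
  candidates <- list(pfe(p0))
  errs <- sqrt(sum((mu_E - candidates[[1L]])^2))
  w <- max_margin_direction(mu_E, candidates)
  converged <- errs[1L] <= tol
  i <- 0L
  while (!converged && i < max_outer_iters) {
    i <- i + 1L
    if (sqrt(sum(w^2)) < 1e-12) break  # nothing separates behavior from
                                        # candidates: no usable signal left
    # reward under the proposal: w . psi = -(w . phi)
    r_cand <- -as.numeric(train$phi %*% w)
    q <- fqi(train, n_iterations = fqi_iterations, regressor = regressor,
             rng_seed = rng_seed, reward = r_cand)
    mu_i <- pfe(greedy_policy(q))
    candidates[[length(candidates) + 1L]] <- mu_i
    errs <- c(errs, sqrt(sum((mu_E - mu_i)^2)))
    converged <- errs[length(errs)] <= tol
    w_new <- max_margin_direction(mu_E, candidates)
    if (sqrt(sum(w_new^2)) < 1e-12) {
      # the candidate hull has reached the behavior point: the behavior is
      # matched and the last separating direction is the estimate
      converged <- TRUE
      break
    }
    w <- w_new
  }
  best <- list(err = min(errs), w = w)
  if (!converged) {
    message("irl_weights: feature matching did not reach tol = ", tol,
            " (best error ", format(best$err, digits = 3),
            "); returning best-so-far weights")
  }
  # psi-space weights are penalty weights in phi space: reward = -(w . phi)
  raw <- best$w
  w_out <- if (sum(abs(raw)) < 1e-12) {
    # no signal to normalize: all-NaN weights, flagged degenerate
    degenerate <- TRUE
    structure(c(iv = NaN, po = NaN, high = NaN, low = NaN),
              class = c("reward_weights", "numeric"))
  } else {
    normalize_weights(raw)
  }
  structure(list(weights = w_out,
                 raw_weights = stats::setNames(as.numeric(raw),
                                               c("iv", "po", "high", "low")),
                 matching_error = best$err,
                 error_trajectory = errs,
                 best_so_far = cummin(errs),
                 converged = converged,
                 degenerate = degenerate,
                 mu_behavior = mu_E_phi,
                 n_outer_iters = i,
                 rng_seed = rng_seed),
            class = "irl_fit")
}

#' @export
print.irl_fit <- function(x, ...) {
  cat("Inverse-RL reward weight estimate (feature matching)\n")
  cat("  weights (iv, po, high, low):",
      paste(format(round(as.numeric(x$weights), 3)), collapse = ", "), "\n")
  cat("  matching error:", format(x$matching_error, digits = 3),
      if (x$converged) "(converged)" else "(budget reached)", "\n")
  if (x$degenerate) cat("  WARNING: degenerate behavior features\n")
  invisible(x)
}
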
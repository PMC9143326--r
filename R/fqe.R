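#' Fitted-Q evaluation (off-policy value estimation)
#'
#' Estimates \eqn{Q^\pi} of a FIXED policy from off-policy transition samples
#' by iterated regression with targets
#' \eqn{y = r + \gamma\, \hat Q_{k-1}(s', \pi(s'))} (terminal samples:
#' \eqn{y = r}). Evaluating the logged historical behavior substitutes the
#' recorded next action for \eqn{\pi(s')}.
#'
#' @param policy a \code{"repletion_policy"}, a [historical_policy()], or a
#'   function mapping a state matrix to catalog indices.
#' @param samples a \code{"transition_set"}.
#' @param n_iterations regression sweeps (default 32, as [fqi()]).
#' @param regressor a [regressor_spec()].
#' @param rng_seed integer seed.
#' @param reward optional replacement reward vector; the inverse-RL loop
#'   passes each penalty feature column here to estimate per-component
#'   discounted feature expectations.
#' @return object of class \code{"fqe"} with the fitted regressor and
#'   metadata; use [predict.fqe()] and [policy_value()] to read values off it.
#' @export
fqe <- function(policy, samples, n_iterations = 32L,
                regressor = regressor_spec("xgboost"), rng_seed = 1L,
                reward = NULL) {
  stopifnot(length(samples$reward) > 0L)
  spec <- samples$spec
  K <- nrow(spec$catalog)
  gamma <- spec$gamma
  r <- reward %||% samples$reward
  stopifnot(length(r) == length(samples$reward))
  nt <- !samples$terminal
  Sp <- samples$next_state[nt, , drop = FALSE]
  next_a <- if (inherits(policy, "historical_policy")) {
    a <- samples$next_action[nt]
    if (anyNA(a)) stop("historical evaluation requires next_action on all ",
                       "non-terminal samples")
    a
  } else {
    policy_actions(policy, Sp)
  }
  X <- encode_sa(samples$state, samples$action, K)
  Xp <- encode_sa(Sp, next_a, K)

  fit <- NULL
  for (k in seq_len(n_iterations)) {
    y <- r
    if (k > 1L && gamma > 0 && any(nt)) {
      y[nt] <- r[nt] + gamma * predict_q_regressor(fit, Xp)
    }
    if (!all(is.finite(y))) {
      stop("non-finite regression targets at FQE iteration ", k)
    }
    fit <- fit_q_regressor(regressor, X, y, seed = rng_seed)
  }
  structure(list(model = fit, catalog = spec$catalog,
                 feature_names = colnames(samples$state),
                 feature_means = colMeans(samples$state),
                 gamma = gamma, n_iterations = n_iterations,
                 policy = policy, spec = spec,
                 n_samples = length(r), rng_seed = rng_seed,
                 regressor = regressor),
            class = "fqe")
}

#' @export
print.fqe <- function(x, ...) {
  who <- if (inherits(x$policy, "historical_policy")) "historical behavior"
         else "target policy"
  cat("Fitted-Q evaluation of", who, "(", x$spec$electrolyte, ")\n")
  cat("  samples:", x$n_samples, " gamma:", x$gamma,
      " iterations:", x$n_iterations, " regressor:", x$regressor$type, "\n")
  invisible(x)
}

#' @rdname predict.fqi
#' @export
predict.fqe <- function(object, states, actions = NULL, ...) {
  predict.fqi(object, states, actions, ...)
}

#' Estimated policy value over a sample set
#'
#' Reads state-action values off a fitted-Q evaluation: at every sample state
#' the evaluated policy's own action is scored (the logged action for
#' historical behavior). \code{at = "initial"} restricts to each visit's first
#' sample, which estimates the expected discounted return from admission and
#' is directly comparable with a Monte-Carlo rollout value.
#'
#' @param fqe_fit an \code{"fqe"} object.
#' @param samples the \code{"transition_set"} to score (typically the test
#'   set).
#' @param at \code{"all"} state-action pairs or \code{"initial"} states only.
#' @return list with \code{mean}, \code{values}, \code{n}.
#' @export
policy_value <- function(fqe_fit, samples, at = c("all", "initial")) {
  at <- match.arg(at)
  keep <- if (at == "initial") !duplicated(samples$visit_id)
          else rep(TRUE, length(samples$visit_id))
  S <- samples$state[keep, , drop = FALSE]
  a <- if (inherits(fqe_fit$policy, "historical_policy")) {
    samples$action[keep]
  } else {
    policy_actions(fqe_fit$policy, S)
  }
  v <- predict.fqi(fqe_fit, S, actions = a)
  list(mean = mean(v), values = v, n = length(v))
}
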
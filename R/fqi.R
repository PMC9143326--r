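#' Fitted Q-iteration for offline policy learning
#'
#' Learns a Q-value function from a fixed batch of one-step transition samples
#' by iterated regression: iteration 1 fits targets \eqn{y = r}; iteration k
#' fits \eqn{y = r + \gamma \max_{a'} Q_{k-1}(s', a')}, with terminal samples
#' always contributing \eqn{y = r}. The regression input is the state vector
#' concatenated with a one-hot encoding of the catalog action, so a single
#' model covers the whole action space. The procedure is deterministic under a
#' fixed seed and regressor specification.
#'
#' @param samples a \code{"transition_set"} from [build_transitions()].
#' @param n_iterations number of regression sweeps; the default 32 matches the
#'   maximum number of 6 h decision points in an eight-day stay.
#' @param regressor a [regressor_spec()].
#' @param rng_seed integer seed for the regressor.
#' @param reward optional replacement reward vector (same length as the
#'   sample set); used by the inverse-RL loop to re-solve the MDP under
#'   candidate weights without rebuilding transitions.
#' @param verbose print the sup-norm change of the Q iterates.
#' @return object of class \code{"fqi"}: the fitted regressor, the catalog,
#'   feature names and training means, gamma, the per-iteration sup-norm
#'   deltas, and training metadata.
#' @seealso [greedy_policy()], [recommend()], [fqe()]
#' @export
fqi <- function(samples, n_iterations = 32L,
                regressor = regressor_spec("xgboost"), rng_seed = 1L,
                reward = NULL, verbose = FALSE) {
  stopifnot(length(samples$reward) > 0L)
  spec <- samples$spec
  K <- nrow(spec$catalog)
  if (any(samples$action < 1L | samples$action > K)) {
    stop("sample actions outside the catalog")
  }
  r <- reward %||% samples$reward
  stopifnot(length(r) == length(samples$reward))
  gamma <- spec$gamma
  X <- encode_sa(samples$state, samples$action, K)
  nt <- !samples$terminal
  Sp <- samples$next_state[nt, , drop = FALSE]

  fit <- NULL
  q_prev <- NULL
  deltas <- numeric(0)
  for (k in seq_len(n_iterations)) {
    y <- r
    if (k > 1L && gamma > 0 && any(nt)) {
      vmax <- apply(q_all_actions(fit, Sp, K), 1L, max)
      y[nt] <- r[nt] + gamma * vmax
    }
    if (!all(is.finite(y))) {
      stop("non-finite regression targets at FQI iteration ", k)
    }
    fit <- fit_q_regressor(regressor, X, y, seed = rng_seed)
    q_cur <- predict_q_regressor(fit, X)
    if (!is.null(q_prev)) {
      deltas <- c(deltas, max(abs(q_cur - q_prev)))
      if (verbose) message(sprintf("FQI iter %d: sup|dQ| = %.3g", k,
                                   deltas[length(deltas)]))
    }
    q_prev <- q_cur
  }
  structure(list(model = fit, catalog = spec$catalog,
                 feature_names = colnames(samples$state),
                 feature_means = colMeans(samples$state),
                 gamma = gamma, n_iterations = n_iterations,
                 spec = spec, deltas = deltas,
                 n_samples = length(r), rng_seed = rng_seed,
                 regressor = regressor),
            class = "fqi")
}

#' @export
print.fqi <- function(x, ...) {
  cat("Fitted Q-iteration policy model (", x$spec$electrolyte, ")\n", sep = "")
  cat("  samples:", x$n_samples, " features:", length(x$feature_names),
      " actions:", nrow(x$catalog), "\n")
  cat("  gamma:", x$gamma, " iterations:", x$n_iterations,
      " regressor:", x$regressor$type, "\n")
  if (length(x$deltas)) {
    cat("  final sup-norm Q change:",
        format(x$deltas[length(x$deltas)], digits = 3), "\n")
  }
  invisible(x)
}

#' @export
summary.fqi <- function(object, ...) {
  print(object)
  cat("  sup-norm Q change by iteration:\n")
  print(round(object$deltas, 5))
  invisible(object)
}

# align arbitrary state input (matrix / data frame / named vector) onto the
# model's feature order; `fill` supplies values for absent features
align_states <- function(states, feature_names, fill = NULL, strict = FALSE) {
  if (is.numeric(states) && !is.matrix(states)) {
    states <- matrix(states, nrow = 1L, dimnames = list(NULL, names(states)))
  }
  states <- as.matrix(states)
  miss <- setdiff(feature_names, colnames(states))
  if (length(miss)) {
    if (strict || is.null(fill)) {
      stop("state is missing feature(s): ", paste(miss, collapse = ", "))
    }
    add <- matrix(rep(fill[miss], each = nrow(states)), nrow = nrow(states),
                  dimnames = list(NULL, miss))
    states <- cbind(states, add)
  }
  states[, feature_names, drop = FALSE]
}

#' Predict Q-values from a fitted Q-function
#'
#' @param object an \code{"fqi"} (or \code{"fqe"}) fit.
#' @param states a state matrix/data frame (or a single named vector); columns
#'   are matched by name, and features the model was trained on but that are
#'   absent are filled with their training means.
#' @param actions optional integer catalog indices (recycled); when omitted,
#'   the full n x |catalog| Q matrix is returned with catalog labels as column
#'   names.
#' @param ... unused.
#' @return numeric vector (when \code{actions} given) or matrix of Q-values.
#' @export
predict.fqi <- function(object, states, actions = NULL, ...) {
  S <- align_states(states, object$feature_names, fill = object$feature_means)
  K <- nrow(object$catalog)
  if (is.null(actions)) {
    q <- q_all_actions(object$model, S, K)
    colnames(q) <- object$catalog$label
    return(q)
  }
  actions <- rep_len(as.integer(actions), nrow(S))
  predict_q_regressor(object$model, encode_sa(S, actions, K))
}

#' Greedy policy of a fitted Q-function
#'
#' Selects the catalog action maximizing Q at each state. Exact ties are
#' broken by catalog order, which places NONE first: on indifference the
#' policy does not treat.
#'
#' @param q an \code{"fqi"} fit.
#' @return object of class \code{"repletion_policy"}.
#' @export
greedy_policy <- function(q) {
  stopifnot(inherits(q, "fqi"))
  structure(list(type = "greedy", q = q, catalog = q$catalog),
            class = "repletion_policy")
}

#' Save / load a fitted Q-function as a policy artifact directory
#'
#' Serializes the regressor (native xgboost format when applicable) next to a
#' JSON sidecar recording the catalog, feature order, discount factor, seed,
#' iteration count and training-sample count — everything needed to audit or
#' reload the policy.
#'
#' @param q an \code{"fqi"} fit.
#' @param dir artifact directory (created).
#' @return \code{save_policy} returns \code{dir} invisibly;
#'   \code{load_policy} returns the restored \code{"fqi"} object.
#' @export
save_policy <- function(q, dir) {
  stopifnot(inherits(q, "fqi"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sidecar <- list(electrolyte = q$spec$electrolyte,
                  regressor = unclass(q$regressor),
                  feature_names = q$feature_names,
                  feature_means = as.list(q$feature_means),
                  gamma = q$gamma,
                  n_iterations = q$n_iterations,
                  n_samples = q$n_samples,
                  rng_seed = q$rng_seed,
                  catalog = as.data.frame(q$catalog))
  jsonlite::write_json(sidecar, file.path(dir, "policy.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (q$model$spec$type == "xgboost") {
    xgboost::xgb.save(q$model$model, file.path(dir, "model.ubj"))
    saveRDS(q[setdiff(names(q), "model")], file.path(dir, "fqi.rds"))
    saveRDS(q$model[setdiff(names(q$model), "model")],
            file.path(dir, "regressor_meta.rds"))
  } else {
    saveRDS(q, file.path(dir, "fqi.rds"))
  }
  invisible(dir)
}

#' @rdname save_policy
#' @export
load_policy <- function(dir) {
  q <- readRDS(file.path(dir, "fqi.rds"))
  if (file.exists(file.path(dir, "model.ubj"))) {
    meta <- readRDS(file.path(dir, "regressor_meta.rds"))
    meta$model <- xgboost::xgb.load(file.path(dir, "model.ubj"))
    class(meta) <- "q_regressor"
    q$model <- meta
    class(q) <- "fqi"
  }
  q
}

#' Marker for the logged historical policy
#'
#' Used with [fqe()] to evaluate the behavior that generated the data: the
#' bootstrap target substitutes the logged next action for \eqn{\pi(s')}.
#'
#' @return object of class \code{"historical_policy"}.
#' @export
historical_policy <- function() {
  structure(list(type = "historical"), class = "historical_policy")
}

#' Actions a policy takes at a batch of states
#'
#' @param policy a \code{"repletion_policy"}, or a plain function mapping a
#'   state matrix to integer catalog indices.
#' @param states state matrix / data frame.
#' @return integer vector of catalog indices.
#' @export
policy_actions <- function(policy, states) {
  if (inherits(policy, "repletion_policy")) {
    qm <- predict.fqi(policy$q, states)
    return(max.col(qm, ties.method = "first"))
  }
  if (is.function(policy)) {
    return(as.integer(policy(states)))
  }
  stop("unsupported policy object")
}

#' Hierarchical repletion recommendation for one patient state
#'
#' Decodes the policy's flat catalog choice into the three-step readout a
#' clinician reviews: replete or not; if so, by which route; and the dose
#' (and infusion duration for IV). All per-action Q-values are included for
#' audit.
#'
#' @param policy a \code{"repletion_policy"}.
#' @param state a single named state vector or 1-row data frame. Every feature
#'   the Q-model was trained on must be present; missing features are an
#'   error naming them.
#' @return list of class \code{"recommendation"}: \code{replete},
#'   \code{route}, \code{po_dose_mg}, \code{iv_dose}, \code{iv_dose_unit},
#'   \code{iv_duration_h}, \code{action_index}, \code{q_values}.
#' @export
recommend <- function(policy, state) {
  stopifnot(inherits(policy, "repletion_policy"))
  S <- align_states(state, policy$q$feature_names, strict = TRUE)
  stopifnot(nrow(S) == 1L)
  qv <- predict.fqi(policy$q, S)[1L, ]
  idx <- which.max(qv)  # ties to first = NONE-first catalog order
  a <- policy$catalog[idx, ]
  structure(list(
    replete = a$route != "NONE",
    route = if (a$route == "NONE") NA_character_ else a$route,
    po_dose_mg = if (a$po_level > 0L) a$po_dose_mg else NA_real_,
    iv_dose = if (a$iv_level > 0L) a$iv_dose else NA_real_,
    iv_dose_unit = if (a$iv_level > 0L) a$iv_dose_unit else NA_character_,
    iv_duration_h = if (a$iv_level > 0L) a$iv_duration_h else NA_real_,
    action_index = as.integer(idx),
    q_values = qv
  ), class = "recommendation")
}

#' @export
print.recommendation <- function(x, ...) {
  if (!x$replete) {
    cat("Recommendation: no repletion\n")
  } else {
    cat("Recommendation: replete via", x$route, "\n")
    if (!is.na(x$po_dose_mg)) cat("  PO dose:", x$po_dose_mg, "mg\n")
    if (!is.na(x$iv_dose)) {
      cat("  IV dose:", x$iv_dose, x$iv_dose_unit, "over", x$iv_duration_h,
          "h\n")
    }
  }
  cat("  top Q-values:\n")
  print(round(sort(x$q_values, decreasing = TRUE)[1:min(5, length(x$q_values))], 4))
  invisible(x)
}
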
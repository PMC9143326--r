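#' Specify the function approximator used by FQI / FQE
#'
#' The Q-function regression is pluggable. Three back-ends are provided:
#' \describe{
#'   \item{\code{"xgboost"}}{gradient-boosted regression trees (the default);
#'     fast single-threaded prediction over catalog-sized action sweeps.}
#'   \item{\code{"ranger"}}{a randomized-tree ensemble, the classical choice
#'     for fitted Q-iteration.}
#'   \item{\code{"tabular"}}{exact interpolation: the prediction for an input
#'     row seen in training is the mean of its training targets, and 0 for
#'     unseen rows. On finite MDPs with full state-action coverage this makes
#'     FQI coincide with empirical value iteration, which is what the
#'     dynamic-programming equivalence tests exploit.}
#' }
#'
#' @param type back-end name.
#' @param nrounds,max_depth,eta xgboost parameters.
#' @param num_trees,min_node ranger parameters.
#' @return list of class \code{"regressor_spec"}.
#' @export
regressor_spec <- function(type = c("xgboost", "ranger", "tabular"),
                           nrounds = 60L, max_depth = 6L, eta = 0.3,
                           num_trees = 100L, min_node = 5L) {
  type <- match.arg(type)
  structure(list(type = type, nrounds = as.integer(nrounds),
                 max_depth = as.integer(max_depth), eta = eta,
                 num_trees = as.integer(num_trees),
                 min_node = as.integer(min_node)),
            class = "regressor_spec")
}

fit_q_regressor <- function(spec, X, y, seed = 1L) {
  stopifnot(all(is.finite(y)))
  model <- switch(spec$type,
    xgboost = {
      dm <- xgboost::xgb.DMatrix(X, label = y)
      xgboost::xgb.train(
        params = list(objective = "reg:squarederror",
                      max_depth = spec$max_depth, eta = spec$eta,
                      nthread = 1L, seed = as.integer(seed)),
        data = dm, nrounds = spec$nrounds, verbose = 0)
    },
    ranger = ranger::ranger(
      x = as.data.frame(X), y = y, num.trees = spec$num_trees,
      min.node.size = spec$min_node, seed = as.integer(seed),
      num.threads = 1L),
    tabular = {
      key <- apply(X, 1L, paste, collapse = "\r")
      list(means = tapply(y, key, mean))
    }
  )
  structure(list(spec = spec, model = model, p = ncol(X),
                 colnames = colnames(X)),
            class = "q_regressor")
}

predict_q_regressor <- function(fit, X) {
  switch(fit$spec$type,
    xgboost = as.numeric(stats::predict(fit$model, xgboost::xgb.DMatrix(X))),
    ranger = {
      df <- as.data.frame(X)
      colnames(df) <- fit$colnames
      as.numeric(stats::predict(fit$model, data = df,
                                num.threads = 1L)$predictions)
    },
    tabular = {
      key <- apply(X, 1L, paste, collapse = "\r")
      v <- as.numeric(fit$model$means[key])
      v[is.na(v)] <- 0
      v
    }
  )
}

# state (+) one-hot action design matrix
encode_sa <- function(states, action_idx, n_actions) {
  n <- nrow(states)
  A <- matrix(0, n, n_actions,
              dimnames = list(NULL, paste0("action_", seq_len(n_actions))))
  A[cbind(seq_len(n), action_idx)] <- 1
  cbind(states, A)
}

# Q(s, a) for every catalog action. Small batches sweep the whole action set
# in one prediction call (cheap for per-state queries); large batches go one
# action at a time to bound the design-matrix footprint.
q_all_actions <- function(fit, states, n_actions) {
  n <- nrow(states)
  if (n * n_actions <= 65536L) {
    total <- n * n_actions
    Sbig <- states[rep(seq_len(n), times = n_actions), , drop = FALSE]
    Abig <- matrix(0, total, n_actions,
                   dimnames = list(NULL, paste0("action_", seq_len(n_actions))))
    Abig[cbind(seq_len(total), rep(seq_len(n_actions), each = n))] <- 1
    return(matrix(predict_q_regressor(fit, cbind(Sbig, Abig)), n, n_actions))
  }
  out <- matrix(NA_real_, n, n_actions)
  A <- matrix(0, n, n_actions,
              dimnames = list(NULL, paste0("action_", seq_len(n_actions))))
  for (a in seq_len(n_actions)) {
    A[, a] <- 1
    out[, a] <- predict_q_regressor(fit, cbind(states, A))
    A[, a] <- 0
  }
  out
}
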
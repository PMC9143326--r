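#' Construct a four-component reward weight vector
#'
#' The reward that guides both policy learning and inverse reward estimation is
#' a weighted sum of four penalty conditions evaluated on a transition: the
#' cost of an IV repletion component, the cost of a PO component, the next
#' electrolyte level being above the reference range, and it being below the
#' range.
#'
#' @param w_iv,w_po,w_high,w_low the four weights (IV cost, PO cost,
#'   above-range, below-range).
#' @return named numeric vector of class \code{"reward_weights"} with names
#'   \code{iv}, \code{po}, \code{high}, \code{low}.
#' @export
reward_weights <- function(w_iv, w_po, w_high, w_low) {
  w <- c(iv = w_iv, po = w_po, high = w_high, low = w_low)
  stopifnot(all(is.finite(w)))
  class(w) <- c("reward_weights", "numeric")
  w
}

#' L1-normalize a reward weight vector
#'
#' Divides by the L1 norm so the absolute weights sum to one; signs are
#' preserved (estimated behavioral weights can legitimately carry negative
#' cost components).
#'
#' @param w numeric 4-vector (any names are kept).
#' @return a [reward_weights()] vector with unit L1 norm.
#' @export
normalize_weights <- function(w) {
  stopifnot(length(w) == 4L, all(is.finite(w)))
  n1 <- sum(abs(w))
  if (n1 == 0) stop("cannot normalize an all-zero weight vector")
  w <- as.numeric(w) / n1
  reward_weights(w[1L], w[2L], w[3L], w[4L])
}

#' Preset reward weight vectors
#'
#' Weight profiles for the three electrolytes: \code{training} is the default
#' profile used to train the learned repletion policy (cost-aware, dominated by
#' the below-range penalty), and \code{historical} is the corresponding
#' estimate of the weights implicitly driving observed clinician behavior,
#' which carries small negative repletion-cost components. All vectors are on
#' the L1 scale (the historical estimates and most training profiles sum to 1
#' in absolute value).
#'
#' @param electrolyte \code{"K"}, \code{"Mg"} or \code{"P"}.
#' @return list with elements \code{training} and \code{historical}, each a
#'   [reward_weights()] vector.
#' @export
weight_presets <- function(electrolyte = c("K", "Mg", "P")) {
  electrolyte <- match.arg(electrolyte)
  tr <- switch(electrolyte,
    K  = c(0.07, 0.04, 0.15, 0.74),
    Mg = c(0.01, 0.01, 0.48, 0.48),
    P  = c(0.08, 0.07, 0.50, 0.35)
  )
  hi <- switch(electrolyte,
    K  = c(-0.05, -0.08, 0.20, 0.67),
    Mg = c(-0.05, -0.01, 0.33, 0.61),
    P  = c(-0.25, 0.11, 0.30, 0.34)
  )
  list(training = reward_weights(tr[1], tr[2], tr[3], tr[4]),
       historical = reward_weights(hi[1], hi[2], hi[3], hi[4]))
}

# vectorized penalty features: one row per event
# phi = (has IV component, has PO component, next level > high, next level < low)
reward_features <- function(has_iv, has_po, next_level, reference_range,
                            form = c("indicator", "graded")) {
  form <- match.arg(form)
  lo <- reference_range[1L]
  hi <- reference_range[2L]
  if (form == "indicator") {
    f_hi <- as.numeric(next_level > hi)
    f_lo <- as.numeric(next_level < lo)
  } else {
    f_hi <- pmax(next_level - hi, 0)
    f_lo <- pmax(lo - next_level, 0)
  }
  cbind(iv = as.numeric(has_iv), po = as.numeric(has_po),
        high = f_hi, low = f_lo)
}

#' Transition reward under the four-term penalty model
#'
#' Computes the penalty feature vector phi and the scalar reward
#' \code{-(w . phi)} for one decision. With the default \code{"indicator"}
#' form each component of phi is a 0/1 flag (IV component taken, PO component
#' taken, next level above range, next level below range), so with
#' non-negative L1-normalized weights the reward is bounded in [-1, 0]. The
#' \code{"graded"} alternative replaces the range flags with the distance from
#' the nearest range endpoint.
#'
#' @param weights a [reward_weights()] vector.
#' @param action catalog index or row.
#' @param next_level the electrolyte level observed in the next interval
#'   (alternatively a named state vector containing the electrolyte feature).
#' @param reference_range length-2 numeric, (low, high).
#' @param catalog the [action_catalog()] the action belongs to.
#' @param form penalty form, \code{"indicator"} (default) or \code{"graded"}.
#' @return list with \code{reward} (scalar) and \code{phi} (named 4-vector).
#' @export
#' @examples
#' cat_k <- action_catalog("K")
#' w <- weight_presets("K")$training
#' reward(w, 1L, 3.2, c(3.5, 5.0), cat_k)$reward   # NONE, hypokalemic: -0.74
reward <- function(weights, action, next_level, reference_range, catalog,
                   form = c("indicator", "graded")) {
  a <- resolve_action(action, catalog)
  if (!is.null(names(next_level)) && length(next_level) > 1L) {
    elec <- attr(catalog, "electrolyte")
    if (!elec %in% names(next_level)) {
      stop("next state does not contain the electrolyte level feature '",
           elec, "'")
    }
    next_level <- next_level[[elec]]
  }
  stopifnot(is.finite(next_level))
  phi <- reward_features(a$iv_level > 0L, a$po_level > 0L, next_level,
                         reference_range, form)[1L, ]
  list(reward = -sum(as.numeric(weights) * phi), phi = phi)
}
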
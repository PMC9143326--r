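#' Discrete repletion action catalog
#'
#' Enumerates every orderable repletion action for one electrolyte: no action,
#' the three oral (PO) dose levels, the intravenous (IV) dose/duration entries,
#' and every PO x IV combination. The catalog is the MDP action space; its row
#' order is fixed and part of the package contract: NONE first, then PO by
#' increasing dose level, then IV by increasing level, then combinations
#' ordered by PO level and, within that, IV level.
#'
#' Catalog sizes are K: 28, Mg: 20, P: 16.
#'
#' @param electrolyte one of \code{"K"}, \code{"Mg"}, \code{"P"}.
#' @return A data frame of class \code{"repletion_catalog"} with columns
#'   \code{index}, \code{route} (\code{NONE/PO/IV/BOTH}), \code{po_level},
#'   \code{iv_level}, \code{po_dose_mg}, \code{iv_dose}, \code{iv_dose_unit},
#'   \code{iv_duration_h} and \code{label}. The electrolyte is stored in
#'   attribute \code{"electrolyte"}.
#' @export
#' @examples
#' cat_k <- action_catalog("K")
#' nrow(cat_k)          # 28
#' cat_k[cat_k$route == "IV", c("iv_dose", "iv_duration_h")]
action_catalog <- function(electrolyte = c("K", "Mg", "P")) {
  electrolyte <- match.arg(electrolyte)
  po <- switch(electrolyte,
    K  = c(20, 40, 60),
    Mg = c(400, 800, 1200),
    P  = c(250, 500, 750)
  )
  iv <- switch(electrolyte,
    # dose, unit, infusion duration (h)
    K  = data.frame(dose = c(20, 40, 60, 20, 40, 60), unit = "mEq",
                    dur = c(2, 4, 6, 1, 2, 3)),
    Mg = data.frame(dose = c(0.5, 1, 1, 1), unit = "g",
                    dur = c(1, 1, 2, 3)),
    P  = data.frame(dose = c(15, 30, 45), unit = "mEq",
                    dur = c(1, 3, 6))
  )
  n_po <- length(po)
  n_iv <- nrow(iv)

  rows <- list(data.frame(route = "NONE", po_level = 0L, iv_level = 0L))
  for (p in seq_len(n_po)) {
    rows[[length(rows) + 1L]] <-
      data.frame(route = "PO", po_level = p, iv_level = 0L)
  }
  for (i in seq_len(n_iv)) {
    rows[[length(rows) + 1L]] <-
      data.frame(route = "IV", po_level = 0L, iv_level = i)
  }
  for (p in seq_len(n_po)) {
    for (i in seq_len(n_iv)) {
      rows[[length(rows) + 1L]] <-
        data.frame(route = "BOTH", po_level = p, iv_level = i)
    }
  }
  out <- do.call(rbind, rows)
  out$po_dose_mg <- ifelse(out$po_level > 0L, po[pmax(out$po_level, 1L)], 0)
  out$iv_dose <- ifelse(out$iv_level > 0L, iv$dose[pmax(out$iv_level, 1L)], 0)
  out$iv_dose_unit <- ifelse(out$iv_level > 0L, iv$unit[1L], "")
  out$iv_duration_h <- ifelse(out$iv_level > 0L, iv$dur[pmax(out$iv_level, 1L)], 0)
  out$index <- seq_len(nrow(out))
  out$label <- ifelse(
    out$route == "NONE", "NONE",
    paste0(
      ifelse(out$po_level > 0L, paste0("PO", out$po_level), ""),
      ifelse(out$po_level > 0L & out$iv_level > 0L, "+", ""),
      ifelse(out$iv_level > 0L, paste0("IV", out$iv_level), "")
    )
  )
  out <- out[, c("index", "route", "po_level", "iv_level", "po_dose_mg",
                 "iv_dose", "iv_dose_unit", "iv_duration_h", "label")]
  attr(out, "electrolyte") <- electrolyte
  class(out) <- c("repletion_catalog", "data.frame")
  out
}

#' @export
print.repletion_catalog <- function(x, ...) {
  cat("Repletion action catalog for", attr(x, "electrolyte"),
      "-", nrow(x), "actions\n")
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

# drug label for medication rows, e.g. "K-IV"
repletion_drug <- function(electrolyte, route) paste0(electrolyte, "-", route)

#' Expand a catalog action into EHR medication rows
#'
#' The inverse of [encode_historical_action()] up to snapping: emits one row
#' per route component (combination actions produce a PO and an IV row sharing
#' the same start time, the way real EHRs record them).
#'
#' @param action a catalog row (or its index) from [action_catalog()].
#' @param catalog the catalog the action belongs to.
#' @param start_hours infusion/administration start time in hours.
#' @return data frame with columns \code{start_hours}, \code{end_hours},
#'   \code{drug}, \code{dose}, \code{route}; zero rows for NONE.
#' @export
action_to_rows <- function(action, catalog, start_hours = 0) {
  a <- resolve_action(action, catalog)
  elec <- attr(catalog, "electrolyte")
  rows <- list()
  if (a$po_level > 0L) {
    rows[[length(rows) + 1L]] <- data.frame(
      start_hours = start_hours, end_hours = start_hours,
      drug = repletion_drug(elec, "PO"), dose = a$po_dose_mg, route = "PO")
  }
  if (a$iv_level > 0L) {
    rows[[length(rows) + 1L]] <- data.frame(
      start_hours = start_hours, end_hours = start_hours + a$iv_duration_h,
      drug = repletion_drug(elec, "IV"), dose = a$iv_dose, route = "IV")
  }
  if (length(rows) == 0L) {
    return(data.frame(start_hours = numeric(0), end_hours = numeric(0),
                      drug = character(0), dose = numeric(0),
                      route = character(0)))
  }
  do.call(rbind, rows)
}

resolve_action <- function(action, catalog) {
  if (is.numeric(action) && length(action) == 1L) {
    stopifnot(action >= 1, action <= nrow(catalog))
    return(catalog[action, ])
  }
  if (is.data.frame(action) && nrow(action) == 1L) return(action)
  stop("`action` must be a catalog index or a single catalog row")
}

# nearest value in `grid` to `x`; ties broken toward the LOWER grid index
snap_lower <- function(x, grid) {
  d <- abs(grid - x)
  which(d <= min(d) + 1e-12)[1L]
}

#' Map raw medication rows in one decision interval onto the action catalog
#'
#' Free-form EHR doses are snapped onto the discrete catalog grid: PO doses to
#' the nearest catalog PO dose; IV orders to the nearest catalog dose first and
#' then, among entries sharing that dose, the nearest infusion duration. Ties
#' always break toward the lower dose level. Multiple rows of the same route
#' within one interval are summed (doses and infusion durations) before
#' snapping. Rows whose drug label does not match the electrolyte's repletion
#' drugs are ignored; their count is returned in attribute
#' \code{"n_unmatched"}.
#'
#' @param med_rows data frame of medication rows in one 6 h bin (columns
#'   \code{drug}, \code{dose}, \code{route}; \code{start_hours}/\code{end_hours}
#'   used for IV durations when present).
#' @param catalog the electrolyte's [action_catalog()].
#' @return the integer catalog index of the encoded action (NONE when no
#'   matching rows), with attribute \code{"n_unmatched"}.
#' @export
encode_historical_action <- function(med_rows, catalog) {
  elec <- attr(catalog, "electrolyte")
  none_idx <- which(catalog$route == "NONE")[1L]
  if (is.null(med_rows) || nrow(med_rows) == 0L) {
    return(structure(none_idx, n_unmatched = 0L))
  }
  match_po <- med_rows$drug == repletion_drug(elec, "PO")
  match_iv <- med_rows$drug == repletion_drug(elec, "IV")
  n_unmatched <- sum(!(match_po | match_iv))

  po_level <- 0L
  if (any(match_po)) {
    total <- sum(med_rows$dose[match_po])
    po_grid <- catalog$po_dose_mg[catalog$route == "PO"]
    po_level <- snap_lower(total, po_grid)
  }
  iv_level <- 0L
  if (any(match_iv)) {
    ivr <- med_rows[match_iv, , drop = FALSE]
    total <- sum(ivr$dose)
    dur <- if (all(c("start_hours", "end_hours") %in% names(ivr))) {
      sum(pmax(ivr$end_hours - ivr$start_hours, 0))
    } else NA_real_
    iv_entries <- catalog[catalog$route == "IV", , drop = FALSE]
    # dose first
    d <- abs(iv_entries$iv_dose - total)
    cand <- which(d <= min(d) + 1e-12)
    if (length(cand) > 1L && is.finite(dur)) {
      dd <- abs(iv_entries$iv_duration_h[cand] - dur)
      cand <- cand[dd <= min(dd) + 1e-12]
    }
    iv_level <- iv_entries$iv_level[cand[1L]]
  }
  idx <- which(catalog$po_level == po_level & catalog$iv_level == iv_level)
  structure(idx[1L], n_unmatched = n_unmatched)
}
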
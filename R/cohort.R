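#' Load raw EHR tables into per-visit records
#'
#' Reads the three-table ingestion contract written by [write_ehr()] (or any
#' source conforming to it). Malformed observation/medication rows (non-finite
#' time or value, unknown visit) are dropped with a reported count. Length of
#' stay is taken from an optional \code{los_hours} column of the static table
#' and otherwise derived as the latest event time, rounded up to a whole hour.
#'
#' @param static_path,observations_path,medications_path CSV paths.
#' @return list of class \code{"ehr_cohort"}: one element per visit, each a
#'   list with \code{visit_id}, \code{age}, \code{sex}, \code{admit_weight},
#'   \code{los_hours}, \code{observations}, \code{medications}. The number of
#'   dropped rows is attached as attribute \code{"n_dropped"}.
#' @export
load_ehr <- function(static_path, observations_path, medications_path) {
  static <- utils::read.csv(static_path, stringsAsFactors = FALSE)
  obs <- utils::read.csv(observations_path, stringsAsFactors = FALSE)
  meds <- utils::read.csv(medications_path, stringsAsFactors = FALSE)

  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss)) {
      stop("missing required column(s) in ", what, ": ",
           paste(miss, collapse = ", "))
    }
  }
  need(static, c("visit_id", "age", "sex", "admit_weight"), "static table")
  need(obs, c("visit_id", "time_hours", "variable", "value"),
       "observations table")
  need(meds, c("visit_id", "start_hours", "end_hours", "drug", "dose", "route"),
       "medications table")

  obs$value <- suppressWarnings(as.numeric(obs$value))
  obs$time_hours <- suppressWarnings(as.numeric(obs$time_hours))
  ok_obs <- is.finite(obs$value) & is.finite(obs$time_hours) &
    obs$time_hours >= 0 & obs$visit_id %in% static$visit_id
  meds$dose <- suppressWarnings(as.numeric(meds$dose))
  meds$start_hours <- suppressWarnings(as.numeric(meds$start_hours))
  meds$end_hours <- suppressWarnings(as.numeric(meds$end_hours))
  ok_med <- is.finite(meds$dose) & is.finite(meds$start_hours) &
    is.finite(meds$end_hours) & meds$visit_id %in% static$visit_id
  n_dropped <- sum(!ok_obs) + sum(!ok_med)
  if (n_dropped > 0L) {
    message("load_ehr: dropped ", n_dropped, " malformed row(s)")
  }
  obs <- obs[ok_obs, , drop = FALSE]
  meds <- meds[ok_med, , drop = FALSE]

  obs_split <- split(obs, obs$visit_id)
  med_split <- split(meds, meds$visit_id)
  visits <- lapply(seq_len(nrow(static)), function(i) {
    vid <- static$visit_id[i]
    o <- obs_split[[vid]] %||%
      obs[0, , drop = FALSE]
    m <- med_split[[vid]] %||%
      meds[0, , drop = FALSE]
    los <- if ("los_hours" %in% names(static) && is.finite(static$los_hours[i])) {
      static$los_hours[i]
    } else {
      ceiling(max(c(o$time_hours, m$end_hours, 0)))
    }
    list(visit_id = vid, age = static$age[i], sex = static$sex[i],
         admit_weight = static$admit_weight[i], los_hours = los,
         observations = o[order(o$time_hours), , drop = FALSE],
         medications = m[order(m$start_hours), , drop = FALSE])
  })
  names(visits) <- static$visit_id
  structure(visits, n_dropped = n_dropped, class = "ehr_cohort")
}

#' Cohort inclusion filter specification
#'
#' Adults (age strictly above \code{min_age}) with a stay between one and
#' eight days by default, at least one recorded value of every required
#' variable, an admission weight if required, and at least one repletion event
#' of the target electrolyte if required.
#'
#' @param min_age years; visits must have \code{age > min_age}.
#' @param min_los,max_los inclusive length-of-stay bounds in hours.
#' @param required_variables variables that must each have >= 1 recorded value.
#' @param require_admission_weight require a finite admission weight.
#' @param target_electrolyte electrolyte whose repletion defines eligibility.
#' @param require_repletion_event require >= 1 repletion medication row of the
#'   target electrolyte.
#' @return list of class \code{"cohort_filter_spec"}.
#' @export
cohort_filter_spec <- function(min_age = 18, min_los = 24, max_los = 192,
                               required_variables = character(),
                               require_admission_weight = TRUE,
                               target_electrolyte = "K",
                               require_repletion_event = TRUE) {
  stopifnot(min_los < max_los)
  structure(list(min_age = min_age, min_los = min_los, max_los = max_los,
                 required_variables = required_variables,
                 require_admission_weight = require_admission_weight,
                 target_electrolyte = target_electrolyte,
                 require_repletion_event = require_repletion_event),
            class = "cohort_filter_spec")
}

#' Apply the cohort inclusion filters
#'
#' A visit is kept iff it passes every filter. Each excluded visit is
#' attributed to the FIRST failed filter, in the fixed order age, length of
#' stay, required variables, admission weight, repletion event — so the
#' exclusion counts form a well-defined selection funnel.
#'
#' @param visits an \code{"ehr_cohort"}.
#' @param spec a [cohort_filter_spec()].
#' @return list with \code{kept} (the filtered \code{"ehr_cohort"}) and
#'   \code{exclusions} (named integer vector of first-failure counts plus
#'   \code{kept}).
#' @export
select_cohort <- function(visits, spec) {
  reasons <- c("age", "length_of_stay", "required_variables",
               "admission_weight", "repletion_event")
  counts <- stats::setNames(integer(length(reasons)), reasons)
  drugs <- repletion_drug(spec$target_electrolyte, c("PO", "IV"))
  keep <- logical(length(visits))
  for (i in seq_along(visits)) {
    v <- visits[[i]]
    fail <- NULL
    if (!(is.finite(v$age) && v$age > spec$min_age)) {
      fail <- "age"
    } else if (!(v$los_hours >= spec$min_los && v$los_hours <= spec$max_los)) {
      fail <- "length_of_stay"
    } else if (length(spec$required_variables) &&
               !all(spec$required_variables %in% v$observations$variable)) {
      fail <- "required_variables"
    } else if (spec$require_admission_weight && !is.finite(v$admit_weight)) {
      fail <- "admission_weight"
    } else if (spec$require_repletion_event &&
               !any(v$medications$drug %in% drugs)) {
      fail <- "repletion_event"
    }
    if (is.null(fail)) keep[i] <- TRUE else counts[fail] <- counts[fail] + 1L
  }
  kept <- structure(visits[keep], class = "ehr_cohort")
  list(kept = kept,
       exclusions = c(counts, kept = sum(keep)))
}

#' Default clinical plausibility bounds
#'
#' Conservative (min, max) clinically viable bounds per variable; measurements
#' outside their variable's bounds are discarded as non-viable before binning.
#' Variables without an entry are never filtered.
#'
#' @return named list of length-2 numeric vectors.
#' @export
plausibility_ranges <- function() {
  list(
    K = c(1, 10), Mg = c(0.1, 10), P = c(0.1, 15),
    heart_rate = c(20, 250), resp_rate = c(2, 80), temp = c(30, 45),
    spo2 = c(40, 100), bp_sys = c(40, 300), bp_dia = c(20, 200),
    urine_output = c(0, 4000), creatinine = c(0.05, 25),
    glucose = c(10, 2000), hemoglobin = c(2, 25), sodium = c(100, 185),
    chloride = c(60, 140), bun = c(1, 250), wbc = c(0.05, 200)
  )
}

#' Divide one visit into fixed-width time bins
#'
#' Bins are half-open, 0-based intervals \code{[k*w, (k+1)*w)}. Within each
#' bin, measurements outside the variable's plausibility bounds are discarded
#' and the arithmetic mean of the survivors fills the cell; a bin with no
#' surviving measurement is left missing (\code{NA}). Medication rows are
#' assigned to the bin containing their start time.
#'
#' @param visit one element of an \code{"ehr_cohort"}.
#' @param bin_width hours per bin (default 6).
#' @param ranges plausibility bounds, as [plausibility_ranges()].
#' @param variables the cohort-wide feature set (columns of the output
#'   matrix); defaults to the variables observed in this visit.
#' @return list of class \code{"binned_visit"}: \code{visit_id}, static
#'   attributes, \code{n_bins}, \code{bin_width}, \code{features} (bins x
#'   variables, possibly with NAs), \code{observed} (logical mask of the same
#'   shape), and \code{medications} with a \code{bin} column.
#' @export
bin_visit <- function(visit, bin_width = 6, ranges = plausibility_ranges(),
                      variables = NULL) {
  stopifnot(bin_width > 0)
  n_bins <- ceiling(visit$los_hours / bin_width)
  obs <- visit$observations
  if (is.null(variables)) variables <- sort(unique(obs$variable))

  feat <- matrix(NA_real_, nrow = n_bins, ncol = length(variables),
                 dimnames = list(NULL, variables))
  n_discarded <- 0L
  if (nrow(obs) > 0L) {
    obs <- obs[obs$variable %in% variables, , drop = FALSE]
    viable <- rep(TRUE, nrow(obs))
    for (v in intersect(unique(obs$variable), names(ranges))) {
      sel <- obs$variable == v
      r <- ranges[[v]]
      viable[sel] <- obs$value[sel] >= r[1L] & obs$value[sel] <= r[2L]
    }
    n_discarded <- sum(!viable)
    obs <- obs[viable, , drop = FALSE]
    if (nrow(obs) > 0L) {
      bin <- pmin(floor(obs$time_hours / bin_width), n_bins - 1L)
      key <- paste(bin, obs$variable, sep = "\r")
      means <- tapply(obs$value, key, mean)
      ij <- do.call(rbind, strsplit(names(means), "\r", fixed = TRUE))
      feat[cbind(as.integer(ij[, 1L]) + 1L, match(ij[, 2L], variables))] <-
        as.numeric(means)
    }
  }
  meds <- visit$medications
  meds$bin <- if (nrow(meds) > 0L) floor(meds$start_hours / bin_width) else integer(0)
  structure(list(visit_id = visit$visit_id, age = visit$age, sex = visit$sex,
                 admit_weight = visit$admit_weight, los_hours = visit$los_hours,
                 n_bins = n_bins, bin_width = bin_width,
                 features = feat, observed = !is.na(feat),
                 medications = meds, n_discarded = n_discarded),
            class = "binned_visit")
}

#' Bin every visit of a cohort over a shared feature set
#'
#' @param visits an \code{"ehr_cohort"}.
#' @inheritParams bin_visit
#' @return list of class \code{"binned_cohort"} of \code{"binned_visit"}s.
#' @export
bin_visits <- function(visits, bin_width = 6, ranges = plausibility_ranges(),
                       variables = NULL) {
  if (is.null(variables)) {
    variables <- sort(unique(unlist(
      lapply(visits, function(v) unique(v$observations$variable)))))
  }
  out <- lapply(visits, bin_visit, bin_width = bin_width, ranges = ranges,
                variables = variables)
  structure(out, variables = variables, class = "binned_cohort")
}

#' Impute missing bin values (capped LOCF, then population mean)
#'
#' Each missing cell takes the most recent observed value of the same variable
#' within the visit, provided that observation is at most \code{locf_max_hours}
#' old at the bin being filled (the gap is measured from the bin in which the
#' value was actually observed). Older gaps and visits with no prior
#' observation fall back to the population mean of observed values. The
#' observed mask is left untouched, so downstream analyses can distinguish real
#' measurements from imputed fill.
#'
#' @param binned a \code{"binned_cohort"} from [bin_visits()].
#' @param locf_max_hours carry-forward cap (default 48).
#' @param means optional named vector of population means (e.g. computed on
#'   the training split only); defaults to means over this cohort's observed
#'   cells.
#' @return the completed \code{"binned_cohort"} (no NA cells remain).
#' @export
impute_cohort <- function(binned, locf_max_hours = 48, means = NULL) {
  variables <- attr(binned, "variables")
  if (is.null(means)) {
    sums <- stats::setNames(numeric(length(variables)), variables)
    ns <- stats::setNames(numeric(length(variables)), variables)
    for (bv in binned) {
      obs <- bv$observed
      f <- bv$features
      f[!obs] <- 0
      sums <- sums + colSums(f)
      ns <- ns + colSums(obs)
    }
    never <- variables[ns == 0]
    if (length(never)) {
      stop("variable(s) never observed in the cohort, population mean ",
           "undefined: ", paste(never, collapse = ", "))
    }
    means <- sums / ns
  }
  max_gap_bins <- floor(locf_max_hours / binned[[1L]]$bin_width)
  out <- lapply(binned, function(bv) {
    f <- bv$features
    for (j in seq_len(ncol(f))) {
      col <- f[, j]
      if (!anyNA(col)) next
      last_val <- NA_real_
      last_bin <- -Inf
      for (t in seq_along(col)) {
        if (!is.na(col[t])) {
          last_val <- col[t]; last_bin <- t
        } else if (t - last_bin <= max_gap_bins) {
          f[t, j] <- last_val
        } else {
          f[t, j] <- means[[colnames(f)[j]]]
        }
      }
    }
    bv$features <- f
    bv
  })
  structure(out, variables = variables, means = means,
            class = "binned_cohort")
}

#' Write a binned cohort as one long table
#'
#' One row per (visit, bin, feature) cell: \code{visit_id},
#' \code{bin_index}, \code{feature}, \code{value}, \code{observed_flag}.
#'
#' @param binned a \code{"binned_cohort"}.
#' @param path CSV path.
#' @return the path, invisibly.
#' @export
write_binned <- function(binned, path) {
  rows <- lapply(binned, function(bv) {
    nb <- bv$n_bins
    nv <- ncol(bv$features)
    data.frame(visit_id = rep(bv$visit_id, nb * nv),
               bin_index = rep(seq_len(nb) - 1L, nv),
               feature = rep(colnames(bv$features), each = nb),
               value = as.numeric(bv$features),
               observed_flag = as.logical(bv$observed))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Random visit-level train/test partition
#'
#' Splits at the visit level (never at the transition-sample level), either by
#' fraction or by an explicit training-set size; deterministic under a fixed
#' seed.
#'
#' @param visit_ids character vector of visit identifiers (an
#'   \code{"ehr_cohort"} or \code{"binned_cohort"} is also accepted).
#' @param train_fraction fraction in (0, 1); ignored when \code{train_count}
#'   is given.
#' @param train_count explicit number of training visits.
#' @param rng_seed integer seed.
#' @return list with character vectors \code{train} and \code{test}, disjoint
#'   and exhaustive.
#' @export
split_cohort <- function(visit_ids, train_fraction = 0.7, train_count = NULL,
                         rng_seed = 1L) {
  if (is.list(visit_ids)) {
    visit_ids <- vapply(visit_ids, function(v) v$visit_id, character(1))
  }
  n <- length(visit_ids)
  k <- if (!is.null(train_count)) as.integer(train_count)
       else {
         stopifnot(train_fraction > 0, train_fraction < 1)
         round(n * train_fraction)
       }
  stopifnot(k >= 0, k <= n)
  with_local_seed(as.integer(rng_seed), {
    tr <- sample(visit_ids, k)
  })
  list(train = sort(tr), test = sort(setdiff(visit_ids, tr)))
}
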
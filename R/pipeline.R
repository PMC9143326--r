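#' End-to-end pipeline configuration
#'
#' Bundles every stage's settings behind a single seeded, validated object.
#' Either raw table paths are supplied, or \code{simulate} is set and a
#' synthetic cohort is generated first. One global seed fans out to
#' deterministic per-stage seeds so any stage can be re-run reproducibly on
#' its own.
#'
#' @param electrolyte target electrolyte.
#' @param simulate logical; generate a synthetic cohort instead of reading
#'   tables.
#' @param sim a [sim_config()] (when simulating).
#' @param behavior a [behavior_config()] (when simulating).
#' @param paths named list with \code{static}, \code{observations},
#'   \code{medications} (when not simulating).
#' @param filter a [cohort_filter_spec()].
#' @param ranges plausibility bounds.
#' @param mdp an [mdp_spec()].
#' @param train_fraction visit-level training share.
#' @param fqi_iterations,fqe_iterations regression sweeps for learning and
#'   evaluation.
#' @param regressor a [regressor_spec()].
#' @param run_irl estimate behavioral reward weights as part of the run.
#' @param cost a [cost_model()].
#' @param rng_seed global seed.
#' @return list of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(electrolyte = "K",
                            simulate = TRUE,
                            sim = sim_config(electrolyte),
                            behavior = behavior_config(),
                            paths = NULL,
                            filter = cohort_filter_spec(
                              target_electrolyte = electrolyte),
                            ranges = plausibility_ranges(),
                            mdp = mdp_spec(electrolyte),
                            train_fraction = 0.7,
                            fqi_iterations = 16L,
                            fqe_iterations = 16L,
                            regressor = regressor_spec("xgboost"),
                            run_irl = FALSE,
                            cost = default_cost_model(electrolyte),
                            rng_seed = 1L) {
  cfg <- structure(list(electrolyte = electrolyte, simulate = simulate,
                        sim = sim, behavior = behavior, paths = paths,
                        filter = filter, ranges = ranges, mdp = mdp,
                        train_fraction = train_fraction,
                        fqi_iterations = as.integer(fqi_iterations),
                        fqe_iterations = as.integer(fqe_iterations),
                        regressor = regressor, run_irl = run_irl,
                        cost = cost, rng_seed = as.integer(rng_seed)),
                   class = "pipeline_config")
  validate_pipeline_config(cfg)
  cfg
}

validate_pipeline_config <- function(cfg) {
  stopifnot(inherits(cfg$filter, "cohort_filter_spec"),
            inherits(cfg$mdp, "mdp_spec"),
            cfg$train_fraction > 0, cfg$train_fraction < 1)
  if (cfg$filter$min_los >= cfg$filter$max_los) {
    stop("invalid cohort filter: min_los must be < max_los")
  }
  if (cfg$simulate) {
    stopifnot(inherits(cfg$sim, "sim_config"))
    validate_sim_config(cfg$sim)
  } else {
    if (is.null(cfg$paths) ||
        !all(c("static", "observations", "medications") %in% names(cfg$paths))) {
      stop("paths must name static, observations and medications tables")
    }
    missing <- !vapply(cfg$paths[c("static", "observations", "medications")],
                       file.exists, logical(1))
    if (any(missing)) {
      stop("input table(s) not found: ",
           paste(unlist(cfg$paths)[missing], collapse = ", "))
    }
  }
  invisible(cfg)
}

# per-stage derived seeds: reproducible fan-out from the global seed
stage_seed <- function(seed, stage) {
  offsets <- c(simulate = 11L, split = 23L, fqi = 37L, fqe = 41L, irl = 53L)
  (seed + offsets[[stage]]) %% .Machine$integer.max
}

#' Run the full repletion-learning pipeline
#'
#' Executes simulate (optional) -> load -> select -> bin -> impute -> split ->
#' transitions -> FQI -> FQE + frequency + pre/post distributions -> cost
#' comparison, writing every artifact plus a run manifest (seed, per-stage row
#' counts) into \code{out_dir}. Identical configuration and seed reproduce
#' identical manifest counts.
#'
#' @param config a [pipeline_config()].
#' @param out_dir run directory (created).
#' @return invisibly, a list with the manifest and the in-memory stage
#'   results (\code{q}, \code{fqe_policy}, \code{fqe_historical},
#'   \code{frequency}, \code{pre_post}, \code{costs}, and \code{irl} when
#'   requested).
#' @export
run_pipeline <- function(config, out_dir) {
  validate_pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(rng_seed = config$rng_seed,
                   electrolyte = config$electrolyte)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  paths <- config$paths
  if (config$simulate) {
    tabs <- stage("simulate", {
      sim <- config$sim
      sim$rng_seed <- as.integer(stage_seed(config$rng_seed, "simulate"))
      simulate_cohort(sim, config$behavior)
    })
    raw_dir <- file.path(out_dir, "raw")
    write_ehr(tabs, raw_dir)
    paths <- list(static = file.path(raw_dir, "static.csv"),
                  observations = file.path(raw_dir, "observations.csv"),
                  medications = file.path(raw_dir, "medications.csv"))
  }

  visits <- stage("load", load_ehr(paths$static, paths$observations,
                                   paths$medications))
  manifest$n_loaded <- length(visits)

  sel <- stage("select", select_cohort(visits, config$filter))
  manifest$exclusions <- as.list(sel$exclusions)
  manifest$n_selected <- length(sel$kept)
  if (manifest$n_selected == 0L) stop("pipeline: no visits pass the cohort filter")

  binned <- stage("bin", bin_visits(sel$kept, ranges = config$ranges))
  sp <- stage("split", split_cohort(binned,
                                    train_fraction = config$train_fraction,
                                    rng_seed = stage_seed(config$rng_seed,
                                                          "split")))
  manifest$n_train_visits <- length(sp$train)
  manifest$n_test_visits <- length(sp$test)

  # population means for imputation from the training split only
  train_binned <- structure(binned[names(binned) %in% sp$train],
                            variables = attr(binned, "variables"),
                            class = "binned_cohort")
  imputed_train <- stage("impute", impute_cohort(train_binned))
  imputed <- stage("impute", impute_cohort(binned,
                                           means = attr(imputed_train, "means")))

  write_binned(imputed, file.path(out_dir, "binned_cohort.csv"))
  jsonlite::write_json(as.data.frame(config$mdp$catalog),
                       file.path(out_dir, "action_catalog.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  samples <- stage("transitions", build_transitions(imputed, config$mdp))
  train_s <- subset_transitions(samples, sp$train)
  test_s <- subset_transitions(samples, sp$test)
  manifest$n_train_samples <- length(train_s$reward)
  manifest$n_test_samples <- length(test_s$reward)
  write_transitions(samples, file.path(out_dir, "transitions.csv"))

  q <- stage("fqi", fqi(train_s, n_iterations = config$fqi_iterations,
                        regressor = config$regressor,
                        rng_seed = stage_seed(config$rng_seed, "fqi")))
  pol <- greedy_policy(q)
  save_policy(q, file.path(out_dir, "policy"))

  fqe_pol <- stage("fqe", fqe(pol, test_s,
                              n_iterations = config$fqe_iterations,
                              regressor = config$regressor,
                              rng_seed = stage_seed(config$rng_seed, "fqe")))
  fqe_hist <- stage("fqe", fqe(historical_policy(), test_s,
                               n_iterations = config$fqe_iterations,
                               regressor = config$regressor,
                               rng_seed = stage_seed(config$rng_seed, "fqe")))
  v_pol <- policy_value(fqe_pol, test_s)
  v_hist <- policy_value(fqe_hist, test_s)
  manifest$mean_value_policy <- v_pol$mean
  manifest$mean_value_historical <- v_hist$mean

  freq <- stage("frequency", frequency_analysis(test_s, pol))
  manifest$repletion_change_pct <- freq$repletion_change_pct
  test_binned <- structure(imputed[names(imputed) %in% sp$test],
                           variables = attr(binned, "variables"),
                           class = "binned_cohort")
  pp <- stage("pre_post", pre_post_distribution(
    test_binned, config$electrolyte, config$mdp$reference_range))
  manifest$frac_within_or_above <- pp$frac_within_or_above

  irl <- NULL
  if (config$run_irl) {
    irl <- stage("irl", irl_weights(
      train_s, regressor = config$regressor,
      rng_seed = stage_seed(config$rng_seed, "irl")))
    manifest$irl_weights <- as.numeric(irl$weights)
  }

  pol_a <- policy_actions(pol, test_s$state)
  costs <- stage("costs", cohort_cost_comparison(
    test_s$action, pol_a, config$cost, config$mdp$catalog,
    n_visits = manifest$n_test_visits))
  manifest$savings_per_visit <- costs$savings_per_visit

  utils::write.csv(freq$counts, file.path(out_dir, "action_frequencies.csv"),
                   row.names = FALSE)
  utils::write.csv(costs$itemized, file.path(out_dir, "cost_itemized.csv"),
                   row.names = FALSE)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(manifest = manifest, q = q, policy = pol,
                 fqe_policy = fqe_pol, fqe_historical = fqe_hist,
                 frequency = freq, pre_post = pp, costs = costs, irl = irl,
                 split = sp, samples = samples))
}
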
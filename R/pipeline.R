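#' Intercept-adjusted habitat-quality truth for a synthetic landscape
#'
#' Uses the published covariate slopes but sets the intercept so that the mean
#' invasion probability over forest cells equals a target prevalence on THIS
#' landscape's covariate scales (the published intercept belongs to the
#' original survey's codings, which the synthetic generator does not
#' reproduce).
#'
#' @param grid a `landscape_grid`.
#' @param target_prevalence desired mean invasion probability over forest
#'   cells (default 0.3).
#' @return an `hq_model`.
#' @export
synthetic_hq_truth <- function(grid, target_prevalence = 0.3) {
  ref <- reference_hq_model()
  cells <- grid$cells[forest_mask(grid), , drop = FALSE]
  X <- as.matrix(cells[names(ref$coefficients)])
  storage.mode(X) <- "double"
  eta_mean <- mean(drop(X %*% ref$coefficients))
  hq_model(qlogis(target_prevalence) - eta_mean, ref$coefficients)
}

#' Default end-to-end pipeline configuration
#'
#' @param seed master seed; all stage seeds derive from it.
#' @param out_dir output directory for stage CSVs and the manifest.
#' @param n_cells landscape size.
#' @param generator list of [generator_config()] overrides.
#' @param target_prevalence invasion prevalence of the habitat-quality truth.
#' @param survey list: `interval`, `noise_sd`, `prop_treated`.
#' @param calibration list: `run` (logical), `true_L` (scale generating the
#'   observed pattern), `candidates`, `sim_years`, `n_runs`, `n_perm`.
#' @param fixed_L scale parameter used when calibration is skipped.
#' @param simulation list: `years`, `n_runs`, `q`, `noise_sd`.
#' @param fire list: `fit` (logical), intercept/dispersion of the generating
#'   fire model, and `n_fit_cells`, the size of the auxiliary plot sample the
#'   fire model is fitted on (the regional fire model is estimated from the
#'   full inventory plot network, which is much larger than the simulated
#'   landscape; crown fires are too rare to fit on a small landscape alone).
#' @param write_trajectories write per-run trajectory CSVs (default FALSE).
#' @return nested list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, out_dir = "results",
                            n_cells = 400,
                            generator = list(),
                            target_prevalence = 0.3,
                            survey = list(),
                            calibration = list(),
                            fixed_L = 1 / 5,
                            simulation = list(),
                            fire = list(),
                            write_trajectories = FALSE) {
  # partial sublists are merged over these stage defaults
  defaults <- list(
    survey = list(interval = 5, noise_sd = 0.25, prop_treated = 0.02),
    calibration = list(run = TRUE, true_L = 1 / 5,
                       candidates = velocity_ladder(), sim_years = 8,
                       n_runs = 20, n_perm = 199),
    simulation = list(years = 20, n_runs = 40, q = 1, noise_sd = 0.2),
    fire = list(fit = TRUE, zero_intercept = 2.6, count_intercept = -3.6,
                dispersion = 1.5, n_fit_cells = 4000)
  )
  cfg <- list(
    seed = seed, out_dir = out_dir, n_cells = n_cells,
    generator = generator, target_prevalence = target_prevalence,
    survey = utils::modifyList(defaults$survey, survey),
    calibration = utils::modifyList(defaults$calibration, calibration),
    fixed_L = fixed_L,
    simulation = utils::modifyList(defaults$simulation, simulation),
    fire = utils::modifyList(defaults$fire, fire),
    write_trajectories = write_trajectories
  )
  class(cfg) <- "pipeline_config"
  cfg
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the end-to-end invasion forecasting pipeline
#'
#' Executes generate, fit-hq, estimate-r, calibrate, fire-fit, simulate and
#' fire-risk in order on a synthetic landscape, writing stage CSVs
#' (`cells.csv`, `hq_coefficients.csv`, `r_estimates.csv`, `r_hq_table.csv`,
#' `calibration_table.csv`, `ensemble_summary.csv`, `fire_risk.csv`) plus a
#' `manifest.json` recording seeds and the config hash, so reruns with the
#' same config are bit-identical.
#'
#' @param config a `pipeline_config`, or path to a JSON file of overrides for
#'   [pipeline_config()].
#' @return invisible list with the stage objects (`grid`, `hq`, `rates`,
#'   `calibration`, `fire_fit`, `ensemble`, `fire_risk`, `manifest`).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) {
    overrides <- jsonlite::read_json(config, simplifyVector = TRUE)
    config <- do.call(pipeline_config, overrides)
  }
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)

  set.seed(config$seed)
  stage_seeds <- setNames(
    as.list(sample.int(.Machine$integer.max, 10)),
    c("generate", "presence", "survey_occ", "survey", "observed", "calibrate",
      "fire_grid", "fire_occ", "fire", "simulate")
  )

  # -- generate ---------------------------------------------------------------
  gen_cfg <- do.call(generator_config, config$generator)
  grid <- run_stage("generate", {
    g <- generate_grid(config$n_cells, gen_cfg, seed = stage_seeds$generate)
    write_cell_table(g, file.path(out, "cells.csv"), config = gen_cfg)
    g
  })
  fmask <- forest_mask(grid)

  # -- fit-hq -----------------------------------------------------------------
  truth_hq <- synthetic_hq_truth(grid, config$target_prevalence)
  hq <- run_stage("fit-hq", {
    presence <- generate_presence(grid, truth_hq, seed = stage_seeds$presence)
    fit <- fit_logistic(grid$cells[fmask, ], presence[fmask],
                        candidates = names(truth_hq$coefficients))
    pred <- predict_hq(fit$model, grid$cells[fmask, ])
    hl <- hosmer_lemeshow(pred, presence[fmask])
    acc <- classification_accuracy(pred, presence[fmask])
    write.csv(fit$report, file.path(out, "hq_coefficients.csv"),
              row.names = FALSE)
    list(fit = fit, hq_hat = pred, hosmer_lemeshow = hl, accuracy = acc,
         truth = truth_hq, presence = presence)
  })

  # -- estimate-r -------------------------------------------------------------
  rates <- run_stage("estimate-r", {
    hq_true <- predict_hq(truth_hq, grid$cells)
    r_true <- predict(reference_spread_rate_model(), hq_true)
    # the rate survey observes every invaded forest plot, not just the sparse
    # simulation foci; leading-edge occupancies are small (<1%) so that five
    # years of exponential growth stays below K for every habitat quality --
    # larger starts saturate at K and censor the rate estimator
    grid_survey <- grid
    inv <- fmask & hq$presence == 1
    set.seed(stage_seeds$survey_occ)
    grid_survey$occupancy0[inv] <- runif(sum(inv), 0.1, 0.8)
    pair <- generate_survey_pair(grid_survey, r_true,
                                 interval = config$survey$interval,
                                 noise_sd = config$survey$noise_sd,
                                 seed = stage_seeds$survey,
                                 prop_treated = config$survey$prop_treated)
    est <- estimate_r(pair)
    hq_forest <- hq$hq_hat
    est_forest <- est[fmask, ]
    rfit <- fit_r_hq(est_forest$r, hq_forest)
    curve <- if (!is.na(rfit$best)) rfit$best_model else {
      message("estimate-r: no r~HQ family passed the significance gate; ",
              "falling back to the reference curve")
      reference_spread_rate_model()
    }
    r_forest <- impute_r(curve, hq_forest, est_forest$r)
    r_all <- rep(0, n_cells(grid))
    r_all[fmask] <- r_forest
    est$r_final <- r_all
    write.csv(est, file.path(out, "r_estimates.csv"), row.names = FALSE)
    write.csv(rfit$table, file.path(out, "r_hq_table.csv"), row.names = FALSE)
    list(pair = pair, estimates = est, fit = rfit, curve = curve, r = r_all,
         r_true = r_true)
  })

  # -- calibrate --------------------------------------------------------------
  cal_cfg <- config$calibration
  calibration <- NULL
  if (isTRUE(cal_cfg$run)) {
    calibration <- run_stage("calibrate", {
      true_kernel <- build_kernel(grid, cal_cfg$true_L)
      obs_params <- sim_params(r = rates$r, kernel = true_kernel,
                               q = config$simulation$q,
                               noise_sd = config$simulation$noise_sd,
                               years = cal_cfg$sim_years, n_runs = 1)
      observed <- run_sim(grid, obs_params,
                          seed = stage_seeds$observed)[cal_cfg$sim_years + 1, ]
      cal <- calibrate_L(grid, observed, rates$r,
                         candidates = cal_cfg$candidates,
                         q = config$simulation$q,
                         noise_sd = config$simulation$noise_sd,
                         sim_years = cal_cfg$sim_years,
                         n_runs = cal_cfg$n_runs, n_perm = cal_cfg$n_perm,
                         seed = stage_seeds$calibrate)
      write.csv(cal$table, file.path(out, "calibration_table.csv"),
                row.names = FALSE)
      cal
    })
    L_sel <- if (!is.na(calibration$selected)) calibration$selected else {
      message("calibrate: no significant candidate; using fixed_L")
      config$fixed_L
    }
  } else {
    L_sel <- config$fixed_L
  }

  # -- fire-fit ---------------------------------------------------------------
  fire_fit <- NULL
  fire_model <- reference_zinb_model(config$fire$zero_intercept,
                                     config$fire$count_intercept,
                                     config$fire$dispersion)
  if (isTRUE(config$fire$fit)) {
    fire_fit <- run_stage("fire-fit", {
      # the fire model is estimated from an auxiliary plot sample standing in
      # for the full regional inventory: ~30% of forest plots invaded at
      # observed occupancies up to 60%
      n_aux <- config$fire$n_fit_cells
      g_aux <- generate_grid(n_aux, gen_cfg, seed = stage_seeds$fire_grid)
      fmask_aux <- forest_mask(g_aux)
      set.seed(stage_seeds$fire_occ)
      occ_aux <- rep(0, n_aux)
      inv_aux <- fmask_aux & runif(n_aux) < 0.3
      occ_aux[inv_aux] <- runif(sum(inv_aux), 0.5, 60)
      counts <- generate_fire_counts(g_aux, occ_aux, fire_model,
                                     seed = stage_seeds$fire)
      fit_zinb(counts[fmask_aux], g_aux$cells[fmask_aux, ],
               occ_aux[fmask_aux])
    })
    fire_model_used <- fire_fit$model
  } else {
    fire_model_used <- fire_model
  }

  # -- simulate ---------------------------------------------------------------
  ensemble <- run_stage("simulate", {
    kernel <- build_kernel(grid, L_sel)
    params <- sim_params(r = rates$r, kernel = kernel,
                         q = config$simulation$q,
                         noise_sd = config$simulation$noise_sd,
                         years = config$simulation$years,
                         n_runs = config$simulation$n_runs)
    ens <- run_ensemble(grid, params, base_seed = stage_seeds$simulate,
                        zinb = fire_model_used)
    write.csv(ens$summary, file.path(out, "ensemble_summary.csv"),
              row.names = FALSE)
    if (isTRUE(config$write_trajectories)) {
      for (k in seq_len(params$n_runs)) {
        traj <- run_sim(grid, params, seed = ens$run_seeds[k])
        write.csv(traj, file.path(out, sprintf("trajectory_%03d.csv", k)),
                  row.names = FALSE)
      }
    }
    ens
  })

  # -- fire-risk --------------------------------------------------------------
  fire_risk <- run_stage("fire-risk", {
    final_mean <- colMeans(ensemble$final_states)
    e5 <- rep(0, n_cells(grid))
    e5[fmask] <- expected_fires(fire_model_used,
                                grid$cells[fmask, ], final_mean[fmask])
    annual <- e5 / 5
    category <- bin_frequencies(annual)
    df <- data.frame(cell_id = grid$cells$cell_id, forest = fmask,
                     occupancy_final = final_mean,
                     expected_fires_5yr = e5, annual_frequency = annual,
                     risk_category = as.character(category))
    write.csv(df, file.path(out, "fire_risk.csv"), row.names = FALSE)
    df
  })

  # -- manifest ---------------------------------------------------------------
  cfg_path <- file.path(out, "pipeline_config.json")
  jsonlite::write_json(unclass(config), cfg_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  manifest <- list(
    package = "privetspread",
    version = as.character(utils::packageVersion("privetspread")),
    seed = config$seed,
    stage_seeds = stage_seeds,
    selected_L = L_sel,
    selected_velocity = velocity_of(L_sel, grid$cell_width),
    config_md5 = unname(tools::md5sum(cfg_path))
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(grid = grid, hq = hq, rates = rates,
                 calibration = calibration, selected_L = L_sel,
                 fire_fit = fire_fit, ensemble = ensemble,
                 fire_risk = fire_risk, manifest = manifest))
}
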
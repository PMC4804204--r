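#' Simulation parameters
#'
#' The annual update for forest cell i is
#' `P' = P + r_i * P * (1 - P/K_i) + q * sum_j k_ji * P_j`, clamped to
#' `[0, K_i]`; non-forest cells stay at 0. Monte Carlo stochasticity enters as
#' a per-cell-per-year lognormal multiplier on `r_i` (median 1, log-sd
#' `noise_sd`); `noise_sd = 0` recovers the deterministic equations.
#'
#' @param r per-cell intrinsic rates.
#' @param kernel a `dispersal_kernel`, or NULL for no between-cell dispersal.
#' @param q immigration scaling constant (>= 0, default 1).
#' @param noise_sd log-sd of the lognormal rate multiplier (default 0).
#' @param years simulation horizon (>= 1).
#' @param n_runs Monte Carlo ensemble size (>= 1).
#' @return list of class `sim_params`.
#' @export
sim_params <- function(r, kernel = NULL, q = 1, noise_sd = 0, years = 20,
                       n_runs = 240) {
  if (q < 0) stop("q must be >= 0")
  if (n_runs < 1) stop("n_runs must be >= 1")
  if (years < 1) stop("years (horizon) must be >= 1")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(r = r, kernel = kernel, q = q, noise_sd = noise_sd,
                 years = years, n_runs = n_runs),
            class = "sim_params")
}

#' Advance occupancy one year
#'
#' One synchronous update of all cells from the year-t state: logistic local
#' growth plus kernel-weighted immigration, computed from the current state
#' and applied simultaneously, then clamped to `[0, K]`. Draws `n_cells`
#' normal deviates from the current RNG state when `noise_sd > 0`.
#'
#' @param P per-cell occupancy, percent.
#' @param grid a `landscape_grid`.
#' @param params a `sim_params`.
#' @return updated occupancy vector.
#' @export
step_occupancy <- function(P, grid, params) {
  n <- n_cells(grid)
  stopifnot(length(P) == n)
  r <- rep_len(params$r, n)
  if (params$noise_sd > 0) {
    r <- r * exp(rnorm(n, 0, params$noise_sd))
  }
  growth <- r * P * (1 - P / grid$carrying_capacity)
  immigration <- 0
  if (!is.null(params$kernel) && params$q > 0) {
    # immigration into i: q * sum_j k_ji P_j, with weights[j, i] = k_ji
    immigration <- params$q * drop(crossprod(params$kernel$weights, P))
  }
  P_new <- P + growth + immigration
  P_new <- pmin(pmax(P_new, 0), grid$carrying_capacity)
  P_new[!forest_mask(grid)] <- 0
  P_new
}

#' Run one seeded simulation
#'
#' @param grid a `landscape_grid`.
#' @param params a `sim_params`.
#' @param seed integer RNG seed.
#' @param P0 initial occupancy (defaults to `grid$occupancy0`).
#' @return matrix of occupancy, `(years + 1) x n_cells`; row 1 is year 0.
#' @export
run_sim <- function(grid, params, seed, P0 = grid$occupancy0) {
  set.seed(seed)
  n <- n_cells(grid)
  traj <- matrix(0, nrow = params$years + 1, ncol = n)
  traj[1, ] <- P0
  P <- P0
  for (t in seq_len(params$years)) {
    P <- step_occupancy(P, grid, params)
    traj[t + 1, ] <- P
  }
  rownames(traj) <- paste0("year", 0:params$years)
  traj
}

#' Run a Monte Carlo ensemble and summarise landscape totals
#'
#' Runs `n_runs` trajectories with per-run seeds derived from `base_seed`, and
#' aggregates the per-year landscape occupancy (mean occupancy percent over
#' forest cells) and, when a fire model is supplied, the landscape total of
#' annual expected crown fires. Standard errors are `sd / sqrt(n_runs)`.
#'
#' @param grid a `landscape_grid`.
#' @param params a `sim_params`.
#' @param base_seed integer seed from which per-run seeds are derived.
#' @param zinb optional `zinb_model`; when given, per-year expected annual
#'   crown fire totals over forest cells are summarised too.
#' @return list of class `ensemble_summary`: `summary` (data frame: year,
#'   occ_mean, occ_se, and fire_mean / fire_se when `zinb` is given),
#'   `final_states` (`n_runs x n_cells` matrix of year-`years` occupancy),
#'   `occ_runs` (`n_runs x (years+1)` per-run occupancy totals), `n_runs`.
#' @export
run_ensemble <- function(grid, params, base_seed, zinb = NULL) {
  set.seed(base_seed)
  run_seeds <- sample.int(.Machine$integer.max, params$n_runs)
  n <- n_cells(grid)
  fmask <- forest_mask(grid)
  years <- params$years
  occ_runs <- matrix(0, params$n_runs, years + 1)
  fire_runs <- if (!is.null(zinb)) matrix(0, params$n_runs, years + 1) else NULL
  final_states <- matrix(0, params$n_runs, n)
  for (k in seq_len(params$n_runs)) {
    traj <- run_sim(grid, params, seed = run_seeds[k])
    occ_runs[k, ] <- rowMeans(traj[, fmask, drop = FALSE])
    if (!is.null(zinb)) {
      for (t in seq_len(years + 1)) {
        e5 <- expected_fires(zinb, grid$cells[fmask, , drop = FALSE],
                             traj[t, fmask])
        fire_runs[k, t] <- sum(e5) / 5  # annual expected frequency
      }
    }
    final_states[k, ] <- traj[years + 1, ]
  }
  se <- function(m) {
    if (nrow(m) < 2) return(rep(NA_real_, ncol(m)))
    apply(m, 2, sd) / sqrt(nrow(m))
  }
  summary <- data.frame(
    year = 0:years,
    occ_mean = colMeans(occ_runs),
    occ_se = se(occ_runs)
  )
  if (!is.null(zinb)) {
    summary$fire_mean <- colMeans(fire_runs)
    summary$fire_se <- se(fire_runs)
  }
  structure(
    list(summary = summary, final_states = final_states,
         occ_runs = occ_runs, fire_runs = fire_runs,
         n_runs = params$n_runs, run_seeds = run_seeds),
    class = "ensemble_summary"
  )
}

#' @export
print.ensemble_summary <- function(x, ...) {
  cat("<ensemble_summary>", x$n_runs, "runs,",
      nrow(x$summary) - 1, "years\n")
  print(utils::head(x$summary), row.names = FALSE)
  if (nrow(x$summary) > 6) cat("...\n")
  invisible(x)
}
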
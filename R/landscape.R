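#' Generator configuration for synthetic landscapes
#'
#' Defaults describe a plausible Alabama/Mississippi forest landscape: mostly
#' private forest land on gentle terrain, warm humid climate (mean daily
#' maximum near 24 degrees C, about 0.38 cm precipitation per day), and a small
#' number of sparse, low-occupancy (<25 percent) invasion foci confined to
#' forest cells.
#'
#' @param land_type_props named numeric vector of land-type proportions over
#'   [LAND_TYPES]; must sum to 1.
#' @param slope_mean,slope_sd slope distribution, degrees (truncated at 0).
#' @param tmax_mean,tmax_sd mean daily maximum temperature, degrees C.
#' @param precip_mean,precip_sd mean daily precipitation, cm (truncated at 0).
#' @param stand_age_mean,stand_age_sd stand age, years (truncated at 0).
#' @param site_productivity_levels,site_productivity_probs ordinal site
#'   productivity classes and their sampling probabilities.
#' @param road_distance_levels,road_distance_probs ordinal distance-to-road
#'   classes and probabilities.
#' @param p_water_adjacent probability a cell lies within 300 m of water.
#' @param p_artificial_regen probability of artificial regeneration.
#' @param p_fire_disturbance probability of recent fire disturbance.
#' @param p_private probability of private ownership.
#' @param physio_props named proportions over [PHYSIO_CLASSES].
#' @param n_foci number of initially invaded forest cells.
#' @param focus_min,focus_max range (percent occupancy) from which initial
#'   focus occupancy is drawn uniformly; `focus_max` defaults to the
#'   low-occupancy ceiling of 25 percent.
#' @param carrying_capacity per-cell carrying capacity, percent.
#' @param cell_width cell width in metres.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(land_type_props = c(
                               urban = 0.06, agricultural = 0.18,
                               rangeland = 0.08, forest = 0.55, water = 0.05,
                               wetland = 0.05, barren = 0.03
                             ),
                             slope_mean = 4, slope_sd = 3,
                             tmax_mean = 24, tmax_sd = 1.5,
                             precip_mean = 0.38, precip_sd = 0.08,
                             stand_age_mean = 40, stand_age_sd = 20,
                             site_productivity_levels = 1:7,
                             site_productivity_probs =
                               c(0.05, 0.15, 0.25, 0.25, 0.15, 0.10, 0.05),
                             road_distance_levels = 1:9,
                             road_distance_probs =
                               c(0.30, 0.20, 0.15, 0.10, 0.08, 0.07, 0.05,
                                 0.03, 0.02),
                             p_water_adjacent = 0.30,
                             p_artificial_regen = 0.25,
                             p_fire_disturbance = 0.05,
                             p_private = 0.85,
                             physio_props = c(
                               xeric = 0.25, mesic = 0.60, hydric = 0.15
                             ),
                             n_foci = 5,
                             focus_min = 0.5, focus_max = 25,
                             carrying_capacity = 100,
                             cell_width = 4927) {
  cfg <- list(
    land_type_props = land_type_props,
    slope_mean = slope_mean, slope_sd = slope_sd,
    tmax_mean = tmax_mean, tmax_sd = tmax_sd,
    precip_mean = precip_mean, precip_sd = precip_sd,
    stand_age_mean = stand_age_mean, stand_age_sd = stand_age_sd,
    site_productivity_levels = site_productivity_levels,
    site_productivity_probs = site_productivity_probs,
    road_distance_levels = road_distance_levels,
    road_distance_probs = road_distance_probs,
    p_water_adjacent = p_water_adjacent,
    p_artificial_regen = p_artificial_regen,
    p_fire_disturbance = p_fire_disturbance,
    p_private = p_private,
    physio_props = physio_props,
    n_foci = n_foci, focus_min = focus_min, focus_max = focus_max,
    carrying_capacity = carrying_capacity,
    cell_width = cell_width
  )
  class(cfg) <- "generator_config"
  cfg
}

new_landscape_grid <- function(cells, cell_width, carrying_capacity,
                               occupancy0) {
  grid <- structure(
    list(
      cells = cells,
      cell_width = cell_width,
      carrying_capacity = carrying_capacity,
      occupancy0 = occupancy0
    ),
    class = "landscape_grid"
  )
  validate_landscape_grid(grid)
  grid
}

validate_landscape_grid <- function(grid) {
  cells <- grid$cells
  n <- nrow(cells)
  required <- c(
    "cell_id", "x", "y", "land_type", "slope", "water_adjacent", "tmax",
    "precip", "stand_age", "site_productivity", "artificial_regen",
    "road_distance", "fire_disturbance", "private_ownership",
    "physiographic_class"
  )
  missing <- setdiff(required, names(cells))
  if (length(missing) > 0) {
    stop("cell table is missing mandatory column(s): ",
         paste(missing, collapse = ", "))
  }
  if (!all(cells$land_type %in% LAND_TYPES)) {
    bad <- cells$cell_id[!cells$land_type %in% LAND_TYPES][1]
    stop("unknown land_type at cell_id ", bad)
  }
  if (!all(cells$physiographic_class %in% PHYSIO_CLASSES)) {
    bad <- cells$cell_id[!cells$physiographic_class %in% PHYSIO_CLASSES][1]
    stop("unknown physiographic_class at cell_id ", bad)
  }
  if (any(cells$slope < 0)) {
    stop("negative slope at cell_id ", cells$cell_id[cells$slope < 0][1])
  }
  for (b in c("water_adjacent", "artificial_regen", "fire_disturbance",
              "private_ownership")) {
    if (!all(cells[[b]] %in% c(0, 1))) {
      stop("column ", b, " must be binary (0/1); offending cell_id ",
           cells$cell_id[!cells[[b]] %in% c(0, 1)][1])
    }
  }
  K <- grid$carrying_capacity
  P0 <- grid$occupancy0
  if (length(K) != n || length(P0) != n) {
    stop("carrying_capacity and occupancy0 must have one value per cell")
  }
  if (any(K > 100 | K < 0)) {
    stop("carrying capacity outside [0, 100] at cell_id ",
         cells$cell_id[K > 100 | K < 0][1])
  }
  bad <- which(P0 < 0 | P0 > K)
  if (length(bad) > 0) {
    stop("occupancy outside [0, K] at cell_id ", cells$cell_id[bad[1]])
  }
  bad <- which(P0 > 0 & cells$land_type != "forest")
  if (length(bad) > 0) {
    stop("non-forest cell with positive occupancy at cell_id ",
         cells$cell_id[bad[1]])
  }
  invisible(grid)
}

#' Number of cells in a landscape grid
#' @param grid a `landscape_grid`.
#' @return integer cell count.
#' @export
n_cells <- function(grid) nrow(grid$cells)

#' Logical mask of forest cells
#' @param grid a `landscape_grid`.
#' @return logical vector, `TRUE` for forest-land cells.
#' @export
forest_mask <- function(grid) grid$cells$land_type == "forest"

#' @export
print.landscape_grid <- function(x, ...) {
  cat("<landscape_grid>", n_cells(x), "cells,",
      sum(forest_mask(x)), "forest;",
      sum(x$occupancy0 > 0), "invaded foci; cell width", x$cell_width, "m\n")
  invisible(x)
}

rtrunc_norm <- function(n, mean, sd, lower = 0) {
  pmax(lower, rnorm(n, mean, sd))
}

#' Generate a synthetic landscape grid
#'
#' Builds a square lattice of cells with land types, environmental covariates
#' and a sparse set of low-occupancy invasion foci confined to forest cells.
#' Deterministic for a fixed seed.
#'
#' @param n_cells number of cells (>= 1); laid out on a near-square lattice
#'   with unit (one grid-width) spacing.
#' @param config a [generator_config()].
#' @param seed integer RNG seed.
#' @return A `landscape_grid`.
#' @export
#' @examples
#' g <- generate_grid(100, generator_config(n_foci = 3), seed = 7)
#' sum(g$occupancy0 > 0)
generate_grid <- function(n_cells, config = generator_config(), seed) {
  if (!is.numeric(n_cells) || n_cells < 1) {
    stop("n_cells must be a positive integer")
  }
  n_cells <- as.integer(n_cells)
  props <- config$land_type_props
  if (abs(sum(props) - 1) > 1e-8) {
    stop("land-type proportions must sum to 1 (got ", sum(props), ")")
  }
  if (!all(names(props) %in% LAND_TYPES)) {
    stop("unknown land type in proportions: ",
         paste(setdiff(names(props), LAND_TYPES), collapse = ", "))
  }
  set.seed(seed)
  ncol_grid <- ceiling(sqrt(n_cells))
  idx <- seq_len(n_cells) - 1L
  x <- idx %% ncol_grid
  y <- idx %/% ncol_grid

  land_type <- sample(names(props), n_cells, replace = TRUE, prob = props)
  cells <- data.frame(
    cell_id = seq_len(n_cells),
    x = x, y = y,
    land_type = land_type,
    slope = rtrunc_norm(n_cells, config$slope_mean, config$slope_sd),
    water_adjacent = rbinom(n_cells, 1, config$p_water_adjacent),
    tmax = rnorm(n_cells, config$tmax_mean, config$tmax_sd),
    precip = rtrunc_norm(n_cells, config$precip_mean, config$precip_sd),
    stand_age = rtrunc_norm(n_cells, config$stand_age_mean,
                            config$stand_age_sd),
    site_productivity = sample(config$site_productivity_levels, n_cells,
                               replace = TRUE,
                               prob = config$site_productivity_probs),
    artificial_regen = rbinom(n_cells, 1, config$p_artificial_regen),
    road_distance = sample(config$road_distance_levels, n_cells,
                           replace = TRUE, prob = config$road_distance_probs),
    fire_disturbance = rbinom(n_cells, 1, config$p_fire_disturbance),
    private_ownership = rbinom(n_cells, 1, config$p_private),
    physiographic_class = sample(names(config$physio_props), n_cells,
                                 replace = TRUE, prob = config$physio_props),
    stringsAsFactors = FALSE
  )

  occupancy0 <- rep(0, n_cells)
  forest_idx <- which(cells$land_type == "forest")
  n_foci <- config$n_foci
  if (n_foci > 0) {
    if (length(forest_idx) < n_foci) {
      stop("landscape has only ", length(forest_idx),
           " forest cells but ", n_foci, " foci were requested")
    }
    foci <- sample(forest_idx, n_foci)
    occupancy0[foci] <- runif(n_foci, config$focus_min, config$focus_max)
  }

  new_landscape_grid(
    cells = cells,
    cell_width = config$cell_width,
    carrying_capacity = rep(config$carrying_capacity, n_cells),
    occupancy0 = occupancy0
  )
}

#' Generate a pair of occupancy surveys with known growth
#'
#' The second survey is the exponential-growth image of the first,
#' `P_t2 = min(K, P_t1 * exp(true_r * interval + noise))`, so the survey-based
#' rate estimator recovers `true_r` exactly when `noise_sd = 0`. Cells can be
#' flagged as treated (site preparation / invasion control), which excludes
#' them from rate estimation downstream.
#'
#' @param grid a `landscape_grid`; first-survey occupancy is `grid$occupancy0`.
#' @param true_r per-cell intrinsic rate (recycled if scalar).
#' @param interval years between surveys (>= 1).
#' @param noise_sd standard deviation of Gaussian noise on the log scale.
#' @param seed integer RNG seed.
#' @param t1 calendar year of the first survey.
#' @param prop_treated proportion of invaded cells randomly flagged as
#'   site-prepared/controlled.
#' @return A list of class `survey_pair` with `t1`, `t2`, `P_t1`, `P_t2`, and
#'   `excluded` (reason code or `NA`).
#' @export
generate_survey_pair <- function(grid, true_r, interval = 5, noise_sd = 0,
                                 seed, t1 = 2003, prop_treated = 0) {
  if (interval < 1) stop("survey interval must be >= 1 year")
  if (any(!is.finite(true_r))) stop("true_r must be finite")
  n <- n_cells(grid)
  true_r <- rep_len(true_r, n)
  set.seed(seed)
  P1 <- grid$occupancy0
  noise <- if (noise_sd > 0) rnorm(n, 0, noise_sd) else rep(0, n)
  P2 <- pmin(grid$carrying_capacity, P1 * exp(true_r * interval + noise))
  excluded <- rep(NA_character_, n)
  if (prop_treated > 0) {
    invaded <- which(P1 > 0)
    n_treat <- round(prop_treated * length(invaded))
    if (n_treat > 0) {
      excluded[sample(invaded, n_treat)] <- "site_prep"
    }
  }
  structure(
    list(t1 = t1, t2 = t1 + interval, P_t1 = P1, P_t2 = P2,
         excluded = excluded),
    class = "survey_pair"
  )
}

#' Draw presence/absence of invasion from a habitat-quality model
#'
#' Bernoulli draws with per-cell probability `predict_hq(model, grid)`; used to
#' create presence data with a known logistic truth for fitting experiments.
#'
#' @param grid a `landscape_grid`.
#' @param model an `hq_model`.
#' @param seed integer RNG seed.
#' @return integer 0/1 vector, one per cell.
#' @export
generate_presence <- function(grid, model, seed) {
  set.seed(seed)
  p <- predict_hq(model, grid$cells)
  rbinom(length(p), 1, p)
}

#' Sample crown-fire counts from a zero-inflated negative binomial model
#'
#' Each cell is a structural zero with its climate-driven probability, and
#' otherwise draws a negative binomial count with the model's conditional mean,
#' so the empirical mean over many cells approaches
#' `(1 - p_zero) * mu`.
#'
#' @param grid a `landscape_grid`.
#' @param occupancy per-cell invader occupancy, percent, in `[0, 100]`.
#' @param model a `zinb_model` with intercepts and dispersion specified.
#' @param seed integer RNG seed.
#' @return integer vector of nonnegative 5-year fire counts, one per cell.
#' @export
generate_fire_counts <- function(grid, occupancy, model, seed) {
  stopifnot(inherits(model, "zinb_model"))
  if (model$dispersion <= 0) stop("dispersion must be > 0")
  n <- n_cells(grid)
  occupancy <- rep_len(occupancy, n)
  set.seed(seed)
  p0 <- zero_probability(model, grid$cells)
  mu <- count_mean(model, grid$cells, occupancy)
  structural <- runif(n) < p0
  counts <- rnbinom(n, size = model$dispersion, mu = mu)
  counts[structural] <- 0L
  as.integer(counts)
}
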
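#' Configuration for the synthetic survey generator
#'
#' Bundles every constant the generator needs to emulate the survey design:
#' a lattice landscape of compositional vegetation covers plus elevation,
#' point counts partitioned into removal intervals, and multi-year
#' detection/non-detection histories at raptor territories.
#'
#' Defaults reproduce the shape of the motivating study design: 983
#' point-count sites surveyed once for five 2-min removal intervals within a
#' 400-m radius (0.5024 km^2 effective area), an 800 m x 800 m covariate
#' lattice, and 97 territories surveyed twice per season over six seasons
#' with roughly 60 of the 1164 surveys missing. The default random-intercept
#' standard deviations follow the pattern reported for the system: no
#' year-to-year variance in occupancy (`sigma_year = 0`) and large
#' territory-to-territory variance in detection
#' (`sigma_territory = sqrt(7.46)`).
#'
#' Coefficient vectors are named; names must match columns of the covariate
#' tables handed to the generators (plus `"(Intercept)"`). Abundance
#' coefficients live on the log scale with densities per km^2 (the area
#' offset is added separately); detection and occupancy coefficients live on
#' the logit scale. Covariates named in the coefficient vectors are used
#' exactly as supplied, so simulation on the 2-SD standardized scale is
#' achieved by standardizing the covariate table first.
#'
#' @param n_sites number of point-count sites.
#' @param n_intervals removal intervals per count (5).
#' @param interval_minutes length of one interval in minutes (2).
#' @param survey_radius_m point-count radius in metres (400).
#' @param offset_area_km2 area sampled by one point count, km^2. The study
#'   convention 0.5024 km^2 is kept as the default (pi * 0.4^2 rounds to
#'   0.5027; the published constant is honoured).
#' @param cell_side_m lattice cell side in metres (800).
#' @param grid_nx,grid_ny lattice dimensions for [simulate_landscape()].
#' @param dirichlet_alpha named non-negative concentration vector for the
#'   per-cell compositional allocation of vegetation classes. Must include
#'   the five modelled classes; an `other` class absorbs the remainder so
#'   per-cell covers sum to at most 100.
#' @param elevation_mean,elevation_sd,elevation_range mean, SD (m) and clip
#'   range of the smoothed elevation field.
#' @param elevation_smooth Gaussian smoothing kernel SD in cell units;
#'   controls the spatial autocorrelation length of elevation.
#' @param abundance_coefs named numeric, log-scale abundance submodel
#'   (intercept = log density per km^2 at covariate zero).
#' @param detection_coefs named numeric, logit-scale per-interval detection
#'   submodel. Factor covariates (e.g. `observer_id`) are reference-coded;
#'   name entries after the design columns, e.g. `observer_idB`.
#' @param n_observers number of observers for generated `observer_id` values.
#' @param day_range,time_range,wind_range ranges (uniform) for generated
#'   detection covariates: ordinal date, minutes after civil twilight, and
#'   wind speed km/h (surveys were not run above 24 km/h).
#' @param n_territories,n_years,surveys_per_year territory survey design.
#' @param missing_fraction fraction of territory surveys lost (default
#'   60/1164, the study's incompletion rate); must be in [0, 1).
#' @param psi_coefs named numeric, logit-scale occupancy submodel applied to
#'   the territory prey-density table.
#' @param p_coefs named numeric, logit-scale territory detection submodel
#'   (intercept + `day_of_year`, applied to a 2-SD standardized ordinal
#'   date).
#' @param occ_day_range ordinal-date range of territory surveys (May 1 to
#'   Jul 2).
#' @param sigma_year SD of the year random intercept on occupancy (>= 0).
#' @param sigma_territory SD of the territory random intercept on detection
#'   (>= 0).
#'
#' @return an object of class `sim_config` (a validated list).
#' @seealso [simulate_landscape()], [simulate_point_counts()],
#'   [simulate_territory_histories()]
#' @export
#' @examples
#' cfg <- sim_config(n_sites = 50, grid_nx = 10, grid_ny = 10)
#' cfg$n_intervals
sim_config <- function(n_sites = 983,
                       n_intervals = 5,
                       interval_minutes = 2,
                       survey_radius_m = 400,
                       offset_area_km2 = 0.5024,
                       cell_side_m = 800,
                       grid_nx = 40,
                       grid_ny = 30,
                       dirichlet_alpha = c(tundra = 3, tussock = 2,
                                           tall_shrub = 1, low_shrub = 2,
                                           sparse = 1, other = 1),
                       elevation_mean = 300,
                       elevation_sd = 150,
                       elevation_range = c(0, 800),
                       elevation_smooth = 2,
                       abundance_coefs = c("(Intercept)" = log(3.3),
                                           tundra = 0.5, tussock = 0.25,
                                           tall_shrub = 0.3,
                                           elevation = -0.3),
                       detection_coefs = c("(Intercept)" = qlogis(0.1),
                                           day_of_year = -0.4,
                                           time_of_day = -0.15,
                                           wind_kmh = -0.15,
                                           observer_idB = 0.3,
                                           observer_idC = -0.3),
                       n_observers = 3,
                       day_range = c(130, 204),
                       time_range = c(0, 420),
                       wind_range = c(0, 24),
                       n_territories = 97,
                       n_years = 6,
                       surveys_per_year = 2,
                       missing_fraction = 60 / 1164,
                       psi_coefs = c("(Intercept)" = 0.12, willow = 0.9,
                                     rock = 0.3, ags = 0.7),
                       p_coefs = c("(Intercept)" = 0.23, day_of_year = -0.6),
                       occ_day_range = c(121, 183),
                       sigma_year = 0,
                       sigma_territory = sqrt(7.46)) {
  cfg <- list(n_sites = as.integer(n_sites),
              n_intervals = as.integer(n_intervals),
              interval_minutes = interval_minutes,
              survey_radius_m = survey_radius_m,
              offset_area_km2 = offset_area_km2,
              cell_side_m = cell_side_m,
              grid_nx = as.integer(grid_nx), grid_ny = as.integer(grid_ny),
              dirichlet_alpha = dirichlet_alpha,
              elevation_mean = elevation_mean, elevation_sd = elevation_sd,
              elevation_range = elevation_range,
              elevation_smooth = elevation_smooth,
              abundance_coefs = abundance_coefs,
              detection_coefs = detection_coefs,
              n_observers = as.integer(n_observers),
              day_range = day_range, time_range = time_range,
              wind_range = wind_range,
              n_territories = as.integer(n_territories),
              n_years = as.integer(n_years),
              surveys_per_year = as.integer(surveys_per_year),
              missing_fraction = missing_fraction,
              psi_coefs = psi_coefs, p_coefs = p_coefs,
              occ_day_range = occ_day_range,
              sigma_year = sigma_year, sigma_territory = sigma_territory)
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_intervals >= 1L,
            cfg$n_sites >= 1L,
            cfg$offset_area_km2 > 0,
            cfg$cell_side_m > 0)
  if (cfg$grid_nx < 1L || cfg$grid_ny < 1L)
    stop("grid dimensions must be positive", call. = FALSE)
  if (cfg$sigma_year < 0 || cfg$sigma_territory < 0)
    stop("random-effect standard deviations must be non-negative",
         call. = FALSE)
  if (cfg$missing_fraction < 0 || cfg$missing_fraction >= 1)
    stop("missing_fraction must lie in [0, 1)", call. = FALSE)
  if (any(cfg$dirichlet_alpha < 0) || sum(cfg$dirichlet_alpha) <= 0)
    stop("dirichlet_alpha must be non-negative with positive sum",
         call. = FALSE)
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic survey design\n")
  cat(sprintf("  point counts : %d sites x %d intervals of %g min (A = %g km^2)\n",
              x$n_sites, x$n_intervals, x$interval_minutes,
              x$offset_area_km2))
  cat(sprintf("  landscape    : %d x %d cells of %g m\n",
              x$grid_nx, x$grid_ny, x$cell_side_m))
  cat(sprintf("  territories  : %d x %d years x %d surveys (%.1f%% missing)\n",
              x$n_territories, x$n_years, x$surveys_per_year,
              100 * x$missing_fraction))
  invisible(x)
}
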
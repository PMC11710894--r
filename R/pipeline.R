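#' Run the full synthetic-study pipeline
#'
#' Orchestrates every stage on generated data: landscape and site
#' placement, removal counts for the three prey species, 2-SD
#' standardization and elevation filtering, maximum-likelihood removal
#' fits with bootstrap GOF, density surfaces, study-area totals,
#' territory-level prey densities, territory history generation, the
#' stacked occupancy fit and its GOF, and the summary tallies. Every
#' random stage consumes a seed derived deterministically from `seed`, so
#' the whole bundle is reproducible from the configuration alone.
#'
#' @param species_configs named list of [sim_config()]s, one per species
#'   (defaults emulate Willow Ptarmigan, Rock Ptarmigan and Arctic ground
#'   squirrel habitat structure).
#' @param seed master integer seed.
#' @param territory_radius_km radius used to collect density cells around
#'   each territory centre; a required study decision (default here 4 km,
#'   an 800-m-lattice-friendly stand-in for an unstated field value).
#' @param gof_B bootstrap replicates for the removal GOF (0 skips it).
#' @param occ_gof_B bootstrap replicates for the occupancy GOF (0 skips).
#' @param out_dir optional directory: stage outputs are written as CSV.
#' @return list bundle: `landscape`, `sites`, per-species `counts`,
#'   `fits`, `gof`, `surfaces`, `totals`, `territory_densities`,
#'   `histories`, `occupancy_fit`, `occupancy_gof`, `summaries`,
#'   `mean_psi_p`, `log`.
#' @export
run_pipeline <- function(species_configs = default_species_configs(),
                         seed = 1L, territory_radius_km = 4,
                         gof_B = 100L, occ_gof_B = 0L, out_dir = NULL) {
  t0 <- Sys.time()
  log <- list()
  note <- function(stage, ...) {
    log[[length(log) + 1]] <<- sprintf("[%s] %s", stage, sprintf(...))
  }
  base_cfg <- species_configs[[1]]
  note("simulate", "seed = %d", seed)

  land <- simulate_landscape(base_cfg, seed = seed)
  sites <- place_sites(base_cfg, land, seed = seed + 1L)

  filt <- filter_sites_by_elevation(sites, max_elevation = 500)
  sites <- filt$sites
  note("preprocess", "%d/%d sites retained below 500 m",
       filt$report$n_retained, filt$report$n_input)

  veg <- c("tundra", "tussock", "tall_shrub", "low_shrub", "sparse")
  screen <- screen_collinearity(sites[, c(veg, "elevation")])
  note("preprocess", "collinearity pairs flagged: %d", nrow(screen))
  std <- standardize(sites, cols = c(veg, "elevation"))
  sites_std <- std$values

  species <- names(species_configs)
  counts <- fits <- gofs <- surfaces <- totals <- list()
  tds <- list()

  # territory centres drawn once on the landscape
  set.seed(seed + 2L)
  n_terr <- base_cfg$n_territories
  tc <- cbind(runif(n_terr, min(land$x_center), max(land$x_center)),
              runif(n_terr, min(land$y_center), max(land$y_center)))

  for (s in seq_along(species)) {
    sp <- species[s]
    cfg <- species_configs[[sp]]
    counts[[sp]] <- simulate_point_counts(cfg, sites_std,
                                          seed = seed + 10L + s)
    ab <- setdiff(names(cfg$abundance_coefs), "(Intercept)")
    det <- detection_terms(cfg$detection_coefs, counts[[sp]])
    # detection covariates standardized with their own training scaler
    dnum <- intersect(det, c("day_of_year", "time_of_day", "wind_kmh"))
    dstd <- standardize(counts[[sp]], cols = dnum)
    dat <- dstd$values
    spec <- removal_spec(ab, det, offset_area = cfg$offset_area_km2,
                         n_intervals = cfg$n_intervals)
    fits[[sp]] <- suppressWarnings(
      fit_removal(dat, spec, scaler = std$scaler))
    note("fit", "%s logLik %.2f converged %s", sp, fits[[sp]]$logLik,
         fits[[sp]]$converged)
    if (!fits[[sp]]$converged)
      stop("abundance fit for species '", sp, "' did not converge ",
           "(|grad| = ", format(fits[[sp]]$grad_norm, digits = 3),
           ", Hessian PD = ", fits[[sp]]$hessian_pd,
           "); this data realization does not support the model",
           call. = FALSE)
    if (gof_B > 0) {
      gofs[[sp]] <- gof_parametric_bootstrap(fits[[sp]], B = gof_B,
                                             seed = seed + 20L + s)
      note("gof", "%s p = %.3f c-hat = %.3f", sp, gofs[[sp]]$p_value,
           gofs[[sp]]$c_hat)
    }
    pg <- build_prediction_grid(land, fits[[sp]])
    surfaces[[sp]] <- map_density(fits[[sp]], pg, seed = seed + 30L + s)
    totals[[sp]] <- total_abundance(surfaces[[sp]], seed = seed + 40L + s)
    note("map", "%s total %.0f (%.0f-%.0f) over %d cells", sp,
         totals[[sp]]$estimate, totals[[sp]]$lower, totals[[sp]]$upper,
         totals[[sp]]$n_cells)
    td <- do.call(rbind, lapply(seq_len(n_terr), function(k)
      suppressWarnings(
        territory_density(surfaces[[sp]], tc[k, ],
                          radius_m = territory_radius_km * 1000,
                          territory_id = k))))
    tds[[sp]] <- td$density_per_km2
  }

  dens <- data.frame(territory_id = seq_len(n_terr))
  for (nm in names(tds)) dens[[nm]] <- tds[[nm]]
  ok <- complete.cases(dens)
  dens <- dens[ok, , drop = FALSE]
  note("territory", "%d/%d territories with valid prey densities",
       nrow(dens), n_terr)

  dens_std <- standardize(dens, cols = names(tds))$values
  occ_cfg <- base_cfg
  occ_cfg$n_territories <- nrow(dens_std)
  hist <- simulate_territory_histories(occ_cfg, dens_std,
                                       seed = seed + 50L)
  day_std <- standardize(hist$day_of_year)
  hist$day_of_year <- day_std$values

  od <- occu_data(hist, dens_std, occ_covs = names(tds))
  ofit <- fit_occupancy(data = od)
  note("occupancy", "sigma_year %.3f sigma_territory %.3f converged %s",
       ofit$sigma_year, ofit$sigma_territory, ofit$converged)
  ogof <- if (occ_gof_B > 0) mb_gof(ofit, B = occ_gof_B,
                                    seed = seed + 60L) else NULL
  mpp <- mean_psi_p(ofit)
  note("occupancy", "mean psi %.3f mean p %.3f", mpp$mean_psi, mpp$mean_p)

  summaries <- lapply(counts, function(ct) {
    ct$year <- rep(2019L, nrow(ct))  # single synthetic season
    summarize_counts(ct)
  })

  bundle <- list(landscape = land, sites = sites_std, counts = counts,
                 fits = fits, gof = gofs, surfaces = surfaces,
                 totals = totals,
                 territory_densities = dens,
                 histories = hist, occupancy_fit = ofit,
                 occupancy_gof = ogof, mean_psi_p = mpp,
                 summaries = summaries,
                 collinearity = screen,
                 elapsed_s = as.numeric(difftime(Sys.time(), t0,
                                                 units = "secs")),
                 log = unlist(log))
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

#' Default per-species generator configurations
#'
#' Three configurations sharing one landscape/design but with
#' species-specific abundance submodels: a widespread shrub/tundra species
#' at moderate density (Willow-Ptarmigan-like), a sparse high-ground
#' species (Rock-Ptarmigan-like) and a colonial sparse-vegetation rodent
#' (ground-squirrel-like).
#'
#' @return named list of three [sim_config()]s.
#' @export
default_species_configs <- function() {
  willow <- sim_config()
  rock <- sim_config(
    abundance_coefs = c("(Intercept)" = log(0.25), tundra = 0.4,
                        low_shrub = 0.1, sparse = 0.45, elevation = 0.1),
    detection_coefs = c("(Intercept)" = qlogis(0.2), day_of_year = -0.5,
                        time_of_day = -0.05, wind_kmh = -0.05,
                        observer_idB = 0.1, observer_idC = -0.1))
  ags <- sim_config(
    abundance_coefs = c("(Intercept)" = log(0.55), tundra = 0.1,
                        low_shrub = 0.35, sparse = 0.45, elevation = 0.4),
    detection_coefs = c("(Intercept)" = qlogis(0.1), day_of_year = -0.2,
                        time_of_day = 0.5, wind_kmh = -0.15,
                        observer_idB = 0.1, observer_idC = -0.1))
  list(willow = willow, rock = rock, ags = ags)
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(bundle$landscape, file.path(out_dir, "landscape.csv"),
            row.names = FALSE)
  for (sp in names(bundle$counts)) {
    write.csv(bundle$counts[[sp]],
              file.path(out_dir, paste0("counts_", sp, ".csv")),
              row.names = FALSE)
    write.csv(as.data.frame(bundle$surfaces[[sp]]),
              file.path(out_dir, paste0("surface_", sp, ".csv")),
              row.names = FALSE)
    write_removal_model(bundle$fits[[sp]],
                        file.path(out_dir, paste0("model_", sp, ".json")))
  }
  write.csv(bundle$territory_densities,
            file.path(out_dir, "territory_densities.csv"),
            row.names = FALSE)
  write.csv(bundle$histories, file.path(out_dir, "histories.csv"),
            row.names = FALSE)
  writeLines(bundle$log, file.path(out_dir, "pipeline.log"))
  invisible(out_dir)
}

#' Serialize / restore a removal fit as structured text
#'
#' Writes coefficients, covariance, scaler, training ranges and the model
#' spec as JSON — everything needed to reproduce predictions exactly.
#'
#' @param fit a `removal_fit`.
#' @param path output file.
#' @export
write_removal_model <- function(fit, path) {
  obj <- list(coefficients = list(name = names(fit$coefficients),
                                  value = unname(fit$coefficients)),
              vcov = fit$vcov, logLik = fit$logLik,
              converged = fit$converged, grad_norm = fit$grad_norm,
              spec = fit$spec[c("abundance", "detection", "offset_area",
                                "n_intervals")],
              ranges = fit$ranges,
              scaler = if (!is.null(fit$scaler))
                list(mean = as.list(fit$scaler$mean),
                     sd = as.list(fit$scaler$sd),
                     divisor = fit$scaler$divisor))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_removal_model
#' @param data the training `removal_counts` table (predictions need the
#'   training design only through ranges/scaler; the data slot restores
#'   marginal-effect baselines).
#' @export
read_removal_model <- function(path, data = NULL) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- removal_spec(obj$spec$abundance %||% character(),
                       obj$spec$detection %||% character(),
                       obj$spec$offset_area, obj$spec$n_intervals)
  coefs <- setNames(obj$coefficients$value, obj$coefficients$name)
  nb <- length(spec$abundance) + 1L
  scaler <- if (!is.null(obj$scaler))
    new_scaler(unlist(obj$scaler$mean), unlist(obj$scaler$sd))
  vc <- as.matrix(obj$vcov)
  dimnames(vc) <- list(names(coefs), names(coefs))
  structure(list(beta = coefs[seq_len(nb)], alpha = coefs[-seq_len(nb)],
                 coefficients = coefs, vcov = vc, logLik = obj$logLik,
                 converged = obj$converged, grad_norm = obj$grad_norm,
                 hessian_pd = TRUE, boundary = FALSE,
                 scaler = scaler,
                 ranges = lapply(obj$ranges, unlist),
                 spec = spec, data = data,
                 n_sites = if (!is.null(data)) nrow(data) else NA_integer_),
            class = "removal_fit")
}
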
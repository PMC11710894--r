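#' Simulate time-removal point counts
#'
#' Generative form of the Poisson N-mixture time-removal model. For each
#' site `i`, latent abundance `N_i ~ Poisson(lambda_i)` with
#' `log(lambda_i) = beta' x_i + log(A)` (A the surveyed area, km^2). Each of
#' the `N_i` individuals is detected for the first time in interval `j` with
#' probability `pi_j = p_i (1 - p_i)^(j-1)`, `logit(p_i) = alpha' w_i`, or
#' never detected with probability `(1 - p_i)^J`. Interval counts are the
#' multinomial allocation of `N_i` over these cells, so the per-site total
#' never exceeds `N_i`.
#'
#' Coefficients are applied to the covariate columns exactly as supplied,
#' with one exception: the three canonical detection covariates
#' `day_of_year`, `time_of_day` and `wind_kmh` are standardized internally
#' by two standard deviations using the exact moments of their configured
#' uniform ranges (mean `(a+b)/2`, SD `(b-a)/sqrt(12)`), whether generated
#' or supplied raw, so `detection_coefs` stay on the comparable 2-SD scale
#' the fitted models use. They are drawn uniformly from the configured
#' ranges if absent from `covariates`, and returned on their raw scales.
#' Abundance covariates are used exactly as supplied: hand this function
#' 2-SD standardized habitat covariates to simulate on the fitted scale.
#'
#' @param cfg a [sim_config()]; `abundance_coefs` / `detection_coefs` name
#'   the covariate columns used.
#' @param covariates data frame with one row per site containing every
#'   covariate named in the coefficient vectors (detection covariates
#'   optional, see above).
#' @param seed integer seed.
#' @return data frame of class `removal_counts`: `site_id`, count columns
#'   `count_1 ... count_J`, and all covariate columns. The latent abundance
#'   vector is attached as attribute `"N"`, the true `lambda` and `p` as
#'   `"lambda"` and `"p"`.
#' @export
#' @examples
#' cfg <- sim_config(n_sites = 20)
#' covs <- data.frame(tundra = rnorm(20), tussock = rnorm(20),
#'                    tall_shrub = rnorm(20), elevation = rnorm(20))
#' y <- simulate_point_counts(cfg, covs, seed = 7)
#' colSums(y[, paste0("count_", 1:5)])
simulate_point_counts <- function(cfg, covariates, seed = 1L) {
  validate_sim_config(cfg)
  covariates <- as.data.frame(covariates)
  n <- nrow(covariates)
  J <- cfg$n_intervals
  set.seed(seed)

  covariates <- fill_detection_covariates(cfg, covariates, n)

  ab_terms <- setdiff(names(cfg$abundance_coefs), "(Intercept)")
  X <- build_design(covariates, ab_terms)
  beta <- align_coefs(cfg$abundance_coefs, X, "abundance")

  det_terms <- detection_terms(cfg$detection_coefs, covariates)
  W <- build_design(reference_standardize(cfg, covariates), det_terms)
  alpha <- align_coefs(cfg$detection_coefs, W, "detection")

  lambda <- exp(drop(X %*% beta) + log(cfg$offset_area_km2))
  p <- plogis(drop(W %*% alpha))

  N <- rpois(n, lambda)
  cells <- removal_cell_probs(p, J)        # n x J matrix + miss vector
  counts <- matrix(0L, n, J)
  pos <- which(N > 0)
  for (i in pos) {
    draw <- rmultinom(1, N[i], c(cells$pi[i, ], cells$miss[i]))
    counts[i, ] <- draw[seq_len(J), 1]
  }
  stopifnot(all(rowSums(counts) <= N))     # conservation check

  out <- data.frame(site_id = covariates$site_id %||% seq_len(n))
  colnames(counts) <- paste0("count_", seq_len(J))
  out <- cbind(out, counts,
               covariates[, setdiff(names(covariates), "site_id"),
                          drop = FALSE])
  class(out) <- c("removal_counts", "data.frame")
  attr(out, "N") <- N
  attr(out, "lambda") <- lambda
  attr(out, "p") <- p
  attr(out, "n_intervals") <- J
  out
}

# which coefficient names refer to plain columns vs factor expansions
detection_terms <- function(coefs, covariates) {
  nm <- setdiff(names(coefs), "(Intercept)")
  plain <- intersect(nm, names(covariates))
  rest <- setdiff(nm, plain)
  # names like observer_idB expand from a factor column that prefixes them
  fac <- unique(unlist(lapply(rest, function(s) {
    hit <- names(covariates)[startsWith(s, names(covariates))]
    if (!length(hit))
      stop("detection coefficient '", s, "' matches no covariate column",
           call. = FALSE)
    hit[which.max(nchar(hit))]
  })))
  c(plain, fac)
}

# 2-SD standardization of the canonical detection covariates with the
# closed-form uniform moments of the configured ranges
reference_standardize <- function(cfg, covariates) {
  ranges <- list(day_of_year = cfg$day_range, time_of_day = cfg$time_range,
                 wind_kmh = cfg$wind_range)
  for (nm in names(ranges)) {
    if (!is.null(covariates[[nm]])) {
      r <- ranges[[nm]]
      mu <- mean(r); s <- diff(r) / sqrt(12)
      covariates[[nm]] <- (covariates[[nm]] - mu) / (2 * s)
    }
  }
  covariates
}

fill_detection_covariates <- function(cfg, covariates, n) {
  if (is.null(covariates$day_of_year) &&
      "day_of_year" %in% names(cfg$detection_coefs))
    covariates$day_of_year <- runif(n, cfg$day_range[1], cfg$day_range[2])
  if (is.null(covariates$time_of_day) &&
      "time_of_day" %in% names(cfg$detection_coefs))
    covariates$time_of_day <- runif(n, cfg$time_range[1], cfg$time_range[2])
  if (is.null(covariates$wind_kmh) &&
      "wind_kmh" %in% names(cfg$detection_coefs))
    covariates$wind_kmh <- runif(n, cfg$wind_range[1], cfg$wind_range[2])
  needs_obs <- any(startsWith(names(cfg$detection_coefs), "observer_id"))
  if (is.null(covariates$observer_id) && needs_obs)
    covariates$observer_id <- sample(LETTERS[seq_len(cfg$n_observers)],
                                     n, replace = TRUE)
  covariates
}
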
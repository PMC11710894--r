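#' Removal-interval cell probabilities
#'
#' Under a time-removal design an individual is first detected in interval
#' `j` with probability `pi_j = p (1 - p)^(j-1)` and escapes detection with
#' probability `(1 - p)^J`, so the cells plus the miss probability always
#' sum to one.
#'
#' @param p per-interval detection probability, scalar or vector in [0, 1].
#' @param n_intervals number of intervals J.
#' @return list with `pi` (length-J vector, or `length(p)` x J matrix) and
#'   `miss`.
#' @export
#' @examples
#' removal_cell_probs(0.5, 5)   # geometric halving, miss 0.03125
removal_cell_probs <- function(p, n_intervals = 5L) {
  if (any(p < 0 | p > 1)) stop("p must lie in [0, 1]", call. = FALSE)
  J <- as.integer(n_intervals)
  q <- 1 - p
  pim <- outer(p, seq_len(J), function(pp, j) pp * (1 - pp)^(j - 1))
  miss <- q^J
  if (length(p) == 1L) pim <- drop(pim)
  list(pi = pim, miss = miss)
}

#' Model specification for the time-removal abundance model
#'
#' Names the abundance and detection covariates (columns of the count
#' table; factors such as `observer_id` expand to reference-coded dummies),
#' the survey-area offset, and the interval count. In the motivating system
#' the Willow Ptarmigan abundance submodel used tundra, tussock, tall shrub
#' and elevation, and the Rock Ptarmigan / Arctic ground squirrel submodels
#' used tundra, low shrub, sparse vegetation and elevation; detection
#' submodels used ordinal date, time of day, wind speed and observer.
#'
#' @param abundance character vector of abundance covariates (may be empty
#'   for an intercept-only model).
#' @param detection character vector of detection covariates.
#' @param offset_area area sampled by one count, km^2 (default 0.5024, the
#'   published 400-m radius constant).
#' @param n_intervals removal intervals (default 5).
#' @return object of class `removal_spec`.
#' @export
removal_spec <- function(abundance = character(),
                         detection = character(),
                         offset_area = 0.5024,
                         n_intervals = 5L) {
  stopifnot(offset_area > 0, n_intervals >= 1)
  structure(list(abundance = abundance, detection = detection,
                 offset_area = offset_area,
                 n_intervals = as.integer(n_intervals)),
            class = "removal_spec")
}

# Assemble y, X, W from a removal_counts table and a spec.
removal_design <- function(data, spec) {
  J <- spec$n_intervals
  ycols <- paste0("count_", seq_len(J))
  if (!all(ycols %in% names(data)))
    stop("count columns ", paste(setdiff(ycols, names(data)), collapse = ", "),
         " missing", call. = FALSE)
  y <- as.matrix(data[, ycols])
  if (any(y < 0) || any(y != round(y)))
    stop("counts must be non-negative integers", call. = FALSE)
  storage.mode(y) <- "double"
  X <- build_design(data, spec$abundance)
  W <- build_design(data, spec$detection)
  list(y = y, X = X, W = W, off = log(spec$offset_area), J = J)
}

#' Multinomial-Poisson factorized log-likelihood
#'
#' The production likelihood of the Poisson N-mixture time-removal model.
#' With Poisson latent abundance the interval counts are independent
#' Poisson, `y_ij ~ Poisson(lambda_i pi_ij)` with
#' `log(lambda_i) = beta' x_i + log(A)` and
#' `pi_ij = p_i (1 - p_i)^(j-1)`, `logit(p_i) = alpha' w_i` — the
#' multinomial-Poisson factorization that removes the latent sum entirely.
#'
#' @param params coefficient vector `c(beta, alpha)` ordered as the design
#'   columns of the abundance then detection submodel.
#' @param data a `removal_counts` data frame (see
#'   [simulate_point_counts()] for the column layout).
#' @param spec a [removal_spec()].
#' @return scalar log-likelihood.
#' @seealso [loglik_nmix_truncated()] for the explicit latent-abundance
#'   form used as a cross-check.
#' @export
loglik_mpn <- function(params, data, spec) {
  d <- removal_design(data, spec)
  mpn_loglik(params, d)
}

# internal fast path on a prebuilt design list
mpn_loglik <- function(params, d) {
  nb <- ncol(d$X)
  beta <- params[seq_len(nb)]
  alpha <- params[-seq_len(nb)]
  lam <- exp(drop(d$X %*% beta) + d$off)
  p <- plogis(drop(d$W %*% alpha))
  mu <- lam * removal_cell_probs(p, d$J)$pi
  if (length(p) == 1L) mu <- matrix(mu, 1L)
  sum(dpois(d$y, mu, log = TRUE))
}

# Analytic gradient of mpn_loglik in c(beta, alpha). Derivation: with
# ytot_i = sum_j y_ij and r_i = sum_j (j-1) y_ij,
#   d l / d eta_lam,i = ytot_i - lam_i (1 - q_i^J),        q = 1 - p
#   d l / d eta_p,i   = ytot_i (1 - p_i) - r_i p_i - lam_i J p_i q_i^J
# both exact for p in (0,1) and continuous at the boundaries.
mpn_grad <- function(params, d) {
  nb <- ncol(d$X)
  beta <- params[seq_len(nb)]
  alpha <- params[-seq_len(nb)]
  lam <- exp(drop(d$X %*% beta) + d$off)
  p <- plogis(drop(d$W %*% alpha))
  q <- 1 - p
  J <- d$J
  ytot <- rowSums(d$y)
  r <- drop(d$y %*% (seq_len(J) - 1))
  gl <- ytot - lam * (1 - q^J)
  gp <- ytot * q - r * p - lam * J * p * q^J
  c(drop(crossprod(d$X, gl)), drop(crossprod(d$W, gp)))
}

#' Truncated latent-abundance log-likelihood (oracle form)
#'
#' The explicit N-mixture form: per site, a sum over latent abundance
#' `N = ytot..K` of `Poisson(N; lambda) * Multinomial(y, N - ytot miss)`.
#' Converges to [loglik_mpn()] as `K` grows (the factorization identity);
#' it is retained as an independent cross-check of the production
#' likelihood, not as a fitting path.
#'
#' @inheritParams loglik_mpn
#' @param K truncation bound for the latent sum; must be at least the
#'   largest observed site total.
#' @return scalar log-likelihood.
#' @export
loglik_nmix_truncated <- function(params, data, spec, K = 100L) {
  d <- removal_design(data, spec)
  nb <- ncol(d$X)
  beta <- params[seq_len(nb)]
  alpha <- params[-seq_len(nb)]
  lam <- exp(drop(d$X %*% beta) + d$off)
  p <- plogis(drop(d$W %*% alpha))
  cells <- removal_cell_probs(p, d$J)
  pim <- cells$pi
  if (length(p) == 1L) pim <- matrix(pim, 1L)
  ytot <- rowSums(d$y)
  if (any(ytot > K)) stop("K below an observed site total", call. = FALSE)
  ll <- 0
  for (i in seq_len(nrow(d$y))) {
    yi <- d$y[i, ]
    Ns <- seq.int(ytot[i], K)
    # log multinomial mass of (y_i, N - ytot) over cells (pi, miss)
    lpi <- log_safe(pim[i, ])
    yterm <- sum(ifelse(yi > 0, yi * lpi, 0))          # 0 * log(0) := 0
    n0 <- Ns - ytot[i]
    mterm <- ifelse(n0 > 0, n0 * log_safe(cells$miss[i]), 0)
    lmult <- lgamma(Ns + 1) - sum(lgamma(yi + 1)) - lgamma(n0 + 1) +
      yterm + mterm
    ll <- ll + logsumexp(dpois(Ns, lam[i], log = TRUE) + lmult)
  }
  ll
}

log_safe <- function(x) ifelse(x > 0, log(x), ifelse(x == 0, -Inf, NaN))

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}
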
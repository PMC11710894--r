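#' Fit the time-removal abundance model by maximum likelihood
#'
#' Maximizes the multinomial-Poisson factorized likelihood ([loglik_mpn()])
#' by quasi-Newton (BFGS with the analytic gradient) from a moment-based
#' null start plus optional random restarts, then polishes with Newton
#' steps on the numeric Hessian until the gradient norm is below `1e-6`.
#' The coefficient covariance is the inverse of the numerically
#' differentiated Hessian at the optimum; if that Hessian is not positive
#' definite the covariance is flagged unavailable and the coefficients are
#' returned with a warning status rather than silently.
#'
#' Covariates are expected already standardized (see [standardize()]); pass
#' the fitted scaler so that predictions standardize new layers with the
#' training statistics.
#'
#' @param data a `removal_counts` data frame.
#' @param spec a [removal_spec()].
#' @param start optional full start vector `c(beta, alpha)`.
#' @param scaler optional `gyr_scaler` used on the covariates; stored for
#'   prediction.
#' @param n_restarts extra random restarts around the null start (default
#'   2; the best optimum is kept).
#' @param control list: `grad_tol` (default 1e-6), `maxit` (500).
#' @return object of class `removal_fit`: `beta`, `alpha`, `coefficients`,
#'   `vcov`, `logLik`, `converged`, `grad_norm`, `hessian_pd`, `scaler`,
#'   `ranges` (training min/max of each abundance covariate, raw scale if a
#'   scaler is stored), `spec`, `data`.
#' @export
fit_removal <- function(data, spec, start = NULL, scaler = NULL,
                        n_restarts = 2L, control = list()) {
  d <- removal_design(data, spec)
  grad_tol <- control$grad_tol %||% 1e-6
  maxit <- control$maxit %||% 500L
  nb <- ncol(d$X); na <- ncol(d$W)
  npar <- nb + na

  nll <- function(par) {
    v <- -mpn_loglik(par, d)
    if (!is.finite(v)) v <- 1e10
    v
  }
  ngr <- function(par) -mpn_grad(par, d)

  ybar <- mean(rowSums(d$y))
  s0 <- numeric(npar)
  s0[1] <- log(max(ybar, 0.05)) - d$off   # null: lambda from mean count, p = 0.5
  starts <- list(s0)
  if (!is.null(start)) starts <- c(list(start), starts)
  if (n_restarts > 0)
    for (k in seq_len(n_restarts))
      starts <- c(starts, list(s0 + rnorm(npar, 0, 0.25)))

  best <- NULL
  for (st in starts) {
    o <- try(optim(st, nll, ngr, method = "BFGS",
                   control = list(maxit = maxit, reltol = 1e-12)),
             silent = TRUE)
    if (inherits(o, "try-error")) next
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (is.null(best)) stop("optimization failed from every start", call. = FALSE)

  # Newton polish on the numeric Hessian
  par <- best$par
  H <- NULL
  for (k in 1:8) {
    g <- ngr(par)
    if (max(abs(g)) < grad_tol) break
    H <- num_hessian(nll, par)
    step <- try(solve(H, g), silent = TRUE)
    if (inherits(step, "try-error")) break
    cand <- par - step
    if (nll(cand) <= nll(par) + 1e-10) par <- cand else break
  }
  g <- ngr(par)
  H <- num_hessian(nll, par)
  pd <- is_pd(H)
  vc <- if (pd) chol2inv(chol(H)) else matrix(NA_real_, npar, npar)

  cn <- c(colnames(d$X), colnames(d$W))
  names(par) <- cn
  dimnames(vc) <- list(cn, cn)
  boundary <- par[1] < log(1e-6) - d$off   # all-zero data pushes lambda to 0

  ranges <- lapply(spec$abundance, function(nm) range(data[[nm]]))
  names(ranges) <- spec$abundance
  if (!is.null(scaler)) {
    for (nm in intersect(spec$abundance, names(scaler$mean))) {
      r <- ranges[[nm]] * scaler$divisor * scaler$sd[[nm]] + scaler$mean[[nm]]
      ranges[[nm]] <- r
    }
  }

  fit <- structure(list(
    beta = par[seq_len(nb)], alpha = par[-seq_len(nb)],
    coefficients = par, vcov = vc,
    logLik = -nll(par),
    converged = max(abs(g)) < max(grad_tol, 1e-5) && pd && !boundary,
    grad_norm = max(abs(g)), hessian_pd = pd, boundary = boundary,
    scaler = scaler, ranges = ranges, spec = spec, data = data,
    n_sites = nrow(d$y)), class = "removal_fit")
  if (!pd)
    warning("Hessian not positive definite; covariance unavailable",
            call. = FALSE)
  if (boundary)
    warning("abundance intercept at the zero-density boundary", call. = FALSE)
  fit
}

num_hessian <- function(f, par, h = 1e-4) {
  n <- length(par)
  H <- matrix(0, n, n)
  hs <- h * pmax(1, abs(par))
  f0 <- f(par)
  for (i in seq_len(n)) for (j in i:n) {
    pp <- par; pp[i] <- pp[i] + hs[i]; pp[j] <- pp[j] + hs[j]
    pm <- par; pm[i] <- pm[i] + hs[i]; pm[j] <- pm[j] - hs[j]
    mp <- par; mp[i] <- mp[i] - hs[i]; mp[j] <- mp[j] + hs[j]
    mm <- par; mm[i] <- mm[i] - hs[i]; mm[j] <- mm[j] - hs[j]
    H[i, j] <- H[j, i] <- (f(pp) - f(pm) - f(mp) + f(mm)) / (4 * hs[i] * hs[j])
  }
  H
}

is_pd <- function(H) {
  if (anyNA(H)) return(FALSE)
  !inherits(try(chol(H), silent = TRUE), "try-error")
}

#' Coefficient table with Wald intervals
#'
#' Estimates, standard errors and `level` Wald confidence intervals on the
#' link scale (log for abundance, logit for detection). A predictor is
#' flagged significant when its interval excludes zero, the criterion used
#' throughout the analysis.
#'
#' @param fit a `removal_fit` (or an `occu_fit`).
#' @param level confidence level (default 0.95).
#' @return data frame: `term`, `submodel`, `estimate`, `se`, `lower`,
#'   `upper`, `significant`.
#' @export
coefficient_table <- function(fit, level = 0.95) {
  UseMethod("coefficient_table")
}

#' @export
coefficient_table.removal_fit <- function(fit, level = 0.95) {
  wald_table(fit$coefficients, fit$vcov,
             submodel = rep(c("abundance", "detection"),
                            c(length(fit$beta), length(fit$alpha))),
             level = level)
}

wald_table <- function(est, vc, submodel, level) {
  se <- sqrt(diag(vc))
  z <- qnorm(1 - (1 - level) / 2)
  lo <- est - z * se
  hi <- est + z * se
  data.frame(term = names(est), submodel = submodel,
             estimate = unname(est), se = unname(se),
             lower = unname(lo), upper = unname(hi),
             significant = unname(lo > 0 | hi < 0),
             row.names = NULL)
}

#' Marginal-effect curve for one predictor
#'
#' Partial relationship between one predictor and the response with every
#' other predictor held at its training mean (factors at the reference
#' level). For abundance predictors the response is the expected density
#' per km^2, `exp(beta' x)`; for detection predictors it is the
#' per-interval detection probability. The 95% band comes from the delta
#' method on the link scale (default) or from multivariate-normal
#' coefficient draws.
#'
#' @param fit a `removal_fit`.
#' @param predictor name of a model covariate.
#' @param values grid of predictor values (default: 50 points over the
#'   training range).
#' @param method `"delta"` or `"mvn"`.
#' @param draws MVN draws when `method = "mvn"`.
#' @param level band level.
#' @param seed seed for the MVN draws.
#' @return data frame: `value`, `fit`, `lower`, `upper` (response scale).
#' @export
marginal_effect <- function(fit, predictor, values = NULL,
                            method = c("delta", "mvn"), draws = 10000L,
                            level = 0.95, seed = 1L) {
  method <- match.arg(method)
  spec <- fit$spec
  in_ab <- predictor %in% spec$abundance
  in_det <- predictor %in% spec$detection
  if (!in_ab && !in_det) stop("unknown predictor: ", predictor, call. = FALSE)
  terms <- if (in_ab) spec$abundance else spec$detection
  est <- if (in_ab) fit$beta else fit$alpha
  idx <- if (in_ab) seq_along(fit$beta) else
    length(fit$beta) + seq_along(fit$alpha)
  vc <- fit$vcov[idx, idx, drop = FALSE]

  if (is.null(values)) {
    r <- range(fit$data[[predictor]])
    values <- seq(r[1], r[2], length.out = 50L)
  }
  base <- fit$data[rep(1L, length(values)), terms, drop = FALSE]
  for (nm in terms) {
    col <- fit$data[[nm]]
    base[[nm]] <- if (is.numeric(col)) mean(col) else
      factor(sort(unique(as.character(col)))[1],
             levels = sort(unique(as.character(col))))
  }
  base[[predictor]] <- values
  Xg <- build_design(base, terms)

  eta <- drop(Xg %*% est)
  link_inv <- if (in_ab) exp else plogis
  z <- qnorm(1 - (1 - level) / 2)
  if (method == "delta" || anyNA(vc)) {
    se <- sqrt(rowSums((Xg %*% vc) * Xg))
    out <- data.frame(value = values, fit = link_inv(eta),
                      lower = link_inv(eta - z * se),
                      upper = link_inv(eta + z * se))
  } else {
    set.seed(seed)
    bdraw <- mvn_draws(est, vc, draws)
    etas <- Xg %*% t(bdraw)
    qs <- apply(etas, 1, quantile, probs = c((1 - level) / 2,
                                             1 - (1 - level) / 2))
    out <- data.frame(value = values, fit = link_inv(eta),
                      lower = link_inv(qs[1, ]), upper = link_inv(qs[2, ]))
  }
  out
}

mvn_draws <- function(mu, Sigma, n) {
  L <- chol(Sigma)
  z <- matrix(rnorm(n * length(mu)), n)
  sweep(z %*% L, 2, mu, `+`)
}

#' @export
print.removal_fit <- function(x, ...) {
  cat("Time-removal N-mixture fit (multinomial-Poisson likelihood)\n")
  cat(sprintf("  sites: %d   intervals: %d   offset: %g km^2\n",
              x$n_sites, x$spec$n_intervals, x$spec$offset_area))
  cat(sprintf("  logLik: %.3f   converged: %s (|grad| = %.2e)\n",
              x$logLik, x$converged, x$grad_norm))
  print(coefficient_table(x), digits = 3)
  invisible(x)
}
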
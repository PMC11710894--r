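# Joint penalized log-likelihood machinery for the stacked occupancy model.
#
# Unit (territory i, year t): psi_it = plogis(a_i + u_t), a = Xocc %*% gamma,
# u_t ~ N(0, sy^2). Record r (a completed survey of unit(r)):
# p_r = plogis(W_r delta + v_i(r)), v_i ~ N(0, sv^2). Unit likelihood
# L = psi B + (1 - psi) I0 with B the Bernoulli product over the unit's
# records and I0 the all-zero indicator. The random-effect vector (u, v) is
# integrated by a joint Laplace approximation: Newton on the penalized joint
# log-likelihood with the (T + M) Hessian solved through its year-block
# Schur complement (the cross block couples every co-surveyed year x
# territory pair), then the log-determinant correction through the same
# factorization. Everything is O(#records) per evaluation.

# grouped sums on the layout occu_data guarantees: records contiguous by
# unit, units contiguous by territory, years via a dense indicator
agg_rec <- function(od, x) {
  s <- cumsum(x)[od$rec_end]
  c(s[1], diff(s))
}
agg_i <- function(od, x) {
  s <- cumsum(x)[od$terr_end]
  out <- numeric(od$M)
  out[od$terr_present] <- c(s[1], diff(s))
  out
}
agg_t <- function(od, x) drop(crossprod(od$Tind, x))

# Per-unit derivative bundle at (u, v): linear predictors assembled here,
# link evaluations and record -> unit reductions in the compiled kernel.
occu_unit_terms <- function(gamma, delta, u, v, od) {
  a <- drop(od$Xocc %*% gamma)              # per territory
  eta_psi <- a[od$unit_i] + u[od$unit_t]
  zeta <- drop(od$W %*% delta) + v[od$rec_i]
  .occu_terms_cpp(eta_psi, zeta, od$y, od$rec_end, od$allzero)
}

# pure-R reference implementation of the same bundle (kept as the oracle
# the compiled kernel is tested against)
occu_unit_terms_ref <- function(gamma, delta, u, v, od) {
  a <- drop(od$Xocc %*% gamma)              # per territory
  eta_psi <- a[od$unit_i] + u[od$unit_t]
  zeta <- drop(od$W %*% delta) + v[od$rec_i]
  lp <- plogis(zeta, log.p = TRUE)          # log p
  lq <- lp - zeta                           # log(1 - p) identity
  p <- exp(lp)

  logB <- agg_rec(od, od$y * lp + (1 - od$y) * lq)
  s <- agg_rec(od, od$y - p)
  q <- agg_rec(od, p * (1 - p))

  lpsi <- plogis(eta_psi, log.p = TRUE)
  l1mpsi <- lpsi - eta_psi
  psi <- exp(lpsi)
  t1 <- lpsi + logB
  logL <- t1
  R1 <- rep.int(1, od$U)                    # psi B / L
  az <- od$allzero == 1
  if (any(az)) {
    m <- pmax(t1[az], l1mpsi[az])
    logL[az] <- m + log1p(exp(-abs(t1[az] - l1mpsi[az])))
    R1[az] <- exp(t1[az] - logL[az])
  }

  gu <- (1 - psi) * R1 - psi * (1 - R1)     # d logL / d u
  gv <- R1 * s                              # d logL / d v
  huu <- (1 - 2 * psi) * gu - gu^2
  hvv <- R1 * (s^2 - q) - gv^2
  huv <- (1 - psi) * R1 * s - gu * gv
  list(logL = logL, gu = gu, gv = gv, huu = huu, hvv = hvv, huv = huv,
       psi = psi, p = p)
}

# likelihood-only evaluation (used in line searches; no derivative work)
occu_unit_logL <- function(gamma, delta, u, v, od) {
  a <- drop(od$Xocc %*% gamma)
  eta_psi <- a[od$unit_i] + u[od$unit_t]
  zeta <- drop(od$W %*% delta) + v[od$rec_i]
  .occu_logL_cpp(eta_psi, zeta, od$y, od$rec_end, od$allzero)
}

occu_joint_loglik <- function(gamma, delta, u, v, od)
  sum(occu_unit_logL(gamma, delta, u, v, od))

# Penalized joint log-likelihood g(u, v); active factors contribute their
# Gaussian penalty and normalization.
occu_penalized <- function(gamma, delta, u, v, sy, sv, od) {
  g <- occu_joint_loglik(gamma, delta, u, v, od)
  if (sy > 0)
    g <- g - sum(u^2) / (2 * sy^2) - od$T * (log(sy) + 0.5 * log(2 * pi))
  if (sv > 0)
    g <- g - sum(v^2) / (2 * sv^2) - od$M * (log(sv) + 0.5 * log(2 * pi))
  g
}

# Marginal log-likelihood. sy/sv equal to zero switch the corresponding
# factor off exactly (its random effects pinned at 0), so the sigma -> 0
# reduction is exact rather than a limit. With a single active factor the
# integral factorizes by group and is evaluated by adaptive Gauss-Hermite
# quadrature centred and scaled at the penalized mode (n_nodes nodes);
# the crossed two-factor case uses the joint Laplace approximation (its
# random effects do not factorize).
occu_laplace <- function(gamma, delta, sy, sv, od,
                         start = NULL, tol = 1e-9, maxit = 60L,
                         n_nodes = 21L, act_tol = 2e-3) {
  Tn <- od$T; M <- od$M
  u <- start$u %||% numeric(Tn)
  v <- start$v %||% numeric(M)
  # a standard deviation at or below act_tol is treated as exactly zero:
  # its random effects are pinned and, if the other factor is active, the
  # likelihood falls back to the (near-exact) single-factor quadrature
  act_u <- sy > act_tol; act_v <- sv > act_tol
  if (!act_u) sy <- 0
  if (!act_v) sv <- 0

  if (!act_u) u <- numeric(Tn)
  if (!act_v) v <- numeric(M)

  if (!act_u && !act_v)
    return(list(ll = occu_joint_loglik(gamma, delta, u, v, od),
                u = u, v = v, converged = TRUE))

  pen <- function(u, v) {
    g <- 0
    if (act_u) g <- g - sum(u^2) / (2 * sy^2) -
        od$T * (log(sy) + 0.5 * log(2 * pi))
    if (act_v) g <- g - sum(v^2) / (2 * sv^2) -
        od$M * (log(sv) + 0.5 * log(2 * pi))
    g
  }
  terms <- occu_unit_terms(gamma, delta, u, v, od)
  g_cur <- sum(terms$logL) + pen(u, v)
  converged <- FALSE
  for (it in seq_len(maxit)) {
    grad_u <- if (act_u) agg_t(od, terms$gu) - u / sy^2 else NULL
    grad_v <- if (act_v) agg_i(od, terms$gv) - v / sv^2 else NULL
    gmax <- max(abs(c(grad_u, grad_v)))
    if (gmax < tol) { converged <- TRUE; break }

    A <- if (act_u) -agg_t(od, terms$huu) + 1 / sy^2 else NULL
    D <- if (act_v) -agg_i(od, terms$hvv) + 1 / sv^2 else NULL

    ridge <- 0
    repeat {
      st <- occu_newton_step(grad_u, grad_v, A, D, terms, od, sy, sv,
                             ridge, act_u, act_v)
      if (!is.null(st)) break
      ridge <- if (ridge == 0) 1e-4 else ridge * 10
      if (ridge > 1e6) break
    }
    if (is.null(st)) break
    step <- 1
    improved <- FALSE
    for (ls in 1:25) {
      u_new <- if (act_u) u + step * st$du else u
      v_new <- if (act_v) v + step * st$dv else v
      terms_new <- occu_unit_terms(gamma, delta, u_new, v_new, od)
      g_new <- sum(terms_new$logL) + pen(u_new, v_new)
      if (is.finite(g_new) && g_new >= g_cur - 1e-12) {
        u <- u_new; v <- v_new; g_cur <- g_new
        terms <- terms_new; improved <- TRUE
        break
      }
      step <- step / 2
    }
    if (!improved) break
  }
  # `terms` already holds the derivative bundle at the mode
  ld <- 0; dim_re <- 0
  if (act_u && act_v) {
    A <- -agg_t(od, terms$huu) + 1 / sy^2
    D <- -agg_i(od, terms$hvv) + 1 / sv^2
    C <- cross_block(terms, od)
    S <- diag(A, Tn) - C %*% (t(C) / D)
    cS <- try(chol(S), silent = TRUE)
    if (inherits(cS, "try-error") || any(D <= 0))
      return(list(ll = NA_real_, u = u, v = v, converged = FALSE))
    ld <- sum(log(D)) + 2 * sum(log(diag(cS)))
    dim_re <- Tn + M
  } else if (act_u) {
    A <- -agg_t(od, terms$huu) + 1 / sy^2
    if (any(A <= 0)) return(list(ll = NA_real_, u = u, v = v,
                                 converged = FALSE))
    ll <- occu_aghq(gamma, delta, sy, sv, od, mode = u,
                    curv = A, factor = "u", n_nodes = n_nodes)
    return(list(ll = ll, u = u, v = v, converged = converged))
  } else {
    D <- -agg_i(od, terms$hvv) + 1 / sv^2
    if (any(D <= 0)) return(list(ll = NA_real_, u = u, v = v,
                                 converged = FALSE))
    ll <- occu_aghq(gamma, delta, sy, sv, od, mode = v,
                    curv = D, factor = "v", n_nodes = n_nodes)
    return(list(ll = ll, u = u, v = v, converged = converged))
  }
  ll <- g_cur + 0.5 * dim_re * log(2 * pi) - 0.5 * ld
  list(ll = ll, u = u, v = v, converged = converged)

}

# Adaptive Gauss-Hermite for a single random factor: per group j,
# log I_j = log sum_k w_k exp(x_k^2) f_j(m_j + sqrt(2) s_j x_k)
#           + log(sqrt(2) s_j),
# with f_j = exp(sum of the group's unit log-likelihoods) * N(x; 0, sigma)
# and s_j = curvature^{-1/2} at the penalized mode m_j.
occu_aghq <- function(gamma, delta, sy, sv, od, mode, curv, factor,
                      n_nodes) {
  gh <- gauss_hermite(n_nodes)
  s <- 1 / sqrt(curv)
  K <- n_nodes
  a <- drop(od$Xocc %*% gamma)
  eta_base <- a[od$unit_i]
  zeta_base <- drop(od$W %*% delta)
  shifts <- mode + sqrt(2) * outer(s, gh$x)        # groups x K

  h <- if (factor == "u") {
    .occu_aghq_u_cpp(eta_base, zeta_base, od$y, od$rec_end, od$allzero,
                     od$unit_t, shifts, od$T)
  } else {
    .occu_aghq_v_cpp(eta_base, zeta_base, od$y, od$rec_end, od$allzero,
                     od$rec_i, od$unit_i, shifts, od$M)
  }
  sigma <- if (factor == "u") sy else sv
  logf <- h + dnorm(shifts, 0, sigma, log = TRUE)
  lw <- sweep(logf, 2, log(gh$w) + gh$x^2, `+`)
  mx <- apply(lw, 1, max)
  logI <- mx + log(rowSums(exp(lw - mx))) + log(sqrt(2) * s)
  sum(logI)
}

# Gauss-Hermite nodes/weights (physicists' convention, weight e^{-x^2})
# by Golub-Welsch on the symmetric Jacobi matrix.
gh_cache <- new.env(parent = emptyenv())

gauss_hermite <- function(n) {
  key <- as.character(n)
  if (!is.null(gh_cache[[key]])) return(gh_cache[[key]])
  if (n == 1L) return(list(x = 0, w = sqrt(pi)))
  b <- sqrt(seq_len(n - 1) / 2)
  Jm <- diag(0, n)
  Jm[cbind(seq_len(n - 1), seq_len(n - 1) + 1L)] <- b
  Jm[cbind(seq_len(n - 1) + 1L, seq_len(n - 1))] <- b
  e <- eigen(Jm, symmetric = TRUE)
  idx <- order(e$values)
  out <- list(x = e$values[idx], w = sqrt(pi) * (e$vectors[1, idx])^2)
  gh_cache[[key]] <- out
  out
}

# T x M cross block of the negative Hessian: entry (t, i) is -huv of unit
# (i, t); zero where the unit was never surveyed.
cross_block <- function(terms, od) {
  C <- matrix(0, od$T, od$M)
  C[cbind(od$unit_t, od$unit_i)] <- -terms$huv
  C
}

# Solve [[A, C], [C', D]] (du, dv) = (grad_u, grad_v) by the Schur
# complement on the (small) year block. Returns NULL when not positive
# definite at the requested ridge.
occu_newton_step <- function(grad_u, grad_v, A, D, terms, od, sy, sv,
                             ridge, act_u, act_v) {
  if (act_u && act_v) {
    A <- A + ridge; D <- D + ridge
    if (any(D <= 0)) return(NULL)
    C <- cross_block(terms, od)
    S <- diag(A, od$T) - C %*% (t(C) / D)
    cS <- try(chol(S), silent = TRUE)
    if (inherits(cS, "try-error")) return(NULL)
    w <- grad_v / D
    du <- backsolve(cS, forwardsolve(t(cS), grad_u - drop(C %*% w)))
    dv <- (grad_v - drop(crossprod(C, du))) / D
    list(du = du, dv = dv)
  } else if (act_u) {
    A <- A + ridge
    if (any(A <= 0)) return(NULL)
    list(du = grad_u / A, dv = NULL)
  } else {
    D <- D + ridge
    if (any(D <= 0)) return(NULL)
    list(du = NULL, dv = grad_v / D)
  }
}

#' Marginal log-likelihood of the stacked occupancy model
#'
#' Integrates the year random intercept on occupancy and the territory
#' random intercept on detection out of the product of territory-year
#' likelihoods: by joint Laplace approximation when both effects are
#' active (they cross, so the integral does not factorize), and by
#' adaptive Gauss-Hermite quadrature per group when only one is. A
#' variance given as exactly zero switches that random effect off, making
#' the reduction to the fixed-effect likelihood exact.
#'
#' @param params list with `gamma` (occupancy coefficients, intercept
#'   first), `delta` (detection coefficients), `sigma_year`,
#'   `sigma_territory`.
#' @param data an [occu_data()] object.
#' @return scalar log-likelihood (NA if the inner optimization failed).
#' @export
marginal_loglik <- function(params, data) {
  res <- occu_laplace(params$gamma, params$delta,
                      params$sigma_year, params$sigma_territory, data)
  res$ll
}
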
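#' MacKenzie-Bailey goodness of fit for the occupancy model
#'
#' Tallies the observed detection histories against their model
#' expectations and calibrates the Pearson statistic by parametric
#' bootstrap. Territory-years are grouped into cohorts by their
#' missingness pattern (which survey slots were completed); within a
#' cohort every distinct history is a tally cell, and its expected count is
#' the sum over the cohort's units of the history probability at the
#' fitted, unit-level `psi` and `p` (random effects at their Laplace
#' modes). Cells with expected count below `pool_threshold` are pooled into
#' one cell per cohort (policy recorded). `B` replicate datasets are
#' simulated from the fitted model — fresh random effects drawn from the
#' estimated variances, same missingness layout — each refitted from the
#' original optimum, and the replicate statistics collected; `p` is the
#' fraction of replicates at least as large as the observed statistic and
#' `c_hat` the observed over the replicate mean.
#'
#' @param fit an `occu_fit`.
#' @param B bootstrap replicates (default 200).
#' @param seed integer seed.
#' @param pool_threshold pool tally cells with expected count below this
#'   (default 2).
#' @return object of class `occu_gof`: `chisq_obs`, `chisq_boot`,
#'   `p_value`, `c_hat`, `B`, `seed`, `policy`, `n_failed`.
#' @export
mb_gof <- function(fit, B = 200L, seed = 1L, pool_threshold = 2) {
  od <- fit$data
  chisq_obs <- mb_chisq(fit, od, pool_threshold)
  set.seed(seed)
  boot <- rep(NA_real_, B)
  n_failed <- 0L
  for (b in seq_len(B)) {
    odb <- simulate_occu_replicate(fit, od)
    fb <- try(suppressWarnings(
      fit_occupancy(data = odb,
                    start = list(gamma = fit$gamma, delta = fit$delta,
                                 log_sigma = log(pmax(c(fit$sigma_year,
                                                        fit$sigma_territory),
                                                      1e-3))),
                    control = list(iter.max = 150L, rel.tol = 1e-8))),
      silent = TRUE)
    if (inherits(fb, "try-error")) { n_failed <- n_failed + 1L; next }
    boot[b] <- mb_chisq(fb, odb, pool_threshold)
  }
  boot <- boot[!is.na(boot)]
  if (!length(boot)) stop("all bootstrap refits failed", call. = FALSE)
  structure(list(chisq_obs = chisq_obs, chisq_boot = boot,
                 p_value = mean(boot >= chisq_obs),
                 c_hat = chisq_obs / mean(boot),
                 B = B, seed = seed,
                 policy = sprintf(
                   "missingness-pattern cohorts; cells with expected < %g pooled",
                   pool_threshold),
                 n_failed = n_failed), class = "occu_gof")
}

# Pearson statistic on cohort x history tallies at the fit's conditional
# psi/p.
mb_chisq <- function(fit, od, pool_threshold) {
  terms <- occu_unit_terms(fit$gamma, fit$delta, fit$u, fit$v, od)
  psi <- terms$psi
  p <- terms$p

  # per-unit observed history over its completed slots and slot p's
  hist_key <- vapply(seq_len(od$U), function(u) {
    idx <- which(od$unit_of_record == u)
    paste0(od$y[idx], collapse = "")
  }, character(1))
  pattern <- vapply(seq_len(od$U), function(u)
    length(which(od$unit_of_record == u)), integer(1))
  # possible histories per unit given its number of completed surveys, and
  # their probabilities
  chisq <- 0
  for (pat in sort(unique(pattern))) {
    units <- which(pattern == pat)
    hs <- binary_histories(pat)
    E <- numeric(nrow(hs))
    for (j in seq_len(nrow(hs))) {
      h <- hs[j, ]
      prob <- vapply(units, function(u) {
        idx <- which(od$unit_of_record == u)
        occupancy_cell_lik(psi[u], p[idx], h)
      }, numeric(1))
      E[j] <- sum(prob)
    }
    keys <- apply(hs, 1, paste0, collapse = "")
    O <- as.numeric(table(factor(hist_key[units], levels = keys)))
    low <- E < pool_threshold
    if (any(low) && sum(low) > 1) {
      E <- c(E[!low], sum(E[low]))
      O <- c(O[!low], sum(O[low]))
    }
    keep <- E > 0
    chisq <- chisq + sum((O[keep] - E[keep])^2 / E[keep])
  }
  chisq
}

binary_histories <- function(n) {
  as.matrix(expand.grid(rep(list(c(0, 1)), n)))
}

# Simulate a replicate occu_data from the fitted model: fresh random
# effects at the estimated variances, same designs and missingness layout.
simulate_occu_replicate <- function(fit, od) {
  u <- rnorm(od$T, 0, fit$sigma_year)
  v <- rnorm(od$M, 0, fit$sigma_territory)
  a <- drop(od$Xocc %*% fit$gamma)
  psi <- plogis(a[od$unit_i] + u[od$unit_t])
  z <- rbinom(od$U, 1, psi)
  p <- plogis(drop(od$W %*% fit$delta) + v[od$rec_i])
  y <- rbinom(length(od$y), 1, z[od$unit_of_record] * p)
  odb <- od
  odb$y <- as.numeric(y)
  odb$allzero <- as.numeric(sum_by(odb$y, od$unit_of_record, od$U) == 0)
  odb
}

#' @export
print.occu_gof <- function(x, ...) {
  cat(sprintf("MacKenzie-Bailey GOF (B = %d, seed = %d)\n", x$B, x$seed))
  cat(sprintf("  Pearson chi-sq = %.2f, p = %.3f, c-hat = %.3f\n",
              x$chisq_obs, x$p_value, x$c_hat))
  cat("  policy:", x$policy, "\n")
  if (x$n_failed > 0) cat("  failed refits dropped:", x$n_failed, "\n")
  invisible(x)
}
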
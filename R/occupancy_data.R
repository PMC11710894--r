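#' Assemble stacked occupancy data
#'
#' Joins a detection-history table (one row per territory x year x survey,
#' `detected` in {0, 1, NA}) with a territory covariate table (typically
#' per-km^2 prey densities, constant across years) into the indexed form
#' the likelihood works on. Each territory-year is one occupancy unit;
#' missing surveys are skipped, and territory-years with no completed
#' survey are dropped with a message (they carry no information).
#'
#' @param histories data frame: `territory_id`, `year`, `survey_index`,
#'   `detected` (0/1/NA), plus any detection covariates (e.g.
#'   `day_of_year`).
#' @param densities data frame: `territory_id` plus the occupancy
#'   covariates. Covariates are used as supplied — standardize first (see
#'   [standardize()]) to fit on the 2-SD scale.
#' @param occ_covs names of occupancy covariate columns in `densities`.
#' @param det_covs names of detection covariate columns in `histories`.
#' @return object of class `occu_data` (a list of index vectors and design
#'   matrices; see fields in the source).
#' @export
occu_data <- function(histories, densities,
                      occ_covs = c("willow", "rock", "ags"),
                      det_covs = "day_of_year") {
  h <- as.data.frame(histories)
  d <- as.data.frame(densities)
  stopifnot(all(c("territory_id", "year", "survey_index", "detected")
                %in% names(h)))
  terr_ids <- sort(unique(d$territory_id))
  if (!all(h$territory_id %in% terr_ids))
    stop("histories contain territories absent from the density table",
         call. = FALSE)
  years <- sort(unique(h$year))
  M <- length(terr_ids); Tn <- length(years)

  d <- d[match(terr_ids, d$territory_id), , drop = FALSE]
  Xocc <- build_design(d, occ_covs)

  h$i <- match(h$territory_id, terr_ids)
  h$t <- match(h$year, years)
  h$unit_key <- (h$i - 1L) * Tn + h$t

  obs <- h[!is.na(h$detected), , drop = FALSE]
  if (any(!obs$detected %in% c(0, 1)))
    stop("detected must be 0, 1 or NA", call. = FALSE)
  unit_keys <- sort(unique(obs$unit_key))
  n_dropped <- length(setdiff(unique(h$unit_key), unit_keys))
  if (n_dropped > 0)
    message(n_dropped, " territory-year(s) with no completed survey dropped")

  unit_i <- ((unit_keys - 1L) %/% Tn) + 1L
  unit_t <- ((unit_keys - 1L) %% Tn) + 1L
  u_of_rec <- match(obs$unit_key, unit_keys)

  W <- build_design(obs, det_covs)
  y <- as.numeric(obs$detected)
  allzero <- as.numeric(sum_by(y, u_of_rec, length(unit_keys)) == 0)

  U <- length(unit_keys)

  # order records by unit so record -> unit sums are contiguous; units are
  # already grouped by territory (unit keys ascend in territory-major
  # order), which makes unit -> territory sums contiguous too. Years are
  # interleaved, so unit -> year sums go through a small dense indicator.
  ord <- order(u_of_rec)
  obs <- obs[ord, , drop = FALSE]
  W <- W[ord, , drop = FALSE]
  y <- y[ord]
  u_of_rec <- u_of_rec[ord]
  rec_end <- cumsum(tabulate(u_of_rec, nbins = U))
  terr_counts <- tabulate(unit_i, nbins = M)
  terr_present <- which(terr_counts > 0)
  terr_end <- cumsum(terr_counts[terr_present])
  Tind <- matrix(0, U, Tn)
  Tind[cbind(seq_len(U), unit_t)] <- 1

  structure(list(M = M, T = Tn, U = U,
                 rec_end = rec_end, terr_present = terr_present,
                 terr_end = terr_end, Tind = Tind,
                 territory_ids = terr_ids, years = years,
                 Xocc = Xocc, W = W, y = y,
                 unit_i = unit_i, unit_t = unit_t,
                 unit_of_record = u_of_rec,
                 rec_i = unit_i[u_of_rec],
                 allzero = allzero,
                 occ_covs = occ_covs, det_covs = det_covs,
                 histories = h, densities = d,
                 n_dropped = n_dropped),
            class = "occu_data")
}

sum_by <- function(x, idx, n) {
  out <- numeric(n)
  tmp <- rowsum(x, idx)
  out[as.integer(rownames(tmp))] <- tmp
  out
}

#' Likelihood of one territory-year detection history
#'
#' The single-unit occupancy likelihood with imperfect detection:
#' `L = psi * prod_j p_j^y_j (1-p_j)^(1-y_j) + (1 - psi) * I[all y_j = 0]`,
#' where missing surveys are skipped.
#'
#' @param psi occupancy probability.
#' @param p vector of per-survey detection probabilities (aligned with
#'   `history`).
#' @param history 0/1/NA vector of detections.
#' @return the probability of the history.
#' @export
#' @examples
#' occupancy_cell_lik(0.5, c(0.5, 0.5), c(0, 0))   # 0.625
occupancy_cell_lik <- function(psi, p, history) {
  keep <- !is.na(history)
  y <- history[keep]
  pk <- p[keep]
  if (length(y) == 0L) return(1)
  if (any(y == 1) && any(is.na(pk)))
    stop("detection recorded but p undefined", call. = FALSE)
  bern <- prod(pk^y * (1 - pk)^(1 - y))
  psi * bern + (1 - psi) * as.numeric(all(y == 0))
}
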
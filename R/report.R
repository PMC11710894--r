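#' Tally counts by year
#'
#' Per-year number of individuals counted and number of points with at
#' least one detection, plus a totals row — the standard summary table for
#' a removal count survey.
#'
#' @param counts a `removal_counts` data frame with a `year` column.
#' @param grouping grouping column (default `"year"`).
#' @return data frame: group, `individuals`, `points_detected`, with a
#'   final `"total"` row.
#' @export
summarize_counts <- function(counts, grouping = "year") {
  if (!grouping %in% names(counts))
    stop("grouping column '", grouping, "' missing", call. = FALSE)
  ycols <- grep("^count_", names(counts), value = TRUE)
  tot <- rowSums(counts[, ycols, drop = FALSE])
  if (nrow(counts) == 0L)
    return(data.frame(group = character(), individuals = numeric(),
                      points_detected = integer()))
  groups <- sort(unique(counts[[grouping]]))
  out <- data.frame(
    group = as.character(groups),
    individuals = vapply(groups, function(g)
      sum(tot[counts[[grouping]] == g]), numeric(1)),
    points_detected = vapply(groups, function(g)
      sum(tot[counts[[grouping]] == g] > 0), numeric(1)))
  rbind(out, data.frame(group = "total", individuals = sum(out$individuals),
                        points_detected = sum(out$points_detected)))
}

#' Share of sites closer than a threshold to a feature
#'
#' Count and percentage (one decimal) of sites whose distance to the
#' nearest feature (e.g. a road) is below a threshold.
#'
#' @param site_distances non-negative distances, one per site (m).
#' @param threshold_m distance threshold (default 200 m).
#' @return list: `n_below`, `n_total`, `percent` (rounded to 1 decimal).
#' @export
#' @examples
#' proximity_report(c(rep(100, 63), rep(500, 920)))  # 63 sites, 6.4%
proximity_report <- function(site_distances, threshold_m = 200) {
  if (any(site_distances < 0))
    stop("distances must be non-negative", call. = FALSE)
  n <- sum(site_distances < threshold_m)
  list(n_below = n, n_total = length(site_distances),
       percent = round(100 * n / length(site_distances), 1))
}
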
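#' Standardize covariates by two standard deviations
#'
#' Centres each numeric covariate on its mean and divides by twice its
#' sample standard deviation (n - 1 denominator), the convention that puts
#' continuous predictors on a scale comparable with binary ones. Factor and
#' character columns pass through untouched. When a fitted `scaler` is
#' supplied, its training means and SDs are applied; it is never refitted —
#' the contract that prediction-grid layers are standardized with the
#' statistics of the data the model was fitted to.
#'
#' @param x numeric vector, or data frame whose numeric columns are scaled.
#' @param scaler optional scaler from a previous call.
#' @param cols for data frames, which columns to scale (default: all
#'   numeric).
#' @return list with `values` (same shape as `x`) and `scaler` (class
#'   `gyr_scaler`: means, sds, divisor 2).
#' @export
#' @examples
#' standardize(c(0, 1, 2))$values   # -0.5, 0, 0.5
standardize <- function(x, scaler = NULL, cols = NULL) {
  if (is.data.frame(x)) {
    if (is.null(cols))
      cols <- names(x)[vapply(x, is.numeric, logical(1))]
    if (is.null(scaler)) {
      mu <- vapply(x[cols], mean, numeric(1))
      sdev <- vapply(x[cols], sd, numeric(1))
      bad <- cols[!is.finite(sdev) | sdev <= 0]
      if (length(bad))
        stop("degenerate covariate (zero variance): ",
             paste(bad, collapse = ", "), call. = FALSE)
      scaler <- new_scaler(mu, sdev)
    }
    for (nm in intersect(names(scaler$mean), names(x)))
      x[[nm]] <- (x[[nm]] - scaler$mean[[nm]]) /
        (scaler$divisor * scaler$sd[[nm]])
    return(list(values = x, scaler = scaler))
  }
  if (is.null(scaler)) {
    if (length(unique(x)) < 2L)
      stop("degenerate covariate (zero variance)", call. = FALSE)
    scaler <- new_scaler(c(x = mean(x)), c(x = sd(x)))
  }
  list(values = (x - scaler$mean[[1]]) / (scaler$divisor * scaler$sd[[1]]),
       scaler = scaler)
}

new_scaler <- function(mu, sdev) {
  structure(list(mean = mu, sd = sdev, divisor = 2), class = "gyr_scaler")
}

#' Invert a 2-SD standardization
#'
#' @param z standardized vector or data frame.
#' @param scaler a `gyr_scaler`.
#' @return values on the original scale.
#' @export
unstandardize <- function(z, scaler) {
  if (is.data.frame(z)) {
    for (nm in names(scaler$mean))
      z[[nm]] <- z[[nm]] * scaler$divisor * scaler$sd[[nm]] +
        scaler$mean[[nm]]
    return(z)
  }
  z * scaler$divisor * scaler$sd[[1]] + scaler$mean[[1]]
}

#' Screen covariate pairs for collinearity
#'
#' Flags every unordered pair of covariates whose Pearson correlation
#' reaches `threshold` in absolute value; an empty result means the set
#' passes the |r| < 0.70 screen. Constant columns, for which the
#' correlation is undefined, are flagged against every partner with reason
#' `"constant"`.
#'
#' @param x numeric matrix or data frame (>= 3 rows).
#' @param threshold absolute correlation at or above which a pair is
#'   flagged (default 0.70).
#' @return data frame: `var1`, `var2`, `r`, `reason`.
#' @export
#' @examples
#' screen_collinearity(data.frame(a = 1:5, b = (1:5) * -1))
screen_collinearity <- function(x, threshold = 0.70) {
  x <- as.data.frame(x)
  num <- names(x)[vapply(x, is.numeric, logical(1))]
  x <- x[num]
  if (nrow(x) < 3L) stop("need at least 3 rows", call. = FALSE)
  const <- num[vapply(x, function(v) sd(v) == 0, logical(1))]
  out <- data.frame(var1 = character(), var2 = character(),
                    r = numeric(), reason = character())
  for (i in seq_along(num)) for (j in seq_along(num)) {
    if (j <= i) next
    a <- num[i]; b <- num[j]
    if (a %in% const || b %in% const) {
      out <- rbind(out, data.frame(var1 = a, var2 = b, r = NA_real_,
                                   reason = "constant"))
    } else {
      r <- cor(x[[a]], x[[b]])
      if (abs(r) >= threshold)
        out <- rbind(out, data.frame(var1 = a, var2 = b, r = r,
                                     reason = "correlated"))
    }
  }
  rownames(out) <- NULL
  out
}

#' Drop survey sites above an elevation cutoff
#'
#' Sites with mean elevation strictly greater than `max_elevation` are
#' removed (a site at exactly the cutoff is retained), mirroring the field
#' rule of excluding points above 500 m.a.s.l.
#'
#' @param sites data frame with an `elevation` column (m).
#' @param max_elevation cutoff in metres (default 500).
#' @return list: `sites` (retained rows), `report` (n_input, n_removed,
#'   n_retained, max_elevation).
#' @export
filter_sites_by_elevation <- function(sites, max_elevation = 500) {
  if (is.null(sites$elevation))
    stop("sites must carry an 'elevation' column", call. = FALSE)
  if (anyNA(sites$elevation)) {
    bad <- which(is.na(sites$elevation))
    id <- if (!is.null(sites$site_id)) sites$site_id[bad] else bad
    stop("missing elevation for site(s): ",
         paste(head(id, 5L), collapse = ", "), call. = FALSE)
  }
  keep <- sites$elevation <= max_elevation
  list(sites = sites[keep, , drop = FALSE],
       report = list(n_input = nrow(sites),
                     n_removed = sum(!keep),
                     n_retained = sum(keep),
                     max_elevation = max_elevation))
}

#' Percent cover and mean elevation within a square window
#'
#' Averages the vegetation percent-cover classes and elevation over all
#' lattice cells whose centres fall inside a square window of side
#' `window_side` centred on `center`. With the default 800-m window on an
#' 800-m lattice this reduces to reading the single enclosing cell; larger
#' windows block-average (for equal-area cells the mean of cell fractions
#' equals the fraction of the merged area, so covers are conserved).
#'
#' @param grid a `covariate_grid` from [simulate_landscape()] (or any data
#'   frame with `x_center`, `y_center`, cover columns and `elevation`).
#' @param center numeric length-2, window centre (m).
#' @param window_side window side length in metres (default 800).
#' @param classes cover columns to aggregate; defaults to every column that
#'   is neither coordinates/indices nor elevation.
#' @return named list: one mean percent cover per class and
#'   `elevation` (mean, m), plus `n_cells`.
#' @export
window_percent_cover <- function(grid, center, window_side = 800,
                                 classes = NULL) {
  if (is.null(classes))
    classes <- setdiff(names(grid),
                       c("cell_id", "x_index", "y_index",
                         "x_center", "y_center", "elevation", "site_id"))
  half <- window_side / 2
  inx <- grid$x_center >= center[1] - half & grid$x_center < center[1] + half
  iny <- grid$y_center >= center[2] - half & grid$y_center < center[2] + half
  cells <- grid[inx & iny, , drop = FALSE]
  if (nrow(cells) == 0L)
    stop("window contains no grid cells", call. = FALSE)
  out <- lapply(cells[classes], mean)
  out$elevation <- mean(cells$elevation)
  out$n_cells <- nrow(cells)
  out
}
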
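#' Silverman bandwidth for a 2-D point set
#'
#' The default kernel bandwidth for the sampling-bias surface: Silverman's
#' rule of thumb applied to the pooled coordinate spread,
#' `1.06 * sd * n^(-1/5)` with `sd` the mean of the per-axis standard
#' deviations.
#'
#' @param points data.frame with `x`, `y` (km).
#' @return bandwidth in km.
#' @export
silverman_bandwidth <- function(points) {
  stopifnot(nrow(points) >= 2)
  s <- mean(c(stats::sd(points$x), stats::sd(points$y)))
  if (!is.finite(s) || s == 0) s <- 1
  1.06 * s * nrow(points)^(-1 / 5)
}

#' Sampling-bias surface by kernel density estimation
#'
#' Counts occurrence records per grid cell and smooths the counts with an
#' isotropic Gaussian kernel of the stated bandwidth, renormalized to sum 1
#' over unmasked cells. Background points drawn from this surface inherit
#' the geographic bias of the survey effort.
#'
#' Smoothing is separable (row then column convolution), which is exactly
#' the 2-D Gaussian kernel on a regular grid.
#'
#' @param occurrences data.frame with `x`, `y` (km) of presence records.
#' @param grid a `raster_grid` defining the output geometry.
#' @param bandwidth Gaussian kernel sd in km; default Silverman's rule on
#'   the occurrence coordinates.
#' @return a `bias_surface`: list(grid = `raster_grid` of density summing to
#'   1, bandwidth).
#' @export
build_bias_surface <- function(occurrences, grid,
                               bandwidth = silverman_bandwidth(occurrences)) {
  stopifnot(nrow(occurrences) >= 1)
  loc <- locate_cells(grid, occurrences$x, occurrences$y)
  if (!any(loc$inside)) {
    stop("build_bias_surface: all occurrences fall outside the grid", call. = FALSE)
  }
  stopifnot(bandwidth > 0)
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  counts <- matrix(0, nr, nc)
  tab <- table(factor(loc$row[loc$inside], levels = seq_len(nr)),
               factor(loc$col[loc$inside], levels = seq_len(nc)))
  counts[] <- as.numeric(tab)
  # separable Gaussian smoothing in units of cells
  h <- bandwidth / grid$cellsize
  k <- function(n) {
    d <- outer(seq_len(n), seq_len(n), function(i, j) (i - j) * 1)
    exp(-d^2 / (2 * h^2))
  }
  sm <- k(nr) %*% counts %*% k(nc)
  mask <- is.na(grid$values)
  sm[mask] <- NA_real_
  sm <- sm / sum(sm, na.rm = TRUE)
  g <- raster_grid(sm, xmin = grid$xmin, ymax = grid$ymax,
                   cellsize = grid$cellsize, crs = grid$crs)
  structure(list(grid = g, bandwidth = bandwidth), class = "bias_surface")
}

#' Sample background (pseudo-absence) points
#'
#' Draws `n` cell-centre locations with replacement, with probability
#' proportional to the bias density, so pseudo-absences carry the same
#' geographic sampling bias as the presences.
#'
#' @param bias a `bias_surface`.
#' @param n number of points (the ensemble default is 500).
#' @param seed integer seed.
#' @return data.frame with `x`, `y`, `row`, `col`.
#' @export
sample_background <- function(bias, n = 500, seed) {
  stopifnot(n >= 1)
  d <- as.vector(bias$grid$values)
  d[is.na(d)] <- 0
  if (sum(d) <= 0) {
    stop("sample_background: degenerate bias density (all zero)", call. = FALSE)
  }
  if (!missing(seed)) set.seed(seed)
  # cell_centres orders cells column-major, matching as.vector(values)
  cc <- cell_centres(bias$grid)
  idx <- sample.int(length(d), n, replace = TRUE, prob = d)
  data.frame(x = cc$x[idx], y = cc$y[idx], row = cc$row[idx], col = cc$col[idx])
}

#' Thin over-represented positive communities
#'
#' Keeps a random `floor(fraction * count)` subset of the positive
#' (case-reporting) communities inside the over-sampled region; positives
#' outside the region and all non-positives pass through untouched. This
#' compensates the geographic imbalance of an intensive regional screening
#' campaign before the suitability models are trained.
#'
#' @param features a `feature_table` (rows with `label == 1` are positives).
#' @param region list(row = c(r1, r2), col = c(c1, c2)) in grid cell indices,
#'   or a logical vector marking rows inside the region.
#' @param grid the `raster_grid` the region indices refer to (ignored when
#'   `region` is logical).
#' @param fraction fraction of region positives retained (default 0.75).
#' @param seed integer seed.
#' @return the thinned `feature_table`; attribute `n_removed`.
#' @export
subsample_positives <- function(features, region, grid = NULL, fraction = 0.75,
                                seed) {
  stopifnot(fraction > 0, fraction <= 1)
  if (is.logical(region)) {
    in_region <- region
  } else {
    loc <- locate_cells(grid, features$x_km, features$y_km)
    in_region <- in_rect(loc$row, loc$col, region) & loc$inside
  }
  if (!missing(seed)) set.seed(seed)
  idx <- which(features$label == 1 & in_region)
  keep_n <- floor(fraction * length(idx))
  drop <- if (length(idx)) sample(idx, length(idx) - keep_n) else integer(0)
  if (length(drop) == 0) return(features)
  out <- features[-drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- length(drop)
  out
}

#' Balance presences against absences and background points
#'
#' Builds the weighted training set for the suitability learners: presences
#' keep weight 1; observed absences and background pseudo-absences share one
#' common weight `n_presence / (n_absence + n_background)`, so the summed
#' weight of the non-presence side equals the summed presence weight.
#'
#' @param presences,absences `feature_table` rows (label 1 / 0).
#' @param background data.frame of background points with covariate columns
#'   matching the feature table (e.g. from [extract_features()] on sampled
#'   points); may have 0 rows.
#' @return a `weighted_training_set` data.frame with `label`
#'   (`"presence"`, `"absence"`, `"background"`) and `weight`.
#' @export
assign_weights <- function(presences, absences, background = NULL) {
  n_p <- nrow(presences)
  n_a <- if (is.null(absences)) 0 else nrow(absences)
  n_b <- if (is.null(background)) 0 else nrow(background)
  if (n_p < 1) stop("assign_weights: at least one presence required", call. = FALSE)
  if (n_a + n_b == 0) {
    stop("assign_weights: no absences and no background points", call. = FALSE)
  }
  covs <- feature_covariate_names(presences)
  pick <- function(df, lab, w) {
    if (is.null(df) || nrow(df) == 0) return(NULL)
    out <- df[, covs, drop = FALSE]
    out$label <- lab
    out$weight <- w
    out
  }
  w <- n_p / (n_a + n_b)
  out <- rbind(pick(presences, "presence", 1),
               pick(absences, "absence", w),
               pick(background, "background", w))
  rownames(out) <- NULL
  class(out) <- c("weighted_training_set", "data.frame")
  out
}
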
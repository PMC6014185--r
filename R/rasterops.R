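#' Nearest-neighbour resampling onto a target grid
#'
#' Each output cell takes the value of the source cell whose centre is
#' nearest to the output cell centre (the standard approach for aligning
#' categorical or already-smooth covariate rasters to a common grid).
#' Distance ties are resolved towards the cell right/below, matching the
#' package-wide containment convention.
#'
#' @param src source `raster_grid`.
#' @param target `raster_grid` supplying the output geometry (values ignored).
#' @return a `raster_grid` on `target`'s geometry.
#' @export
resample_nearest <- function(src, target) {
  if (!identical(src$crs, target$crs)) {
    stop("resample_nearest: src and target CRS differ (", src$crs, " vs ",
         target$crs, "); reproject first", call. = FALSE)
  }
  sx <- c(src$xmin, src$xmin + ncol(src$values) * src$cellsize)
  sy <- c(src$ymax - nrow(src$values) * src$cellsize, src$ymax)
  tx <- c(target$xmin, target$xmin + ncol(target$values) * target$cellsize)
  ty <- c(target$ymax - nrow(target$values) * target$cellsize, target$ymax)
  if (sx[2] <= tx[1] || tx[2] <= sx[1] || sy[2] <= ty[1] || ty[2] <= sy[1]) {
    stop(sprintf(
      "resample_nearest: disjoint extents; src x[%g,%g] y[%g,%g] vs target x[%g,%g] y[%g,%g]",
      sx[1], sx[2], sy[1], sy[2], tx[1], tx[2], ty[1], ty[2]), call. = FALSE)
  }
  cc <- cell_centres(target)
  # on a regular grid the nearest src centre is the containing cell under the
  # half-open convention; half-distance ties go to the cell right/below
  col <- pmin(pmax(floor((cc$x - src$xmin) / src$cellsize) + 1, 1), ncol(src$values))
  row <- pmin(pmax(floor((src$ymax - cc$y) / src$cellsize) + 1, 1), nrow(src$values))
  out <- matrix(src$values[cbind(row, col)],
                nrow = nrow(target$values), ncol = ncol(target$values))
  raster_grid(out, xmin = target$xmin, ymax = target$ymax,
              cellsize = target$cellsize, crs = target$crs)
}

refuse_degree_crs <- function(g, op) {
  if (grepl("deg|4326|longlat|wgs84", tolower(g$crs))) {
    stop(op, ": grid CRS '", g$crs,
         "' looks geographic (degree units); project to a planar km CRS first",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Euclidean distance surface
#'
#' Straight-line distance in km from every cell centre to the nearest
#' feature point (water bodies, stable night lights, ... are represented as
#' point sets; line features should be densified to points first). Cells
#' containing a feature are 0 by definition.
#'
#' @param features data.frame with columns `x`, `y` (km).
#' @param grid a `raster_grid` defining the output geometry.
#' @return a `raster_grid` of distances (km).
#' @export
euclidean_distance <- function(features, grid) {
  if (is.null(features) || nrow(features) == 0) {
    stop("euclidean_distance: empty feature set", call. = FALSE)
  }
  refuse_degree_crs(grid, "euclidean_distance")
  cc <- cell_centres(grid)
  d2 <- rep(Inf, nrow(cc))
  for (k in seq_len(nrow(features))) {
    d2 <- pmin(d2, (cc$x - features$x[k])^2 + (cc$y - features$y[k])^2)
  }
  out <- matrix(NA_real_, nrow(grid$values), ncol(grid$values))
  out[cbind(cc$row, cc$col)] <- sqrt(d2)
  loc <- locate_cells(grid, features$x, features$y)
  ok <- loc$inside
  out[cbind(loc$row[ok], loc$col[ok])] <- 0
  raster_grid(out, xmin = grid$xmin, ymax = grid$ymax,
              cellsize = grid$cellsize, crs = grid$crs)
}

#' Terrain slope in degrees (Horn's method)
#'
#' The 3x3 finite-difference operator of Horn (the one GIS packages use for
#' DEM slope): weighted central differences in x and y, slope =
#' atan(sqrt(gx^2 + gy^2)). Edge cells are handled by clamping the
#' neighbourhood at the border, which reduces to one-sided differences.
#'
#' @param elevation `raster_grid`; z units must match the horizontal units
#'   after multiplying by `z_scale` (e.g. metres on a km grid needs
#'   `z_scale = 1e-3`).
#' @param z_scale factor converting z units to the grid's horizontal units.
#' @return `raster_grid` of slope in degrees, in `[0, 90)`.
#' @export
slope_degrees <- function(elevation, z_scale = 1) {
  refuse_degree_crs(elevation, "slope_degrees")
  z <- elevation$values * z_scale
  nr <- nrow(z); nc <- ncol(z)
  if (nr < 3 || nc < 3) {
    stop("slope_degrees: grid must be at least 3x3", call. = FALSE)
  }
  up <- function(i) pmax(i - 1, 1); dn <- function(i, n) pmin(i + 1, n)
  ri <- seq_len(nr); ci <- seq_len(nc)
  zNW <- z[up(ri), up(ci)]; zN <- z[up(ri), ci];       zNE <- z[up(ri), dn(ci, nc)]
  zW  <- z[ri,     up(ci)];                             zE  <- z[ri,     dn(ci, nc)]
  zSW <- z[dn(ri, nr), up(ci)]; zS <- z[dn(ri, nr), ci]; zSE <- z[dn(ri, nr), dn(ci, nc)]
  cs <- elevation$cellsize
  gx <- ((zNE + 2 * zE + zSE) - (zNW + 2 * zW + zSW)) / (8 * cs)
  gy <- ((zSW + 2 * zS + zSE) - (zNW + 2 * zN + zNE)) / (8 * cs)
  slope <- atan(sqrt(gx^2 + gy^2)) * 180 / pi
  raster_grid(slope, xmin = elevation$xmin, ymax = elevation$ymax,
              cellsize = elevation$cellsize, crs = elevation$crs)
}

#' Standardize a covariate stack
#'
#' z-scores every layer over its unmasked cells and records the constants so
#' point extractions stay consistent with grid predictions. Tree learners
#' are scale-invariant, but the geostatistical linear predictor benefits
#' numerically from standardized covariates.
#'
#' @param stack a `raster_stack`.
#' @return a `raster_stack` with a `$standardization` data.frame
#'   (`layer`, `centre`, `scale`).
#' @export
standardize_stack <- function(stack) {
  consts <- data.frame(layer = names(stack$layers), centre = NA_real_, scale = NA_real_)
  for (i in seq_along(stack$layers)) {
    v <- stack$layers[[i]]$values
    mu <- mean(v, na.rm = TRUE)
    sd <- stats::sd(as.vector(v), na.rm = TRUE)
    if (!is.finite(sd) || sd == 0) sd <- 1
    stack$layers[[i]]$values <- (v - mu) / sd
    consts$centre[i] <- mu; consts$scale[i] <- sd
  }
  stack$standardization <- consts
  stack
}

#' Extract covariates at survey communities
#'
#' Builds the model feature table: one row per community carrying the
#' covariate values of the containing cell, the screening counts, the
#' presence label (1 if at least one confirmed case, else 0) and a unit
#' regression weight. Points outside the grid or hitting nodata are dropped
#' and counted.
#'
#' @param stack a `raster_stack` of covariates.
#' @param surveys data.frame with `community_id`, `x_km`, `y_km`,
#'   `n_screened`, `n_cases`.
#' @return a `feature_table` data.frame with attribute `dropped`
#'   (list: `outside`, `nodata`).
#' @export
extract_features <- function(stack, surveys) {
  req <- c("community_id", "x_km", "y_km", "n_screened", "n_cases")
  stopifnot(all(req %in% names(surveys)))
  g <- raster_grid(stack$layers[[1]]$values, xmin = stack$geometry$xmin,
                   ymax = stack$geometry$ymax, cellsize = stack$geometry$cellsize,
                   crs = stack$geometry$crs)
  loc <- locate_cells(g, surveys$x_km, surveys$y_km)
  n_outside <- sum(!loc$inside)
  keep <- loc$inside
  idx <- cbind(loc$row[keep], loc$col[keep])
  covs <- sapply(stack$layers, function(l) l$values[idx])
  if (is.null(dim(covs))) covs <- matrix(covs, ncol = length(stack$layers),
                                         dimnames = list(NULL, names(stack$layers)))
  complete <- stats::complete.cases(covs)
  n_nodata <- sum(!complete)
  out <- cbind(
    surveys[keep, req, drop = FALSE][complete, , drop = FALSE],
    as.data.frame(covs[complete, , drop = FALSE])
  )
  out$label <- as.integer(out$n_cases >= 1)
  out$weight <- 1
  rownames(out) <- NULL
  if (n_outside + n_nodata > 0) {
    message(sprintf("extract_features: dropped %d point(s) outside the grid, %d on nodata",
                    n_outside, n_nodata))
  }
  attr(out, "dropped") <- list(outside = n_outside, nodata = n_nodata)
  class(out) <- c("feature_table", "data.frame")
  out
}

feature_covariate_names <- function(features) {
  setdiff(names(features),
          c("community_id", "x_km", "y_km", "n_screened", "n_cases",
            "label", "weight"))
}
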
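#' Adult population surface
#'
#' Scales a gridded population surface by the adult (>= 15 years) fraction,
#' either a scalar or a per-cell raster.
#'
#' @param pop `raster_grid` of population counts per cell (>= 0).
#' @param adult_fraction scalar in `[0, 1]` or an aligned `raster_grid`.
#' @return `raster_grid` of adults per cell.
#' @export
adult_population <- function(pop, adult_fraction) {
  if (any(pop$values < 0, na.rm = TRUE)) {
    stop("adult_population: negative population", call. = FALSE)
  }
  if (inherits(adult_fraction, "raster_grid")) {
    stop_if_misaligned(pop, adult_fraction, "population / adult fraction")
    f <- adult_fraction$values
  } else {
    f <- adult_fraction
  }
  if (any(f < 0 | f > 1, na.rm = TRUE)) {
    stop("adult_population: adult_fraction outside [0, 1]", call. = FALSE)
  }
  out <- pop
  out$values <- pop$values * f
  out
}

#' Case-count surfaces from prevalence and adults
#'
#' Cell-wise products of the predicted prevalence surfaces (mean and 95%
#' bounds) with the adult population surface. Grids must align exactly; no
#' silent resampling. Nodata propagates.
#'
#' @param prev a `prevalence_prediction` (or a list with `mean`, `ci_low`,
#'   `ci_high` `raster_grid`s).
#' @param adults `raster_grid` of adults per cell.
#' @return list of `raster_grid`s: `mean`, `low`, `high`, and `se` when the
#'   prediction carries a prevalence SE surface.
#' @export
cases_surface <- function(prev, adults) {
  stop_if_misaligned(prev$mean, adults, "prevalence / adults")
  mul <- function(g) {
    out <- g
    out$values <- g$values * adults$values
    out
  }
  out <- list(mean = mul(prev$mean), low = mul(prev$ci_low),
              high = mul(prev$ci_high))
  if (!is.null(prev$se)) out$se <- mul(prev$se)
  out
}

#' Read administrative polygons from GeoJSON
#'
#' Supports `Polygon` and `MultiPolygon` features (with holes); the first
#' available of `name` / `NAME` / `id` properties labels each unit.
#' Coordinates are taken as planar km, matching the pipeline CRS.
#'
#' @param path GeoJSON file.
#' @return an `admin_polygons` list: per unit, `name` and `rings` (list of
#'   two-column coordinate matrices; ring orientation is ignored, holes are
#'   handled by the even-odd rule).
#' @export
read_geojson_polygons <- function(path) {
  gj <- jsonlite::read_json(path)
  feats <- gj$features %||% list(gj)
  units <- lapply(seq_along(feats), function(i) {
    f <- feats[[i]]
    props <- f$properties %||% list()
    nm <- props$name %||% props$NAME %||% props$id %||% paste0("unit", i)
    geom <- f$geometry %||% f
    ring_mat <- function(r) {
      do.call(rbind, lapply(r, function(pt) c(pt[[1]], pt[[2]])))
    }
    rings <- switch(geom$type,
      Polygon = lapply(geom$coordinates, ring_mat),
      MultiPolygon = unlist(lapply(geom$coordinates,
                                   function(poly) lapply(poly, ring_mat)),
                            recursive = FALSE),
      stop("read_geojson_polygons: unsupported geometry type ", geom$type,
           call. = FALSE))
    list(name = nm, rings = rings)
  })
  structure(units, class = "admin_polygons")
}

#' Build admin polygons from coordinate rings
#'
#' Programmatic constructor used by the synthetic pipeline: one unit per
#' list element, each a list of rings (two-column x, y matrices in km).
#'
#' @param units named list; each element a list of ring matrices.
#' @return an `admin_polygons` object.
#' @export
admin_polygons <- function(units) {
  structure(lapply(names(units), function(nm) {
    list(name = nm, rings = units[[nm]])
  }), class = "admin_polygons")
}

# even-odd ray-casting containment of points in one ring set
points_in_rings <- function(x, y, rings) {
  inside <- rep(FALSE, length(x))
  for (r in rings) {
    xs <- r[, 1]; ys <- r[, 2]
    n <- length(xs)
    j <- c(n, seq_len(n - 1))
    for (k in seq_len(n)) {
      xi <- xs[k]; yi <- ys[k]; xj <- xs[j[k]]; yj <- ys[j[k]]
      crosses <- ((yi > y) != (yj > y)) &
        (x < (xj - xi) * (y - yi) / (yj - yi) + xi)
      inside <- xor(inside, crosses)
    }
  }
  inside
}

#' Aggregate case and population surfaces to administrative units
#'
#' Assigns every unmasked cell to the polygon containing its centre
#' (even-odd rule; overlapping polygons are an error) and sums the case and
#' population surfaces per unit. Cells in no polygon land in a residual
#' `"unassigned"` row, so column totals conserve the grid totals exactly.
#'
#' @param cases list of `raster_grid`s from [cases_surface()].
#' @param adults `raster_grid` of adults per cell.
#' @param admin an `admin_polygons` object.
#' @param limits optional binary `raster_grid`: population at risk counts
#'   only cells with `limits = 1`.
#' @return a `burden_table` data.frame: `name`, `population_at_risk`,
#'   `cases_mean`, `cases_low`, `cases_high`.
#' @export
aggregate_burden <- function(cases, adults, admin, limits = NULL) {
  stop_if_misaligned(cases$mean, adults, "cases / adults")
  cc <- cell_centres(adults)
  v_adults <- as.vector(adults$values)
  keep <- !is.na(v_adults)
  assign <- rep(NA_integer_, length(v_adults))
  for (u in seq_along(admin)) {
    hit <- points_in_rings(cc$x, cc$y, admin[[u]]$rings) & keep
    clash <- hit & !is.na(assign)
    if (any(clash)) {
      stop(sprintf("aggregate_burden: polygons '%s' and '%s' overlap (%d shared cells)",
                   admin[[assign[which(clash)[1]]]]$name, admin[[u]]$name,
                   sum(clash)), call. = FALSE)
    }
    assign[hit] <- u
  }
  unit_names <- c(vapply(admin, `[[`, "", "name"), "unassigned")
  assign[keep & is.na(assign)] <- length(unit_names)
  par_v <- v_adults
  if (!is.null(limits)) {
    stop_if_misaligned(adults, limits, "adults / limits")
    par_v <- par_v * (as.vector(limits$values) >= 0.5)
  }
  sum_by <- function(v) {
    out <- rep(0, length(unit_names))
    s <- tapply(v[keep], assign[keep], sum, na.rm = TRUE)
    out[as.integer(names(s))] <- s
    out
  }
  tab <- data.frame(
    name = unit_names,
    population_at_risk = sum_by(par_v),
    cases_mean = sum_by(as.vector(cases$mean$values)),
    cases_low = sum_by(as.vector(cases$low$values)),
    cases_high = sum_by(as.vector(cases$high$values)))
  class(tab) <- c("burden_table", "data.frame")
  tab
}

#' Endemicity summary of a burden table
#'
#' Threshold counts (units with at least `t` mean cases for each `t`),
#' per-unit shares of total cases and of population at risk, and the
#' largest-contributing units. Shares are computed on column sums, which is
#' robust to presentation rounding of any printed grand total.
#'
#' @param burden a `burden_table` (or any data.frame with `name`,
#'   `cases_mean` and optionally `population_at_risk`).
#' @param thresholds case-count thresholds (default 100 and 500).
#' @return list: `counts` (data.frame `threshold`, `n_units`), `shares`
#'   (per-unit `cases_share_pct`, `par_share_pct`, 1 dp), `largest_unit`,
#'   `total_cases`, `total_population_at_risk`.
#' @export
summarize_endemicity <- function(burden, thresholds = c(100, 500)) {
  if (nrow(burden) == 0) {
    return(list(counts = data.frame(threshold = thresholds,
                                    n_units = rep(0L, length(thresholds))),
                shares = data.frame(name = character(), cases_share_pct = numeric(),
                                    par_share_pct = numeric()),
                largest_unit = NA_character_, total_cases = 0,
                total_population_at_risk = 0))
  }
  total_cases <- sum(burden$cases_mean)
  total_par <- if ("population_at_risk" %in% names(burden)) {
    sum(burden$population_at_risk)
  } else NA_real_
  shares <- data.frame(
    name = burden$name,
    cases_share_pct = round(100 * burden$cases_mean / total_cases, 1),
    par_share_pct = if (is.na(total_par)) NA_real_ else
      round(100 * burden$population_at_risk / total_par, 1))
  counts <- data.frame(
    threshold = thresholds,
    n_units = vapply(thresholds, function(t) sum(burden$cases_mean >= t),
                     integer(1)))
  list(counts = counts, shares = shares,
       largest_unit = burden$name[which.max(burden$cases_mean)],
       total_cases = total_cases, total_population_at_risk = total_par)
}

#' Share of total cases held by a set of units
#'
#' @param burden a `burden_table`-like data.frame.
#' @param units unit names.
#' @param column `"cases_mean"` or `"population_at_risk"`.
#' @return percentage share, rounded to 1 dp.
#' @export
burden_share <- function(burden, units, column = "cases_mean") {
  missing_units <- setdiff(units, burden$name)
  if (length(missing_units)) {
    stop("burden_share: unknown units: ", paste(missing_units, collapse = ", "),
         call. = FALSE)
  }
  round(100 * sum(burden[[column]][burden$name %in% units]) /
          sum(burden[[column]]), 1)
}

#' Read a pre-aggregated regional burden table
#'
#' CSV in the layout of a published regional summary: `region`,
#' `population_at_risk`, `par_lower`, `par_upper`, `cases`, `cases_lower`,
#' `cases_upper`. Returned as a `burden_table` so the same summaries apply.
#'
#' @param path CSV path.
#' @return a `burden_table` data.frame.
#' @export
read_burden_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("region", "population_at_risk", "cases")
  if (!all(req %in% names(df))) {
    stop("read_burden_csv: need columns ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  tab <- data.frame(
    name = df$region,
    population_at_risk = df$population_at_risk,
    cases_mean = df$cases,
    cases_low = df$cases_lower %||% NA_real_,
    cases_high = df$cases_upper %||% NA_real_)
  class(tab) <- c("burden_table", "data.frame")
  tab
}
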
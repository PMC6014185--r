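#' Georeferenced regular grid
#'
#' The package's raster container: a numeric matrix on a regular planar grid.
#' Rows run north to south, columns west to east; `NA` is nodata. The
#' coordinate system is a projected, planar CRS in kilometres (the synthetic
#' pipeline works entirely in km; geographic degree-unit data must be
#' projected before entering the pipeline).
#'
#' Cell containment follows a half-open convention: a point on a shared
#' vertical edge belongs to the cell on the right, on a shared horizontal
#' edge to the cell below, so extraction is deterministic.
#'
#' @param values numeric matrix (rows x cols).
#' @param xmin x coordinate (km) of the west edge.
#' @param ymax y coordinate (km) of the north edge.
#' @param cellsize cell edge length, km.
#' @param crs character CRS label; `"planar-km"` marks projected km units.
#' @return an object of class `raster_grid`.
#' @export
raster_grid <- function(values, xmin = 0, ymax = nrow(values) * cellsize,
                        cellsize = 1, crs = "planar-km") {
  values <- as.matrix(values)
  stopifnot(is.numeric(values) || is.logical(values), cellsize > 0)
  storage.mode(values) <- "double"
  structure(
    list(values = values, xmin = xmin, ymax = ymax,
         cellsize = cellsize, crs = crs),
    class = "raster_grid"
  )
}

#' @export
print.raster_grid <- function(x, ...) {
  v <- x$values
  cat(sprintf("raster_grid: %d x %d cells of %g km (%s)\n",
              nrow(v), ncol(v), x$cellsize, x$crs))
  cat(sprintf("  extent: x [%g, %g], y [%g, %g] km; %d nodata cells\n",
              x$xmin, x$xmin + ncol(v) * x$cellsize,
              x$ymax - nrow(v) * x$cellsize, x$ymax, sum(is.na(v))))
  rng <- range(v, na.rm = TRUE)
  cat(sprintf("  values: [%g, %g]\n", rng[1], rng[2]))
  invisible(x)
}

#' @export
dim.raster_grid <- function(x) dim(x$values)

grid_ncell <- function(g) length(g$values)

#' Do two grids share geometry exactly?
#'
#' Bit-level equality of origin, cell size, shape and CRS — the alignment
#' contract every multi-surface operation enforces.
#'
#' @param a,b `raster_grid` objects.
#' @return logical.
#' @export
same_geometry <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    identical(a$xmin, b$xmin) && identical(a$ymax, b$ymax) &&
    identical(a$cellsize, b$cellsize) && identical(a$crs, b$crs)
}

stop_if_misaligned <- function(a, b, what = "rasters") {
  if (!same_geometry(a, b)) {
    stop(sprintf("misaligned %s: grids must share transform, shape and CRS exactly (no silent resampling)", what),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Cell-centre coordinates
#'
#' @param g a `raster_grid`.
#' @return data.frame with `row`, `col`, `x`, `y` (km), one row per cell in
#'   column-major order of the value matrix.
#' @export
cell_centres <- function(g) {
  nr <- nrow(g$values); nc <- ncol(g$values)
  rows <- rep(seq_len(nr), times = nc)
  cols <- rep(seq_len(nc), each = nr)
  data.frame(
    row = rows, col = cols,
    x = g$xmin + (cols - 0.5) * g$cellsize,
    y = g$ymax - (rows - 0.5) * g$cellsize
  )
}

#' Locate points on a grid
#'
#' Maps planar coordinates to (row, col) under the half-open cell convention
#' (edge points belong to the cell right/below). Points outside the extent
#' get `NA` indices.
#'
#' @param g a `raster_grid`.
#' @param x,y point coordinates, km.
#' @return data.frame with `row`, `col`, `inside`.
#' @export
locate_cells <- function(g, x, y) {
  nr <- nrow(g$values); nc <- ncol(g$values)
  col <- floor((x - g$xmin) / g$cellsize) + 1
  row <- floor((g$ymax - y) / g$cellsize) + 1
  # north edge: y == ymax falls in row 1 (the cell "below" the edge is row 1)
  row[y == g$ymax] <- 1L
  inside <- row >= 1 & row <= nr & col >= 1 & col <= nc
  row[!inside] <- NA_integer_; col[!inside] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col), inside = inside)
}

#' Extract raster values at points
#'
#' @inheritParams locate_cells
#' @param g a `raster_grid`.
#' @return numeric vector; `NA` for points outside the grid or on nodata.
#' @export
grid_value_at <- function(g, x, y) {
  loc <- locate_cells(g, x, y)
  out <- rep(NA_real_, length(x))
  ok <- loc$inside
  out[ok] <- g$values[cbind(loc$row[ok], loc$col[ok])]
  out
}

#' Aligned stack of covariate rasters
#'
#' A named list of `raster_grid`s sharing geometry exactly. Nodata
#' propagates: a cell masked in any layer is masked in every layer.
#'
#' @param layers named list of `raster_grid`s.
#' @return object of class `raster_stack`.
#' @export
raster_stack <- function(layers) {
  stopifnot(is.list(layers), length(layers) >= 1)
  if (is.null(names(layers)) || any(!nzchar(names(layers)))) {
    names(layers) <- paste0("cov", seq_along(layers))
  }
  ref <- layers[[1]]
  for (i in seq_along(layers)) {
    stop_if_misaligned(ref, layers[[i]], "stack layers")
  }
  mask <- Reduce(`|`, lapply(layers, function(l) is.na(l$values)))
  layers <- lapply(layers, function(l) {
    l$values[mask] <- NA_real_
    l
  })
  structure(list(layers = layers, geometry = ref[c("xmin", "ymax", "cellsize", "crs")],
                 shape = dim(ref$values)),
            class = "raster_stack")
}

#' @export
print.raster_stack <- function(x, ...) {
  cat(sprintf("raster_stack: %d layers (%s), %d x %d cells\n",
              length(x$layers), paste(names(x$layers), collapse = ", "),
              x$shape[1], x$shape[2]))
  invisible(x)
}

#' @export
names.raster_stack <- function(x) names(x$layers)

stack_matrix <- function(stack, cells = NULL) {
  # covariate matrix for the given cell indices (default: all unmasked cells)
  m <- sapply(stack$layers, function(l) as.vector(l$values))
  if (is.null(dim(m))) m <- matrix(m, ncol = length(stack$layers))
  colnames(m) <- names(stack$layers)
  if (is.null(cells)) cells <- which(stats::complete.cases(m))
  list(cells = cells, x = m[cells, , drop = FALSE])
}

#' Read / write ESRI ASCII grid rasters
#'
#' Plain-text raster interchange (`.asc`): a six-line header (`ncols`,
#' `nrows`, `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`) followed by
#' rows north to south. Coordinates are interpreted as planar km.
#'
#' @param path file path.
#' @param crs CRS label to attach on read.
#' @return `read_asc()` a `raster_grid`; `write_asc()` the path, invisibly.
#' @export
read_asc <- function(path, crs = "planar-km") {
  lines <- readLines(path, n = 6)
  kv <- do.call(rbind, strsplit(trimws(lines), "\\s+"))
  hdr <- stats::setNames(as.numeric(kv[, 2]), tolower(kv[, 1]))
  vals <- scan(path, skip = 6, quiet = TRUE)
  m <- matrix(vals, nrow = hdr[["nrows"]], ncol = hdr[["ncols"]], byrow = TRUE)
  m[m == hdr[["nodata_value"]]] <- NA_real_
  raster_grid(m,
              xmin = hdr[["xllcorner"]],
              ymax = hdr[["yllcorner"]] + hdr[["nrows"]] * hdr[["cellsize"]],
              cellsize = hdr[["cellsize"]], crs = crs)
}

#' @rdname read_asc
#' @param g a `raster_grid` to write.
#' @param nodata numeric value encoding nodata cells on disk.
#' @export
write_asc <- function(g, path, nodata = -9999) {
  v <- g$values
  v[is.na(v)] <- nodata
  hdr <- c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10g", g$xmin),
    sprintf("yllcorner %.10g", g$ymax - nrow(v) * g$cellsize),
    sprintf("cellsize %.10g", g$cellsize),
    sprintf("NODATA_value %g", nodata)
  )
  body <- apply(v, 1, function(r) paste(format(r, digits = 10, trim = TRUE), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}
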
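#' Single-band raster grid
#'
#' The universal currency of the pipeline: a rectangular lattice of cell
#' values with projected-CRS georeferencing. Values live at cell centres;
#' row 1 is the northern edge, distances are metres of the projected CRS.
#'
#' @param values Numeric matrix (row 1 = north). `NA` marks nodata.
#' @param cell_size Cell edge length in metres (> 0).
#' @param origin Numeric length-2: (x, y) of the north-west corner.
#' @param crs CRS identifier string, e.g. `"EPSG:32648"`.
#' @param nodata Sentinel written to file for `NA` cells.
#'
#' @return An object of class `grid_raster`.
#' @export
#' @examples
#' r <- grid_raster(matrix(1:9, 3, 3), cell_size = 30)
#' r
grid_raster <- function(values, cell_size, origin = c(0, nrow(values) * cell_size),
                        crs = "EPSG:32648", nodata = -9999) {
  if (!is.matrix(values) || nrow(values) < 1L || ncol(values) < 1L)
    stop("`values` must be a non-empty matrix", call. = FALSE)
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("`cell_size` must be a single positive number", call. = FALSE)
  storage.mode(values) <- "double"
  structure(
    list(values = values, cell_size = as.numeric(cell_size),
         origin = as.numeric(origin), crs = crs, nodata = as.numeric(nodata)),
    class = "grid_raster"
  )
}

#' @export
print.grid_raster <- function(x, ...) {
  v <- x$values
  cat(sprintf("<grid_raster> %d x %d cells, %.10g m cell size, crs %s\n",
              nrow(v), ncol(v), x$cell_size, x$crs))
  fin <- v[is.finite(v)]
  if (length(fin))
    cat(sprintf("  finite cells: %d  range [%.6g, %.6g]  mean %.6g\n",
                length(fin), min(fin), max(fin), mean(fin)))
  cat(sprintf("  nodata cells: %d\n", sum(!is.finite(v))))
  invisible(x)
}

#' @export
as.matrix.grid_raster <- function(x, ...) x$values

#' @export
dim.grid_raster <- function(x) dim(x$values)

#' Replace the value matrix, keeping georeferencing
#'
#' @param template A `grid_raster` supplying cell size, origin and CRS.
#' @param values New value matrix with the template's dimensions.
#' @return A `grid_raster`.
#' @export
raster_like <- function(template, values) {
  stopifnot(inherits(template, "grid_raster"))
  if (is.vector(values)) values <- matrix(values, nrow(template$values), ncol(template$values))
  if (!all(dim(values) == dim(template$values)))
    stop("replacement values do not match template dimensions", call. = FALSE)
  grid_raster(values, template$cell_size, template$origin, template$crs, template$nodata)
}

#' Cell-centre coordinates
#'
#' @param raster A `grid_raster`.
#' @param rows,cols Integer vectors of 1-based row/column indices (recycled).
#' @return A tibble with columns `row`, `col`, `x`, `y`.
#' @export
cell_centres <- function(raster, rows, cols) {
  cs <- raster$cell_size
  tibble::tibble(
    row = as.integer(rows), col = as.integer(cols),
    x = raster$origin[1] + (as.numeric(cols) - 0.5) * cs,
    y = raster$origin[2] - (as.numeric(rows) - 0.5) * cs
  )
}

#' Map projected coordinates to cell indices
#'
#' @param raster A `grid_raster`.
#' @param x,y Coordinate vectors in the raster's CRS.
#' @return A tibble with `row`, `col`; coordinates outside the grid give `NA`.
#' @export
cell_at <- function(raster, x, y) {
  cs <- raster$cell_size
  col <- floor((x - raster$origin[1]) / cs) + 1L
  row <- floor((raster$origin[2] - y) / cs) + 1L
  bad <- row < 1L | col < 1L | row > nrow(raster$values) | col > ncol(raster$values)
  row[bad] <- NA_integer_; col[bad] <- NA_integer_
  tibble::tibble(row = as.integer(row), col = as.integer(col))
}

#' Do two rasters share the same grid?
#' @param a,b `grid_raster` objects.
#' @return Logical scalar.
#' @export
same_grid <- function(a, b) {
  all(dim(a$values) == dim(b$values)) &&
    isTRUE(all.equal(a$cell_size, b$cell_size)) &&
    isTRUE(all.equal(a$origin, b$origin)) &&
    identical(a$crs, b$crs)
}

check_aligned <- function(..., what = "rasters") {
  rs <- list(...)
  ref <- rs[[1]]
  for (r in rs[-1])
    if (!same_grid(ref, r))
      stop(sprintf("%s are not aligned (shape/cell size/origin/crs differ)", what),
           call. = FALSE)
  invisible(TRUE)
}

#' Min-max rescale a raster to [0, 1]
#'
#' Degenerate (constant) rasters map to 0 everywhere, with a warning.
#'
#' @param raster A `grid_raster`.
#' @return A `grid_raster` in `[0, 1]`.
#' @export
rescale01 <- function(raster) {
  v <- raster$values
  fin <- is.finite(v)
  if (!any(fin)) stop("raster has no finite cells", call. = FALSE)
  rng <- range(v[fin])
  if (diff(rng) == 0) {
    warning("constant raster: rescale01 returns 0 everywhere")
    v[fin] <- 0
  } else v[fin] <- (v[fin] - rng[1]) / diff(rng)
  raster_like(raster, v)
}

#' Summary statistics over finite cells
#' @param raster A `grid_raster`.
#' @return A tibble with `n`, `mean`, `sd`, `min`, `max`.
#' @export
raster_stats <- function(raster) {
  v <- raster$values[is.finite(raster$values)]
  tibble::tibble(n = length(v), mean = mean(v), sd = stats::sd(v),
                 min = min(v), max = max(v))
}

#' Area of a cell mask in square kilometres
#' @param raster A `grid_raster` whose cells are counted where `mask` is TRUE.
#' @param mask Logical matrix (default: all finite cells).
#' @return Numeric scalar, km^2.
#' @export
mask_area_km2 <- function(raster, mask = is.finite(raster$values)) {
  sum(mask, na.rm = TRUE) * raster$cell_size^2 / 1e6
}
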
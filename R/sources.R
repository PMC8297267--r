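#' Mask of the top service-value quantile
#'
#' Cells at or above the `(1 - q)` quantile of the finite cell values; with
#' the default `q = 0.2` this keeps the top 20% of each service surface,
#' the "chief ecological patches". Ties at the quantile are kept, so the
#' selected fraction can exceed `q` by at most one tie group; the selection
#' depends only on ranks (invariant under monotone transforms).
#'
#' @param service [grid_raster] of a service value.
#' @param q Proportion to keep (0 < q < 1), default 0.2.
#' @return [grid_raster] mask (1 = selected, 0 = not, NA = nodata).
#' @export
top_quantile_mask <- function(service, q = 0.2) {
  stopifnot(q > 0, q < 1)
  v <- service$values
  fin <- is.finite(v)
  if (!any(fin)) stop("service raster has no finite cells", call. = FALSE)
  # cut at the k-th largest value, k = floor(q n): with distinct values the
  # selected fraction is exactly q; ties at the cut are all kept
  k <- max(1L, floor(q * sum(fin)))
  cut <- sort(v[fin], decreasing = TRUE)[k]
  out <- matrix(NA_real_, nrow(v), ncol(v))
  out[fin] <- as.numeric(v[fin] >= cut)
  raster_like(service, out)
}

#' Per-cell count of services in which a cell is top-quantile
#'
#' The "merged" dominant-service surface: for each cell, in how many of the
#' service masks it is selected (0..number of services).
#'
#' @param masks List of aligned binary [grid_raster] masks.
#' @return [grid_raster] of integer counts.
#' @export
service_richness <- function(masks) {
  stopifnot(length(masks) >= 1)
  do.call(check_aligned, c(unname(masks), list(what = "service masks")))
  acc <- 0
  na_any <- FALSE
  for (m in masks) {
    v <- m$values
    na_any <- na_any | !is.finite(v)
    v[!is.finite(v)] <- 0
    acc <- acc + (v != 0)
  }
  acc[na_any & acc == 0] <- NA_real_
  raster_like(masks[[1]], acc)
}

#' Getis-Ord Gi* hotspot z-scores
#'
#' Local Gi* statistic with binary distance-band weights including the cell
#' itself: for each cell, the standardised deviation of its neighbourhood
#' sum from the expectation under spatial randomness,
#' `z_i = (sum_j w_ij x_j - xbar W_i) / (S sqrt((n W_i - W_i^2)/(n - 1)))`
#' with `W_i` the in-band finite-cell count, `xbar` and `S` the global mean
#' and standard deviation over the `n` finite cells. Positive z marks
#' hotspots (clustered high values), negative z cold spots.
#'
#' @param field [grid_raster]; must have at least two distinct finite values.
#' @param radius Neighbourhood radius in metres (>= cell size).
#' @return [grid_raster] of z-scores (NA on nodata cells).
#' @export
gi_star <- function(field, radius) {
  v <- field$values
  cs <- field$cell_size
  if (radius < cs) stop("radius must be at least one cell size", call. = FALSE)
  fin <- is.finite(v)
  n <- sum(fin)
  vals <- v[fin]
  if (length(unique(vals)) < 2L)
    stop("zero variance: Gi* undefined on a constant field", call. = FALSE)
  xbar <- mean(vals)
  s <- sqrt(sum(vals^2) / n - xbar^2)
  maxd <- floor(radius / cs)
  x0 <- v; x0[!fin] <- 0
  m0 <- matrix(as.numeric(fin), nrow(v), ncol(v))
  sum_x <- matrix(0, nrow(v), ncol(v))
  w_cnt <- matrix(0, nrow(v), ncol(v))
  for (dr in -maxd:maxd) for (dc in -maxd:maxd) {
    if ((dr^2 + dc^2) * cs^2 > radius^2) next
    sum_x <- sum_x + shift_matrix(x0, dr, dc)
    w_cnt <- w_cnt + shift_matrix(m0, dr, dc)
  }
  denom <- s * sqrt(pmax(n * w_cnt - w_cnt^2, 0) / (n - 1))
  z <- (sum_x - xbar * w_cnt) / denom
  z[denom == 0] <- 0  # window covers every finite cell: no deviation possible
  z[!fin] <- NA_real_
  raster_like(field, z)
}

# Shift a matrix by (dr, dc) with zero padding: the result at (r, c) is
# m[r + dr, c + dc] where defined.
shift_matrix <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  if (max(1, 1 - dr) > min(nr, nr - dr) ||
      max(1, 1 - dc) > min(nc, nc - dc)) return(out)
  rs <- max(1, 1 - dr):min(nr, nr - dr)
  cs <- max(1, 1 - dc):min(nc, nc - dc)
  out[rs, cs] <- m[rs + dr, cs + dc]
  out
}

#' Extract ecological source patches from a hotspot surface
#'
#' Thresholds the Gi* z-score surface, takes 8-connected components,
#' drops components smaller than the minimum area (patches with area below
#' the threshold are removed; area exactly at the threshold is kept), and
#' polygonizes the survivors. Each source gets a centre point at its cell
#' of maximal z (ties broken by distance to the component centroid), used
#' downstream as the ant start/end terminal.
#'
#' @param z [grid_raster] of Gi* z-scores.
#' @param z_threshold Hotspot significance cut-off (default 1.65, 90%
#'   confidence — the conventional GIS hot-spot default).
#' @param min_area_km2 Minimum patch area in km^2 (default 6.26).
#' @param richness Optional aligned richness raster; if given, each source
#'   reports the maximum dominant-service count over its cells.
#' @return A `source_set` tibble: `id`, `n_cells`, `area_km2`, `geometry`,
#'   `cells`, `centre_row/col/x/y`, optionally `dominant_service_count`,
#'   with the template raster as attribute `template`.
#' @export
extract_source_patches <- function(z, z_threshold = 1.65, min_area_km2 = 6.26,
                                   richness = NULL) {
  stopifnot(min_area_km2 > 0)
  mask <- is.finite(z$values) & z$values >= z_threshold
  if (!any(mask)) {
    warning("no cell reaches the hotspot threshold; empty source set")
    out <- tibble::tibble(id = integer(), n_cells = integer(), area_km2 = numeric(),
                          geometry = list(), cells = list(),
                          centre_row = integer(), centre_col = integer(),
                          centre_x = numeric(), centre_y = numeric())
    return(as_source_set(out, z))
  }
  labels <- label_components(mask)
  patches <- polygonize_labels(z, labels)
  patches <- patches[patches$area_km2 >= min_area_km2, , drop = FALSE]
  if (nrow(patches)) {
    cen <- lapply(patches$cells, function(cells) {
      zs <- z$values[cells]
      best <- which(zs == max(zs))
      if (length(best) > 1L) {
        ctr <- colMeans(cells)
        d2 <- (cells[best, 1] - ctr[1])^2 + (cells[best, 2] - ctr[2])^2
        best <- best[which.min(d2)]
      }
      cells[best, ]
    })
    patches$centre_row <- vapply(cen, `[[`, integer(1), 1L)
    patches$centre_col <- vapply(cen, `[[`, integer(1), 2L)
    cc <- cell_centres(z, patches$centre_row, patches$centre_col)
    patches$centre_x <- cc$x
    patches$centre_y <- cc$y
    if (!is.null(richness)) {
      check_aligned(z, richness, what = "z and richness")
      patches$dominant_service_count <-
        vapply(patches$cells, function(cl) max(richness$values[cl], na.rm = TRUE),
               numeric(1))
    }
    patches$id <- seq_len(nrow(patches))
  } else {
    warning("all hotspot patches fall below the minimum area; empty source set")
    patches$centre_row <- integer(); patches$centre_col <- integer()
    patches$centre_x <- numeric(); patches$centre_y <- numeric()
  }
  as_source_set(patches, z)
}

as_source_set <- function(tbl, template) {
  attr(tbl, "template") <- template
  class(tbl) <- c("source_set", class(tbl))
  tbl
}

#' Convert a source set to point/polygon features for [write_vector()]
#' @param sources A `source_set`.
#' @param what `"polygons"` or `"centres"`.
#' @return A feature tibble with a `geometry` list-column.
#' @export
source_features <- function(sources, what = c("polygons", "centres")) {
  what <- match.arg(what)
  if (what == "polygons")
    return(tibble::tibble(id = sources$id, area_km2 = sources$area_km2,
                          geometry = sources$geometry))
  tibble::tibble(
    id = sources$id,
    geometry = lapply(seq_len(nrow(sources)), function(i)
      list(type = "Point",
           coordinates = c(sources$centre_x[i], sources$centre_y[i]))))
}
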
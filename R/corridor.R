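#' Weighted kernel density surface of pheromone points
#'
#' Smooths the filtered pheromone points into a density raster. The default
#' kernel is the quartic (biweight) kernel conventional in GIS kernel
#' density tools, `K(d) = 3/(pi h^2) (1 - (d/h)^2)^2` for `d < h`; a
#' Gaussian kernel (sd = bandwidth, truncated at 4 sd) is selectable. The
#' raster integrates to the total point weight up to edge losses, which are
#' reported as an attribute.
#'
#' @param points Tibble with `x`, `y`, `weight` (e.g. from
#'   [filter_pheromone_points()]).
#' @param bandwidth_m Kernel bandwidth in metres (>= one cell).
#' @param template [grid_raster] defining the output grid.
#' @param kernel `"quartic"` or `"gaussian"`.
#' @return [grid_raster] of density (weight per m^2) with attribute
#'   `edge_loss` (fraction of mass lost off-grid).
#' @export
kernel_density <- function(points, bandwidth_m, template,
                           kernel = c("quartic", "gaussian")) {
  kernel <- match.arg(kernel)
  if (nrow(points) == 0) stop("empty point set", call. = FALSE)
  cs <- template$cell_size
  if (bandwidth_m < cs) stop("bandwidth must be at least one cell", call. = FALSE)
  nr <- nrow(template$values); nc <- ncol(template$values)
  h <- bandwidth_m
  rad <- if (kernel == "quartic") ceiling(h / cs) else ceiling(4 * h / cs)
  offs <- expand.grid(dr = -rad:rad, dc = -rad:rad)
  dens <- matrix(0, nr, nc)
  at <- cell_at(template, points$x, points$y)
  for (i in seq_len(nrow(points))) {
    r0 <- at$row[i]; c0 <- at$col[i]
    if (is.na(r0)) next
    # true distances from the point to candidate cell centres
    rr2 <- r0 + offs$dr; cc2 <- c0 + offs$dc
    px <- template$origin[1] + (cc2 - 0.5) * cs
    py <- template$origin[2] - (rr2 - 0.5) * cs
    d <- sqrt((px - points$x[i])^2 + (py - points$y[i])^2)
    k <- if (kernel == "quartic") {
      ifelse(d < h, 3 / (pi * h^2) * (1 - (d / h)^2)^2, 0)
    } else {
      exp(-d^2 / (2 * h^2)) / (2 * pi * h^2)
    }
    ok <- rr2 >= 1 & cc2 >= 1 & rr2 <= nr & cc2 <= nc & k > 0
    idx <- cbind(rr2[ok], cc2[ok])
    dens[idx] <- dens[idx] + points$weight[i] * k[ok]
  }
  out <- raster_like(template, dens)
  total <- sum(points$weight)
  attr(out, "edge_loss") <- max(0, 1 - sum(dens) * cs^2 / total)
  out
}

#' Quantile classification of a density surface
#'
#' Splits the positive-density cells into `n_classes` equal-count classes,
#' 1 = sparsest to `n_classes` = densest; ties go to the higher class and
#' zero-density cells stay unclassed (NA). Classes depend only on ranks.
#'
#' @param density [grid_raster] of density.
#' @param n_classes Number of grades (default 9).
#' @return [grid_raster] of integer classes.
#' @export
quantile_classes <- function(density, n_classes = 9) {
  v <- density$values
  pos <- which(is.finite(v) & v > 0)
  if (!length(pos)) stop("all-zero density surface", call. = FALSE)
  vals <- v[pos]
  if (length(unique(vals)) < n_classes)
    warning(sprintf("fewer than %d distinct positive values: classes collapse",
                    n_classes))
  rk <- rank(vals, ties.method = "max")
  cls <- ceiling(rk * n_classes / length(vals))
  out <- matrix(NA_real_, nrow(v), ncol(v))
  out[pos] <- cls
  raster_like(density, out)
}

#' Delineate main and potential corridor extents
#'
#' The main corridor is the polygonized union of cells in the three top
#' density grades (class >= `main_min_class` of 9, 8-connected); the
#' potential corridor is the remainder of the search region, the area the
#' ants could roam without concentrating. If no cell reaches the main
#' grades the corridor is flagged unsupported.
#'
#' @param classes [grid_raster] from [quantile_classes()].
#' @param region [grid_raster] search-region mask.
#' @param centreline The corridor's `lcp_path`.
#' @param main_min_class Lowest grade counted as main (default 7).
#' @return A `corridor_set`: list with `main` polygon tibble, `main_mask`,
#'   `potential_mask` rasters, `main_area_km2`, `potential_area_km2`,
#'   `centreline`, `unsupported` flag.
#' @export
delineate_corridors <- function(classes, region, centreline, main_min_class = 7) {
  check_aligned(classes, region, what = "classes and region")
  regm <- region$values != 0 & is.finite(region$values)
  main <- regm & is.finite(classes$values) & classes$values >= main_min_class
  unsupported <- !any(main)
  if (unsupported)
    warning("no cell reaches the main corridor grades: corridor unsupported")
  labels <- label_components(main)
  polys <- polygonize_labels(classes, labels)
  pot <- regm & !main
  structure(
    list(main = polys,
         main_mask = raster_like(classes, matrix(as.numeric(main),
                                                 nrow(main), ncol(main))),
         potential_mask = raster_like(classes, matrix(as.numeric(pot),
                                                      nrow(pot), ncol(pot))),
         main_area_km2 = mask_area_km2(classes, main),
         potential_area_km2 = mask_area_km2(classes, pot),
         classes = classes, region = region, centreline = centreline,
         unsupported = unsupported),
    class = "corridor_set")
}

#' @export
print.corridor_set <- function(x, ...) {
  cat(sprintf("<corridor_set> main %.4g km^2 (%d patches), potential %.4g km^2%s\n",
              x$main_area_km2, nrow(x$main), x$potential_area_km2,
              if (x$unsupported) " [unsupported]" else ""))
  invisible(x)
}

#' Ecological restoration points of a corridor system
#'
#' Emits the key points where corridor continuity breaks:
#' \itemize{
#' \item discontinuities — midpoints of maximal runs (at least
#'   `gap_min_cells` long) of centreline cells not covered by the main
#'   corridor;
#' \item resistance mutations — local maxima of resistance along the
#'   centreline exceeding the search region's `mutation_quantile`;
#' \item intersections — where two corridor centrelines cross outside the
#'   sources.
#' }
#' Points closer than `dedup_m` to an already retained point are dropped.
#'
#' @param corridors A `corridor_set` or list of them.
#' @param resistance [grid_raster] of corrected resistance.
#' @param gap_min_cells Minimum uncovered run length (default 3).
#' @param mutation_quantile Resistance quantile for mutation points
#'   (default 0.9).
#' @param sources Optional `source_set`; centreline cells inside source
#'   polygons are ignored for intersections.
#' @param dedup_m Deduplication distance in metres (default 10 cells).
#' @return Tibble `x`, `y`, `row`, `col`, `kind`, `corridors`.
#' @export
restoration_points <- function(corridors, resistance, gap_min_cells = 3,
                               mutation_quantile = 0.9, sources = NULL,
                               dedup_m = NULL) {
  if (inherits(corridors, "corridor_set")) corridors <- list(corridors)
  cs <- resistance$cell_size
  if (is.null(dedup_m)) dedup_m <- 10 * cs
  pts <- tibble::tibble(x = numeric(), y = numeric(), row = integer(),
                        col = integer(), kind = character(),
                        corridors = character())
  add <- function(row, col, kind, ids) {
    cc <- cell_centres(resistance, row, col)
    tibble::tibble(x = cc$x, y = cc$y, row = as.integer(row),
                   col = as.integer(col), kind = kind,
                   corridors = paste(ids, collapse = "+"))
  }
  src_cells <- character(0)
  if (!is.null(sources) && nrow(sources))
    src_cells <- unlist(lapply(sources$cells, function(m)
      paste(m[, 1], m[, 2])))
  for (ci in seq_along(corridors)) {
    cor <- corridors[[ci]]
    cells <- cor$centreline$cells
    covered <- cor$main_mask$values[cbind(cells$row, cells$col)] != 0
    # discontinuities: maximal uncovered runs
    r <- rle(!covered)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in seq_along(r$values)) {
      if (r$values[k] && r$lengths[k] >= gap_min_cells) {
        mid <- starts[k] + (r$lengths[k] - 1L) %/% 2L
        pts <- rbind(pts, add(cells$row[mid], cells$col[mid],
                              "discontinuity", ci))
      }
    }
    # resistance mutation points along the centreline
    regm <- cor$region$values != 0
    cut <- stats::quantile(resistance$values[regm & is.finite(resistance$values)],
                           mutation_quantile, names = FALSE)
    rv <- resistance$values[cbind(cells$row, cells$col)]
    n <- length(rv)
    if (n >= 3) for (k in 2:(n - 1)) {
      if (is.finite(rv[k]) && rv[k] > rv[k - 1] && rv[k] > rv[k + 1] &&
          rv[k] > cut)
        pts <- rbind(pts, add(cells$row[k], cells$col[k],
                              "resistance_mutation", ci))
    }
  }
  # intersections between centrelines, outside sources
  if (length(corridors) >= 2) {
    keys <- lapply(corridors, function(cor)
      paste(cor$centreline$cells$row, cor$centreline$cells$col))
    for (a in seq_along(corridors)) for (b in seq_len(a - 1L)) {
      shared <- setdiff(intersect(keys[[a]], keys[[b]]), src_cells)
      if (!length(shared)) next
      rc <- do.call(rbind, strsplit(shared, " "))
      rows <- as.integer(rc[, 1]); cols <- as.integer(rc[, 2])
      # one point per 8-connected cluster of shared cells
      m <- matrix(FALSE, nrow(resistance$values), ncol(resistance$values))
      m[cbind(rows, cols)] <- TRUE
      lab <- label_components(m)
      for (id in setdiff(unique(lab[lab > 0]), 0)) {
        cl <- which(lab == id, arr.ind = TRUE)
        ctr <- round(colMeans(cl))
        best <- which.min((cl[, 1] - ctr[1])^2 + (cl[, 2] - ctr[2])^2)
        pts <- rbind(pts, add(cl[best, 1], cl[best, 2], "intersection",
                              c(b, a)))
      }
    }
  }
  if (nrow(pts) <= 1) return(pts)
  keep <- rep(TRUE, nrow(pts))
  for (i in 2:nrow(pts)) {
    prev <- which(keep[seq_len(i - 1L)])
    d <- sqrt((pts$x[prev] - pts$x[i])^2 + (pts$y[prev] - pts$y[i])^2)
    if (any(d < dedup_m)) keep[i] <- FALSE
  }
  pts[keep, ]
}

#' Restoration points as features for [write_vector()]
#' @param points Tibble from [restoration_points()].
#' @return Feature tibble.
#' @export
restoration_features <- function(points) {
  tibble::tibble(
    kind = points$kind, corridors = points$corridors,
    geometry = lapply(seq_len(nrow(points)), function(i)
      list(type = "Point", coordinates = c(points$x[i], points$y[i]))))
}
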
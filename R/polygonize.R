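# Connected components and cell-mask polygonization shared by the source
# and corridor modules.

#' Label 8-connected components of a logical mask
#'
#' @param mask Logical matrix.
#' @return Integer matrix: 0 outside the mask, component id (1..k) inside.
#' @export
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  mask[is.na(mask)] <- FALSE
  lab <- matrix(0L, nr, nc)
  idx <- which(mask)
  if (!length(idx)) return(lab)
  stack <- integer(length(idx))
  k <- 0L
  for (s in idx) {
    if (lab[s] != 0L) next
    k <- k + 1L
    top <- 1L; stack[1L] <- s; lab[s] <- k
    while (top > 0L) {
      cur <- stack[top]; top <- top - 1L
      r <- (cur - 1L) %% nr + 1L
      cl <- (cur - 1L) %/% nr + 1L
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; cc <- cl + dc
        if (rr < 1L || cc < 1L || rr > nr || cc > nc) next
        j <- (cc - 1L) * nr + rr
        if (mask[j] && lab[j] == 0L) {
          lab[j] <- k
          top <- top + 1L; stack[top] <- j
        }
      }
    }
  }
  lab
}

# Dissolve one labelled component into a MultiPolygon of row-run rectangles
# (area-exact union of the cell squares).
component_multipolygon <- function(raster, labels, id) {
  cs <- raster$cell_size
  x0 <- raster$origin[1]; y0 <- raster$origin[2]
  cells <- which(labels == id, arr.ind = TRUE)
  polys <- list()
  for (r in sort(unique(cells[, 1]))) {
    cols <- sort(cells[cells[, 1] == r, 2])
    runs <- split(cols, cumsum(c(1L, diff(cols) != 1L)))
    for (run in runs) {
      xl <- x0 + (min(run) - 1) * cs; xr <- x0 + max(run) * cs
      yt <- y0 - (r - 1) * cs; yb <- y0 - r * cs
      ring <- rbind(c(xl, yb), c(xr, yb), c(xr, yt), c(xl, yt), c(xl, yb))
      polys[[length(polys) + 1L]] <- list(ring)
    }
  }
  list(type = "MultiPolygon", coordinates = polys)
}

# Tibble of polygonized components: id, n_cells, area_km2, geometry, cells.
polygonize_labels <- function(raster, labels) {
  ids <- sort(unique(labels[labels > 0L]))
  tibble::tibble(
    id = ids,
    n_cells = vapply(ids, function(i) sum(labels == i), integer(1)),
    area_km2 = vapply(ids, function(i) sum(labels == i) * raster$cell_size^2 / 1e6,
                      numeric(1)),
    geometry = lapply(ids, function(i) component_multipolygon(raster, labels, i)),
    cells = lapply(ids, function(i) which(labels == i, arr.ind = TRUE))
  )
}
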
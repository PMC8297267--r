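#' Read a raster layer from an ESRI ASCII grid
#'
#' Rasters are exchanged as ESRI ASCII grids (`.asc`), the plain-text GIS
#' raster format, with the CRS carried in a `.prj` sidecar file next to the
#' grid. A layer without a CRS sidecar is refused: every downstream distance
#' computation assumes a projected CRS in metres.
#'
#' @param path Path to an `.asc` file.
#' @return A [grid_raster].
#' @export
read_raster <- function(path) {
  if (!file.exists(path))
    stop(sprintf("raster file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  i <- 1L
  while (i <= length(lines) && grepl("^[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr)))
    stop(sprintf("not an ESRI ASCII grid (missing header): %s", path), call. = FALSE)
  prj <- sub("\\.[^.]*$", ".prj", path)
  if (!file.exists(prj))
    stop(sprintf("layer has no CRS: expected sidecar %s", prj), call. = FALSE)
  crs <- trimws(readLines(prj, warn = FALSE)[1])
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               what = double(), quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows)
    stop(sprintf("corrupt grid %s: expected %d values, found %d",
                 path, hdr$ncols * hdr$nrows, length(vals)), call. = FALSE)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m[m == nodata] <- NA_real_
  # header may be corner- or centre-registered; both give the same NW corner
  xll <- if (!is.null(hdr$xllcorner)) hdr$xllcorner else hdr$xllcenter - hdr$cellsize / 2
  yll <- if (!is.null(hdr$yllcorner)) hdr$yllcorner else hdr$yllcenter - hdr$cellsize / 2
  grid_raster(m, hdr$cellsize,
              origin = c(xll, yll + hdr$nrows * hdr$cellsize),
              crs = crs, nodata = nodata)
}

#' Write a raster layer as an ESRI ASCII grid
#'
#' @param raster A [grid_raster].
#' @param path Output path (`.asc`); a `.prj` sidecar is written alongside.
#' @return `path`, invisibly.
#' @export
write_raster <- function(raster, path) {
  stopifnot(inherits(raster, "grid_raster"))
  dir <- dirname(path)
  if (!dir.exists(dir))
    stop(sprintf("parent directory does not exist: %s", dir), call. = FALSE)
  if (file.access(dir, 2) != 0)
    stop(sprintf("directory not writable: %s", dir), call. = FALSE)
  v <- raster$values
  nr <- nrow(v); nc <- ncol(v)
  hdr <- c(
    sprintf("ncols %d", nc),
    sprintf("nrows %d", nr),
    sprintf("xllcorner %.10g", raster$origin[1]),
    sprintf("yllcorner %.10g", raster$origin[2] - nr * raster$cell_size),
    sprintf("cellsize %.10g", raster$cell_size),
    sprintf("NODATA_value %.10g", raster$nodata)
  )
  v[!is.finite(v)] <- raster$nodata
  body <- apply(v, 1L, function(r) paste(sprintf("%.17g", r), collapse = " "))
  writeLines(c(hdr, body), path)
  writeLines(raster$crs, sub("\\.[^.]*$", ".prj", path))
  invisible(path)
}

#' Align a named list of rasters onto a common grid
#'
#' Resamples every layer onto the grid of a reference layer: categorical
#' layers by nearest neighbour (no new class values can appear), continuous
#' layers bilinearly. Layers already on the reference grid pass through
#' unchanged, so the operation is idempotent. All layers must share a CRS;
#' no reprojection engine is bundled.
#'
#' @param rasters Named list of [grid_raster] objects.
#' @param reference Name or index of the reference layer (default: first).
#' @param categorical Character vector naming the categorical layers.
#' @return A named list of aligned rasters (a factor stack).
#' @export
align_stack <- function(rasters, reference = 1L, categorical = character()) {
  if (length(rasters) == 0) stop("empty raster list", call. = FALSE)
  if (is.null(names(rasters)) || anyDuplicated(names(rasters)))
    stop("rasters must be uniquely named", call. = FALSE)
  ref <- rasters[[reference]]
  crss <- vapply(rasters, function(r) r$crs, "")
  if (length(unique(crss)) > 1)
    stop("layers have differing CRS and no reprojection engine is available: ",
         paste(unique(crss), collapse = ", "), call. = FALSE)
  out <- lapply(names(rasters), function(nm) {
    r <- rasters[[nm]]
    if (same_grid(r, ref)) return(r)
    resample_onto(r, ref,
                  method = if (nm %in% categorical) "nearest" else "bilinear")
  })
  names(out) <- names(rasters)
  out
}

# Resample `r` onto the grid of `ref` (same CRS assumed).
resample_onto <- function(r, ref, method = c("nearest", "bilinear")) {
  method <- match.arg(method)
  nrr <- nrow(ref$values); ncr <- ncol(ref$values)
  ctr <- cell_centres(ref, rep(seq_len(nrr), ncr), rep(seq_len(ncr), each = nrr))
  # fractional source indices (1-based, value at cell centre)
  fc <- (ctr$x - r$origin[1]) / r$cell_size + 0.5
  fr <- (r$origin[2] - ctr$y) / r$cell_size + 0.5
  nr <- nrow(r$values); nc <- ncol(r$values)
  inside <- fr >= 0.5 & fr <= nr + 0.5 & fc >= 0.5 & fc <= nc + 0.5
  if (!any(inside))
    stop("no spatial overlap between layer and reference grid", call. = FALSE)
  v <- rep(NA_real_, nrr * ncr)
  if (method == "nearest") {
    ri <- pmin(pmax(round(fr), 1), nr); ci <- pmin(pmax(round(fc), 1), nc)
    v[inside] <- r$values[cbind(ri, ci)][inside]
  } else {
    r0 <- pmin(pmax(floor(fr), 1), nr - 1); c0 <- pmin(pmax(floor(fc), 1), nc - 1)
    wr <- pmin(pmax(fr - r0, 0), 1); wc <- pmin(pmax(fc - c0, 0), 1)
    g <- function(i, j) r$values[cbind(i, j)]
    v[inside] <- ((1 - wr) * (1 - wc) * g(r0, c0) + (1 - wr) * wc * g(r0, c0 + 1) +
                    wr * (1 - wc) * g(r0 + 1, c0) + wr * wc * g(r0 + 1, c0 + 1))[inside]
  }
  raster_like(ref, matrix(v, nrr, ncr))
}

# ---- vector I/O (GeoJSON) ---------------------------------------------------

#' Write point/polygon/line features to GeoJSON
#'
#' Features are a tibble with a `geometry` list-column; each element is a
#' list with `type` (`"Point"`, `"LineString"`, `"Polygon"`, `"MultiPolygon"`)
#' and `coordinates` (numeric vector, matrix, or list of ring matrices in
#' GeoJSON nesting). All other columns become feature properties.
#'
#' @param features Tibble with a `geometry` list-column (may have zero rows).
#' @param path Output `.geojson` path.
#' @param crs CRS string recorded as a foreign member.
#' @param repair Repair invalid (self-intersecting) polygon rings by taking
#'   their convex hull; if `FALSE` (default) such rings are an error.
#' @return `path`, invisibly.
#' @export
write_vector <- function(features, path, crs = "EPSG:32648", repair = FALSE) {
  stopifnot(is.data.frame(features))
  props <- setdiff(names(features), "geometry")
  feats <- lapply(seq_len(nrow(features)), function(i) {
    geom <- features$geometry[[i]]
    geom <- validate_geometry(geom, repair = repair)
    p <- lapply(props, function(nm) features[[nm]][[i]])
    names(p) <- props
    list(type = "Feature", properties = p, geometry = geojson_geometry(geom))
  })
  fc <- list(type = "FeatureCollection", crs = crs, features = feats)
  writeLines(jsonlite::toJSON(fc, auto_unbox = TRUE, digits = 10, null = "null"),
             path)
  invisible(path)
}

geojson_geometry <- function(geom) {
  co <- geom$coordinates
  wrap <- function(m) lapply(seq_len(nrow(m)), function(i) as.numeric(m[i, ]))
  co <- switch(geom$type,
    Point = as.numeric(co),
    LineString = wrap(co),
    Polygon = lapply(co, wrap),
    MultiPolygon = lapply(co, function(poly) lapply(poly, wrap)),
    stop("unsupported geometry type: ", geom$type, call. = FALSE))
  list(type = geom$type, coordinates = co)
}

validate_geometry <- function(geom, repair = FALSE) {
  if (geom$type != "Polygon") return(geom)
  geom$coordinates <- lapply(geom$coordinates, function(ring) {
    ring <- as.matrix(ring)
    if (!all(ring[1, ] == ring[nrow(ring), ]))
      ring <- rbind(ring, ring[1, , drop = FALSE])
    if (ring_self_intersects(ring)) {
      if (!repair)
        stop("invalid geometry: self-intersecting polygon ring (set repair = TRUE)",
             call. = FALSE)
      h <- grDevices::chull(ring[-nrow(ring), 1], ring[-nrow(ring), 2])
      ring <- ring[c(h, h[1]), , drop = FALSE]
    }
    ring
  })
  geom
}

# O(n^2) proper-crossing test between non-adjacent edges of a closed ring.
ring_self_intersects <- function(ring) {
  n <- nrow(ring) - 1L
  if (n < 4L) return(FALSE)
  seg <- function(i) list(p = ring[i, ], q = ring[i + 1L, ])
  crossdir <- function(o, a, b) (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  for (i in seq_len(n - 2L)) {
    for (j in seq.int(i + 2L, n)) {
      if (i == 1L && j == n) next  # adjacent through closure
      s1 <- seg(i); s2 <- seg(j)
      d1 <- crossdir(s1$p, s1$q, s2$p); d2 <- crossdir(s1$p, s1$q, s2$q)
      d3 <- crossdir(s2$p, s2$q, s1$p); d4 <- crossdir(s2$p, s2$q, s1$q)
      if (((d1 > 0) != (d2 > 0)) && ((d3 > 0) != (d4 > 0)) &&
          d1 != 0 && d2 != 0 && d3 != 0 && d4 != 0) return(TRUE)
    }
  }
  FALSE
}

#' Read a GeoJSON file written by [write_vector()]
#'
#' @param path A `.geojson` path.
#' @return A tibble with property columns and a `geometry` list-column.
#' @export
read_vector <- function(path) {
  if (!file.exists(path)) stop(sprintf("vector file not found: %s", path), call. = FALSE)
  fc <- jsonlite::fromJSON(readLines(path, warn = FALSE), simplifyVector = FALSE)
  feats <- fc$features
  unwrap <- function(co) do.call(rbind, lapply(co, as.numeric))
  geoms <- lapply(feats, function(f) {
    g <- f$geometry
    co <- switch(g$type,
      Point = as.numeric(g$coordinates),
      LineString = unwrap(g$coordinates),
      Polygon = lapply(g$coordinates, unwrap),
      MultiPolygon = lapply(g$coordinates, function(p) lapply(p, unwrap)),
      stop("unsupported geometry type: ", g$type, call. = FALSE))
    list(type = g$type, coordinates = co)
  })
  prop_names <- unique(unlist(lapply(feats, function(f) names(f$properties))))
  out <- tibble::tibble(.rows = length(feats))
  for (nm in prop_names) {
    vals <- lapply(feats, function(f) f$properties[[nm]])
    if (all(vapply(vals, function(v) is.null(v) || is.numeric(v), TRUE)))
      out[[nm]] <- vapply(vals, function(v) if (is.null(v)) NA_real_ else as.numeric(v), numeric(1))
    else
      out[[nm]] <- vapply(vals, function(v) if (is.null(v)) NA_character_ else as.character(v), character(1))
  }
  out$geometry <- geoms
  out
}
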
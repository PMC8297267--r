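#' Specification of a synthetic karst mountain landscape
#'
#' Defines the study conditions for a generated landscape: a spatially
#' autocorrelated mountain terrain with a karst/non-karst split, a patchy
#' land-cover mosaic, elevated sensitivity indices inside the karst region,
#' a set of disjoint ecological source patches on low-resistance terrain,
#' and optionally planted low-resistance channels between sources that act
#' as known corridors for recovery experiments.
#'
#' Defaults: a 200 x 200 grid of 100 m cells (a 20 km x 20 km mountain
#' county subregion), 3 sources, karst over three quarters of the area (the
#' typical karst-county share), one planted channel of 9 cells (900 m)
#' width between sources 1 and 2, and noise with a 15-cell autocorrelation
#' length.
#'
#' @param shape `c(rows, cols)`, at least 20 x 20.
#' @param cell_size Cell size in metres.
#' @param seed Integer seed fixing all randomness.
#' @param n_sources Number of source patches.
#' @param channels List of channels, each `list(from, to, width_cells,
#'   level)` with `from`/`to` source indices and `level` the target basic
#'   resistance regime of the channel floor.
#' @param karst_fraction Proportion of the area flagged karst.
#' @param noise `list(length, amplitude)`: autocorrelation length in cells
#'   and amplitude multiplier of the random fields.
#' @param source_separation Minimum centre separation in cells between
#'   sources; default one third of the shorter grid side (at least 10) so
#'   corridors are long relative to their width.
#' @return A `landscape_spec` list.
#' @export
landscape_spec <- function(shape = c(200, 200), cell_size = 100, seed = 1,
                           n_sources = 3,
                           channels = list(list(from = 1, to = 2,
                                                width_cells = 9, level = "low")),
                           karst_fraction = 0.75,
                           noise = list(length = 15, amplitude = 1),
                           source_separation = NULL) {
  stopifnot(length(shape) == 2, all(shape >= 20), cell_size > 0,
            karst_fraction >= 0, karst_fraction <= 1, n_sources >= 1)
  if (is.null(source_separation))
    source_separation <- max(10L, round(min(shape) / 3))
  structure(list(shape = as.integer(shape), cell_size = cell_size,
                 seed = as.integer(seed), n_sources = as.integer(n_sources),
                 channels = channels, karst_fraction = karst_fraction,
                 noise = noise, source_separation = source_separation),
            class = "landscape_spec")
}

# Spatially autocorrelated standard field: Gaussian-filtered white noise,
# reflect-padded at the edges, renormalised to mean 0, sd 1.
smooth_field <- function(nr, nc, len) {
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  if (len >= 1) {
    half <- min(ceiling(3 * len), min(nr, nc) - 1L)  # reflect pad cannot exceed the axis
    k <- stats::dnorm(-half:half, sd = len)
    k <- k / sum(k)
    conv <- function(x) {
      n <- length(x)
      xp <- c(rev(x[seq_len(half)]), x, rev(x[seq.int(n - half + 1, n)]))
      as.numeric(stats::filter(xp, k, sides = 2))[half + seq_len(n)]
    }
    z <- apply(z, 2L, conv)
    z <- t(apply(z, 1L, conv))
  }
  (z - mean(z)) / stats::sd(z)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Generate a synthetic landscape
#'
#' Produces the six aligned resistance-factor rasters (altitude and slope
#' spatially autocorrelated, slope derived from the altitude gradient; a
#' patchy land-cover mosaic; carbonate bedrock classes confined to the
#' karst region), three sensitivity rasters (rocky desertification, karst
#' collapse and soil erosion indices, elevated inside the karst region),
#' the source patches, and the planted channel masks. Channels are carved
#' as low-altitude, thin-soil, forest-floored valleys whose basic
#' resistance is strictly below the surrounding terrain, so the
#' minimum-resistance path between their endpoint sources stays inside the
#' channel.
#'
#' @param spec A [landscape_spec()].
#' @return A list with `factors` (named raster list), `sensitivity`
#'   (`rdi`, `kci`, `sei` rasters), `sources` (a `source_set`),
#'   `channel_masks` (list of logical matrices), `karst` mask raster, and
#'   the `spec`.
#' @export
make_landscape <- function(spec) {
  stopifnot(inherits(spec, "landscape_spec"))
  nr <- spec$shape[1]; nc <- spec$shape[2]
  cs <- spec$cell_size
  len <- spec$noise$length; amp <- spec$noise$amplitude
  set.seed(spec$seed)
  f <- replicate(8, smooth_field(nr, nc, len), simplify = FALSE)

  tmpl <- grid_raster(matrix(0, nr, nc), cs)
  # terrain: mountain elevations, floor above the lowest altitude class so
  # planted channels can undercut every natural cell
  altitude <- clamp(1280 + 400 * amp * f[[1]], 850, 2400)
  gx <- (cbind(altitude[, -1], altitude[, nc]) -
           cbind(altitude[, 1], altitude[, -nc])) / (2 * cs)
  gy <- (rbind(altitude[-1, ], altitude[nr, ]) -
           rbind(altitude[1, ], altitude[-nr, ])) / (2 * cs)
  slope <- atan(sqrt(gx^2 + gy^2)) * 180 / pi

  karst <- f[[2]] > stats::quantile(f[[2]], 1 - spec$karst_fraction)
  vegetation <- clamp(55 + 25 * amp * f[[3]] - 15 * karst, 0, 100)
  soil <- clamp(25 + 15 * amp * f[[4]] - 12 * karst, 1, 60)

  bedrock <- matrix(1, nr, nc)                     # non-carbonate
  if (any(karst)) {
    sub <- f[[5]][karst]
    qs <- stats::quantile(sub, c(0.25, 0.5, 0.8))
    code <- 2L + findInterval(sub, qs)             # limestone .. clastic mix
    bedrock[karst] <- code
  }

  lc <- matrix(2, nr, nc)                          # grassland default
  lc[f[[6]] > 0.2 | slope > 25] <- 1               # forest on rough/high-noise
  lc[f[[6]] < -0.4 & slope < 15] <- 4              # cultivated valley floors
  lc[f[[7]] > 1.6] <- 3                            # garden pockets
  lc[f[[7]] < -1.9] <- 5                           # waters
  lc[f[[8]] > 1.9 & slope < 15] <- 8               # construction

  rdi <- clamp(0.12 + 0.55 * karst + 0.12 * amp * f[[6]] + 0.1 * (1 - vegetation / 100), 0, 1)
  kci <- clamp(0.10 + 0.50 * karst + 0.15 * amp * f[[7]], 0, 1)
  sei <- clamp(0.15 + 0.35 * karst + 0.15 * amp * f[[8]] + 0.1 * slope / 45, 0, 1)

  factors <- list(
    land_cover = raster_like(tmpl, lc),
    slope = raster_like(tmpl, slope),
    altitude = raster_like(tmpl, altitude),
    vegetation = raster_like(tmpl, vegetation),
    soil_thickness = raster_like(tmpl, soil),
    bedrock = raster_like(tmpl, bedrock))

  # place sources greedily on low-resistance terrain with a minimum
  # pairwise separation
  table <- default_resistance_table()
  classified <- mapply(classify_factor, factors, table, SIMPLIFY = FALSE)
  weights <- vapply(table, `[[`, numeric(1), "weight")
  base <- base_resistance(classified, weights)
  ord <- order(base$values)
  centres <- matrix(0L, 0, 2)
  sep2 <- spec$source_separation^2
  margin <- 4L
  for (i in ord) {
    r <- (i - 1L) %% nr + 1L; c2 <- (i - 1L) %/% nr + 1L
    if (r <= margin || c2 <= margin || r > nr - margin || c2 > nc - margin) next
    if (nrow(centres) &&
        any((centres[, 1] - r)^2 + (centres[, 2] - c2)^2 < sep2)) next
    centres <- rbind(centres, c(r, c2))
    if (nrow(centres) == spec$n_sources) break
  }
  if (nrow(centres) < spec$n_sources)
    stop(sprintf(paste("could not place %d disjoint sources at separation %d;",
                       "shrink n_sources or source_separation"),
                 spec$n_sources, spec$source_separation), call. = FALSE)

  # carve channels between source centres
  channel_masks <- list()
  for (ch in spec$channels) {
    a <- centres[ch$from, ]; b <- centres[ch$to, ]
    mask <- segment_band_mask(nr, nc, a, b, ch$width_cells)
    channel_masks[[length(channel_masks) + 1L]] <- mask
    factors$land_cover$values[mask] <- 1
    factors$altitude$values[mask] <- 700
    factors$slope$values[mask] <- 5
    factors$vegetation$values[mask] <- 20
    factors$soil_thickness$values[mask] <- 5
    factors$bedrock$values[mask] <- 1
    rdi[mask] <- 0.05; kci[mask] <- 0.05; sei[mask] <- 0.05
  }

  # source patches: 5x5 squares around the centres (disjoint by separation)
  labels <- matrix(0L, nr, nc)
  for (k in seq_len(nrow(centres))) {
    rs <- clamp(centres[k, 1] + (-2:2), 1, nr)
    cc <- clamp(centres[k, 2] + (-2:2), 1, nc)
    labels[rs, cc] <- k
  }
  patches <- polygonize_labels(tmpl, labels)
  patches$centre_row <- centres[, 1]
  patches$centre_col <- centres[, 2]
  ctr <- cell_centres(tmpl, centres[, 1], centres[, 2])
  patches$centre_x <- ctr$x; patches$centre_y <- ctr$y

  list(factors = factors,
       sensitivity = list(rdi = raster_like(tmpl, rdi),
                          kci = raster_like(tmpl, kci),
                          sei = raster_like(tmpl, sei)),
       sources = as_source_set(patches, tmpl),
       channel_masks = channel_masks,
       karst = raster_like(tmpl, matrix(as.numeric(karst), nr, nc)),
       spec = spec)
}

# Logical mask of cells within width/2 cells of the segment a-b (cell space).
segment_band_mask <- function(nr, nc, a, b, width_cells) {
  rc <- expand.grid(row = seq_len(nr), col = seq_len(nc))
  ab <- c(b[1] - a[1], b[2] - a[2])
  len2 <- sum(ab^2)
  t <- ((rc$row - a[1]) * ab[1] + (rc$col - a[2]) * ab[2]) / len2
  t <- clamp(t, 0, 1)
  dr <- rc$row - (a[1] + t * ab[1]); dc <- rc$col - (a[2] + t * ab[2])
  matrix(sqrt(dr^2 + dc^2) <= width_cells / 2, nr, nc)
}

#' Fig-7-style local resistance regimes for behavioural tests
#'
#' Builds a resistance raster realising one of five local regimes a
#' corridor can encounter, plus the start/end terminals (mid-row, near the
#' left and right edges):
#' \describe{
#' \item{a}{corridor band uniformly high (80) in a moderate background (30);}
#' \item{b}{corridor band uniformly low (5) in the same background;}
#' \item{c}{low corridor crossing a high band (90) that has exactly one
#'   low-resistance gap;}
#' \item{d}{uniform low field (10) abutting a high block (90) that
#'   straddles the straight line between the terminals;}
#' \item{e}{fragmented mosaic of high patches (80) separated by low seams
#'   (10).}
#' }
#'
#' @param kind One of `"a"`..`"e"`.
#' @param shape `c(rows, cols)`, default 80 x 120.
#' @param cell_size Metres per cell.
#' @param seed Unused for the deterministic constructions; kept so callers
#'   can treat all scenario builders uniformly.
#' @return List with `resistance` raster, `start`, `end` cells, and regime
#'   annotations (`corridor_rows`, `wall_cols`, `gap_rows`, `block`,
#'   `seam_mask` where applicable).
#' @export
make_fig7_scenario <- function(kind, shape = c(80, 120), cell_size = 100,
                               seed = 1) {
  kind <- match.arg(kind, c("a", "b", "c", "d", "e"))
  nr <- shape[1]; nc <- shape[2]
  mid <- nr %/% 2
  start <- c(mid, 6L); end <- c(mid, nc - 5L)
  band_rows <- (mid - 4):(mid + 4)
  band_cols <- 6:(nc - 5)
  out <- list(start = start, end = end)
  v <- matrix(30, nr, nc)
  if (kind == "a") {
    v[band_rows, band_cols] <- 80
    out$corridor_rows <- band_rows
  } else if (kind == "b") {
    v[band_rows, band_cols] <- 5
    out$corridor_rows <- band_rows
  } else if (kind == "c") {
    v[band_rows, band_cols] <- 5
    wall_cols <- (nc %/% 2 - 2):(nc %/% 2 + 2)
    gap_rows <- (mid - 2):(mid + 2)
    v[, wall_cols] <- 90
    v[gap_rows, wall_cols] <- 5
    out$corridor_rows <- band_rows
    out$wall_cols <- wall_cols
    out$gap_rows <- gap_rows
  } else if (kind == "d") {
    v[] <- 10
    block <- list(rows = (mid - 15):(mid + 15),
                  cols = (nc %/% 2 - 8):(nc %/% 2 + 8))
    v[block$rows, block$cols] <- 90
    out$block <- block
  } else {
    v[] <- 80
    tile <- 12L; seam <- 4L
    period <- tile + seam
    seam_row <- (((seq_len(nr) - mid) %% period) < seam)
    seam_col <- (((seq_len(nc) - 6L) %% period) < seam)
    v[seam_row, ] <- 10
    v[, seam_col] <- 10
    out$seam_mask <- v == 10
  }
  out$resistance <- grid_raster(v, cell_size)
  out
}

#' Generate aligned ecosystem-service input rasters
#'
#' Produces the per-cell inputs of the five service operators for a
#' synthetic landscape: APAR and light-use efficiency, habitat attribute
#' and degradation, RUSLE factors, annual water-balance terms (mm), NDVI,
#' a cropland mask, a 2 x 2 block of administrative regions and their
#' grain outputs. All fields are deterministic functions of the landscape
#' and of noise seeded from the spec.
#'
#' @param spec A [landscape_spec()].
#' @param landscape Optional pre-built [make_landscape()] output for the
#'   same spec (rebuilt if missing).
#' @return Named list of rasters plus `region_output` (named vector).
#' @export
make_service_stack <- function(spec, landscape = NULL) {
  if (is.null(landscape)) landscape <- make_landscape(spec)
  nr <- spec$shape[1]; nc <- spec$shape[2]
  set.seed(spec$seed + 1L)
  g <- replicate(4, smooth_field(nr, nc, spec$noise$length), simplify = FALSE)
  tmpl <- landscape$factors$altitude
  veg <- landscape$factors$vegetation$values / 100
  lc <- landscape$factors$land_cover$values
  slope <- landscape$factors$slope$values
  karst <- landscape$karst$values > 0

  hj_table <- c(1, 0.7, 0.6, 0.4, 0.9, 0.2, 0.05, 0)
  apar <- clamp(600 + 600 * veg + 120 * g[[1]], 0, Inf)
  eps <- clamp(0.45 + 0.2 * veg + 0.05 * g[[2]], 0.05, 1)
  hab <- matrix(hj_table[lc], nr, nc)
  deg <- clamp(0.25 + 0.3 * karst + 0.15 * g[[3]] + 0.25 * (lc == 8), 0, 1)
  ndvi <- clamp(0.15 + 0.6 * veg + 0.08 * g[[4]], 0, 1)

  c_table <- c(0.003, 0.05, 0.2, 0.35, 0, 0.5, 0.9, 0.9)[lc]
  p_table <- c(1, 1, 0.8, 0.5, 1, 1, 1, 1)[lc]
  ls <- clamp(0.2 + slope / 10, 0.1, 10)

  precip <- clamp(1050 + 120 * g[[1]], 600, 1600)
  et <- clamp(650 + 90 * g[[2]] + 100 * veg, 300, 1200)
  runoff <- clamp(150 + 40 * g[[3]] - 60 * veg, 10, 600)

  region <- matrix(1, nr, nc)
  region[seq_len(nr) > nr / 2, ] <- region[seq_len(nr) > nr / 2, ] + 2
  region[, seq_len(nc) > nc / 2] <- region[, seq_len(nc) > nc / 2] + 1
  crop <- lc == 4
  region_output <- vapply(1:4, function(k) {
    n <- sum(crop & region == k)
    500 * n * (tmpl$cell_size / 100)^2
  }, numeric(1))
  names(region_output) <- as.character(1:4)

  mk <- function(m) raster_like(tmpl, m)
  list(apar = mk(apar), epsilon = mk(eps),
       habitat = mk(hab), degradation = mk(deg),
       k_erod = mk(clamp(0.28 + 0.08 * g[[4]] + 0.05 * karst, 0.05, 0.6)),
       r_eros = mk(clamp(280 + 60 * g[[1]], 50, 600)),
       ls = mk(ls), c_cover = mk(matrix(c_table, nr, nc)),
       p_practice = mk(matrix(p_table, nr, nc)),
       precip = mk(precip), et = mk(et), runoff = mk(runoff),
       ndvi = mk(ndvi),
       cropland_mask = mk(matrix(as.numeric(crop), nr, nc)),
       region_mask = mk(region),
       region_output = region_output)
}
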
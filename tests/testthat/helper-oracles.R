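# Independent oracles used to pin down expected values.

# Exhaustive branch-and-bound enumeration of simple 8-connected paths:
# minimum accumulated cost from a source cell to every cell, step cost
# d * (Ra + Rb) / 2. Independent of the igraph-based implementation.
enumerate_mcr <- function(res, source_rc, cell_size = 1) {
  nr <- nrow(res); nc <- ncol(res)
  best <- matrix(Inf, nr, nc)
  best[source_rc[1], source_rc[2]] <- 0
  visited <- matrix(FALSE, nr, nc)
  recurse <- function(r, c, acc) {
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rr <- r + dr; cc <- c + dc
      if (rr < 1 || cc < 1 || rr > nr || cc > nc) next
      if (visited[rr, cc]) next
      d <- if (dr != 0 && dc != 0) cell_size * sqrt(2) else cell_size
      nacc <- acc + d * (res[r, c] + res[rr, cc]) / 2
      if (nacc >= best[rr, cc]) next      # prune: cannot improve
      best[rr, cc] <<- nacc
      visited[rr, cc] <<- TRUE
      recurse(rr, cc, nacc)
      visited[rr, cc] <<- FALSE
    }
  }
  visited[source_rc[1], source_rc[2]] <- TRUE
  recurse(source_rc[1], source_rc[2], 0)
  best
}

# Direct textbook evaluation of the Gi* statistic with binary distance-band
# weights including self (double loop; no shifting tricks).
brute_gi_star <- function(v, cell_size, radius) {
  nr <- nrow(v); nc <- ncol(v)
  fin <- is.finite(v)
  n <- sum(fin)
  xbar <- mean(v[fin])
  s <- sqrt(sum(v[fin]^2) / n - xbar^2)
  z <- matrix(NA_real_, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!fin[r, c]) next
    sx <- 0; w <- 0
    for (rr in seq_len(nr)) for (cc in seq_len(nc)) {
      if (!fin[rr, cc]) next
      if (((rr - r)^2 + (cc - c)^2) * cell_size^2 <= radius^2) {
        sx <- sx + v[rr, cc]; w <- w + 1
      }
    }
    den <- s * sqrt((n * w - w^2) / (n - 1))
    z[r, c] <- if (den == 0) 0 else (sx - xbar * w) / den
  }
  z
}

# Scalar evaluation of the habitat-quality response.
scalar_habitat_quality <- function(h, d, k, z) h * (1 - d^z / (d^z + k^z))

# Small constant raster helper.
const_raster <- function(value, nr = 3, nc = 3, cell_size = 30) {
  grid_raster(matrix(value, nr, nc), cell_size)
}

# Build a minimal corridor_set by hand (for restoration-point fixtures).
manual_corridor <- function(template, centre_rows, centre_cols, main_mask,
                            region_mask = NULL) {
  if (is.null(region_mask))
    region_mask <- matrix(1, nrow(template$values), ncol(template$values))
  cells <- cell_centres(template, centre_rows, centre_cols)
  path <- structure(list(cells = cells, total_cost = NA_real_,
                         endpoints = c(NA, NA)), class = "lcp_path")
  structure(list(
    main = tibble::tibble(),
    main_mask = raster_like(template, matrix(as.numeric(main_mask),
                                             nrow(main_mask), ncol(main_mask))),
    potential_mask = raster_like(template, 1 - as.numeric(main_mask)),
    main_area_km2 = NA_real_, potential_area_km2 = NA_real_,
    classes = template,
    region = raster_like(template, matrix(as.numeric(region_mask),
                                          nrow(region_mask), ncol(region_mask))),
    centreline = path, unsupported = FALSE), class = "corridor_set")
}
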
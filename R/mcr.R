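# Minimum-cumulative-resistance cost surfaces and least-cost paths.
#
# Accumulated cost follows the standard GIS cost-distance convention: a step
# between adjacent cells costs d * (R_a + R_b) / 2, with d the cell size for
# orthogonal moves and cell size * sqrt(2) for diagonal moves. Any strictly
# increasing transform of accumulated cost leaves the minimising paths
# unchanged, so the monotone link of the MCR formulation is taken as the
# identity.

# 8-neighbour offset table used for backlinks (row, col).
.mcr_offsets <- cbind(
  dr = c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L),
  dc = c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
)

# Build the weighted lattice edge list over finite-resistance cells.
lattice_edges <- function(resistance) {
  v <- resistance$values
  nr <- nrow(v); nc <- ncol(v)
  cs <- resistance$cell_size
  fin <- is.finite(v)
  if (any(v[fin] <= 0))
    stop("resistance must be positive on all traversable cells", call. = FALSE)
  from <- integer(0); to <- integer(0); w <- numeric(0)
  for (off in list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))) {
    dr <- off[1]; dc <- off[2]
    if (max(1L, 1L - dr) > min(nr, nr - dr) ||
        max(1L, 1L - dc) > min(nc, nc - dc)) next
    r1 <- seq.int(max(1L, 1L - dr), min(nr, nr - dr))
    c1 <- seq.int(max(1L, 1L - dc), min(nc, nc - dc))
    a_r <- rep(r1, times = length(c1)); a_c <- rep(c1, each = length(r1))
    b_r <- a_r + dr; b_c <- a_c + dc
    a <- (a_c - 1L) * nr + a_r; b <- (b_c - 1L) * nr + b_r
    ok <- fin[a] & fin[b]
    d <- if (dr != 0L && dc != 0L) cs * sqrt(2) else cs
    from <- c(from, a[ok]); to <- c(to, b[ok])
    w <- c(w, d * (v[a[ok]] + v[b[ok]]) / 2)
  }
  list(from = from, to = to, weight = w, n = nr * nc)
}

cost_from_cells <- function(resistance, seed_cells_list) {
  ed <- lattice_edges(resistance)
  nv <- ed$n
  k <- length(seed_cells_list)
  nr <- nrow(resistance$values)
  virt <- nv + seq_len(k)
  vfrom <- integer(0); vto <- integer(0)
  for (i in seq_len(k)) {
    cells <- seed_cells_list[[i]]
    ids <- (cells[, 2] - 1L) * nr + cells[, 1]
    vfrom <- c(vfrom, rep(virt[i], length(ids))); vto <- c(vto, ids)
  }
  g <- igraph::make_empty_graph(n = nv + k, directed = FALSE)
  g <- igraph::add_edges(g, c(rbind(ed$from, ed$to), rbind(vfrom, vto)))
  wts <- c(ed$weight, rep(0, length(vfrom)))
  d <- igraph::distances(g, v = virt, weights = wts, algorithm = "dijkstra")
  d[, seq_len(nv), drop = FALSE]
}

#' Cost-distance (minimum cumulative resistance) surface
#'
#' For every cell, the minimum over 8-connected paths from any source of
#' the accumulated step costs on the resistance surface. Source cells cost
#' 0; cells disconnected from every source get `Inf` and are counted.
#'
#' @param resistance [grid_raster], positive on traversable cells, NA = barrier.
#' @param sources A `source_set` (its polygon cells seed the accumulation)
#'   or a list of integer `cbind(row, col)` matrices, one per source.
#' @return A `cost_surface`: list with `mcr` raster, `source_id` raster
#'   (nearest source by cost), `backlink` integer raster (predecessor
#'   direction 1..8 into [.mcr_offsets], 0 at sources), `n_unreachable`.
#' @export
cost_distance <- function(resistance, sources) {
  seeds <- if (inherits(sources, "source_set")) sources$cells else sources
  if (length(seeds) < 1L) stop("need at least one source", call. = FALSE)
  seeds <- lapply(seeds, function(s) {
    s <- as.matrix(s); storage.mode(s) <- "integer"; s
  })
  d <- cost_from_cells(resistance, seeds)
  nr <- nrow(resistance$values); nc <- ncol(resistance$values)
  mcr <- apply(d, 2L, min)
  sid <- apply(d, 2L, which.min)
  fin <- is.finite(resistance$values)
  mcr[!fin] <- NA_real_
  sid[!fin | !is.finite(mcr)] <- NA_integer_
  mcr_m <- matrix(mcr, nr, nc)
  out <- structure(
    list(mcr = raster_like(resistance, mcr_m),
         source_id = raster_like(resistance, matrix(as.numeric(sid), nr, nc)),
         backlink = backlink_from_mcr(resistance, mcr_m),
         resistance = resistance,
         n_unreachable = sum(fin & !is.finite(mcr_m))),
    class = "cost_surface")
  out
}

# Predecessor direction per cell: the neighbour through which the
# accumulated cost was achieved (first offset satisfying the relaxation
# identity within tolerance).
backlink_from_mcr <- function(resistance, mcr) {
  v <- resistance$values
  nr <- nrow(v); nc <- ncol(v)
  cs <- resistance$cell_size
  bl <- matrix(0L, nr, nc)
  undecided <- is.finite(mcr) & mcr > 0
  for (k in seq_len(nrow(.mcr_offsets))) {
    if (!any(undecided)) break
    dr <- .mcr_offsets[k, 1]; dc <- .mcr_offsets[k, 2]
    nb_mcr <- shift_na(mcr, dr, dc)
    nb_res <- shift_na(v, dr, dc)
    d <- if (dr != 0L && dc != 0L) cs * sqrt(2) else cs
    step <- d * (v + nb_res) / 2
    hit <- undecided & is.finite(nb_mcr) &
      abs(mcr - (nb_mcr + step)) <= 1e-7 * (1 + abs(mcr))
    bl[hit] <- k
    undecided <- undecided & !hit
  }
  bl
}

shift_na <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(NA_real_, nr, nc)
  if (max(1, 1 - dr) > min(nr, nr - dr) ||
      max(1, 1 - dc) > min(nc, nc - dc)) return(out)
  rs <- max(1, 1 - dr):min(nr, nr - dr)
  cs <- max(1, 1 - dc):min(nc, nc - dc)
  out[rs, cs] <- m[rs + dr, cs + dc]
  out
}

#' Trace the least-cost path from a target back to the source
#'
#' Follows the backlink directions of a [cost_distance()] surface from the
#' target cell down to a zero-cost (source) cell.
#'
#' @param cost A `cost_surface`.
#' @param target Target as `c(x, y)` coordinates, or a 1-row
#'   `cbind(row, col)` matrix.
#' @param endpoints Optional length-2 labels stored on the path.
#' @return An `lcp_path`: list with `cells` tibble (`row`, `col`, `x`, `y`),
#'   `total_cost`, `endpoints`.
#' @export
least_cost_path <- function(cost, target, endpoints = c(NA, NA)) {
  tmpl <- cost$mcr
  if (is.matrix(target)) {
    rc <- c(target[1, 1], target[1, 2])
  } else {
    at <- cell_at(tmpl, target[1], target[2])
    rc <- c(at$row[1], at$col[1])
  }
  if (any(is.na(rc))) stop("target lies outside the grid", call. = FALSE)
  mcr <- tmpl$values
  if (!is.finite(mcr[rc[1], rc[2]]))
    stop("target is unreachable from the sources", call. = FALSE)
  nr <- nrow(mcr)
  rows <- integer(0); cols <- integer(0)
  r <- rc[1]; cl <- rc[2]
  repeat {
    rows <- c(rows, r); cols <- c(cols, cl)
    k <- cost$backlink[r, cl]
    if (k == 0L) break
    r <- r + .mcr_offsets[k, 1]; cl <- cl + .mcr_offsets[k, 2]
    if (length(rows) > length(mcr)) stop("backlink cycle detected", call. = FALSE)
  }
  rows <- rev(rows); cols <- rev(cols)
  cells <- cell_centres(tmpl, rows, cols)
  structure(list(cells = cells,
                 total_cost = mcr[rc[1], rc[2]],
                 endpoints = endpoints),
            class = "lcp_path")
}

#' @export
print.lcp_path <- function(x, ...) {
  cat(sprintf("<lcp_path> %d cells, total cost %.6g\n", nrow(x$cells), x$total_cost))
  invisible(x)
}

#' Least-cost corridor network between source terminals
#'
#' Builds the candidate corridor set as the union of the cost-weighted
#' minimum spanning tree over the source terminals and each terminal's
#' `k_neighbors` nearest-by-cost neighbours, then traces one least-cost
#' path per retained edge. Geometrically duplicate paths (at least 90%
#' shared cells) are merged; sources unreachable from every other source
#' are dropped with a warning.
#'
#' @param resistance [grid_raster] of (corrected) resistance.
#' @param sources A `source_set` with terminal centre cells.
#' @param k_neighbors Nearest-neighbour edges per source (default 2).
#' @return A `corridor_network` tibble: `from`, `to`, `total_cost`,
#'   `path` (list of `lcp_path`).
#' @export
corridor_network <- function(resistance, sources, k_neighbors = 2) {
  k <- nrow(sources)
  if (k < 2L) stop("need at least two sources", call. = FALSE)
  terminals <- lapply(seq_len(k), function(i)
    cbind(row = sources$centre_row[i], col = sources$centre_col[i]))
  surfaces <- lapply(terminals, function(t) cost_distance(resistance, list(t)))
  cost_mat <- matrix(Inf, k, k)
  for (i in seq_len(k)) for (j in seq_len(k)) if (i != j)
    cost_mat[i, j] <- surfaces[[i]]$mcr$values[terminals[[j]][1, 1],
                                               terminals[[j]][1, 2]]
  cost_mat <- (cost_mat + t(cost_mat)) / 2  # symmetrise fp noise
  reachable <- apply(is.finite(cost_mat) | diag(k) == 1, 1L, any)
  unreach <- which(!apply(matrix(is.finite(cost_mat), k, k), 1L, any))
  if (length(unreach)) {
    warning("sources unreachable from all others, excluded: ",
            paste(sources$id[unreach], collapse = ", "))
  }
  keep <- setdiff(seq_len(k), unreach)
  if (length(keep) < 2L) stop("fewer than two mutually reachable sources", call. = FALSE)
  sub <- cost_mat[keep, keep, drop = FALSE]
  m <- length(keep)
  g <- igraph::graph_from_adjacency_matrix(sub, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  mst <- igraph::mst(g, weights = igraph::E(g)$weight)
  edges <- igraph::as_edgelist(mst)
  sel <- unique(t(apply(edges, 1L, function(e) sort(as.integer(e)))))
  for (i in seq_len(m)) {
    ord <- order(sub[i, ])
    nn <- setdiff(ord, i)[seq_len(min(k_neighbors, m - 1L))]
    for (j in nn) sel <- rbind(sel, sort(c(i, j)))
  }
  sel <- unique(sel)
  paths <- list(); from <- integer(0); to <- integer(0); cost <- numeric(0)
  for (e in seq_len(nrow(sel))) {
    i <- keep[sel[e, 1]]; j <- keep[sel[e, 2]]
    p <- least_cost_path(surfaces[[i]], terminals[[j]],
                         endpoints = c(sources$id[i], sources$id[j]))
    paths[[length(paths) + 1L]] <- p
    from <- c(from, sources$id[i]); to <- c(to, sources$id[j])
    cost <- c(cost, p$total_cost)
  }
  # merge geometric duplicates (>= 90% shared cells)
  keep_path <- rep(TRUE, length(paths))
  key <- lapply(paths, function(p) paste(p$cells$row, p$cells$col))
  for (a in seq_along(paths)) for (b in seq_len(a - 1L)) {
    if (!keep_path[a] || !keep_path[b]) next
    shared <- length(intersect(key[[a]], key[[b]]))
    if (shared / min(length(key[[a]]), length(key[[b]])) >= 0.9)
      keep_path[a] <- FALSE
  }
  out <- tibble::tibble(from = from, to = to, total_cost = cost,
                        path = paths)[keep_path, ]
  class(out) <- c("corridor_network", class(out))
  attr(out, "cost_matrix") <- cost_mat
  out
}

#' Convert corridor paths to LineString features for [write_vector()]
#' @param network A `corridor_network`.
#' @return A feature tibble.
#' @export
network_features <- function(network) {
  tibble::tibble(
    from = network$from, to = network$to, total_cost = network$total_cost,
    geometry = lapply(network$path, function(p)
      list(type = "LineString",
           coordinates = cbind(p$cells$x, p$cells$y))))
}
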
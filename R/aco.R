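#' Parameters for the modified ant-colony corridor search
#'
#' Defaults follow the corridor-search study conditions: 200 ants per
#' iteration, 50 iterations (pheromone concentration stops growing well
#' before that), a 1500 m search buffer around the least-cost centreline,
#' canonical ant-system exponents (`alpha = 1` on pheromone, `beta = 2` on
#' the inverse-resistance heuristic), 10% evaporation per iteration, and
#' the jump rule for escaping high-resistance surroundings.
#'
#' @param n_ants Ants per iteration.
#' @param n_iterations Iterations (global pheromone updates).
#' @param alpha Pheromone exponent.
#' @param beta Heuristic (inverse resistance) exponent.
#' @param rho Evaporation rate in (0, 1).
#' @param deposit Pheromone quantum Q; each successful ant deposits `Q / L`
#'   per visited cell, `L` its accumulated step cost.
#' @param jump_radius Chebyshev radius (cells) of the jump neighbourhood.
#' @param jump_threshold Resistance quantile (within the search region)
#'   above which a neighbour counts as "higher resistance".
#' @param max_steps Per-ant step budget; `NULL` = 30 times the Chebyshev
#'   cell distance between the terminals.
#' @param seed Integer seed fixing all randomness.
#' @param buffer_m Search-region half-width around the centreline (metres).
#' @param tau0 Initial uniform pheromone; `NULL` = the per-cell deposit of
#'   one ideal straight-line ant (`Q / L_straight`), so reinforcement and
#'   the prior start on the same scale.
#' @return A list of class `ant_params`.
#' @export
ant_params <- function(n_ants = 200, n_iterations = 50, alpha = 1, beta = 2,
                       rho = 0.1, deposit = 1, jump_radius = 3,
                       jump_threshold = 0.9, max_steps = NULL, seed = 1,
                       buffer_m = 1500, tau0 = NULL) {
  stopifnot(n_ants >= 1, n_iterations >= 1, rho > 0, rho < 1,
            jump_radius >= 1, jump_threshold > 0, jump_threshold <= 1,
            buffer_m > 0, deposit > 0)
  structure(list(n_ants = as.integer(n_ants),
                 n_iterations = as.integer(n_iterations),
                 alpha = alpha, beta = beta, rho = rho, deposit = deposit,
                 jump_radius = as.integer(jump_radius),
                 jump_threshold = jump_threshold, max_steps = max_steps,
                 seed = as.integer(seed), buffer_m = buffer_m, tau0 = tau0),
            class = "ant_params")
}

#' Search region: buffer around a corridor centreline
#'
#' Cells whose centres lie within `buffer_m` of any centreline cell centre.
#'
#' @param path An `lcp_path` (or a tibble with `row`, `col` columns).
#' @param buffer_m Buffer half-width in metres (>= one cell).
#' @param template [grid_raster] defining the grid.
#' @return [grid_raster] mask (1 inside the region, 0 outside).
#' @export
search_region <- function(path, buffer_m, template) {
  cells <- if (inherits(path, "lcp_path")) path$cells else path
  if (nrow(cells) == 0) stop("empty path", call. = FALSE)
  cs <- template$cell_size
  if (buffer_m < cs)
    stop("buffer narrower than one cell", call. = FALSE)
  nr <- nrow(template$values); nc <- ncol(template$values)
  mask <- matrix(FALSE, nr, nc)
  rad <- ceiling(buffer_m / cs)
  # precompute the in-buffer disc offsets once
  offs <- expand.grid(dr = -rad:rad, dc = -rad:rad)
  offs <- offs[(offs$dr^2 + offs$dc^2) * cs^2 <= buffer_m^2, ]
  for (i in seq_len(nrow(cells))) {
    rr <- cells$row[i] + offs$dr
    cc <- cells$col[i] + offs$dc
    ok <- rr >= 1L & cc >= 1L & rr <= nr & cc <= nc
    mask[cbind(rr[ok], cc[ok])] <- TRUE
  }
  raster_like(template, matrix(as.numeric(mask), nr, nc))
}

#' Single-step transition probabilities of the modified ant rule
#'
#' Reference implementation of the move rule the colony applies at every
#' step: admissible moves are the unvisited in-region 8-neighbours whose
#' direction differs from the previous step by at most 90 degrees (all
#' in-region neighbours on the first step); each admissible move gets
#' probability proportional to `tau^alpha * (1/resistance)^beta`. If no
#' admissible neighbour is at or below the jump resistance cut-off, the
#' candidate set becomes every unvisited region cell within the jump
#' radius ("jumping").
#'
#' @param cell `c(row, col)` of the current cell.
#' @param prev_dir `c(dr, dc)` of the previous step, or `NULL` on the first
#'   step or after a jump.
#' @param tau Pheromone matrix.
#' @param resistance [grid_raster] (or matrix) of resistance.
#' @param region Logical matrix of the search region.
#' @param visited Logical matrix of cells this ant has already visited.
#' @param params An [ant_params()] list.
#' @param jump_cut Resistance value of the jump quantile; `NULL` recomputes
#'   it from the region.
#' @return Tibble `row`, `col`, `prob`, `jump` (logical: candidate set is
#'   the jump neighbourhood). Zero rows if the ant is trapped.
#' @export
transition_probabilities <- function(cell, prev_dir = NULL, tau, resistance,
                                     region, visited = NULL,
                                     params = ant_params(), jump_cut = NULL) {
  resv <- if (inherits(resistance, "grid_raster")) resistance$values else resistance
  nr <- nrow(resv); nc <- ncol(resv)
  if (is.null(visited)) visited <- matrix(FALSE, nr, nc)
  if (is.null(jump_cut))
    jump_cut <- stats::quantile(resv[region & is.finite(resv)],
                                params$jump_threshold, names = FALSE)
  offs <- cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
                dc = c(-1, 0, 1, -1, 1, -1, 0, 1))
  adm <- integer(0)
  for (k in seq_len(8)) {
    rr <- cell[1] + offs[k, 1]; cc <- cell[2] + offs[k, 2]
    if (rr < 1 || cc < 1 || rr > nr || cc > nc) next
    if (!region[rr, cc] || visited[rr, cc]) next
    if (!is.null(prev_dir) &&
        sum(prev_dir * offs[k, ]) < 0) next
    adm <- c(adm, k)
  }
  jump <- length(adm) == 0 ||
    !any(resv[cbind(cell[1] + offs[adm, 1], cell[2] + offs[adm, 2])] <= jump_cut)
  if (!jump) {
    rows <- cell[1] + offs[adm, 1]; cols <- cell[2] + offs[adm, 2]
  } else {
    jr <- params$jump_radius
    grid <- expand.grid(dr = -jr:jr, dc = -jr:jr)
    grid <- grid[!(grid$dr == 0 & grid$dc == 0), ]
    rows <- cell[1] + grid$dr; cols <- cell[2] + grid$dc
    ok <- rows >= 1 & cols >= 1 & rows <= nr & cols <= nc
    rows <- rows[ok]; cols <- cols[ok]
    ok <- region[cbind(rows, cols)] & !visited[cbind(rows, cols)]
    rows <- rows[ok]; cols <- cols[ok]
  }
  if (!length(rows))
    return(tibble::tibble(row = integer(), col = integer(),
                          prob = numeric(), jump = logical()))
  w <- tau[cbind(rows, cols)]^params$alpha *
    (1 / resv[cbind(rows, cols)])^params$beta
  p <- if (sum(w) > 0) w / sum(w) else rep(1 / length(w), length(w))
  tibble::tibble(row = as.integer(rows), col = as.integer(cols),
                 prob = p, jump = jump)
}

#' Run the ant colony between two terminals
#'
#' Per iteration, `n_ants` ants walk from the start terminal towards the
#' end terminal (success = entering the end cell's 8-neighbourhood within
#' the step budget); after each iteration the pheromone field evaporates
#' globally and every successful ant deposits `Q / L` over its visited
#' cells. The field is bit-reproducible for a fixed seed.
#'
#' @param resistance [grid_raster] of (corrected) resistance, positive.
#' @param region [grid_raster] search-region mask from [search_region()].
#' @param start,end Terminals as `c(row, col)` cells or `c(x, y)` points
#'   (points are mapped to cells).
#' @param params An [ant_params()] list.
#' @return A `pheromone_field`: list with `tau` and `visits` rasters, the
#'   region mask, a per-iteration `log` tibble (success fraction), and the
#'   parameters used.
#' @export
run_colony <- function(resistance, region, start, end, params = ant_params()) {
  resv <- resistance$values
  regm <- region$values != 0 & is.finite(region$values)
  to_cell <- function(p) {
    if (length(p) == 2 && all(p == round(p)) &&
        p[1] >= 1 && p[1] <= nrow(resv) && p[2] >= 1 && p[2] <= ncol(resv) &&
        regm[p[1], p[2]]) return(as.integer(p))
    at <- cell_at(resistance, p[1], p[2])
    c(at$row[1], at$col[1])
  }
  s <- to_cell(start); e <- to_cell(end)
  if (any(is.na(s)) || any(is.na(e))) stop("terminal outside grid", call. = FALSE)
  if (all(s == e)) stop("start and end terminals coincide", call. = FALSE)
  if (!regm[s[1], s[2]] || !regm[e[1], e[2]])
    stop("terminals must lie inside the search region", call. = FALSE)
  if (any(resv[regm] <= 0, na.rm = TRUE) || any(!is.finite(resv[regm])))
    stop("resistance must be finite and positive inside the region", call. = FALSE)

  jump_cut <- stats::quantile(resv[regm], params$jump_threshold, names = FALSE)
  cheb <- max(abs(s - e))
  max_steps <- if (is.null(params$max_steps)) 30L * cheb else as.integer(params$max_steps)
  tau0 <- params$tau0
  if (is.null(tau0)) {
    # per-cell deposit of one ideal chamfer-path ant at mean regional resistance
    l0 <- chamfer_cost(s, e, mean(resv[regm]), resistance$cell_size)
    tau0 <- params$deposit / l0
  }
  set.seed(params$seed)
  out <- aco_run_cpp(resv, regm, s[1] - 1L, s[2] - 1L, e[1] - 1L, e[2] - 1L,
                     params$n_ants, params$n_iterations, params$alpha,
                     params$beta, params$rho, params$deposit,
                     params$jump_radius, jump_cut, max_steps,
                     resistance$cell_size, tau0)
  if (all(out$success_frac == 0))
    stop("no ant reached the end terminal; increase max_steps or jump_radius",
         call. = FALSE)
  structure(
    list(tau = raster_like(resistance, out$tau),
         visits = raster_like(resistance, out$visits),
         region = region,
         log = tibble::tibble(iteration = seq_along(out$success_frac),
                              success_frac = as.numeric(out$success_frac)),
         params = params, terminals = list(start = s, end = e),
         jump_cut = jump_cut, tau0 = tau0),
    class = "pheromone_field")
}

# Cost of the chamfer (straight 8-connected) path between two cells at
# uniform resistance r.
chamfer_cost <- function(a, b, r, cell_size) {
  dr <- abs(a[1] - b[1]); dc <- abs(a[2] - b[2])
  diag <- min(dr, dc); straight <- max(dr, dc) - diag
  (diag * sqrt(2) + straight) * cell_size * r
}

#' @export
print.pheromone_field <- function(x, ...) {
  cat(sprintf("<pheromone_field> %d x %d, %d iterations, final success %.0f%%\n",
              nrow(x$tau$values), ncol(x$tau$values), nrow(x$log),
              100 * utils::tail(x$log$success_frac, 1)))
  invisible(x)
}

#' Pheromone points above the global mean concentration
#'
#' Converts the pheromone field into weighted vector points, keeping the
#' cells whose pheromone strictly exceeds the mean over visited cells (the
#' globally optimal trace); weight = pheromone mass.
#'
#' @param field A `pheromone_field`.
#' @return Tibble `row`, `col`, `x`, `y`, `weight`.
#' @export
filter_pheromone_points <- function(field) {
  visited <- field$visits$values > 0
  tauv <- field$tau$values
  if (!any(visited)) stop("empty pheromone field", call. = FALSE)
  m <- mean(tauv[visited])
  keep <- visited & tauv > m
  if (!any(keep)) {
    warning("all visited cells carry equal pheromone; no points retained")
    return(tibble::tibble(row = integer(), col = integer(),
                          x = numeric(), y = numeric(), weight = numeric()))
  }
  idx <- which(keep, arr.ind = TRUE)
  cc <- cell_centres(field$tau, idx[, 1], idx[, 2])
  tibble::tibble(row = cc$row, col = cc$col, x = cc$x, y = cc$y,
                 weight = tauv[keep])
}
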
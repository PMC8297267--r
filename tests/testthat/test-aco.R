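test_that("the search region is a band of the right width containing the path", {
  tmpl <- grid_raster(matrix(0, 120, 120), cell_size = 30)
  path <- structure(list(cells = cell_centres(tmpl, rep(60, 100), 11:110),
                         total_cost = 0, endpoints = c(1, 2)),
                    class = "lcp_path")
  region <- search_region(path, 1500, tmpl)
  widths <- colSums(region$values[, 40:80])
  expect_true(all(widths == 101))          # 2 * 50 + 1 cells at 30 m
  expect_true(all(region$values[cbind(path$cells$row, path$cells$col)] == 1))
  expect_error(search_region(path, 10, tmpl), "narrower than one cell")
})

test_that("first-step transition probabilities are uniform on a flat field", {
  tau <- matrix(1, 9, 9)
  res <- grid_raster(matrix(10, 9, 9), 30)
  region <- matrix(TRUE, 9, 9)
  p <- transition_probabilities(c(5, 5), NULL, tau, res, region)
  expect_equal(nrow(p), 8)
  expect_equal(p$prob, rep(1 / 8, 8))
  expect_false(any(p$jump))
})

test_that("a large heuristic exponent concentrates mass on the cheapest move", {
  tau <- matrix(1, 5, 5)
  v <- matrix(20, 5, 5); v[3, 4] <- 1     # one strictly cheapest neighbour
  res <- grid_raster(v, 30)
  region <- matrix(TRUE, 5, 5)
  p <- transition_probabilities(c(3, 3), NULL, tau, res, region,
                                params = ant_params(beta = 40),
                                jump_cut = 20)
  expect_gt(p$prob[p$row == 3 & p$col == 4], 0.999999)
})

test_that("the 90-degree rule censors backward moves", {
  tau <- matrix(1, 9, 9)
  res <- grid_raster(matrix(10, 9, 9), 30)
  region <- matrix(TRUE, 9, 9)
  # previous step was due east: the three westward neighbours are barred
  p <- transition_probabilities(c(5, 5), c(0, 1), tau, res, region)
  expect_equal(nrow(p), 5)
  expect_true(all(p$col >= 5))
})

test_that("surrounded by high resistance, the candidate set becomes the jump set", {
  v <- matrix(100, 9, 9); v[5, 5] <- 1
  v[2, 2] <- 1                             # a low cell two steps away
  res <- grid_raster(v, 30)
  tau <- matrix(1, 9, 9)
  region <- matrix(TRUE, 9, 9)
  p <- transition_probabilities(c(5, 5), NULL, tau, res, region,
                                params = ant_params(jump_radius = 3),
                                jump_cut = 50)
  expect_true(all(p$jump))
  expect_equal(nrow(p), 48)                # full 7x7 Chebyshev ring
  expect_gt(p$prob[p$row == 2 & p$col == 2], max(p$prob[p$row != 2 | p$col != 2]))
})

test_that("visited cells are excluded from the candidate set", {
  tau <- matrix(1, 5, 5)
  res <- grid_raster(matrix(10, 5, 5), 30)
  region <- matrix(TRUE, 5, 5)
  visited <- matrix(FALSE, 5, 5); visited[2, 2:4] <- TRUE
  p <- transition_probabilities(c(3, 3), NULL, tau, res, region, visited)
  expect_equal(nrow(p), 5)
  expect_false(any(p$row == 2))
})

test_that("colony runs are bit-reproducible under a fixed seed", {
  sc <- make_fig7_scenario("c", shape = c(60, 80))
  region <- raster_like(sc$resistance, matrix(1, 60, 80))
  pars <- ant_params(n_ants = 40, n_iterations = 10, seed = 99)
  f1 <- run_colony(sc$resistance, region, sc$start, sc$end, pars)
  f2 <- run_colony(sc$resistance, region, sc$start, sc$end, pars)
  expect_identical(f1$tau$values, f2$tau$values)
  expect_identical(f1$visits$values, f2$visits$values)
  f3 <- run_colony(sc$resistance, region, sc$start, sc$end,
                   ant_params(n_ants = 40, n_iterations = 10, seed = 100))
  expect_false(identical(f1$tau$values, f3$tau$values))
})

test_that("pheromone stays inside the region and obeys the update bookkeeping", {
  sc <- make_fig7_scenario("b", shape = c(40, 60))
  region <- raster_like(sc$resistance, matrix(0, 40, 60))
  region$values[10:30, ] <- 1
  pars <- ant_params(n_ants = 20, n_iterations = 8, seed = 5,
                     deposit = 1e-12, tau0 = 1)
  f <- run_colony(sc$resistance, region, c(20, 6), c(20, 55), pars)
  expect_true(all(f$tau$values[region$values == 0] == 0))
  # with a negligible deposit quantum, tau is pure geometric evaporation
  expect_equal(unique(round(f$tau$values[region$values == 1], 9)),
               round((1 - pars$rho)^8, 9))
  # deposits only add: with a real quantum tau never drops below evaporation
  pars2 <- ant_params(n_ants = 20, n_iterations = 8, seed = 5, tau0 = 1)
  f2 <- run_colony(sc$resistance, region, c(20, 6), c(20, 55), pars2)
  expect_true(all(f2$tau$values[region$values == 1] >= (1 - pars2$rho)^8 - 1e-12))
  expect_true(any(f2$tau$values > (1 - pars2$rho)^8 + 1e-12))
})

test_that("on a uniform corridor the pheromone is transversely symmetric", {
  u <- grid_raster(matrix(10, 41, 81), 100)
  region <- raster_like(u, matrix(1, 41, 81))
  f <- run_colony(u, region, c(21, 6), c(21, 76),
                  ant_params(n_ants = 100, n_iterations = 20, seed = 31))
  tau <- f$tau$values[, 10:70]
  offset <- rowSums(tau) / sum(tau)
  mean_off <- sum((seq_len(41) - 21) * offset)
  expect_lt(abs(mean_off), 1.5)            # Monte-Carlo tolerance in cells
  # per-cell pheromone decays away from the centreline
  bins <- c(mean(tau[19:23, ]), mean(tau[c(14:18, 24:28), ]),
            mean(tau[c(9:13, 29:33), ]))
  expect_true(all(diff(bins) < 0))
})

test_that("pheromone points above the global mean are retained with their weights", {
  tmpl <- grid_raster(matrix(0, 3, 3), 30)
  tau <- matrix(0, 3, 3); tau[1, 1:3] <- c(1, 2, 3)
  visits <- matrix(0, 3, 3); visits[1, 1:3] <- 1
  field <- structure(list(tau = raster_like(tmpl, tau),
                          visits = raster_like(tmpl, visits)),
                     class = "pheromone_field")
  pts <- filter_pheromone_points(field)
  expect_equal(nrow(pts), 1)
  expect_equal(pts$weight, 3)
  expect_equal(c(pts$row, pts$col), c(1, 3))

  flat <- structure(list(tau = raster_like(tmpl, matrix(1, 3, 3)),
                         visits = raster_like(tmpl, matrix(1, 3, 3))),
                    class = "pheromone_field")
  expect_warning(p0 <- filter_pheromone_points(flat), "equal pheromone")
  expect_equal(nrow(p0), 0)
})
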
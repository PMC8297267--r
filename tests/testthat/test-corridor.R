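test_that("kernel density conserves mass and is linear in weights", {
  tmpl <- grid_raster(matrix(0, 60, 60), cell_size = 30)
  ctr <- cell_centres(tmpl, 30, 30)
  pts <- tibble::tibble(x = ctr$x, y = ctr$y, weight = 5)
  d <- kernel_density(pts, bandwidth_m = 300, tmpl)
  expect_equal(sum(d$values) * 30^2, 5, tolerance = 0.01)
  expect_lt(attr(d, "edge_loss"), 0.01)

  # two coincident points double the surface exactly
  pts2 <- rbind(pts, pts)
  d2 <- kernel_density(pts2, bandwidth_m = 300, tmpl)
  expect_equal(d2$values, 2 * d$values, tolerance = 1e-12)

  # the maximum sits at the centroid of a symmetric cluster
  cc <- cell_centres(tmpl, c(28, 32, 30, 30), c(30, 30, 28, 32))
  sym <- tibble::tibble(x = cc$x, y = cc$y, weight = 1)
  ds <- kernel_density(sym, bandwidth_m = 300, tmpl)
  expect_equal(which(ds$values == max(ds$values)),
               which(matrix(seq_len(3600), 60, 60) == (30 - 1) * 60 + 30))

  expect_error(kernel_density(pts[0, ], 300, tmpl), "empty point set")
  expect_error(kernel_density(pts, 10, tmpl), "at least one cell")
})

test_that("gaussian kernel integrates to the point weight as well", {
  tmpl <- grid_raster(matrix(0, 80, 80), cell_size = 30)
  ctr <- cell_centres(tmpl, 40, 40)
  pts <- tibble::tibble(x = ctr$x, y = ctr$y, weight = 2)
  d <- kernel_density(pts, bandwidth_m = 120, tmpl, kernel = "gaussian")
  expect_equal(sum(d$values) * 30^2, 2, tolerance = 0.01)
})

test_that("quantile classes split positive cells into equal-count grades", {
  tmpl9 <- grid_raster(matrix(1:9, 3, 3), 30)
  c9 <- quantile_classes(tmpl9, 9)
  expect_equal(sort(as.numeric(c9$values)), 1:9)

  v18 <- grid_raster(matrix(1:18, 3, 6), 30)
  c18 <- quantile_classes(v18, 9)
  expect_equal(as.numeric(table(c18$values)), rep(2, 9))

  # monotone transforms do not change the classes
  c18b <- quantile_classes(raster_like(v18, exp(v18$values / 4)), 9)
  expect_equal(c18b$values, c18$values)

  expect_warning(cc <- quantile_classes(const_raster(3), 9), "collapse")
  expect_equal(unique(as.numeric(cc$values)), 9)

  zero <- grid_raster(matrix(c(0, 0, 2:9, 10, 12), 3, 4), 30)
  cz <- quantile_classes(zero, 9)
  expect_true(all(is.na(cz$values[zero$values == 0])))
  expect_error(quantile_classes(const_raster(0), 9), "all-zero")
})

test_that("corridor delineation partitions the region into main and potential", {
  tmpl <- grid_raster(matrix(0, 30, 30), 100)
  cls <- matrix(NA_real_, 30, 30)
  cls[10:18, ] <- matrix(rep(1:9, length.out = 9 * 30), 9, 30)
  classes <- raster_like(tmpl, cls)
  region <- raster_like(tmpl, matrix(as.numeric(row(cls) >= 8 & row(cls) <= 22),
                                     30, 30))
  path <- structure(list(cells = cell_centres(tmpl, rep(15, 30), 1:30),
                         total_cost = 0, endpoints = c(1, 2)), class = "lcp_path")
  cs <- delineate_corridors(classes, region, path)
  n_main <- sum(cls >= 7, na.rm = TRUE)
  expect_equal(sum(cs$main_mask$values), n_main)
  expect_equal(n_main / sum(!is.na(cls)), 3 / 9)
  # main and potential partition the region exactly
  expect_equal(cs$main_mask$values + cs$potential_mask$values,
               region$values)
  expect_true(all(cs$main_mask$values[region$values == 0] == 0))
  expect_equal(cs$main_area_km2 + cs$potential_area_km2,
               mask_area_km2(tmpl, region$values == 1))

  # no pheromone: everything potential, corridor flagged unsupported
  empty <- raster_like(tmpl, matrix(NA_real_, 30, 30))
  expect_warning(c0 <- delineate_corridors(empty, region, path), "unsupported")
  expect_true(c0$unsupported)
  expect_equal(sum(c0$potential_mask$values), sum(region$values))
})

test_that("a planted uncovered band yields exactly one discontinuity at its midpoint", {
  tmpl <- grid_raster(matrix(10, 50, 50), 100)
  main <- matrix(FALSE, 50, 50)
  main[8:12, 5:45] <- TRUE
  main[, 20:26] <- FALSE                 # the band: 7 uncovered columns
  res <- matrix(10, 50, 50); res[, 20:26] <- 90
  cor <- manual_corridor(tmpl, rep(10, 41), 5:45, main)
  pts <- restoration_points(cor, raster_like(tmpl, res), gap_min_cells = 3)
  disc <- pts[pts$kind == "discontinuity", ]
  expect_equal(nrow(disc), 1)
  expect_equal(disc$col, 23)             # midpoint of columns 20..26
  expect_equal(disc$row, 10)
})

test_that("crossing centrelines produce one intersection point", {
  tmpl <- grid_raster(matrix(10, 50, 50), 100)
  all_main <- matrix(TRUE, 50, 50)
  a <- manual_corridor(tmpl, rep(25, 41), 5:45, all_main)
  b <- manual_corridor(tmpl, 5:45, rep(25, 41), all_main)
  pts <- restoration_points(list(a, b), tmpl)
  expect_equal(nrow(pts), 1)
  expect_equal(pts$kind, "intersection")
  expect_equal(c(pts$row, pts$col), c(25, 25))
})

test_that("a clean fully-covered corridor yields no restoration points", {
  tmpl <- grid_raster(matrix(10, 40, 40), 100)
  cor <- manual_corridor(tmpl, rep(20, 31), 5:35, matrix(TRUE, 40, 40))
  pts <- restoration_points(cor, tmpl)
  expect_equal(nrow(pts), 0)
})

test_that("resistance mutation points are isolated local maxima above the quantile", {
  tmpl <- grid_raster(matrix(10, 40, 40), 100)
  res <- matrix(10, 40, 40)
  res[20, 18] <- 95                       # single-cell spike on the centreline
  cor <- manual_corridor(tmpl, rep(20, 31), 5:35, matrix(TRUE, 40, 40))
  pts <- restoration_points(cor, raster_like(tmpl, res),
                            mutation_quantile = 0.9)
  expect_equal(nrow(pts), 1)
  expect_equal(pts$kind, "resistance_mutation")
  expect_equal(c(pts$row, pts$col), c(20, 18))
})
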
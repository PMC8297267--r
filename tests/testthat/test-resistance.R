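tbl <- default_resistance_table()

test_that("factor classification reproduces the shipped coefficient system", {
  slope <- grid_raster(matrix(c(5, 15, 20, 25, 34.9, 35, 60, 0, 14.99), 3, 3), 30)
  got <- classify_factor(slope, tbl$slope)$values
  expect_equal(as.numeric(got), c(10, 30, 30, 50, 50, 80, 80, 10, 10))

  lc <- grid_raster(matrix(c(1, 2, 4, 8), 2, 2), 30)   # codes in class order
  expect_equal(as.numeric(classify_factor(lc, tbl$land_cover)$values),
               c(5, 10, 30, 100))

  bedrock <- grid_raster(matrix(c(1, 4), 1, 2), 30)    # non-carbonate, dolomite
  expect_equal(as.numeric(classify_factor(bedrock, tbl$bedrock)$values),
               c(10, 70))

  alt <- grid_raster(matrix(c(799, 800, 1300, 1500, 1501, 100), 2, 3), 30)
  expect_equal(as.numeric(classify_factor(alt, tbl$altitude)$values),
               c(10, 30, 50, 80, 80, 10))

  expect_error(classify_factor(grid_raster(matrix(-5, 1, 1), 30), tbl$slope),
               "outside all classes")
  expect_error(classify_factor(grid_raster(matrix(9, 1, 1), 30), tbl$land_cover),
               "unmapped")
})

test_that("classification is idempotent on already-classified rasters", {
  slope <- grid_raster(matrix(c(5, 20, 40, 12), 2, 2), 30)
  once <- classify_factor(slope, tbl$slope)
  twice <- classify_factor(once, tbl$slope)
  expect_identical(twice$values, once$values)
})

test_that("entropy weights satisfy the method's contracts", {
  w <- entropy_weights(cbind(a = c(1, 1, 1, 1), b = c(1, 2, 3, 4)))
  expect_equal(unname(w), c(0, 1))

  # identical columns up to scaling share the weight equally
  x <- c(2, 5, 9, 4)
  w2 <- entropy_weights(cbind(a = x, b = 10 * x))
  expect_equal(unname(w2), c(0.5, 0.5))

  set.seed(2)
  m <- matrix(rexp(60), 20, 3)
  w3 <- entropy_weights(m)
  expect_true(all(w3 >= 0))
  expect_equal(sum(w3), 1)

  expect_error(entropy_weights(cbind(c(1, 1), c(2, 2))), "no information")
})

test_that("basic resistance is the weighted overlay of the factor coefficients", {
  weights <- vapply(tbl, `[[`, numeric(1), "weight")
  expect_equal(sum(weights), 1)
  mins <- c(land_cover = 5, slope = 10, altitude = 10, vegetation = 10,
            soil_thickness = 10, bedrock = 10)
  cl <- lapply(names(tbl), function(nm) const_raster(mins[[nm]]))
  names(cl) <- names(tbl)
  expect_equal(base_resistance(cl, weights)$values[1, 1], 9.1645)

  all100 <- lapply(tbl, function(e) const_raster(100))
  expect_equal(base_resistance(all100, weights)$values, matrix(100, 3, 3))

  single <- list(slope = grid_raster(matrix(c(10, 30, 50, 80), 2, 2), 30))
  expect_equal(base_resistance(single, c(slope = 1))$values,
               single$slope$values)
  expect_error(base_resistance(cl, weights[-1]), "count differ")
})

test_that("basic resistance stays inside the coefficient hull", {
  set.seed(7)
  weights <- vapply(tbl, `[[`, numeric(1), "weight")
  cl <- lapply(tbl, function(e) {
    co <- if (e$type == "interval") e$coefficients else unname(e$classes)
    grid_raster(matrix(sample(co, 25, replace = TRUE), 5, 5), 30)
  })
  out <- base_resistance(cl, weights)$values
  lo <- min(vapply(cl, function(r) min(r$values), numeric(1)))
  hi <- max(vapply(cl, function(r) max(r$values), numeric(1)))
  expect_true(all(out >= lo & out <= hi))
})

test_that("the sensitivity index combines the three indices with its weights", {
  one <- const_raster(1); zero <- const_raster(0)
  # RDI = 1, KCI = SEI = 0 isolates the first printed weight
  rdi <- grid_raster(matrix(c(1, 0), 1, 2), 30)
  z2 <- grid_raster(matrix(0, 1, 2), 30)
  s <- sensitivity_index(rdi, z2, z2)
  expect_equal(s$esi$values[1, 1], 0.483)
  expect_equal(s$esi_max, 0.483)
  expect_warning(s1 <- sensitivity_index(one, one, one), "constant")
  expect_equal(s1$esi$values, matrix(1, 3, 3))
  expect_true(s1$constant)
  expect_warning(s0 <- sensitivity_index(zero, zero, zero), "constant")
  expect_equal(s0$esi$values, matrix(0, 3, 3))
  expect_true(s0$constant)
  expect_error(sensitivity_index(one, zero, zero, a = 0.5, b = 0.5, c = 0.5),
               "sum to 1")
  expect_error(sensitivity_index(const_raster(1.4), zero, zero), "\\[0, 1\\]")
})

test_that("sensitivity correction rescales resistance around the regional mean", {
  set.seed(4)
  basic <- grid_raster(matrix(runif(25, 10, 80), 5, 5), 30)
  rdi <- grid_raster(matrix(runif(25), 5, 5), 30)
  kci <- grid_raster(matrix(runif(25), 5, 5), 30)
  sei <- grid_raster(matrix(runif(25), 5, 5), 30)
  st <- sensitivity_index(rdi, kci, sei)
  rs <- correct_resistance(basic, st)
  direct <- basic$values * st$esi_std$values / mean(st$esi_std$values)
  expect_equal(rs$corrected$values, direct)
  # a cell at exactly twice the regional mean doubles its resistance
  ratio <- st$esi_std$values / mean(st$esi_std$values)
  expect_equal(rs$corrected$values / basic$values, ratio)

  # uniform sensitivity: bitwise no-op
  suppressWarnings({
    u <- const_raster(0.4, 5, 5)
    stc <- sensitivity_index(u, u, u)
    rsc <- correct_resistance(basic, stc)
  })
  expect_identical(rsc$corrected$values, basic$values)
})

test_that("uniformly rescaling the indices leaves the corrected surface unchanged", {
  set.seed(8)
  basic <- grid_raster(matrix(runif(25, 10, 80), 5, 5), 30)
  rdi <- matrix(runif(25), 5, 5); kci <- matrix(runif(25), 5, 5)
  sei <- matrix(runif(25), 5, 5)
  mk <- function(m) grid_raster(m, 30)
  r1 <- correct_resistance(basic, sensitivity_index(mk(rdi), mk(kci), mk(sei)))
  r2 <- correct_resistance(basic, sensitivity_index(mk(rdi / 2), mk(kci / 2),
                                                    mk(sei / 2)))
  expect_equal(r2$corrected$values, r1$corrected$values, tolerance = 1e-12)
})

test_that("with independent fields the correction roughly preserves the mean", {
  set.seed(12)
  basic <- grid_raster(matrix(runif(10000, 10, 80), 100, 100), 30)
  mk <- function() grid_raster(matrix(runif(10000), 100, 100), 30)
  rs <- correct_resistance(basic, sensitivity_index(mk(), mk(), mk()))
  expect_equal(mean(rs$corrected$values), mean(basic$values), tolerance = 0.03)
  g <- glance(rs)
  expect_equal(g$mean_basic, mean(basic$values))
  expect_equal(g$n_cells, 10000)
})
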
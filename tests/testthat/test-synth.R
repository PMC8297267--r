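small_spec <- function(...) {
  landscape_spec(shape = c(60, 60), cell_size = 100, n_sources = 2,
                 channels = list(list(from = 1, to = 2, width_cells = 7,
                                      level = "low")),
                 source_separation = 25, ...)
}

test_that("the generator is deterministic in its seed", {
  l1 <- make_landscape(small_spec(seed = 5))
  l2 <- make_landscape(small_spec(seed = 5))
  for (nm in names(l1$factors))
    expect_identical(l1$factors[[nm]]$values, l2$factors[[nm]]$values)
  expect_identical(l1$sensitivity$rdi$values, l2$sensitivity$rdi$values)
  expect_identical(l1$sources$centre_row, l2$sources$centre_row)
  l3 <- make_landscape(small_spec(seed = 6))
  expect_false(identical(l1$factors$altitude$values, l3$factors$altitude$values))
})

test_that("factor stacks come out aligned and in their physical ranges", {
  l <- make_landscape(small_spec(seed = 2))
  st <- align_stack(l$factors, categorical = c("land_cover", "bedrock"))
  for (nm in names(st))
    expect_identical(st[[nm]]$values, l$factors[[nm]]$values)  # idempotent
  expect_true(all(l$factors$land_cover$values %in% 1:8))
  expect_true(all(l$factors$bedrock$values %in% 1:5))
  expect_true(all(l$factors$vegetation$values >= 0 &
                    l$factors$vegetation$values <= 100))
  expect_true(all(l$factors$slope$values >= 0 & l$factors$slope$values < 90))
  for (s in l$sensitivity)
    expect_true(all(s$values >= 0 & s$values <= 1))
})

test_that("karst controls the bedrock split and sensitivity background", {
  l0 <- make_landscape(landscape_spec(shape = c(40, 40), n_sources = 2,
                                      channels = list(), karst_fraction = 0,
                                      source_separation = 15, seed = 3))
  expect_true(all(l0$factors$bedrock$values == 1))
  # without karst the indices sit at their low background levels
  expect_lt(max(l0$sensitivity$kci$values), 0.6)
  l1 <- make_landscape(landscape_spec(shape = c(40, 40), n_sources = 2,
                                      channels = list(), karst_fraction = 0.75,
                                      source_separation = 15, seed = 3))
  expect_gt(mean(l1$sensitivity$rdi$values), mean(l0$sensitivity$rdi$values))
  expect_true(any(l1$factors$bedrock$values > 1))
})

test_that("sources are disjoint patches and infeasible requests error", {
  l <- make_landscape(landscape_spec(shape = c(100, 100), n_sources = 3,
                                     channels = list(), seed = 4,
                                     source_separation = 30))
  expect_equal(nrow(l$sources), 3)
  expect_true(all(l$sources$n_cells >= 1))
  all_cells <- do.call(rbind, l$sources$cells)
  expect_equal(nrow(all_cells), nrow(unique(all_cells)))  # disjoint
  expect_error(
    make_landscape(landscape_spec(shape = c(30, 30), n_sources = 50,
                                  channels = list(), source_separation = 10)),
    "shrink n_sources")
})

test_that("the planted channel carries the minimum-resistance path", {
  l <- make_landscape(small_spec(seed = 11))
  table <- default_resistance_table()
  classified <- mapply(classify_factor, l$factors, table, SIMPLIFY = FALSE)
  basic <- base_resistance(classified,
                           vapply(table, `[[`, numeric(1), "weight"))
  a <- c(l$sources$centre_row[1], l$sources$centre_col[1])
  b <- c(l$sources$centre_row[2], l$sources$centre_col[2])
  cs <- cost_distance(basic, list(cbind(a[1], a[2])))
  p <- least_cost_path(cs, cbind(b[1], b[2]))
  inside <- l$channel_masks[[1]][cbind(p$cells$row, p$cells$col)]
  expect_true(all(inside))
  # the channel floor is the minimal-coefficient overlay
  expect_equal(min(basic$values), 9.1645)
  expect_true(all(basic$values[!l$channel_masks[[1]]] > 9.1645))
})

test_that("the regime scenarios realise their constructions", {
  b <- make_fig7_scenario("b", shape = c(40, 60))
  expect_true(all(b$resistance$values[b$corridor_rows, 6:55] == 5))
  a <- make_fig7_scenario("a", shape = c(40, 60))
  expect_true(all(a$resistance$values[a$corridor_rows, 6:55] == 80))

  cc <- make_fig7_scenario("c", shape = c(40, 60))
  wall <- cc$resistance$values[, cc$wall_cols]
  low_rows <- which(apply(wall, 1, function(r) any(r < 90)))
  expect_equal(low_rows, cc$gap_rows)      # exactly one gap through the band

  e <- make_fig7_scenario("e", shape = c(40, 60))
  lab <- label_components(e$resistance$values == 80)
  expect_gte(max(lab), 2)                  # several high patches
  expect_true(any(e$seam_mask))
  d <- make_fig7_scenario("d", shape = c(40, 60))
  expect_true(all(d$resistance$values[d$block$rows, d$block$cols] == 90))
  expect_true(all(d$resistance$values[-d$block$rows, -d$block$cols] == 10))

  expect_error(make_fig7_scenario("q"), "should be one of")
  s1 <- make_fig7_scenario("e", shape = c(40, 60))
  expect_identical(s1$resistance$values, e$resistance$values)
})

test_that("service inputs are aligned, deterministic and physically plausible", {
  spec <- small_spec(seed = 13)
  st1 <- make_service_stack(spec)
  st2 <- make_service_stack(spec)
  expect_identical(st1$apar$values, st2$apar$values)
  expect_identical(st1$region_output, st2$region_output)

  rasters <- st1[vapply(st1, inherits, TRUE, "grid_raster")]
  for (r in rasters) expect_true(same_grid(r, st1$apar))
  expect_true(all(st1$c_cover$values >= 0 & st1$c_cover$values <= 1))
  expect_true(all(st1$p_practice$values >= 0 & st1$p_practice$values <= 1))
  expect_true(all(st1$degradation$values >= 0 & st1$degradation$values <= 1))
  expect_true(all(st1$apar$values >= 0))
  expect_true(all(st1$ndvi$values >= 0 & st1$ndvi$values <= 1))
})
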
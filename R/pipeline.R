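#' Run the full ecological-security-pattern pipeline
#'
#' Chains every stage on one landscape: ecosystem-service scoring, top-20%
#' masks and dominant-service richness, Gi* hotspot extraction of
#' ecological sources, entropy-weighted basic resistance corrected by the
#' ecological sensitivity index, least-cost corridor network, per-corridor
#' ant-colony runs, kernel-density corridor delineation, and restoration
#' points. With `out_dir` set, every artifact (rasters, polygons, points,
#' run log) is written to disk.
#'
#' @param spec A [landscape_spec()]; the synthetic landscape to analyse.
#' @param params An [ant_params()]; per-corridor colonies derive their
#'   seeds from `params$seed` plus the corridor index.
#' @param min_area_km2 Minimum hotspot patch area kept as a source. The
#'   default 1 km^2 suits the default 20 km landscape; county-scale data
#'   uses larger thresholds (such as 6.26 km^2).
#' @param z_threshold Gi* hotspot significance cut-off (default 1.65).
#' @param gi_radius_cells Gi* neighbourhood radius in cells (default 3).
#' @param bandwidth_cells KDE bandwidth in cells (default 10).
#' @param k_neighbors Corridor network nearest-neighbour edges (default 2).
#' @param resistance_floor Fraction of the mean basic resistance used to
#'   floor the corrected surface away from zero (the sensitivity ratio
#'   zeroes the least-sensitive cell, which no cost accumulation over a
#'   positive surface can accept); default 0.01.
#' @param weights `"table"` uses the shipped factor weights; `"entropy"`
#'   recomputes them from the landscape's cells.
#' @param out_dir Optional output directory (created if missing).
#' @return An `esp_result` list with every intermediate and final product.
#' @export
run_esp_pipeline <- function(spec = landscape_spec(), params = ant_params(),
                             min_area_km2 = 1, z_threshold = 1.65,
                             gi_radius_cells = 3, bandwidth_cells = 10,
                             k_neighbors = 2, resistance_floor = 0.01,
                             weights = c("table", "entropy"),
                             out_dir = NULL) {
  weights <- match.arg(weights)
  landscape <- make_landscape(spec)
  inputs <- make_service_stack(spec, landscape)
  tmpl <- landscape$factors$altitude
  cs <- tmpl$cell_size

  services <- list(
    npp = compute_npp(inputs$apar, inputs$epsilon),
    habitat = compute_habitat_quality(inputs$habitat, inputs$degradation),
    soil = compute_soil_conservation(inputs$k_erod, inputs$r_eros, inputs$ls,
                                     inputs$c_cover, inputs$p_practice),
    water = compute_water_yield(inputs$precip, inputs$et, inputs$runoff),
    food = allocate_food_supply(inputs$ndvi, inputs$cropland_mask,
                                inputs$region_mask, inputs$region_output))

  masks <- lapply(services, top_quantile_mask, q = 0.2)
  richness <- service_richness(masks)
  gi_z <- gi_star(richness, radius = gi_radius_cells * cs)
  sources <- extract_source_patches(gi_z, z_threshold = z_threshold,
                                    min_area_km2 = min_area_km2,
                                    richness = richness)

  table <- default_resistance_table()
  classified <- mapply(classify_factor, landscape$factors, table,
                       SIMPLIFY = FALSE)
  w <- if (weights == "table") {
    vapply(table, `[[`, numeric(1), "weight")
  } else {
    samples <- do.call(cbind, lapply(classified, function(r) as.numeric(r$values)))
    entropy_weights(samples)
  }
  basic <- base_resistance(classified, w)
  sens <- sensitivity_index(landscape$sensitivity$rdi, landscape$sensitivity$kci,
                            landscape$sensitivity$sei)
  surface <- correct_resistance(basic, sens)
  floor_val <- resistance_floor * mean(basic$values, na.rm = TRUE)
  corrected <- raster_like(surface$corrected,
                           pmax(surface$corrected$values, floor_val))

  network <- corridor_network(corrected, sources, k_neighbors = k_neighbors)
  cost <- cost_distance(corrected, sources)

  corridors <- list(); fields <- list(); densities <- list()
  for (i in seq_len(nrow(network))) {
    p <- network$path[[i]]
    region <- search_region(p, params$buffer_m, tmpl)
    cp <- params; cp$seed <- params$seed + i
    n_cells <- nrow(p$cells)
    field <- run_colony(corrected, region,
                        start = c(p$cells$row[1], p$cells$col[1]),
                        end = c(p$cells$row[n_cells], p$cells$col[n_cells]),
                        params = cp)
    pts <- filter_pheromone_points(field)
    dens <- kernel_density(pts, bandwidth_cells * cs, tmpl)
    classes <- quantile_classes(dens)
    corridors[[i]] <- delineate_corridors(classes, region, p)
    fields[[i]] <- field; densities[[i]] <- dens
  }
  restoration <- restoration_points(corridors, corrected, sources = sources,
                                    dedup_m = bandwidth_cells * cs)

  result <- structure(
    list(spec = spec, params = params, landscape = landscape,
         services = services, masks = masks, richness = richness,
         gi_z = gi_z, sources = sources, weights = w, basic = basic,
         sensitivity = sens, surface = surface, corrected = corrected,
         network = network, cost = cost, fields = fields,
         densities = densities, corridors = corridors,
         restoration = restoration),
    class = "esp_result")
  if (!is.null(out_dir)) write_esp_artifacts(result, out_dir)
  result
}

#' @export
print.esp_result <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(paste0("<esp_result> %d sources (%.4g km^2, %.2f%% of area), ",
                     "%d corridors\n  main %.4g km^2, potential %.4g km^2, ",
                     "%d restoration points\n"),
              g$n_sources, g$source_area_km2, g$source_area_pct,
              g$n_corridors, g$main_area_km2, g$potential_area_km2,
              g$n_restoration_points))
  invisible(x)
}

#' One-row summary of a pipeline run
#' @param x An `esp_result`.
#' @param ... Unused.
#' @return A tibble of headline quantities.
#' @export
glance.esp_result <- function(x, ...) {
  total_km2 <- mask_area_km2(x$basic)
  main <- sum(vapply(x$corridors, `[[`, numeric(1), "main_area_km2"))
  pot <- sum(vapply(x$corridors, `[[`, numeric(1), "potential_area_km2"))
  tibble::tibble(
    n_sources = nrow(x$sources),
    source_area_km2 = sum(x$sources$area_km2),
    source_area_pct = 100 * sum(x$sources$area_km2) / total_km2,
    mean_basic_resistance = mean(x$basic$values, na.rm = TRUE),
    mean_corrected_resistance = mean(x$surface$corrected$values, na.rm = TRUE),
    n_corridors = nrow(x$network),
    main_area_km2 = main,
    potential_area_km2 = pot,
    n_restoration_points = nrow(x$restoration))
}

#' Per-corridor summary of a pipeline run
#' @param x An `esp_result`.
#' @param ... Unused.
#' @return A tibble, one row per corridor.
#' @export
tidy.esp_result <- function(x, ...) {
  tibble::tibble(
    corridor = seq_len(nrow(x$network)),
    from = x$network$from, to = x$network$to,
    total_cost = x$network$total_cost,
    centreline_cells = vapply(x$network$path, function(p) nrow(p$cells), integer(1)),
    main_area_km2 = vapply(x$corridors, `[[`, numeric(1), "main_area_km2"),
    potential_area_km2 = vapply(x$corridors, `[[`, numeric(1), "potential_area_km2"),
    final_success_frac = vapply(x$fields, function(f)
      utils::tail(f$log$success_frac, 1), numeric(1)))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' Write every pipeline artifact to a directory
#'
#' Emits the service, richness, hotspot, resistance and cost rasters as
#' ASCII grids, per-corridor pheromone/density/class rasters, GeoJSON
#' sources (polygons and centre points), corridor centrelines, main
#' corridor polygons, restoration points, and a YAML run log with every
#' parameter.
#'
#' @param result An `esp_result`.
#' @param out_dir Output directory (created recursively).
#' @return `out_dir`, invisibly.
#' @export
write_esp_artifacts <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)
  for (nm in names(result$services))
    write_raster(result$services[[nm]], p(sprintf("service_%s.asc", nm)))
  write_raster(result$richness, p("service_richness.asc"))
  write_raster(result$gi_z, p("gi_star_z.asc"))
  write_raster(result$basic, p("resistance_basic.asc"))
  write_raster(result$surface$corrected, p("resistance_corrected.asc"))
  write_raster(result$cost$mcr, p("mcr_cost.asc"))
  for (i in seq_along(result$fields)) {
    write_raster(result$fields[[i]]$tau, p(sprintf("corridor_%02d_tau.asc", i)))
    write_raster(result$densities[[i]], p(sprintf("corridor_%02d_density.asc", i)))
    write_raster(result$corridors[[i]]$classes,
                 p(sprintf("corridor_%02d_classes.asc", i)))
  }
  write_vector(source_features(result$sources, "polygons"), p("sources.geojson"))
  write_vector(source_features(result$sources, "centres"), p("source_centres.geojson"))
  write_vector(network_features(result$network), p("corridor_centrelines.geojson"))
  mains <- do.call(rbind, lapply(seq_along(result$corridors), function(i) {
    m <- result$corridors[[i]]$main
    if (!nrow(m)) return(NULL)
    tibble::tibble(corridor = i, patch = m$id, area_km2 = m$area_km2,
                   geometry = m$geometry)
  }))
  if (is.null(mains))
    mains <- tibble::tibble(corridor = integer(), patch = integer(),
                            area_km2 = numeric(), geometry = list())
  write_vector(mains, p("main_corridors.geojson"))
  write_vector(restoration_features(result$restoration),
               p("restoration_points.geojson"))
  g <- glance(result)
  log <- list(
    spec = unclass(result$spec),
    params = unclass(result$params),
    weights = as.list(result$weights),
    summary = as.list(g),
    corridors = lapply(seq_len(nrow(result$network)), function(i)
      list(from = result$network$from[i], to = result$network$to[i],
           total_cost = result$network$total_cost[i],
           main_area_km2 = result$corridors[[i]]$main_area_km2)))
  yaml::write_yaml(log, p("run_log.yaml"))
  invisible(out_dir)
}
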
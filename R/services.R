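#' Net primary productivity (gas regulation proxy)
#'
#' Per-cell light-use-efficiency product `NPP = APAR * epsilon`: absorbed
#' photosynthetically active radiation times the light-energy conversion
#' rate of the vegetation. Both inputs are consumed as rasters; estimating
#' them from imagery is out of scope.
#'
#' @param apar [grid_raster] of absorbed PAR (e.g. MJ m^-2 a^-1).
#' @param epsilon [grid_raster] of light-use efficiency (gC MJ^-1).
#' @return [grid_raster] of NPP; nodata propagates from either input.
#' @export
compute_npp <- function(apar, epsilon) {
  check_aligned(apar, epsilon, what = "NPP inputs")
  raster_like(apar, apar$values * epsilon$values)
}

#' Habitat quality (habitat-maintenance service)
#'
#' InVEST-style habitat quality
#' `Q = H * (1 - D^z / (D^z + k^z))`
#' where `H` is the habitat attribute of the cell's land-use class, `D` the
#' habitat degradation in `[0, 1]`, `k` the half-saturation constant and `z`
#' the saturation exponent. At `D = k` the degradation term halves `H`.
#'
#' @param habitat [grid_raster] of habitat attribute `H` (0..1 typical).
#' @param degradation [grid_raster] of degradation `D` in `[0, 1]`.
#' @param k Half-saturation constant (> 0), default 0.5.
#' @param z Saturation exponent, default 2.
#' @return [grid_raster] of habitat quality, in `[0, H]` per cell.
#' @export
compute_habitat_quality <- function(habitat, degradation, k = 0.5, z = 2) {
  if (k <= 0) stop("half-saturation constant k must be > 0", call. = FALSE)
  check_aligned(habitat, degradation, what = "habitat inputs")
  d <- degradation$values
  fin <- is.finite(d)
  if (any(d[fin] < 0 | d[fin] > 1))
    stop("degradation must lie in [0, 1]", call. = FALSE)
  q <- habitat$values * (1 - d^z / (d^z + k^z))
  raster_like(habitat, q)
}

#' Soil conservation (RUSLE overlay)
#'
#' `A = K * R * LS * (1 - C * P)`: soil erodibility, rainfall erosivity and
#' the terrain factor, discounted by the cover-management and support
#' practice factors. The RUSLE factors are consumed as rasters.
#'
#' @param k_erod [grid_raster] soil erodibility K.
#' @param r_eros [grid_raster] rainfall erosivity R.
#' @param ls [grid_raster] slope length-steepness factor LS.
#' @param c_cover [grid_raster] cover-management factor C in `[0, 1]`.
#' @param p_practice [grid_raster] support practice factor P in `[0, 1]`.
#' @return [grid_raster] of annual soil conservation (>= 0).
#' @export
compute_soil_conservation <- function(k_erod, r_eros, ls, c_cover, p_practice) {
  check_aligned(k_erod, r_eros, ls, c_cover, p_practice, what = "RUSLE factors")
  for (r in list(c_cover, p_practice)) {
    v <- r$values[is.finite(r$values)]
    if (any(v < 0 | v > 1)) stop("C and P factors must lie in [0, 1]", call. = FALSE)
  }
  a <- k_erod$values * r_eros$values * ls$values *
    (1 - c_cover$values * p_practice$values)
  raster_like(k_erod, a)
}

#' Water yield by annual water balance
#'
#' `W = P - ET - Q` (all mm a^-1). Cells where evapotranspiration plus
#' runoff exceed precipitation keep their negative balance — a clipped
#' surface would hide inconsistent inputs — and are counted in a deficit
#' attribute.
#'
#' @param precip [grid_raster] annual precipitation (mm).
#' @param et [grid_raster] annual evapotranspiration (mm).
#' @param runoff [grid_raster] annual surface runoff (mm).
#' @param clip_negative Set negative balances to 0 instead of keeping them.
#' @return [grid_raster] with attribute `n_deficit_cells`.
#' @export
compute_water_yield <- function(precip, et, runoff, clip_negative = FALSE) {
  check_aligned(precip, et, runoff, what = "water-balance inputs")
  w <- precip$values - et$values - runoff$values
  n_deficit <- sum(w < 0, na.rm = TRUE)
  if (clip_negative) w[w < 0] <- 0
  out <- raster_like(precip, w)
  attr(out, "n_deficit_cells") <- n_deficit
  out
}

#' Allocate regional grain output over cropland by NDVI
#'
#' Spatially interpolates each region's statistical-yearbook grain output
#' onto its cropland cells in proportion to NDVI, so that the per-region
#' sum of the resulting raster equals the region's reported output exactly.
#' Non-cropland cells receive 0.
#'
#' @param ndvi [grid_raster] of NDVI (>= 0 on cropland).
#' @param cropland_mask [grid_raster]; non-zero marks cropland.
#' @param region_mask [grid_raster] of integer region ids.
#' @param region_output Named numeric vector: region id -> total output.
#' @return [grid_raster] of per-cell food supply.
#' @export
allocate_food_supply <- function(ndvi, cropland_mask, region_mask, region_output) {
  check_aligned(ndvi, cropland_mask, region_mask, what = "food-supply inputs")
  out <- matrix(0, nrow(ndvi$values), ncol(ndvi$values))
  crop <- is.finite(cropland_mask$values) & cropland_mask$values != 0
  if (any(ndvi$values[crop] < 0, na.rm = TRUE))
    stop("NDVI must be nonnegative on cropland", call. = FALSE)
  for (rid in names(region_output)) {
    total <- region_output[[rid]]
    sel <- crop & !is.na(region_mask$values) &
      region_mask$values == as.numeric(rid)
    s <- sum(ndvi$values[sel], na.rm = TRUE)
    if (total > 0 && (!any(sel) || s == 0))
      stop(sprintf("region %s has output %g but no cropland NDVI mass", rid, total),
           call. = FALSE)
    if (any(sel) && s > 0) out[sel] <- total * ndvi$values[sel] / s
  }
  out[!is.finite(ndvi$values)] <- NA_real_
  out[is.na(out)] <- NA_real_
  raster_like(ndvi, out)
}
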
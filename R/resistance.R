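#' Default resistance classification system
#'
#' The shipped factor classification: six resistance factors (land cover,
#' slope, altitude, vegetation coverage, soil thickness, bedrock type), each
#' with ordered classes mapped to a basic resistance coefficient, plus an
#' entropy-method factor weight. Interval classes are left-closed,
#' right-open (a 15 degree slope falls in the 15-25 class); the top class is
#' closed above. Categorical rasters may carry either integer codes in the
#' listed class order or the coefficient values themselves.
#'
#' @return A named list, one entry per factor, each with `type`
#'   (`"interval"` or `"categorical"`), class definitions, and `weight`.
#' @export
default_resistance_table <- function() {
  list(
    land_cover = list(
      type = "categorical",
      classes = c("Forest land" = 5, "Grassland" = 10, "Garden land" = 20,
                  "Cultivated land" = 30, "Waters" = 50, "Unutilized land" = 70,
                  "Traffic land" = 80, "Construction land" = 100),
      weight = 0.1671),
    slope = list(
      type = "interval",
      breaks = c(0, 15, 25, 35, Inf), coefficients = c(10, 30, 50, 80),
      weight = 0.1198),
    altitude = list(
      type = "interval",
      breaks = c(-Inf, 800, 1300, 1500, Inf), coefficients = c(10, 30, 50, 80),
      weight = 0.2054),
    vegetation = list(
      type = "interval",
      breaks = c(-Inf, 35, 50, 65, Inf), coefficients = c(10, 30, 50, 80),
      weight = 0.1436),
    soil_thickness = list(
      type = "interval",
      breaks = c(-Inf, 10, 30, Inf), coefficients = c(10, 40, 70),
      weight = 0.1496),
    bedrock = list(
      type = "categorical",
      classes = c("Non-carbonate rock" = 10, "Limestone" = 30,
                  "Interformation of limestone and dolomite" = 50,
                  "Dolomite" = 70, "Carbonate rock with clastic rock" = 90),
      weight = 0.2145)
  )
}

#' Classify a factor raster into basic resistance coefficients
#'
#' Maps every cell of an environmental factor raster to the basic
#' resistance coefficient of its class. A raster whose values already all
#' equal class coefficients is returned unchanged, which makes
#' classification idempotent.
#'
#' @param factor_raster [grid_raster] of factor values (continuous) or
#'   integer class codes (categorical, in the table's class order).
#' @param entry One entry of a classification table
#'   (see [default_resistance_table()]).
#' @return [grid_raster] of resistance coefficients.
#' @export
classify_factor <- function(factor_raster, entry) {
  v <- factor_raster$values
  fin <- is.finite(v)
  coeffs <- if (entry$type == "interval") entry$coefficients else unname(entry$classes)
  if (all(v[fin] %in% coeffs)) return(factor_raster)  # already classified
  out <- rep(NA_real_, length(v))
  if (entry$type == "interval") {
    idx <- findInterval(v[fin], entry$breaks, rightmost.closed = TRUE)
    bad <- idx < 1L | idx > length(entry$coefficients)
    if (any(bad))
      stop("values outside all classes: ",
           paste(utils::head(unique(v[fin][bad]), 5), collapse = ", "), call. = FALSE)
    out[fin] <- entry$coefficients[idx]
  } else {
    idx <- match(v[fin], seq_along(entry$classes))
    bad <- is.na(idx)
    if (any(bad))
      stop("unmapped categories: ",
           paste(utils::head(unique(v[fin][bad]), 5), collapse = ", "), call. = FALSE)
    out[fin] <- unname(entry$classes)[idx]
  }
  raster_like(factor_raster, matrix(out, nrow(v), ncol(v)))
}

#' Entropy weights for a cells-by-factors sample matrix
#'
#' The entropy weight method: each column is min-shifted to be nonnegative
#' and normalised to proportions `p_ij`; its entropy is
#' `e_j = -(ln n)^-1 sum p ln p` (with `0 ln 0 := 0`), its divergence
#' `d_j = 1 - e_j`, and the weights are `w_j = d_j / sum d`. A factor that
#' is constant across cells carries no information and receives weight 0.
#'
#' @param samples Numeric matrix, cells (rows) by factors (columns).
#' @return Named numeric weight vector (nonnegative, sums to 1).
#' @export
entropy_weights <- function(samples) {
  samples <- as.matrix(samples)
  n <- nrow(samples)
  if (n < 2L) stop("need at least 2 sample rows", call. = FALSE)
  d <- apply(samples, 2L, function(x) {
    x <- x[is.finite(x)]
    if (length(unique(x)) < 2L) return(0)
    x <- x - min(x)
    p <- x / sum(x)
    e <- -sum(p[p > 0] * log(p[p > 0])) / log(length(x))
    1 - e
  })
  if (all(d == 0))
    stop("no information in any factor (all columns constant)", call. = FALSE)
  w <- d / sum(d)
  names(w) <- colnames(samples)
  w
}

#' Basic resistance surface as a weighted factor overlay
#'
#' Per-cell convex combination `sum_j w_j coeff_j` of the classified factor
#' coefficient rasters; output is bounded by the smallest and largest
#' coefficient present.
#'
#' @param classified Named list of aligned coefficient rasters.
#' @param weights Numeric weights, one per factor, in stack order (or named
#'   to match); must sum to 1.
#' @return [grid_raster] of basic resistance.
#' @export
base_resistance <- function(classified, weights) {
  if (length(classified) != length(weights))
    stop("factor count and weight count differ", call. = FALSE)
  if (!is.null(names(weights)) && !is.null(names(classified)))
    weights <- weights[names(classified)]
  if (abs(sum(weights) - 1) > 1e-6)
    stop("weights must sum to 1", call. = FALSE)
  do.call(check_aligned, c(unname(classified), list(what = "classified factors")))
  acc <- 0
  for (j in seq_along(classified)) acc <- acc + weights[[j]] * classified[[j]]$values
  raster_like(classified[[1]], acc)
}

#' Ecological sensitivity index
#'
#' Weighted combination `ESI = a RDI + b KCI + c SEI` of the rocky
#' desertification, karst collapse and soil erosion indices (each in
#' `[0, 1]`), followed by min-max standardisation
#' `ESI_std = (ESI - ESI_min) / (ESI_max - ESI_min)`. The default weights
#' (0.483, 0.282, 0.235) are the entropy-method weights of the index
#' system; they must sum to 1.
#'
#' @param rdi,kci,sei Aligned [grid_raster]s in `[0, 1]`.
#' @param a,b,c Index weights summing to 1.
#' @return A `sensitivity_stack`: list with `esi`, `esi_std` rasters,
#'   `esi_min`, `esi_max`, `weights`, and a `constant` flag set when the
#'   index has no spatial variation (standardisation undefined).
#' @export
sensitivity_index <- function(rdi, kci, sei, a = 0.483, b = 0.282, c = 0.235) {
  if (abs(a + b + c - 1) > 1e-6)
    stop("sensitivity weights must sum to 1", call. = FALSE)
  check_aligned(rdi, kci, sei, what = "sensitivity indices")
  for (r in list(rdi, kci, sei)) {
    v <- r$values[is.finite(r$values)]
    if (length(v) && (min(v) < -1e-9 || max(v) > 1 + 1e-9))
      stop("sensitivity indices must be rescaled to [0, 1]", call. = FALSE)
  }
  esi <- a * rdi$values + b * kci$values + c * sei$values
  fin <- is.finite(esi)
  esi_min <- min(esi[fin]); esi_max <- max(esi[fin])
  constant <- (esi_max - esi_min) == 0
  std <- esi
  if (constant) {
    warning("ESI is spatially constant; standardisation undefined, correction will be a no-op")
    std[fin] <- NA_real_
  } else {
    std[fin] <- (esi[fin] - esi_min) / (esi_max - esi_min)
  }
  structure(
    list(esi = raster_like(rdi, esi), esi_std = raster_like(rdi, std),
         esi_min = esi_min, esi_max = esi_max,
         weights = c(a = a, b = b, c = c), constant = constant),
    class = "sensitivity_stack")
}

#' Correct the basic resistance surface by ecological sensitivity
#'
#' Ratio-to-mean correction: each cell's basic resistance is scaled by its
#' standardised sensitivity relative to the regional mean,
#' `R_i = R * ESI_std / mean(ESI_std)`, so cells of average sensitivity
#' keep their basic resistance, more sensitive cells resist more, and the
#' correction is invariant to any uniform rescaling of the indices. With a
#' spatially constant index the correction is a no-op (`R_i = R`).
#'
#' @param basic [grid_raster] of basic resistance (positive where defined).
#' @param stack A `sensitivity_stack` from [sensitivity_index()].
#' @param numerator `"standardized"` (default) divides the standardised
#'   field by its own regional mean; `"raw"` uses the raw ESI field.
#' @return A `resistance_surface`: list with `basic` and `corrected` rasters.
#' @export
correct_resistance <- function(basic, stack, numerator = c("standardized", "raw")) {
  numerator <- match.arg(numerator)
  stopifnot(inherits(stack, "sensitivity_stack"))
  check_aligned(basic, stack$esi, what = "resistance and sensitivity")
  if (stack$constant) {
    warning("constant sensitivity index: corrected surface equals basic surface")
    corrected <- basic
  } else {
    num <- if (numerator == "standardized") stack$esi_std$values else stack$esi$values
    m <- mean(num[is.finite(num)])
    stopifnot(m > 0)  # min-max standardised non-constant field has positive mean
    corrected <- raster_like(basic, basic$values * num / m)
  }
  structure(list(basic = basic, corrected = corrected),
            class = "resistance_surface")
}

#' @export
print.resistance_surface <- function(x, ...) {
  cat("<resistance_surface>\n  basic:    ")
  print(x$basic)
  cat("  corrected: ")
  print(x$corrected)
  invisible(x)
}

#' One-row summary of a resistance surface
#' @param x A `resistance_surface`.
#' @param ... Unused.
#' @return A tibble with basic/corrected means and ranges.
#' @export
glance.resistance_surface <- function(x, ...) {
  b <- raster_stats(x$basic); k <- raster_stats(x$corrected)
  tibble::tibble(mean_basic = b$mean, min_basic = b$min, max_basic = b$max,
                 mean_corrected = k$mean, min_corrected = k$min,
                 max_corrected = k$max, n_cells = b$n)
}

#' @importFrom generics glance
#' @export
generics::glance
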
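# ggplot2 visualisation helpers.

raster_df <- function(raster, name = "value") {
  v <- raster$values
  d <- cell_centres(raster, rep(seq_len(nrow(v)), ncol(v)),
                    rep(seq_len(ncol(v)), each = nrow(v)))
  d[[name]] <- as.numeric(v)
  d
}

#' Plot a raster layer
#' @param object A [grid_raster].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.grid_raster <- function(object, ...) {
  d <- raster_df(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y,
                                  fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL)
}

#' Plot a pheromone field with its terminals
#' @param object A `pheromone_field`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pheromone_field <- function(object, ...) {
  p <- autoplot.grid_raster(object$tau) +
    ggplot2::labs(fill = "pheromone")
  term <- rbind(object$terminals$start, object$terminals$end)
  td <- cell_centres(object$tau, term[, 1], term[, 2])
  p + ggplot2::geom_point(data = td, ggplot2::aes(x = .data$x, y = .data$y),
                          inherit.aes = FALSE, colour = "red", size = 2)
}

#' Plot the delineated corridor (main/potential extents and centreline)
#' @param object A `corridor_set`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.corridor_set <- function(object, ...) {
  regm <- object$region$values != 0
  main <- object$main_mask$values != 0
  cls <- ifelse(main, "main", ifelse(regm, "potential", NA))
  d <- raster_df(object$region)
  d$extent <- as.vector(cls)
  d <- d[!is.na(d$extent), ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y,
                                  fill = .data$extent)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = c(main = "#1b7837", potential = "#d9f0d3")) +
    ggplot2::geom_path(data = object$centreline$cells,
                       ggplot2::aes(x = .data$x, y = .data$y),
                       inherit.aes = FALSE, linewidth = 0.3) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = "corridor")
}

#' Overview map of a full pipeline run
#'
#' Corrected resistance as the base layer, source patches, corridor
#' centrelines and restoration points on top.
#'
#' @param object An `esp_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.esp_result <- function(object, ...) {
  p <- autoplot.grid_raster(object$corrected) +
    ggplot2::labs(fill = "resistance")
  src <- do.call(rbind, lapply(seq_len(nrow(object$sources)), function(i) {
    cells <- object$sources$cells[[i]]
    cc <- cell_centres(object$corrected, cells[, 1], cells[, 2])
    cc$source <- object$sources$id[i]
    cc
  }))
  if (!is.null(src))
    p <- p + ggplot2::geom_tile(data = src,
                                ggplot2::aes(x = .data$x, y = .data$y),
                                inherit.aes = FALSE, fill = "#2166ac")
  for (path in object$network$path)
    p <- p + ggplot2::geom_path(data = path$cells,
                                ggplot2::aes(x = .data$x, y = .data$y),
                                inherit.aes = FALSE, colour = "white",
                                linewidth = 0.4)
  if (nrow(object$restoration))
    p <- p + ggplot2::geom_point(data = object$restoration,
                                 ggplot2::aes(x = .data$x, y = .data$y),
                                 inherit.aes = FALSE, colour = "red",
                                 shape = 4, size = 2, stroke = 1)
  p
}

#' @importFrom ggplot2 autoplot .data
#' @export
ggplot2::autoplot
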
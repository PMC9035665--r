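#' Occlusion saliency map
#'
#' Slides a `window x window` mid-gray patch over the image with the given
#' stride (windows fully inside the image, no padding) and records, at each
#' position, the drop in the model's predicted probability for the target
#' label: `attribution = p_target(original) - p_target(occluded)`. Positive
#' values mark regions that support the target label. The position grid has
#' `floor((side - window) / stride) + 1` rows and columns.
#'
#' @param model A `face_classifier` (or any object with a `predict` method
#'   returning the four probability columns).
#' @param image An image array.
#' @param target Target label (typically the image's true label).
#' @param window Occlusion window side in pixels (default 20).
#' @param stride Stride in pixels (default 10).
#' @param fill Fill value for the occluded window (mid-gray 0.5).
#' @return An object of class `saliency_map` with the attribution `grid`
#'   (rows index vertical positions), `window`, `stride`, `target` and the
#'   source image side.
#' @export
#' @examples
#' # a 64 x 64 image with window 20 and stride 10 gives a 5 x 5 grid
occlusion_map <- function(model, image, target, window = 20L, stride = 10L,
                          fill = 0.5) {
  target <- match_label(target, disease_labels(), "target label")
  n <- dim(image)[1]
  if (window > n) stop("window exceeds image side", call. = FALSE)
  if (stride < 1) stop("stride must be at least 1", call. = FALSE)
  g <- floor((n - window) / stride) + 1
  starts <- (seq_len(g) - 1) * stride + 1
  tcol <- c(WS = "p_ws", `22q` = "p_22q", control = "p_control",
            unaffected = "p_unaffected")[[target]]

  occluded <- vector("list", g * g)
  k <- 0L
  for (r in starts) {
    for (cc in starts) {
      img2 <- image
      img2[r:(r + window - 1), cc:(cc + window - 1), ] <- fill
      k <- k + 1L
      occluded[[k]] <- img2
    }
  }
  p0 <- predict(model, list(image))[[tcol]]
  pv <- predict(model, occluded)[[tcol]]
  grid <- matrix(p0 - pv, g, g, byrow = TRUE)
  structure(list(grid = grid, window = as.integer(window),
                 stride = as.integer(stride), target = target,
                 image_size = n, n = 1L),
            class = "saliency_map")
}

#' @export
print.saliency_map <- function(x, ...) {
  cat(sprintf("<saliency_map> %dx%d grid (window %d, stride %d, target %s)\n",
              nrow(x$grid), ncol(x$grid), x$window, x$stride, x$target))
  invisible(x)
}

#' Ensemble-averaged saliency map
#'
#' The elementwise mean of the per-member occlusion maps. All ensemble
#' members contribute by default; set `filter_confident = TRUE` to restrict
#' to members whose maximum predicted probability on the image reaches the
#' ensemble's confidence threshold.
#'
#' @param ensemble A [face_ensemble()].
#' @param image Image array.
#' @param target Target label.
#' @param filter_confident Apply the 0.5 confidence filter to members before
#'   averaging (default `FALSE`).
#' @inheritParams occlusion_map
#' @return A `saliency_map`.
#' @export
ensemble_saliency <- function(ensemble, image, target, window = 20L,
                              stride = 10L, fill = 0.5,
                              filter_confident = FALSE) {
  models <- ensemble$models
  if (filter_confident) {
    keep <- vapply(models, function(m) {
      max(as.numeric(predict(m, list(image))[1, 1:4])) >= ensemble$threshold
    }, TRUE)
    if (any(keep)) models <- models[keep]
  }
  maps <- lapply(models, occlusion_map, image = image, target = target,
                 window = window, stride = stride, fill = fill)
  composite_saliency(maps, target = target)
}

#' Composite saliency map
#'
#' Elementwise mean of a set of saliency maps sharing a grid shape — e.g.
#' the maps of all test images in one (disease, age bracket) cell, or the
#' per-member maps of an ensemble. Records how many maps contributed.
#'
#' @param maps Nonempty list of `saliency_map` objects with identical grids.
#' @param disease,age Optional group metadata.
#' @param target Optional target label override.
#' @return A `saliency_map` with `n` set to the number of contributing maps
#'   (and `disease` / `age` metadata when given).
#' @export
composite_saliency <- function(maps, disease = NULL, age = NULL,
                               target = NULL) {
  if (!length(maps)) stop("empty map list", call. = FALSE)
  dims <- vapply(maps, function(m) dim(m$grid), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("saliency maps have mismatched grid shapes", call. = FALSE)
  }
  grid <- Reduce(`+`, lapply(maps, `[[`, "grid")) / length(maps)
  out <- maps[[1]]
  out$grid <- grid
  out$n <- sum(vapply(maps, function(m) m$n %||% 1L, 1L))
  out$target <- target %||% out$target
  out$disease <- disease
  out$age <- age
  out
}

#' Nearest-neighbour upsampling of a saliency grid
#'
#' Expands the position grid to a per-pixel rendering for visualisation or
#' for feeding the map to an image-domain embedder; statistics should use
#' the raw grid.
#'
#' @param map A `saliency_map`.
#' @param size Output side in pixels (defaults to the source image size).
#' @return A `size x size` numeric matrix.
#' @export
upsample_map <- function(map, size = map$image_size) {
  g <- dim(map$grid)
  ri <- pmin(g[1], pmax(1, ceiling(seq_len(size) / size * g[1])))
  ci <- pmin(g[2], pmax(1, ceiling(seq_len(size) / size * g[2])))
  map$grid[ri, ci, drop = FALSE]
}

#' @export
tidy.saliency_map <- function(x, ...) {
  g <- x$grid
  tibble::tibble(
    row = rep(seq_len(nrow(g)), ncol(g)),
    col = rep(seq_len(ncol(g)), each = nrow(g)),
    attribution = as.vector(g)
  )
}

#' Plot a saliency map
#'
#' Diverging heatmap of the attribution grid: green marks positive
#' contribution to the target label, red negative.
#'
#' @param object A `saliency_map`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.saliency_map <- function(object, ...) {
  df <- tidy(object)
  lim <- max(abs(df$attribution), 1e-12)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$attribution)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "#b2182b", mid = "white",
                                  high = "#1b7837",
                                  limits = c(-lim, lim)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("Occlusion saliency (target %s, n = %d)",
                                  object$target, object$n),
                  x = NULL, y = NULL, fill = "attribution") +
    ggplot2::theme_minimal()
}
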
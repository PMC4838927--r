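# Trace imaging: binary rasters of one cycle's swimming traces and the
# 25-element trace-momentum (TM) vector counted from them.

.sqmap_cache <- new.env(parent = emptyenv())

# cached pixel -> square map for (layout, resolution)
get_sqmap <- function(layout, resolution) {
  key <- paste(layout$square_width, layout$passage_width, layout$rows,
               layout$cols, resolution, sep = "|")
  m <- get0(key, .sqmap_cache, inherits = FALSE)
  if (is.null(m)) {
    m <- pixel_square_map(layout, resolution)
    assign(key, m, .sqmap_cache)
  }
  m
}

#' Create a blank trace image
#'
#' A binary raster covering the chamber bounding box at the given
#' resolution. Pixel (i, j) covers the square of side `resolution` um whose
#' center is at ((i - 0.5) res, (j - 0.5) res); i indexes x (rightward), j
#' indexes y (downward).
#'
#' @param layout An [grid_layout()] object.
#' @param resolution Pixel size, um/pixel (default 4, i.e. a 480 um square
#'   well spans 120 x 120 pixels).
#' @return A raw matrix of class `aq_trace` with attributes `resolution`
#'   and `side`.
#' @export
trace_image <- function(layout, resolution = 4) {
  if (resolution <= 0) stop("resolution must be positive", call. = FALSE)
  W <- as.integer(ceiling(layout$side / resolution))
  img <- matrix(as.raw(0), W, W)
  structure(img, class = "aq_trace", resolution = resolution,
            side = layout$side)
}

#' @export
print.aq_trace <- function(x, ...) {
  cat(sprintf("<aq_trace> %d x %d px at %g um/px, %d set\n",
              nrow(x), ncol(x), attr(x, "resolution"),
              sum(as.integer(x))))
  invisible(x)
}

#' Rasterize swimming traces for one feedback cycle
#'
#' Draws each agent's sub-tick polyline as a stroked line (a capsule) of the
#' agent's body width: a pixel is set when its center lies within
#' `width/2 + resolution/2` of a trajectory segment. A single-point polyline
#' (a stationary cell) marks its body-footprint disk. The result is the
#' binary union over agents.
#'
#' @param trajectories List of numeric matrices, one per agent, each
#'   `m x 2` with (x, y) positions in um inside the chamber interior.
#' @param widths Numeric vector of per-agent stroke widths, um (> 0).
#' @param layout An [grid_layout()] object.
#' @param resolution Pixel size, um/pixel.
#' @return An `aq_trace` raster with attribute `tm`, the [compute_tm()]
#'   vector accumulated while drawing.
#' @examples
#' lay <- grid_layout()
#' img <- render_cycle(list(cbind(240, 240)), widths = 20, lay)
#' sum(as.integer(img))  # footprint disk of a stationary 20-um cell
#' @export
render_cycle <- function(trajectories, widths, layout, resolution = 4) {
  img <- trace_image(layout, resolution)
  if (length(trajectories) == 0L) {
    attr(img, "tm") <- integer(25)
    return(img)
  }
  stopifnot(length(widths) == length(trajectories))
  trajectories <- lapply(trajectories, function(m) {
    m <- as.matrix(m)
    if (ncol(m) != 2L) stop("each trajectory must be an m x 2 matrix",
                            call. = FALSE)
    storage.mode(m) <- "double"
    m
  })
  for (m in trajectories) {
    loc <- locate_point(m[, 1], m[, 2], layout)
    if (any(loc$region %in% c("outside")))
      stop("trajectory positions must lie inside the chamber", call. = FALSE)
  }
  sqmap <- get_sqmap(layout, resolution)
  W <- nrow(img)
  tm <- cpp_raster_polylines(trajectories, as.numeric(widths), img,
                             W, W, resolution, sqmap, TRUE)
  attr(img, "tm") <- as.integer(tm)
  img
}

#' Trace momentum: per-square trace pixel counts
#'
#' TM of square i is the number of set pixels whose um-coordinates locate to
#' square i. Pixels over passages and walls belong to no square and are not
#' counted.
#'
#' @param image An `aq_trace` raster (or any 0/1 matrix with a `resolution`
#'   attribute matching the layout).
#' @param layout An [grid_layout()] object.
#' @return Integer vector of 25 counts ordered by square index.
#' @export
compute_tm <- function(image, layout) {
  resolution <- attr(image, "resolution")
  if (is.null(resolution))
    stop("image must carry a resolution attribute", call. = FALSE)
  W <- as.integer(ceiling(layout$side / resolution))
  if (nrow(image) != W || ncol(image) != W)
    stop("image dimensions do not match the layout at this resolution",
         call. = FALSE)
  sqmap <- get_sqmap(layout, resolution)
  set <- as.integer(image) != 0L
  tabulate(sqmap[set], nbins = 25L)
}

#' Signed group trace-momentum ratio
#'
#' The imbalance (TM_I - TM_II) / (TM_I + TM_II), where TM_I and TM_II sum
#' the 12 group-I and group-II entries of the TM vector; the center square
#' is excluded. This is the quantity compared against the prefixed threshold
#' by the two-state flipping algorithm.
#'
#' @param tm Integer vector of 25 per-square TM values.
#' @param layout An [grid_layout()] object.
#' @return A value in \[-1, 1\], or `NA_real_` when both group sums are zero
#'   (callers treat an undefined ratio as "no flip").
#' @examples
#' lay <- grid_layout()
#' tm <- integer(25)
#' tm[group_squares(lay, "I")] <- 62L
#' tm[group_squares(lay, "II")] <- 38L
#' tm_ratio(tm, lay)  # 0.24
#' @export
tm_ratio <- function(tm, layout) {
  if (length(tm) != 25L) stop("tm must have 25 entries", call. = FALSE)
  s1 <- sum(tm[layout$group_of == "I"])
  s2 <- sum(tm[layout$group_of == "II"])
  tot <- s1 + s2
  if (tot == 0) return(NA_real_)
  (s1 - s2) / tot
}
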
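#' Build the 25-square micro-aquarium layout
#'
#' Constructs the geometry of the closed chamber used throughout the package:
#' a `rows` x `cols` grid of square wells (default 5 x 5, 480 um wide,
#' 120 um deep) interconnected by square passages (default 90 um wide and
#' long) centered on every shared wall. Squares are indexed 1..25 in
#' row-major order from the upper-left to the lower-right corner.
#'
#' Coordinates have their origin at the outer upper-left corner, with x
#' increasing rightward and y downward, in micrometres. A square owns its low
#' (left/top) edge but not its high edge, so every interior point belongs to
#' exactly one region. Depth is carried as metadata only; all dynamics are 2D
#' top-view projections.
#'
#' For the feedback experiments the 25 squares are divided into two groups of
#' 12 plus the always-dark center square (index 13). The exact group
#' membership used in the original chamber is not published; this layout uses
#' the parity checkerboard: group I is the 12 squares with odd (row + col)
#' parity, group II the remaining 12 even-parity squares excluding the
#' center.
#'
#' @param square_width Side length of each square well, um.
#' @param passage_width Width (and length) of the connecting passages, um.
#' @param depth Chamber depth, um (metadata only).
#' @param rows,cols Grid dimensions; the feedback algorithms assume 5 x 5.
#'
#' @return An object of class `aq_layout`: a list with the geometry
#'   parameters, `pitch` (square + passage), `side` (total footprint),
#'   `group_of` (factor `"I"`, `"II"`, `"center"` by square index), and
#'   `center` (index of the center square).
#' @examples
#' lay <- grid_layout()
#' lay$side            # 2760 um
#' table(lay$group_of) # 12 / 12 / 1
#' @export
grid_layout <- function(square_width = 480, passage_width = 90, depth = 120,
                        rows = 5L, cols = 5L) {
  if (!is.numeric(square_width) || square_width <= 0 ||
      !is.numeric(passage_width) || passage_width <= 0 || depth <= 0)
    stop("layout dimensions must be positive", call. = FALSE)
  if (rows != 5L || cols != 5L)
    stop("the interlink chamber is a 5 x 5 grid", call. = FALSE)
  if (passage_width >= square_width)
    stop("passage_width must be smaller than square_width", call. = FALSE)
  rows <- as.integer(rows); cols <- as.integer(cols)
  n <- rows * cols
  idx <- seq_len(n)
  row <- (idx - 1L) %/% cols + 1L
  col <- (idx - 1L) %% cols + 1L
  center <- (n + 1L) %/% 2L
  grp <- ifelse((row + col) %% 2L == 1L, "I", "II")
  grp[center] <- "center"
  structure(list(
    rows = rows, cols = cols,
    square_width = square_width,
    passage_width = passage_width,
    depth = depth,
    pitch = square_width + passage_width,
    side = cols * square_width + (cols - 1L) * passage_width,
    index = idx, row = row, col = col,
    group_of = factor(grp, levels = c("I", "II", "center")),
    center = center
  ), class = "aq_layout")
}

#' @export
print.aq_layout <- function(x, ...) {
  cat(sprintf("<aq_layout> %dx%d squares, %g um wide, %g um passages, footprint %g um\n",
              x$rows, x$cols, x$square_width, x$passage_width, x$side))
  cat(sprintf("groups: I=%d, II=%d, center=square %d\n",
              sum(x$group_of == "I"), sum(x$group_of == "II"), x$center))
  invisible(x)
}

#' Square indices belonging to a group
#'
#' @param layout An [grid_layout()] object.
#' @param group `"I"`, `"II"` or `"center"`.
#' @return Integer vector of square indices.
#' @export
group_squares <- function(layout, group = c("I", "II", "center")) {
  group <- match.arg(group)
  which(layout$group_of == group)
}

#' Locate points within the micro-aquarium
#'
#' Maps 2D positions (um, origin upper-left) to the region containing them:
#' a square well, a connecting passage, the PDMS wall between wells, or
#' outside the chamber footprint. Region ownership follows the half-open
#' convention (a region owns its low edge, not its high edge), so the mapping
#' is single-valued.
#'
#' @param x,y Numeric vectors of coordinates in um.
#' @param layout An [grid_layout()] object.
#' @return A data.frame with columns `region` (`"square"`, `"passage"`,
#'   `"wall"`, `"outside"`), `square` (index 1..25 or `NA`), and `passage`
#'   (id string such as `"7-8"` joining the two connected squares, or `NA`).
#' @examples
#' lay <- grid_layout()
#' locate_point(240, 240, lay)   # interior of square 1
#' @export
locate_point <- function(x, y, layout) {
  stopifnot(length(x) == length(y))
  sw <- layout$square_width; pw <- layout$passage_width
  pitch <- layout$pitch; side <- layout$side; nc <- layout$cols
  lo <- (sw - pw) / 2; hi <- (sw + pw) / 2

  cx <- pmin(floor(x / pitch), nc - 1L); offx <- x - cx * pitch
  cy <- pmin(floor(y / pitch), layout$rows - 1L); offy <- y - cy * pitch
  in_sx <- offx >= 0 & offx < sw
  in_sy <- offy >= 0 & offy < sw
  pass_x <- offx >= lo & offx < hi   # centered band, for vertical passages
  pass_y <- offy >= lo & offy < hi

  region <- rep("wall", length(x))
  square <- rep(NA_integer_, length(x))
  passage <- rep(NA_character_, length(x))

  out <- x < 0 | y < 0 | x >= side | y >= side | !is.finite(x) | !is.finite(y)
  region[out] <- "outside"

  sq <- !out & in_sx & in_sy
  square[sq] <- (cy[sq] * nc + cx[sq] + 1L)
  region[sq] <- "square"

  # horizontal passage: in the x-gap between columns cx and cx+1
  hp <- !out & !in_sx & in_sy & pass_y
  if (any(hp)) {
    a <- cy[hp] * nc + cx[hp] + 1L
    passage[hp] <- paste0(a, "-", a + 1L)
    region[hp] <- "passage"
  }
  # vertical passage: in the y-gap between rows cy and cy+1
  vp <- !out & in_sx & !in_sy & pass_x
  if (any(vp)) {
    a <- cy[vp] * nc + cx[vp] + 1L
    passage[vp] <- paste0(a, "-", a + nc)
    region[vp] <- "passage"
  }
  data.frame(region = region, square = square, passage = passage,
             stringsAsFactors = FALSE)
}

#' Center coordinates of a square well
#'
#' @param index Square index (vectorized, 1..25).
#' @param layout An [grid_layout()] object.
#' @return A two-column matrix of (x, y) in um.
#' @export
square_center <- function(index, layout) {
  if (any(index < 1L | index > layout$rows * layout$cols))
    stop("square index out of range", call. = FALSE)
  r <- (index - 1L) %/% layout$cols
  c <- (index - 1L) %% layout$cols
  cbind(x = c * layout$pitch + layout$square_width / 2,
        y = r * layout$pitch + layout$square_width / 2)
}

#' 4-neighborhood of a square
#'
#' Returns the squares connected to `index` by a passage: the 4-neighborhood
#' restricted to the grid, so corner squares have 2 neighbors, edge squares 3
#' and interior squares 4.
#'
#' @inheritParams square_center
#' @return Sorted integer vector of neighboring square indices.
#' @export
square_neighbors <- function(index, layout) {
  n <- layout$rows * layout$cols
  if (length(index) != 1L || is.na(index) || index < 1L || index > n)
    stop("square index out of range", call. = FALSE)
  index <- as.integer(index)
  r <- (index - 1L) %/% layout$cols
  c <- (index - 1L) %% layout$cols
  nb <- integer(0)
  if (r > 0L) nb <- c(nb, index - layout$cols)
  if (r < layout$rows - 1L) nb <- c(nb, index + layout$cols)
  if (c > 0L) nb <- c(nb, index - 1L)
  if (c < layout$cols - 1L) nb <- c(nb, index + 1L)
  sort(nb)
}

#' Export the group map as a data.frame
#'
#' One row per square: index, row, col, group. Convenient for writing the
#' layout to CSV alongside an experiment log.
#'
#' @param layout An [grid_layout()] object.
#' @return A data.frame with 25 rows.
#' @export
layout_table <- function(layout) {
  data.frame(index = layout$index, row = layout$row, col = layout$col,
             group = as.character(layout$group_of), stringsAsFactors = FALSE)
}

# Per-pixel square map for a raster covering the layout bounding box:
# integer vector (column-major, W x H) with the square index owning each
# pixel center, 0 for passage/wall pixels. Cached on the layout by callers.
pixel_square_map <- function(layout, resolution) {
  W <- ceiling(layout$side / resolution)
  centers <- (seq_len(W) - 0.5) * resolution
  g <- expand.grid(x = centers, y = centers) # column-major: x fastest
  loc <- locate_point(g$x, g$y, layout)
  m <- ifelse(loc$region == "square", loc$square, 0L)
  as.integer(m)
}
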
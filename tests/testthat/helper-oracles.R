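# Independent brute-force oracles used to check the fast implementations.

# squared distance from points (px, py) to segment (x0,y0)-(x1,y1)
dist2_seg <- function(px, py, x0, y0, x1, y1) {
  dx <- x1 - x0; dy <- y1 - y0
  len2 <- dx * dx + dy * dy
  if (len2 <= 0) return((px - x0)^2 + (py - y0)^2)
  t <- ((px - x0) * dx + (py - y0) * dy) / len2
  t <- pmin(pmax(t, 0), 1)
  (px - (x0 + t * dx))^2 + (py - (y0 + t * dy))^2
}

# per-pixel rasterization oracle: set a pixel when its center lies within
# width/2 + resolution/2 of any trajectory segment
oracle_raster <- function(polylines, widths, layout, resolution) {
  W <- ceiling(layout$side / resolution)
  xs <- (seq_len(W) - 0.5) * resolution
  px <- matrix(xs, W, W)               # x varies along rows
  py <- matrix(xs, W, W, byrow = TRUE) # y varies along columns
  set <- matrix(FALSE, W, W)
  for (i in seq_along(polylines)) {
    m <- as.matrix(polylines[[i]])
    r2 <- (widths[i] / 2 + resolution / 2)^2
    if (nrow(m) == 1L) {
      set <- set | (dist2_seg(px, py, m[1, 1], m[1, 2], m[1, 1],
                              m[1, 2]) <= r2)
    } else {
      for (k in seq_len(nrow(m) - 1L))
        set <- set | (dist2_seg(px, py, m[k, 1], m[k, 2], m[k + 1, 1],
                                m[k + 1, 2]) <= r2)
    }
  }
  set
}

# TM oracle: classify every set pixel's center with locate_point
oracle_tm <- function(set, layout, resolution) {
  idx <- which(set, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(integer(25))
  loc <- locate_point((idx[, 1] - 0.5) * resolution,
                      (idx[, 2] - 0.5) * resolution, layout)
  tabulate(loc$square[loc$region == "square"], nbins = 25L)
}

# k lowest/highest selection by repeated scanning (ties to lowest index)
oracle_ranking <- function(tm, select, k = 12L) {
  lit <- logical(25)
  avail <- rep(TRUE, 25)
  for (j in seq_len(k)) {
    cand <- which(avail)
    v <- tm[cand]
    pick <- cand[if (select == "lowest") which.min(v) else which.max(v)]
    lit[pick] <- TRUE
    avail[pick] <- FALSE
  }
  lit
}

# connected components by iterative label relaxation (different algorithm
# from the package's flood fill)
oracle_components <- function(cells, rows = 5L, cols = 5L) {
  lab <- ifelse(cells, seq_along(cells), 0L)
  repeat {
    new <- lab
    for (s in which(cells)) {
      r <- (s - 1L) %/% cols; c <- (s - 1L) %% cols
      nb <- c(if (r > 0L) s - cols, if (r < rows - 1L) s + cols,
              if (c > 0L) s - 1L, if (c < cols - 1L) s + 1L)
      nb <- nb[cells[nb]]
      new[s] <- min(c(lab[s], lab[nb]))
    }
    if (identical(new, lab)) break
    lab <- new
  }
  length(unique(lab[cells]))
}

# boundary oracle from an explicit adjacency list
oracle_boundaries <- function(pattern, rows = 5L, cols = 5L) {
  n <- 0L
  for (s in seq_len(rows * cols)) {
    r <- (s - 1L) %/% cols; c <- (s - 1L) %% cols
    if (c < cols - 1L && pattern[s] != pattern[s + 1L]) n <- n + 1L
    if (r < rows - 1L && pattern[s] != pattern[s + cols]) n <- n + 1L
  }
  n
}

# small simulation configs used across tests
small_config <- function(...) {
  args <- list(n_euglena = 60L, n_chlamy = 150L, total_steps = 80L,
               warmup_steps = 15L, cooldown_steps = 15L)
  args <- utils::modifyList(args, list(...))
  do.call(experiment_config, args)
}

random_pattern <- function(k = 12L) {
  p <- logical(25)
  p[sample.int(25L, k)] <- TRUE
  p
}
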
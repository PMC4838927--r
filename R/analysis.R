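# Headline metrics extracted from experiment logs: oscillation period and
# phase delay (from illumination flip events), illumination coincidence,
# per-square duty ratios, grid clustering, and ranked pattern frequencies.

flips_of <- function(log, dish, group = NULL) {
  f <- log$flips[log$flips$dish == dish, , drop = FALSE]
  if (!is.null(group)) f <- f[f$group == group, , drop = FALSE]
  f
}

#' Oscillation period from flip events
#'
#' The full period is the mean time between consecutive flips of one dish's
#' illumination to group I (one full cycle contains two alternating flips).
#' Dish B is the default reference: its commands arrive fast and cleanly
#' because the dish-B trace momentum responds within a fraction of a minute.
#'
#' @param log An `aq_log`.
#' @param dish `"B"` (default) or `"A"`.
#' @param group Reference group marking the start of a cycle.
#' @return A list of class `aq_osc` with `period_mean`, `period_sd`
#'   (minutes) and `n_cycles`.
#' @export
oscillation_period <- function(log, dish = "B", group = "I") {
  f <- flips_of(log, dish, group)
  if (nrow(f) < 2L)
    stop("insufficient oscillation: fewer than 2 flips of dish ", dish,
         " to group ", group, call. = FALSE)
  per <- diff(f$time_s) / 60
  structure(list(period_mean = mean(per), period_sd = stats::sd(per),
                 n_cycles = length(per)),
            class = "aq_osc")
}

#' @export
print.aq_osc <- function(x, ...) {
  if (!is.null(x$period_mean))
    cat(sprintf("period %.2f +/- %.2f min over %d cycles\n",
                x$period_mean, x$period_sd, x$n_cycles))
  if (!is.null(x$delay_mean))
    cat(sprintf("phase delay %.2f +/- %.2f min over %d flips\n",
                x$delay_mean, x$delay_sd, x$n_pairs))
  invisible(x)
}

#' Phase delay between the two dishes
#'
#' Mean time from each dish-B illumination flip to the next dish-A flip.
#' A trailing dish-B flip with no subsequent dish-A flip before the log ends
#' is dropped; any other unmatched flip (two dish-B flips without an
#' intervening dish-A flip) raises an error listing the orphan steps.
#'
#' @param log An `aq_log`.
#' @return A list of class `aq_osc` with `delay_mean`, `delay_sd` (minutes)
#'   and `n_pairs`.
#' @export
phase_delay <- function(log) {
  fb <- flips_of(log, "B"); fa <- flips_of(log, "A")
  if (nrow(fb) == 0L || nrow(fa) == 0L)
    stop("phase delay needs flips in both dishes", call. = FALSE)
  nxt <- findInterval(fb$step, fa$step) + 1L  # first A flip strictly later
  # same A flip claimed by two B flips => the earlier B flip is orphaned
  orphan <- fb$step[duplicated(nxt, fromLast = TRUE)]
  if (length(orphan) > 0L)
    stop("unmatched dish-B flips at steps ",
         paste(orphan, collapse = ", "), call. = FALSE)
  keep <- nxt <= nrow(fa)                     # drop trailing unmatched flip
  lag <- (fa$time_s[nxt[keep]] - fb$time_s[keep]) / 60
  structure(list(delay_mean = mean(lag), delay_sd = stats::sd(lag),
                 n_pairs = length(lag)),
            class = "aq_osc")
}

#' Illumination coincidence between two patterns
#'
#' Number of corresponding squares (0-25) with the same
#' illumination/non-illumination status in both dishes. When both patterns
#' light exactly 12 squares the coincidence is always odd.
#'
#' @param patternA,patternB Logical vectors of 25 illumination flags.
#' @return Integer count in 0..25.
#' @export
coincidence <- function(patternA, patternB) {
  stopifnot(length(patternA) == length(patternB))
  sum(patternA == patternB)
}

#' Coincidence time series with moving average
#'
#' Per-step illumination coincidence between the two dishes, plus a
#' centered moving average over +/- `half_width` steps (windows truncated
#' at the log edges, not padded).
#'
#' @param log An `aq_log`.
#' @param half_width Moving-average half width, steps.
#' @return A data.frame with `step`, `time_s`, `coincidence`, `smoothed`.
#' @export
coincidence_series <- function(log, half_width = 10L) {
  raw <- rowSums(log$patternA == log$patternB)
  n <- length(raw)
  cs <- cumsum(c(0, raw))
  i <- seq_len(n)
  a <- pmax(i - half_width, 1L); b <- pmin(i + half_width, n)
  sm <- (cs[b + 1L] - cs[a]) / (b - a + 1L)
  data.frame(step = log$step, time_s = log$time_s,
             coincidence = as.integer(raw), smoothed = sm)
}

#' Per-square illumination duty ratio
#'
#' Fraction of feedback-active steps during which each square was lit:
#' (illumination-On time steps) / (total feedback time steps).
#'
#' @param log An `aq_log`.
#' @param dish `"A"` or `"B"`.
#' @return Numeric vector of 25 fractions in \[0, 1\].
#' @export
duty_ratio <- function(log, dish = c("A", "B")) {
  dish <- match.arg(dish)
  w <- feedback_window(log)
  if (length(w) == 0L) stop("feedback window is empty", call. = FALSE)
  pat <- if (dish == "A") log$patternA else log$patternB
  colMeans(pat[w, , drop = FALSE])
}

# 4-connected components of TRUE cells on the rows x cols grid
grid_components <- function(cells, rows = 5L, cols = 5L) {
  lab <- integer(length(cells))
  comp <- 0L
  for (s in which(cells)) {
    if (lab[s] > 0L) next
    comp <- comp + 1L
    queue <- s
    lab[s] <- comp
    while (length(queue) > 0L) {
      v <- queue[[1L]]; queue <- queue[-1L]
      r <- (v - 1L) %/% cols; c <- (v - 1L) %% cols
      nb <- c(if (r > 0L) v - cols, if (r < rows - 1L) v + cols,
              if (c > 0L) v - 1L, if (c < cols - 1L) v + 1L)
      nb <- nb[cells[nb] & lab[nb] == 0L]
      lab[nb] <- comp
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Number of clustered domains in a pattern
#'
#' Counts the 4-connected components (passages exist only on shared walls,
#' so diagonal contact does not join domains) of lit or unlit squares on the
#' 5 x 5 grid. A single tight cluster of non-illuminated squares gives 1.
#'
#' @param pattern Logical vector of 25 illumination flags.
#' @param status Count components of `"lit"` or `"unlit"` squares.
#' @return Integer component count (0 when no square has the status).
#' @export
cluster_count <- function(pattern, status = c("unlit", "lit")) {
  status <- match.arg(status)
  stopifnot(length(pattern) == 25L)
  cells <- if (status == "lit") as.logical(pattern) else !pattern
  grid_components(cells)
}

#' Number of lit/unlit boundaries in a pattern
#'
#' Counts the 4-adjacent square pairs whose illumination status differs.
#' Fewer boundaries means tighter domain clustering.
#'
#' @param pattern Logical vector of 25 illumination flags.
#' @return Integer count (0..40 on the 5 x 5 grid).
#' @export
boundary_count <- function(pattern) {
  stopifnot(length(pattern) == 25L)
  p <- matrix(as.logical(pattern), 5L, 5L, byrow = TRUE)
  sum(p[-5L, ] != p[-1L, ]) + sum(p[, -5L] != p[, -1L])
}

#' Ranked illumination-pattern histogram
#'
#' Over the feedback-active steps whose illumination coincidence falls in
#' `coincidence_filter`, counts identical 25-square lit masks of the chosen
#' dish and ranks them by frequency (ties broken by first occurrence).
#'
#' @param log An `aq_log`.
#' @param dish `"A"` or `"B"`.
#' @param coincidence_filter Integer vector of admissible coincidence
#'   values (default 21:25, the high-reversal patterns).
#' @return A data.frame with `pattern` (25-char 0/1 mask), `count`, and
#'   `first_step`; rows sorted by decreasing count.
#' @export
pattern_histogram <- function(log, dish = c("A", "B"),
                              coincidence_filter = 21:25) {
  dish <- match.arg(dish)
  w <- feedback_window(log)
  co <- rowSums(log$patternA[w, , drop = FALSE] ==
                  log$patternB[w, , drop = FALSE])
  w <- w[co %in% coincidence_filter]
  if (length(w) == 0L)
    return(data.frame(pattern = character(), count = integer(),
                      first_step = integer(), stringsAsFactors = FALSE))
  pat <- if (dish == "A") log$patternA else log$patternB
  masks <- apply(pat[w, , drop = FALSE], 1L, function(z)
    paste(as.integer(z), collapse = ""))
  first <- !duplicated(masks)
  counts <- table(factor(masks, levels = masks[first]))
  out <- data.frame(pattern = names(counts), count = as.integer(counts),
                    first_step = w[first], stringsAsFactors = FALSE)
  out[order(-out$count, seq_len(nrow(out))), , drop = FALSE]
}
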
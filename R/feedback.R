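#' Two-state flipping decision
#'
#' Rule of the oscillation algorithm: when the group trace-momentum
#' imbalance of one dish crosses the prefixed threshold, the TM-dominant
#' group becomes the illuminated group of the counter-dish at the next time
#' step. Level-triggered: while the threshold remains exceeded the same
#' group keeps being commanded (re-assignment of an already-lit group is a
#' no-op upstream).
#'
#' @param ratio Signed group-TM ratio in \[-1, 1\] (`NA` when undefined).
#' @param threshold Prefixed threshold in (0, 1).
#' @return `"I"`, `"II"`, or `"none"`.
#' @examples
#' flip_target(-0.45, 0.40)  # "II"
#' flip_target(0.24, 0.40)   # "none"
#' flip_target(0.49, 0.40)   # "I"
#' @export
flip_target <- function(ratio, threshold) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1)
    stop("threshold must be in (0, 1)", call. = FALSE)
  if (is.na(ratio)) return("none")
  if (abs(ratio) > 1) stop("|ratio| must be <= 1", call. = FALSE)
  if (abs(ratio) < threshold) return("none")
  if (ratio > 0) "I" else "II"
}

#' Fixed group illumination pattern
#'
#' The oscillation algorithm's pattern: the 12 squares of one group lit, the
#' other group and the center square dark.
#'
#' @param group `"I"` or `"II"`.
#' @param layout An [grid_layout()] object.
#' @return Logical vector of 25 illumination flags by square index.
#' @export
group_pattern <- function(group = c("I", "II"), layout) {
  group <- match.arg(group)
  layout$group_of == group
}

#' Ranking illumination pattern
#'
#' The separation/clustering algorithm's pattern: light the squares holding
#' the `k` lowest (or highest) TM values of the counter-dish, over all 25
#' squares (center included). Ties resolve to the lower square index.
#'
#' @param tm Numeric vector of 25 TM values.
#' @param select `"lowest"` or `"highest"`.
#' @param k Number of squares to light (default 12).
#' @return Logical vector of 25 illumination flags.
#' @export
ranking_pattern <- function(tm, select = c("lowest", "highest"), k = 12L) {
  select <- match.arg(select)
  if (length(tm) != 25L) stop("tm must have 25 entries", call. = FALSE)
  if (k > 25L) stop("k must be <= 25", call. = FALSE)
  key <- if (select == "lowest") tm else -tm
  lit <- logical(25)
  lit[order(key, seq_along(tm))[seq_len(k)]] <- TRUE
  lit
}

#' One interlink exchange
#'
#' Given the TM vectors measured in both dishes at the current step,
#' computes the illumination patterns both dishes will apply at the next
#' step, per the chosen algorithm. Oscillation mode: dish A's ratio decides
#' dish B's lit group (and vice versa) through [flip_target()]; `"none"`
#' leaves a group unchanged. Ranking mode: dish B gets the 12 lowest-TM
#' squares of dish A, dish A the 12 highest-TM squares of dish B.
#'
#' @param tmA,tmB TM vectors (25) measured at the same step.
#' @param state Controller state: list with `threshold`, `groupA`, `groupB`
#'   (current lit groups, oscillation mode only).
#' @param algorithm `"oscillation"` or `"ranking"`.
#' @param layout An [grid_layout()] object.
#' @return List with `patternA`, `patternB` (logical 25, to apply next
#'   step), updated `state`, and `flips`: a data.frame (possibly empty) of
#'   flip events with columns `dish`, `group`.
#' @export
interlink_step <- function(tmA, tmB, state, algorithm = c("oscillation",
                                                          "ranking"),
                           layout) {
  algorithm <- match.arg(algorithm)
  flips <- data.frame(dish = character(), group = character(),
                      stringsAsFactors = FALSE)
  if (algorithm == "ranking") {
    return(list(patternA = ranking_pattern(tmB, "highest"),
                patternB = ranking_pattern(tmA, "lowest"),
                state = state, flips = flips))
  }
  ratioA <- tm_ratio(tmA, layout)
  ratioB <- tm_ratio(tmB, layout)
  tgtB <- flip_target(ratioA, state$threshold) # A's imbalance commands B
  tgtA <- flip_target(ratioB, state$threshold)
  if (tgtB != "none" && tgtB != state$groupB) {
    state$groupB <- tgtB
    flips <- rbind(flips, data.frame(dish = "B", group = tgtB,
                                     stringsAsFactors = FALSE))
  }
  if (tgtA != "none" && tgtA != state$groupA) {
    state$groupA <- tgtA
    flips <- rbind(flips, data.frame(dish = "A", group = tgtA,
                                     stringsAsFactors = FALSE))
  }
  list(patternA = group_pattern(state$groupA, layout),
       patternB = group_pattern(state$groupB, layout),
       state = state, flips = flips)
}

#' Experiment configuration
#'
#' Assembles and validates everything a run needs: the schedule (4000 time
#' steps of 1.47 s with feedback suspended during the first and last 500),
#' cell counts (about 400 Euglena-like cells in dish A, 1300
#' Chlamydomonas-like in dish B), the feedback algorithm and threshold, the
#' imaging resolution, and the behavioral parameters.
#'
#' @param algorithm `"oscillation"` (two-state flipping) or `"ranking"`.
#' @param threshold Prefixed ratio threshold for the flipping algorithm.
#' @param n_euglena,n_chlamy Cell counts for dishes A and B.
#' @param seed Master seed; all randomness in the run derives from it.
#' @param total_steps,warmup_steps,cooldown_steps Schedule, in feedback
#'   cycles. Feedback is active on steps `warmup_steps + 1` through
#'   `total_steps - cooldown_steps`.
#' @param cycle_s Feedback cycle duration, s (0.68 Hz refresh).
#' @param n_subticks Motion sub-ticks per cycle.
#' @param resolution Trace-image pixel size, um/pixel.
#' @param sync_jitter_cycles Maximum extra TM-exchange delay, cycles
#'   (models the inter-system synchronization error; 0 = perfectly
#'   synchronous, 1 = up to one extra cycle, drawn uniformly per step).
#' @param resting_fraction Initial resting fraction of the dish-B cells.
#' @param params A [behavior_params()] object.
#' @param layout An [grid_layout()] object.
#' @return A list of class `aq_config`.
#' @export
experiment_config <- function(algorithm = c("oscillation", "ranking"),
                              threshold = 0.40,
                              n_euglena = 400L, n_chlamy = 1300L,
                              seed = 1L,
                              total_steps = 4000L, warmup_steps = 500L,
                              cooldown_steps = 500L,
                              cycle_s = 1.47, n_subticks = 10L,
                              resolution = 4,
                              sync_jitter_cycles = 0L,
                              resting_fraction = 0.5,
                              params = behavior_params(),
                              layout = grid_layout()) {
  algorithm <- match.arg(algorithm)
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must be in (0, 1)", call. = FALSE)
  if (total_steps < 1L || warmup_steps < 0L || cooldown_steps < 0L ||
      warmup_steps + cooldown_steps >= total_steps)
    stop("warmup + cooldown must be smaller than total_steps",
         call. = FALSE)
  if (cycle_s <= 0) stop("cycle_s must be positive", call. = FALSE)
  if (n_subticks < 1L) stop("n_subticks must be >= 1", call. = FALSE)
  if (sync_jitter_cycles < 0L)
    stop("sync_jitter_cycles must be >= 0", call. = FALSE)
  if (resting_fraction < 0 || resting_fraction > 1)
    stop("resting_fraction must be in [0, 1]", call. = FALSE)
  stopifnot(inherits(params, "aq_params"), inherits(layout, "aq_layout"))
  structure(list(
    algorithm = algorithm, threshold = threshold,
    n_euglena = as.integer(n_euglena), n_chlamy = as.integer(n_chlamy),
    seed = as.integer(seed),
    total_steps = as.integer(total_steps),
    warmup_steps = as.integer(warmup_steps),
    cooldown_steps = as.integer(cooldown_steps),
    cycle_s = cycle_s, n_subticks = as.integer(n_subticks),
    resolution = resolution,
    sync_jitter_cycles = as.integer(sync_jitter_cycles),
    resting_fraction = resting_fraction,
    params = params, layout = layout
  ), class = "aq_config")
}

#' @export
print.aq_config <- function(x, ...) {
  cat(sprintf("<aq_config> %s, threshold %g, %d+%d cells, %d steps (%g s each), seed %d\n",
              x$algorithm, x$threshold, x$n_euglena, x$n_chlamy,
              x$total_steps, x$cycle_s, x$seed))
  invisible(x)
}

#' Run a full interlinked experiment
#'
#' Simulates both dishes cycle by cycle: advance the cells through
#' `n_subticks` motion sub-ticks under the current illumination patterns,
#' rasterize the cycle's swimming traces, count the per-square trace
#' momentum, exchange the TM vectors, and compute the next patterns with the
#' configured algorithm. Feedback illumination is suspended (all squares
#' dark) during the warmup and cooldown windows; TM is measured on every
#' step regardless. Patterns applied at step t + 1 depend only on TM
#' measured at steps <= t.
#'
#' All randomness derives from `config$seed` through independent per-dish
#' streams, so a rerun with the same configuration reproduces the log
#' exactly, and dish-A trajectories do not depend on dish-B settings.
#'
#' @param config An [experiment_config()] object.
#' @param progress Print a progress line every 500 steps.
#' @return An object of class `aq_log`: list with `step`, `time_s` (time at
#'   the end of each cycle), `patternA`/`patternB` (steps x 25 logical),
#'   `tmA`/`tmB` (steps x 25 integer), `ratioA`/`ratioB`, `flips` (data
#'   frame: step, time_s, dish, group), and the `config`.
#' @export
run_experiment <- function(config, progress = FALSE) {
  stopifnot(inherits(config, "aq_config"))
  lay <- config$layout
  res <- config$resolution
  sqmap <- get_sqmap(lay, res)
  W <- as.integer(ceiling(lay$side / res))
  img <- raw(W * W)
  dt <- config$cycle_s / config$n_subticks
  nsub <- config$n_subticks
  N <- config$total_steps
  fb_start <- config$warmup_steps + 1L
  fb_end <- N - config$cooldown_steps

  seeds <- derive_seeds(config$seed, 3L)
  stA <- make_stream(seeds[1]); stB <- make_stream(seeds[2])
  stJ <- make_stream(seeds[3])

  popA <- with_stream(stA, init_population("euglena", config$n_euglena, lay))
  popB <- with_stream(stB, init_population("chlamy", config$n_chlamy, lay,
                                           config$resting_fraction))
  dA <- pop_dims(popA); dB <- pop_dims(popB)
  txA <- matrix(0, popA$n, nsub + 1L); tyA <- matrix(0, popA$n, nsub + 1L)
  swA <- matrix(0, popA$n, nsub)
  txB <- matrix(0, popB$n, nsub + 1L); tyB <- matrix(0, popB$n, nsub + 1L)
  swB <- matrix(0, popB$n, nsub)
  parA <- unclass(config$params); parB <- parA
  glay <- unclass(lay)

  patternA <- matrix(FALSE, N, 25L); patternB <- matrix(FALSE, N, 25L)
  tmA <- matrix(0L, N, 25L); tmB <- matrix(0L, N, 25L)
  ratioA <- rep(NA_real_, N); ratioB <- rep(NA_real_, N)
  flips <- vector("list", 64L); nflip <- 0L

  off <- logical(25L)
  litA <- off; litB <- off
  grpA <- grpB <- "I"
  osc <- config$algorithm == "oscillation"

  exchange_tm <- function(step) {
    # TM dataset available to the controller when computing patterns for
    # `step`: measured at step - 1 minus an optional jitter delay.
    lag <- 1L
    if (config$sync_jitter_cycles > 0L)
      lag <- lag + with_stream(stJ, sample.int(config$sync_jitter_cycles +
                                                 1L, 1L) - 1L)
    max(step - lag, 1L)
  }

  for (step in seq_len(N)) {
    # illumination pattern applied during this cycle
    if (step < fb_start || step > fb_end) {
      litA <- off; litB <- off
    } else if (step == fb_start) {
      if (osc) {
        grpA <- grpB <- "I" # rule: start the feedback lit on group I
        litA <- litB <- group_pattern("I", lay)
      } else {
        s0 <- exchange_tm(step)
        litB <- ranking_pattern(tmA[s0, ], "lowest")
        litA <- ranking_pattern(tmB[s0, ], "highest")
      }
    } else {
      s0 <- exchange_tm(step)
      if (osc) {
        tgtB <- flip_target(ratioA[s0], config$threshold)
        if (tgtB != "none" && tgtB != grpB) {
          grpB <- tgtB; nflip <- nflip + 1L
          flips[[nflip]] <- list(step = step, dish = "B", group = tgtB)
        }
        tgtA <- flip_target(ratioB[s0], config$threshold)
        if (tgtA != "none" && tgtA != grpA) {
          grpA <- tgtA; nflip <- nflip + 1L
          flips[[nflip]] <- list(step = step, dish = "A", group = tgtA)
        }
        litA <- group_pattern(grpA, lay); litB <- group_pattern(grpB, lay)
      } else {
        litB <- ranking_pattern(tmA[s0, ], "lowest")
        litA <- ranking_pattern(tmB[s0, ], "highest")
      }
    }
    patternA[step, ] <- litA; patternB[step, ] <- litB

    with_stream(stA, cpp_cycle(popA$x, popA$y, popA$heading, popA$speed,
                               popA$mode, dA$d1, dA$d2, dA$code, litA,
                               glay, parA, dt, nsub, txA, tyA, swA))
    tmA[step, ] <- cpp_raster_tm(txA, tyA, swA, img, W, W, res, sqmap, TRUE)
    with_stream(stB, cpp_cycle(popB$x, popB$y, popB$heading, popB$speed,
                               popB$mode, dB$d1, dB$d2, dB$code, litB,
                               glay, parB, dt, nsub, txB, tyB, swB))
    tmB[step, ] <- cpp_raster_tm(txB, tyB, swB, img, W, W, res, sqmap, TRUE)
    ratioA[step] <- tm_ratio(tmA[step, ], lay)
    ratioB[step] <- tm_ratio(tmB[step, ], lay)

    if (progress && step %% 500L == 0L)
      message(sprintf("step %d / %d", step, N))
    if (nflip == length(flips)) flips <- c(flips, vector("list", nflip))
  }

  fl <- if (nflip > 0L) {
    do.call(rbind, lapply(flips[seq_len(nflip)], function(f)
      data.frame(step = f$step, time_s = f$step * config$cycle_s,
                 dish = f$dish, group = f$group, stringsAsFactors = FALSE)))
  } else {
    data.frame(step = integer(), time_s = numeric(), dish = character(),
               group = character(), stringsAsFactors = FALSE)
  }
  structure(list(step = seq_len(N), time_s = seq_len(N) * config$cycle_s,
                 patternA = patternA, patternB = patternB,
                 tmA = tmA, tmB = tmB, ratioA = ratioA, ratioB = ratioB,
                 flips = fl, config = config),
            class = "aq_log")
}

#' @export
print.aq_log <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<aq_log> %d steps (%s mode), %d flip events, duration %.1f min\n",
              length(x$step),
              if (is.null(cfg)) "?" else cfg$algorithm,
              nrow(x$flips), max(x$time_s) / 60))
  invisible(x)
}

# Feedback-active window of a log, as a step-index vector.
feedback_window <- function(log) {
  cfg <- log$config
  seq.int(cfg$warmup_steps + 1L, cfg$total_steps - cfg$cooldown_steps)
}
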
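#' Behavioral parameters of the two cell models
#'
#' Collects the free parameters of the stochastic cell models. The shipped
#' defaults were calibrated so that the full interlinked simulation
#' reproduces the reference oscillation-period anchors (1.6 min at threshold
#' 0.05, 6.5 min at 0.40) and the 0.43 min phase delay; see the methods
#' vignette for the calibration procedure.
#'
#' @param euglena_border_turn_prob Probability that a swimming Euglena-like
#'   cell approaching an illuminated square turns back at the illumination
#'   border instead of crossing it.
#' @param euglena_heading_noise Heading diffusion of swimming cells,
#'   rad/sqrt(s).
#' @param euglena_tumble_speed_frac Drift speed while tumbling, as a
#'   fraction of the cell's own swimming speed. Together with
#'   `euglena_tumble_reorient` this sets the effective diffusivity of the
#'   light-induced tumble and hence the escape rate from illuminated
#'   squares, which governs the oscillation period.
#' @param euglena_tumble_reorient Probability per sub-tick that a tumbling
#'   cell re-randomizes its heading.
#' @param euglena_tumble_stroke_frac Stroke width of the tumbling trace as a
#'   fraction of body length (the spinning body sweeps laterally). Chosen so
#'   the per-cell trace area is close between swimming and tumbling states,
#'   making the group-TM ratio occupancy-driven.
#' @param chlamy_k_act Light-driven resting-to-active rate, 1/s.
#' @param chlamy_k_rest Dark active-to-resting rate, 1/s.
#' @param chlamy_heading_noise Heading diffusion of active cells,
#'   rad/sqrt(s).
#' @param chlamy_exit_damping Probability that an active cell in an
#'   illuminated square succeeds in an attempt to leave that square
#'   (bottom-side illumination makes cells fail to find the exits).
#' @param wall_jitter Amplitude (rad) of the uniform heading jitter added on
#'   wall reflections.
#' @param draw_resting Whether resting cells contribute their static body
#'   footprint to the trace image.
#'
#' @return A named list of class `aq_params`.
#' @export
behavior_params <- function(euglena_border_turn_prob = 0.85,
                            euglena_heading_noise = 0.3,
                            euglena_tumble_speed_frac = 0.67,
                            euglena_tumble_reorient = 0.12,
                            euglena_tumble_stroke_frac = 0.30,
                            chlamy_k_act = 0.075,
                            chlamy_k_rest = 0.05,
                            chlamy_heading_noise = 1.2,
                            chlamy_exit_damping = 0.1,
                            wall_jitter = 0.3,
                            draw_resting = TRUE) {
  p <- list(euglena_border_turn_prob = euglena_border_turn_prob,
            euglena_heading_noise = euglena_heading_noise,
            euglena_tumble_speed_frac = euglena_tumble_speed_frac,
            euglena_tumble_reorient = euglena_tumble_reorient,
            euglena_tumble_stroke_frac = euglena_tumble_stroke_frac,
            chlamy_k_act = chlamy_k_act,
            chlamy_k_rest = chlamy_k_rest,
            chlamy_heading_noise = chlamy_heading_noise,
            chlamy_exit_damping = chlamy_exit_damping,
            wall_jitter = wall_jitter,
            draw_resting = draw_resting)
  probs <- c("euglena_border_turn_prob", "euglena_tumble_reorient",
             "chlamy_exit_damping")
  for (nm in setdiff(names(p), "draw_resting"))
    if (!is.numeric(p[[nm]]) || p[[nm]] < 0)
      stop(nm, " must be non-negative", call. = FALSE)
  for (nm in probs)
    if (p[[nm]] > 1) stop(nm, " is a probability and must be <= 1",
                          call. = FALSE)
  structure(p, class = "aq_params")
}

#' @export
print.aq_params <- function(x, ...) {
  cat("<aq_params>\n")
  for (nm in names(x)) cat(sprintf("  %-28s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

# Species constants: published body-size and swimming-speed ranges.
species_ranges <- function(species) {
  switch(species,
    euglena = list(speed = c(30, 90), body_length = c(20, 100),
                   body_width = c(5, 15)),
    chlamy  = list(speed = c(20, 100), diameter = c(10, 30)),
    stop("unknown species: ", species, call. = FALSE))
}

#' Initialize a cell population
#'
#' Draws `n` cells with positions uniform over the square-well interiors,
#' headings uniform on \[0, 2*pi), and per-cell constant speeds and body
#' sizes uniform over the species' published ranges (Euglena-like: 30-90 um/s,
#' body 20-100 um long; Chlamydomonas-like: 20-100 um/s, 10-30 um diameter).
#' Euglena-like cells start swimming; Chlamydomonas-like cells start with a
#' configurable resting fraction.
#'
#' The population is a mutable state container (an environment): the
#' stepping functions advance it in place.
#'
#' @param species `"euglena"` or `"chlamy"`.
#' @param n Number of cells (> 0).
#' @param layout An [grid_layout()] object.
#' @param resting_fraction For `"chlamy"`, initial fraction of resting
#'   cells (default 0.5).
#'
#' @return An environment of class `aq_population` with numeric vectors
#'   `x`, `y`, `heading`, `speed`, `mode` and the species body dimensions
#'   (`body_width`/`body_length` or `diameter`). Mode coding: Euglena
#'   0 = swimming, 1 = tumbling; Chlamy 0 = resting, 1 = active.
#' @export
init_population <- function(species = c("euglena", "chlamy"), n, layout,
                            resting_fraction = 0.5) {
  species <- match.arg(species)
  if (!is.numeric(n) || length(n) != 1L || n <= 0)
    stop("population size must be positive", call. = FALSE)
  n <- as.integer(n)
  rg <- species_ranges(species)
  sq <- sample.int(layout$rows * layout$cols, n, replace = TRUE)
  r <- (sq - 1L) %/% layout$cols
  cc <- (sq - 1L) %% layout$cols
  pop <- new.env(parent = emptyenv())
  pop$species <- species
  pop$n <- n
  pop$x <- cc * layout$pitch + runif(n) * layout$square_width
  pop$y <- r * layout$pitch + runif(n) * layout$square_width
  pop$heading <- runif(n, 0, 2 * pi)
  pop$speed <- runif(n, rg$speed[1], rg$speed[2])
  if (species == "euglena") {
    pop$body_length <- runif(n, rg$body_length[1], rg$body_length[2])
    pop$body_width <- runif(n, rg$body_width[1], rg$body_width[2])
    pop$mode <- integer(n)                       # all swimming
  } else {
    pop$diameter <- runif(n, rg$diameter[1], rg$diameter[2])
    pop$mode <- as.integer(runif(n) >= resting_fraction) # 1 = active
  }
  class(pop) <- "aq_population"
  pop
}

#' @export
print.aq_population <- function(x, ...) {
  cat(sprintf("<aq_population> %d %s cells (%d in mode 1)\n",
              x$n, x$species, sum(x$mode == 1L)))
  invisible(x)
}

# stroke dimensions passed to the C++ core
pop_dims <- function(pop) {
  if (pop$species == "euglena")
    list(d1 = pop$body_width, d2 = pop$body_length, code = 0L)
  else
    list(d1 = pop$diameter, d2 = pop$diameter, code = 1L)
}

#' Advance a population through one feedback cycle
#'
#' Runs `n_subticks` stochastic sub-ticks of length `dt` under the given
#' illumination pattern, mutating the population in place. Euglena-like
#' cells swim straight with heading noise in the dark, tumble (slow
#' re-orienting drift) under light, turn away at illuminated borders with
#' probability `euglena_border_turn_prob`, and reflect specularly off walls.
#' Chlamydomonas-like cells switch between resting and active states at the
#' light-dependent rates and, while illuminated, succeed in leaving their
#' square only with probability `chlamy_exit_damping`.
#'
#' @param pop An [init_population()] object (mutated in place).
#' @param lit Logical vector of 25 illumination flags by square index.
#' @param layout An [grid_layout()] object.
#' @param params A [behavior_params()] object.
#' @param dt Sub-tick duration, s (> 0).
#' @param n_subticks Sub-ticks per cycle.
#'
#' @return Invisibly, a list with the cycle's trajectories: `tx`, `ty`
#'   (`n x (n_subticks + 1)` matrices of positions, um) and `segw`
#'   (`n x n_subticks` stroke widths, um; 0 marks undrawn segments of
#'   resting cells when `draw_resting` is off).
#' @export
step_population <- function(pop, lit, layout, params, dt = 0.147,
                            n_subticks = 10L) {
  if (!is.numeric(dt) || dt <= 0) stop("dt must be positive", call. = FALSE)
  stopifnot(inherits(pop, "aq_population"), length(lit) == 25L)
  d <- pop_dims(pop)
  tx <- matrix(0, pop$n, n_subticks + 1L)
  ty <- matrix(0, pop$n, n_subticks + 1L)
  segw <- matrix(0, pop$n, n_subticks)
  cpp_cycle(pop$x, pop$y, pop$heading, pop$speed, pop$mode,
            d$d1, d$d2, d$code, as.logical(lit), unclass(layout),
            unclass(params), dt, as.integer(n_subticks), tx, ty, segw)
  invisible(list(tx = tx, ty = ty, segw = segw))
}

#' Wall-respecting move with specular reflection
#'
#' Applies the containment rule used by the simulator to a single proposed
#' move: if the move stays in the chamber interior (squares or passages) it
#' is taken; if it would cross a wall, the heading component normal to the
#' blocked axis is reversed with added uniform jitter and the cell slides
#' along the open axis; a blocked corner reverses the heading. The returned
#' position is always interior.
#'
#' @param x,y Current position, um (must be interior).
#' @param nx,ny Proposed position, um.
#' @param heading Current heading, rad.
#' @param layout An [grid_layout()] object.
#' @param jitter Uniform heading-jitter amplitude on reflection, rad.
#' @return A list with the updated `x`, `y`, `heading`.
#' @export
enforce_walls <- function(x, y, nx, ny, heading, layout, jitter = 0.3) {
  if (!all(is.finite(c(x, y, nx, ny, heading))))
    stop("positions and heading must be finite", call. = FALSE)
  cpp_reflect(x, y, nx, ny, heading, unclass(layout), jitter)
}
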
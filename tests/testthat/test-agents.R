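lay <- grid_layout()
off <- logical(25)
all_lit <- rep(TRUE, 25)

# place a whole population at one point with fixed kinematics
pin_population <- function(pop, x, y, heading = 0, speed = 60) {
  pop$x[] <- x; pop$y[] <- y
  pop$heading[] <- heading; pop$speed[] <- speed
  pop
}

test_that("populations initialize within the published species ranges", {
  set.seed(1)
  pe <- init_population("euglena", 400, lay)
  expect_equal(pe$n, 400L)
  expect_true(all(pe$speed >= 30 & pe$speed <= 90))
  expect_true(all(pe$body_length >= 20 & pe$body_length <= 100))
  expect_true(all(pe$mode == 0L)) # all swimming
  loc <- locate_point(pe$x, pe$y, lay)
  expect_true(all(loc$region == "square"))

  pc <- init_population("chlamy", 1300, lay)
  expect_equal(pc$n, 1300L)
  expect_true(all(pc$speed >= 20 & pc$speed <= 100))
  expect_true(all(pc$diameter >= 10 & pc$diameter <= 30))
  # default resting fraction 0.5
  expect_gt(mean(pc$mode == 0L), 0.4)
  expect_lt(mean(pc$mode == 0L), 0.6)

  expect_error(init_population("euglena", 0, lay), "positive")
})

test_that("population initialization is reproducible under a fixed seed", {
  set.seed(99); p1 <- init_population("euglena", 50, lay)
  set.seed(99); p2 <- init_population("euglena", 50, lay)
  for (f in c("x", "y", "heading", "speed", "body_length", "body_width"))
    expect_identical(p1[[f]], p2[[f]])
})

test_that("dark swimming advances speed * dt along the heading", {
  set.seed(2)
  pop <- init_population("euglena", 1, lay)
  pop <- pin_population(pop, 240, 240, heading = 0, speed = 60)
  par <- behavior_params(euglena_heading_noise = 0, wall_jitter = 0)
  step_population(pop, off, lay, par, dt = 0.147, n_subticks = 1L)
  expect_equal(pop$x, 240 + 60 * 0.147) # 8.82 um advance
  expect_equal(pop$y, 240)
  expect_equal(pop$mode, 0L)
  expect_error(step_population(pop, off, lay, par, dt = 0), "positive")
})

test_that("tumble displacement follows the random-walk RMS law", {
  # reorienting every sub-tick at drift fraction f, each sub-tick is an
  # independent step of length f*v*dt, so after m sub-ticks
  # E|dx|^2 = m (f v dt)^2
  set.seed(3)
  n <- 4000; m <- 16L; f <- 0.3; v <- 60; dt <- 0.147
  pop <- init_population("euglena", n, lay)
  pop <- pin_population(pop, 240, 240, speed = v)
  par <- behavior_params(euglena_tumble_speed_frac = f,
                         euglena_tumble_reorient = 1,
                         wall_jitter = 0)
  step_population(pop, all_lit, lay, par, dt = dt, n_subticks = m)
  expect_true(all(pop$mode == 1L)) # tumbling under light
  rms <- sqrt(mean((pop$x - 240)^2 + (pop$y - 240)^2))
  expect_equal(rms, sqrt(m) * f * v * dt, tolerance = 0.05)
})

test_that("a certain border turn keeps cells out of illuminated squares", {
  set.seed(4)
  pop <- init_population("euglena", 1, lay)
  # heading straight at the passage into lit square 2
  pop <- pin_population(pop, 478, 240, heading = 0, speed = 90)
  lit2 <- logical(25); lit2[2] <- TRUE
  par <- behavior_params(euglena_border_turn_prob = 1,
                         euglena_heading_noise = 0)
  visited_lit <- FALSE
  for (i in 1:50) {
    step_population(pop, lit2, lay, par)
    sq <- locate_point(pop$x, pop$y, lay)$square
    if (!is.na(sq) && sq == 2L) visited_lit <- TRUE
  }
  expect_false(visited_lit)

  # one direct approach: the single blocked step leaves the cell in place
  pop <- pin_population(pop, 565, 240, heading = 0, speed = 60)
  step_population(pop, lit2, lay, par, n_subticks = 1L)
  expect_equal(locate_point(pop$x, pop$y, lay)$region, "passage")
  expect_equal(pop$x, 565)
})

test_that("chlamy light activation and dark resting follow exponential law", {
  set.seed(5)
  n <- 10000
  pop <- init_population("chlamy", n, lay, resting_fraction = 1)
  pop$x[] <- 240; pop$y[] <- 240
  k_act <- 0.1
  par <- behavior_params(chlamy_k_act = k_act, chlamy_k_rest = 0,
                         wall_jitter = 0)
  # 100 sub-ticks of 0.147 s = 14.7 s under light
  step_population(pop, all_lit, lay, par, dt = 0.147, n_subticks = 100L)
  expect_equal(mean(pop$mode == 1L), 1 - exp(-k_act * 14.7),
               tolerance = 0.02)

  pop2 <- init_population("chlamy", n, lay, resting_fraction = 0)
  par2 <- behavior_params(chlamy_k_act = 0, chlamy_k_rest = 0.01)
  # 1000 sub-ticks = 147 s in the dark
  step_population(pop2, off, lay, par2, dt = 0.147, n_subticks = 1000L)
  expect_equal(mean(pop2$mode == 1L), exp(-0.01 * 147), tolerance = 0.02)

  # resting cells in the dark stay resting and do not move
  pop3 <- init_population("chlamy", 100, lay, resting_fraction = 1)
  x0 <- pop3$x
  step_population(pop3, off, lay, behavior_params())
  expect_true(all(pop3$mode == 0L))
  expect_identical(pop3$x, x0)
})

test_that("walls reflect specularly and passages stay open", {
  lay <- grid_layout()
  # head-on approach to the right wall of square 1 (no passage at y = 30)
  r <- enforce_walls(478, 30, 486, 30, heading = 0, lay, jitter = 0)
  expect_equal(cos(r$heading), -1) # normal component reversed
  expect_equal(r$x, 478); expect_equal(r$y, 30)
  # move through the passage midline into square 2
  r2 <- enforce_walls(478, 240, 486, 240, heading = 0, lay, jitter = 0)
  expect_equal(r2$x, 486)
  expect_equal(locate_point(r2$x, r2$y, lay)$region, "passage")
  expect_error(enforce_walls(1, 1, Inf, 1, 0, lay), "finite")
})

test_that("no agent ever leaves the chamber interior", {
  set.seed(6)
  # stress both species with fast, noisy motion for many cycles
  pe <- init_population("euglena", 150, lay)
  pc <- init_population("chlamy", 150, lay, resting_fraction = 0)
  par <- behavior_params(euglena_tumble_speed_frac = 1.5,
                         euglena_tumble_reorient = 0.5,
                         chlamy_heading_noise = 3)
  lit <- group_pattern("I", lay)
  for (i in 1:60) {
    step_population(pe, lit, lay, par)
    step_population(pc, lit, lay, par)
    if (i %% 20L == 0L) {
      le <- locate_point(pe$x, pe$y, lay)
      lc <- locate_point(pc$x, pc$y, lay)
      expect_true(all(le$region %in% c("square", "passage")))
      expect_true(all(lc$region %in% c("square", "passage")))
    }
  }
})

test_that("static illumination drives the photophobic fluxes", {
  set.seed(7)
  lit <- group_pattern("I", lay)
  in_lit <- function(pop) {
    loc <- locate_point(pop$x, pop$y, lay)
    sum(!is.na(loc$square) & loc$square %in% which(lit))
  }
  par <- behavior_params()
  pe <- init_population("euglena", 400, lay)
  n0 <- in_lit(pe)
  for (i in 1:150) step_population(pe, lit, lay, par)
  n_mid <- in_lit(pe)
  for (i in 1:150) step_population(pe, lit, lay, par)
  n_end <- in_lit(pe)
  # Euglena vacate the illuminated group toward an asymptote
  expect_lt(n_mid, n0)
  expect_lte(n_end, n_mid)

  pc <- init_population("chlamy", 800, lay, resting_fraction = 0.8)
  act_lit <- function(pop) {
    loc <- locate_point(pop$x, pop$y, lay)
    sum(pop$mode == 1L & !is.na(loc$square) & loc$square %in% which(lit))
  }
  a0 <- act_lit(pc)
  for (i in 1:100) step_population(pc, lit, lay, par)
  expect_gt(act_lit(pc), a0) # light awakens resting cells
})
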
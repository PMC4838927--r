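lay <- grid_layout()

# hand-built log with explicit flip times (minutes-scale arithmetic checks)
flip_log <- function(bsteps, bgroups, asteps = integer(0),
                     agroups = character(0), cycle_s = 1.47,
                     total = 4000L) {
  fl <- rbind(
    data.frame(step = bsteps, time_s = bsteps * cycle_s,
               dish = rep("B", length(bsteps)), group = bgroups,
               stringsAsFactors = FALSE),
    data.frame(step = asteps, time_s = asteps * cycle_s,
               dish = rep("A", length(asteps)), group = agroups,
               stringsAsFactors = FALSE))
  fl <- fl[order(fl$step), , drop = FALSE]
  structure(list(step = seq_len(total), time_s = seq_len(total) * cycle_s,
                 patternA = matrix(FALSE, total, 25L),
                 patternB = matrix(FALSE, total, 25L),
                 tmA = matrix(0L, total, 25L), tmB = matrix(0L, total, 25L),
                 ratioA = rep(NA_real_, total),
                 ratioB = rep(NA_real_, total),
                 flips = fl, config = experiment_config()),
            class = "aq_log")
}

test_that("oscillation_period averages the dish-B full-cycle intervals", {
  # alternate flips every 133 steps: full period 2 * 133 * 1.47 s
  bs <- seq(600L, 3400L, by = 133L)
  gs <- rep(c("II", "I"), length.out = length(bs))
  log <- flip_log(bs, gs)
  p <- oscillation_period(log)
  expect_equal(p$period_mean, 2 * 133 * 1.47 / 60) # 6.517 min
  expect_equal(p$period_sd, 0)
  expect_equal(p$n_cycles, sum(gs == "I") - 1L)

  # no flips at all -> insufficient oscillation
  expect_error(oscillation_period(flip_log(integer(0), character(0))),
               "insufficient")
  # a single flip to group I is not a cycle either
  expect_error(oscillation_period(flip_log(c(600L, 733L), c("II", "I"))),
               "insufficient")
})

test_that("phase_delay pairs each dish-B flip with the next dish-A flip", {
  bs <- seq(600L, 3000L, by = 200L)
  gs <- rep(c("II", "I"), length.out = length(bs))
  log <- flip_log(bs, gs, asteps = bs + 18L, agroups = gs)
  d <- phase_delay(log)
  expect_equal(d$delay_mean, 18 * 1.47 / 60) # 0.441 min
  expect_equal(d$delay_sd, 0)
  expect_equal(d$n_pairs, length(bs))

  # a reference single-cycle example: B at 16.7 min, A at 17.2 min
  sb <- round(16.7 * 60 / 1.47); sa <- round(17.2 * 60 / 1.47)
  log2 <- flip_log(c(sb, sb + 400L), c("II", "I"),
                   asteps = c(sa, sa + 400L), agroups = c("II", "I"))
  d2 <- phase_delay(log2)
  expect_equal(d2$delay_mean, (sa - sb) * 1.47 / 60, tolerance = 1e-10)
  expect_equal(round(d2$delay_mean, 1), 0.5)

  # simultaneous-step flips have zero delay only if A flips strictly later;
  # an A flip one step after B gives one cycle's delay
  log3 <- flip_log(1000L, "II", asteps = 1001L, agroups = "II")
  expect_equal(phase_delay(log3)$delay_mean, 1.47 / 60)

  # two B flips without an intervening A flip are orphaned
  log4 <- flip_log(c(1000L, 1200L), c("II", "I"),
                   asteps = 1300L, agroups = "I")
  expect_error(phase_delay(log4), "unmatched")
  # a trailing B flip with no later A flip is dropped silently
  log5 <- flip_log(c(1000L, 1400L), c("II", "I"),
                   asteps = 1018L, agroups = "II")
  expect_equal(phase_delay(log5)$n_pairs, 1L)
})

test_that("coincidence counts agreeing squares", {
  p1 <- group_pattern("I", lay)
  p2 <- group_pattern("II", lay)
  expect_equal(coincidence(p1, p1), 25L)
  expect_equal(coincidence(p1, p2), 1L) # only the dark center agrees
  expect_equal(coincidence(p1, !p1), 0L)
})

test_that("coincidence of two 12-lit patterns is always odd", {
  set.seed(30)
  for (i in 1:2000) {
    a <- random_pattern(); b <- random_pattern()
    co <- coincidence(a, b)
    expect_equal(co %% 2L, 1L)
    expect_equal(co, 1L + 2L * sum(a & b))
  }
})

test_that("coincidence_series smooths with truncated windows", {
  log <- make_fixture_log("fixed_pattern", total_steps = 100L,
                          warmup_steps = 20L, cooldown_steps = 20L)
  co <- coincidence_series(log)
  expect_equal(nrow(co), 100L)
  expect_true(all(co$coincidence == 25L)) # identical patterns throughout
  expect_true(all(co$smoothed == 25))

  # an impulse (flipping the unlit square 13 in one dish only) spreads
  # over 2 * 10 + 1 steps of the moving average
  log$patternA[50, 13] <- TRUE
  co2 <- coincidence_series(log)
  expect_equal(sum(co2$smoothed != 25), 21L)
  expect_equal(co2$smoothed[50], (20 * 25 + 24) / 21)
  # truncated edge: the first step averages steps 1..11 only
  log$patternA[50, 13] <- FALSE
  log$patternA[1, 13] <- TRUE
  co3 <- coincidence_series(log)
  expect_equal(co3$smoothed[1], (10 * 25 + 24) / 11)
})

test_that("duty_ratio is the per-square lit fraction of feedback steps", {
  log <- make_fixture_log("fixed_pattern", total_steps = 100L,
                          warmup_steps = 20L, cooldown_steps = 20L)
  dr <- duty_ratio(log, "A")
  expect_equal(dr, c(rep(1, 12), rep(0, 13)))
  # counting identity: 12 lit per step -> mean duty over squares = 12/25
  expect_equal(mean(dr), 12 / 25)
  set.seed(31)
  log2 <- make_fixture_log("random_patterns", total_steps = 100L,
                           warmup_steps = 20L, cooldown_steps = 20L)
  expect_equal(mean(duty_ratio(log2, "B")), 12 / 25)
})

test_that("cluster_count matches the component-labeling oracle", {
  # all one status
  expect_equal(cluster_count(rep(TRUE, 25), "lit"), 1L)
  expect_equal(cluster_count(rep(TRUE, 25), "unlit"), 0L)
  # checkerboard: 13 isolated unlit squares
  chk <- ((1:25 - 1) %/% 5 + (1:25 - 1) %% 5) %% 2 == 1
  expect_equal(cluster_count(chk, "unlit"), 13L)
  expect_equal(boundary_count(chk), 40L) # every adjacency differs
  # solid 3x4 block plus the center square
  blk <- logical(25)
  blk[c(1:4, 6:9, 11:14)] <- TRUE
  expect_equal(cluster_count(!blk, "unlit"), oracle_components(blk))
  set.seed(32)
  for (i in 1:2000) {
    p <- random_pattern(sample(0:25, 1))
    expect_equal(cluster_count(p, "lit"), oracle_components(p))
    expect_equal(cluster_count(p, "unlit"), oracle_components(!p))
    expect_equal(boundary_count(p), oracle_boundaries(p))
  }
})

test_that("boundary_count handles simple patterns", {
  expect_equal(boundary_count(rep(TRUE, 25)), 0L)
  corner <- logical(25); corner[1] <- TRUE
  expect_equal(boundary_count(corner), 2L)
})

test_that("unlighting a bridge square merges unlit domains", {
  # two unlit domains separated by a lit column; unlighting the bridge
  # square can only reduce the number of unlit components
  p <- logical(25)
  p[c(3, 8, 13, 18, 23)] <- TRUE # lit middle column
  before <- cluster_count(p, "unlit")
  expect_equal(before, 2L)
  p[13] <- FALSE
  expect_lte(cluster_count(p, "unlit"), before)
})

test_that("pattern_histogram ranks masks by frequency", {
  log <- make_fixture_log("fixed_pattern", total_steps = 100L,
                          warmup_steps = 20L, cooldown_steps = 20L)
  h <- pattern_histogram(log, "A")
  expect_equal(nrow(h), 1L)
  expect_equal(h$count, 60L)
  expect_equal(h$pattern, attr(log, "truth")$pattern)

  # constructed 60/30/10 split ranks X, Y, Z
  pX <- random_pattern(); pY <- random_pattern(); pZ <- random_pattern()
  w <- 21:80
  log$patternA[w[1:36], ] <- matrix(pX, 36, 25, byrow = TRUE)
  log$patternA[w[37:54], ] <- matrix(pY, 18, 25, byrow = TRUE)
  log$patternA[w[55:60], ] <- matrix(pZ, 6, 25, byrow = TRUE)
  log$patternB[w, ] <- matrix(pX, 60, 25, byrow = TRUE)
  h2 <- pattern_histogram(log, "A", coincidence_filter = 0:25)
  expect_equal(h2$count, c(36L, 18L, 6L))
  expect_equal(h2$pattern[1], paste(as.integer(pX), collapse = ""))
  expect_equal(sum(h2$count), 60L)

  # the coincidence filter excludes disagreeing steps
  h3 <- pattern_histogram(log, "A", coincidence_filter = 21:25)
  expect_equal(sum(h3$count), sum(
    rowSums(log$patternA[w, ] == log$patternB[w, ]) >= 21))
})
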
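lay <- grid_layout()

test_that("flip_target applies the prefixed-threshold rule", {
  expect_equal(flip_target(-0.45, 0.40), "II")
  expect_equal(flip_target(0.24, 0.40), "none")
  expect_equal(flip_target(0.49, 0.40), "I")
  expect_equal(flip_target(0.40, 0.40), "I")  # level trigger at the bound
  expect_equal(flip_target(NA_real_, 0.40), "none")
  expect_error(flip_target(1.2, 0.40), "ratio")
  expect_error(flip_target(0.2, 0), "threshold")
  expect_error(flip_target(0.2, 1), "threshold")
})

test_that("group patterns light 12 squares and never the center", {
  p1 <- group_pattern("I", lay)
  p2 <- group_pattern("II", lay)
  expect_equal(sum(p1), 12L)
  expect_equal(sum(p2), 12L)
  expect_false(p1[13]); expect_false(p2[13])
  expect_equal(sum(p1 & p2), 0L)             # disjoint
  expect_equal(which(p1 == p2), 13L)         # agree only on the dark center
})

test_that("ranking_pattern selects k extremes with index tie-breaks", {
  expect_equal(which(ranking_pattern(rep(5, 25), "lowest")), 1:12)
  expect_equal(which(ranking_pattern(1:25, "lowest")), 1:12)
  expect_equal(which(ranking_pattern(1:25, "highest")), 14:25)
  expect_equal(sum(ranking_pattern(rnorm(25), "lowest", k = 5)), 5L)
  expect_error(ranking_pattern(1:10, "lowest"), "25")
  expect_error(ranking_pattern(1:25, "lowest", k = 26), "<= 25")
})

test_that("ranking_pattern agrees with the selection oracle", {
  set.seed(20)
  for (i in 1:2000) {
    tm <- sample.int(40, 25, replace = TRUE) # many ties
    sel <- if (i %% 2 == 0) "lowest" else "highest"
    expect_identical(ranking_pattern(tm, sel), oracle_ranking(tm, sel))
  }
})

test_that("interlink_step exchanges TM between the dishes", {
  st <- list(threshold = 0.40, groupA = "I", groupB = "I")
  mk <- function(rI, rII) {
    tm <- integer(25)
    tm[group_squares(lay, "I")] <- rI
    tm[group_squares(lay, "II")] <- rII
    tm
  }
  # ratioA = -0.41 flips dish B to II; ratioB = 0.1 leaves dish A alone
  out <- interlink_step(mk(59, 141), mk(110, 90), st, "oscillation", lay)
  expect_equal(out$state$groupB, "II")
  expect_equal(out$state$groupA, "I")
  expect_equal(out$flips$dish, "B")
  expect_equal(out$patternB, group_pattern("II", lay))
  # level trigger: repeating the same imbalance is a no-op, no flip logged
  out2 <- interlink_step(mk(59, 141), mk(110, 90), out$state,
                         "oscillation", lay)
  expect_equal(nrow(out2$flips), 0L)
  expect_equal(out2$state$groupB, "II")

  # ranking: dish B gets the 12 lowest-TM squares of dish A
  tmA <- 1:25
  out3 <- interlink_step(tmA, 25:1, st, "ranking", lay)
  expect_equal(which(out3$patternB), 1:12)
  expect_equal(which(out3$patternA), 1:12) # highest of decreasing tmB
})

test_that("experiment_config validates the schedule", {
  expect_error(experiment_config(threshold = 1.5), "threshold")
  expect_error(experiment_config(total_steps = 100, warmup_steps = 60,
                                 cooldown_steps = 50), "smaller")
  expect_error(experiment_config(cycle_s = 0), "positive")
  cfg <- experiment_config()
  expect_equal(cfg$total_steps * cfg$cycle_s / 60, 98) # 98 min experiment
})

test_that("runs are deterministic and respect the illumination schedule", {
  cfg <- small_config(seed = 5)
  log1 <- run_experiment(cfg)
  log2 <- run_experiment(cfg)
  expect_identical(log1$tmA, log2$tmA)
  expect_identical(log1$tmB, log2$tmB)
  expect_identical(log1$patternB, log2$patternB)
  expect_identical(log1$flips, log2$flips)

  # warmup and cooldown fully dark; feedback window lights 12 per dish
  act <- 16:65
  expect_true(all(rowSums(log1$patternA[-act, ]) == 0))
  expect_true(all(rowSums(log1$patternB[-act, ]) == 0))
  expect_true(all(rowSums(log1$patternA[act, ]) == 12))
  expect_true(all(rowSums(log1$patternB[act, ]) == 12))
  # oscillation mode starts with group I lit in both dishes
  expect_equal(log1$patternA[16, ], unname(group_pattern("I", lay)))
  expect_equal(log1$patternB[16, ], unname(group_pattern("I", lay)))
  # center never lit in oscillation mode
  expect_true(all(!log1$patternA[, 13]))
})

test_that("dish A results are independent of dish-B settings", {
  cfg1 <- small_config(seed = 9)
  cfg2 <- small_config(seed = 9, n_chlamy = 200L)
  l1 <- run_experiment(cfg1)
  l2 <- run_experiment(cfg2)
  # same euglena trajectories during warmup (before any coupling)
  expect_identical(l1$tmA[1:15, ], l2$tmA[1:15, ])
})

test_that("ranking mode lights 12 squares from the first feedback step", {
  cfg <- small_config(algorithm = "ranking", seed = 5)
  log <- run_experiment(cfg)
  act <- 16:65
  expect_true(all(rowSums(log$patternA[act, ]) == 12))
  expect_true(all(rowSums(log$patternB[act, ]) == 12))
  # the first feedback pattern ranks the TM measured in the last warmup step
  expect_equal(log$patternB[16, ],
               unname(ranking_pattern(log$tmA[15, ], "lowest")))
  expect_equal(log$patternA[16, ],
               unname(ranking_pattern(log$tmB[15, ], "highest")))
  # causality: next patterns are a function of the previous step's TM
  expect_equal(log$patternB[30, ],
               unname(ranking_pattern(log$tmA[29, ], "lowest")))
})

test_that("exchange jitter keeps patterns valid", {
  cfg <- small_config(algorithm = "ranking", seed = 5,
                      sync_jitter_cycles = 1L)
  log <- run_experiment(cfg)
  expect_true(all(rowSums(log$patternB[16:65, ]) == 12))
})
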
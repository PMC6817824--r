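# Transition classification, growth extents, migration rate, expansion
# region, secondary-growth bias, accumulation identities.

test_that("classifyTransitions maps label pairs to the event table", {
  n <- 9
  arena <- mkTestArena(n)
  prev <- matrix(0L, n, n); curr <- matrix(0L, n, n)
  prev[4, 4] <- 0L; curr[4, 4] <- 1L   # primary
  prev[4, 5] <- 2L; curr[4, 5] <- 1L   # secondary
  prev[5, 4] <- 1L; curr[5, 4] <- 2L   # refinement
  prev[5, 5] <- 1L; curr[5, 5] <- 1L   # none
  tm <- classifyTransitions(prev, curr, arena)
  expect_equal(tm@events[4, 4], EVENTS[["PRIMARY"]])
  expect_equal(tm@events[4, 5], EVENTS[["SECONDARY"]])
  expect_equal(tm@events[5, 4], EVENTS[["REFINEMENT"]])
  expect_equal(tm@events[5, 5], EVENTS[["NONE"]])
  expect_equal(tm@events[3, 3], EVENTS[["NONE"]])  # unexplored -> unexplored
})

test_that("coverageFractions count in-arena pixels and sum to one", {
  n <- 21
  arena <- mkTestArena(n)
  allSlime <- matrix(1L, n, n)
  expect_equal(coverageFractions(allSlime, arena),
               c(slime = 1, mucus = 0, unexplored = 0))
  # split mask: fractions are exact in-arena pixel counts
  lab <- matrix(0L, n, n); lab[, 1:10] <- 1L
  fr <- coverageFractions(lab, arena)
  expect_equal(unname(sum(fr)), 1)
  expect_equal(unname(fr["slime"]),
               sum(arena@mask[, 1:10]) / sum(arena@mask))
  set.seed(7)
  rand <- matrix(sample(0:2, n * n, TRUE), n, n)
  expect_equal(unname(sum(coverageFractions(rand, arena))), 1)
})

test_that("growthExtents equals brute-force nearest-slime distances", {
  n <- 25
  arena <- mkTestArena(n, arenaDiameterMm = 2 * (n / 2 - 1))  # 1 mm per px
  prev <- matrix(0L, n, n); prev[mkDisc(n, 5)] <- 1L
  curr <- matrix(0L, n, n); curr[mkDisc(n, 8)] <- 1L
  tm <- classifyTransitions(prev, curr, arena)
  ext <- growthExtents(tm, prev == 1L)
  bd <- bruteDistToSet(prev == 1L)
  grown <- curr == 1L & prev == 0L
  expect_equal(sort(ext), sort(bd[grown]), tolerance = 1e-9)
  # annulus of width 3 around a disc: max extent = 3 px up to discretization
  expect_lt(abs(max(ext) - 3), 0.75)

  # growth pixel 4-adjacent to previous slime is at exactly one pixel
  prev2 <- matrix(0L, n, n); prev2[12, 12] <- 1L
  curr2 <- prev2; curr2[12, 13] <- 1L
  tm2 <- classifyTransitions(prev2, curr2, arena)
  expect_equal(growthExtents(tm2, prev2 == 1L), 1 * arena@mmPerPx)

  # no growth -> empty extents; lost slime -> error
  tm3 <- classifyTransitions(prev2, prev2, arena)
  expect_length(growthExtents(tm3, prev2 == 1L), 0)
  expect_error(growthExtents(tm2, matrix(FALSE, n, n)), "empty")
})

test_that("migrationRate is max extent over interval, zero without growth", {
  expect_equal(migrationRate(c(0.2, 1, 0.7), 5), 0.2)
  expect_equal(migrationRate(numeric(0), 5), 0)
  expect_error(migrationRate(1, 0))
})

test_that("expansionRegion is the annulus beyond the slime contour", {
  n <- 161
  arena <- makeArena(c(81, 81), 79, 2 * 79, c(n, n))  # 1 mm per px
  r <- 50; k <- 10
  prev <- matrix(0L, n, n); prev[mkDisc(n, r)] <- 1L
  expect_equal(sum(expansionRegion(prev, arena, 0)), 0)
  reg <- expansionRegion(prev, arena, k)
  expect_true(all(!(reg & (prev == 1L))))
  analytic <- pi * ((r + k)^2 - r^2)
  expect_lt(abs(sum(reg) / analytic - 1), 0.02)
  # offset beyond the arena: saturates to all non-slime arena pixels
  regAll <- expansionRegion(prev, arena, 1e4)
  expect_equal(sum(regAll), sum(arena@mask & prev == 0L))
})

test_that("secondary-growth fractions match their definitions", {
  n <- 41   # shapes placed well inside the arena circle
  arena <- mkTestArena(n)
  prev <- matrix(0L, n, n)
  curr <- matrix(0L, n, n)
  # 20 primary (col 18) + 30 secondary (cols 19-20) transitions
  prev[12:31, 18] <- 0L; curr[12:31, 18] <- 1L
  prev[12:26, 19] <- 2L; curr[12:26, 19] <- 1L
  prev[12:26, 20] <- 2L; curr[12:26, 20] <- 1L
  stopifnot(all(arena@mask[12:31, 18:28]))
  tm <- classifyTransitions(prev, curr, arena)
  region <- matrix(FALSE, n, n)
  region[12:31, 24:28] <- TRUE                  # 100 pixels
  prevReg <- prev; prevReg[12:31, 24:26] <- 2L  # 60 mucus in region
  b <- secondaryGrowthBias(tm, region, prevReg)
  expect_equal(unname(b["observed"]), 30 / 50)
  expect_equal(unname(b["expected"]), 60 / 100)
  # degenerate interval: both reported missing
  tm0 <- classifyTransitions(prev, prev, arena)
  b0 <- secondaryGrowthBias(tm0, matrix(FALSE, n, n), prev)
  expect_true(all(is.na(b0)))
})

test_that("uniformly random growth makes observed match expected (MC oracle)", {
  n <- 61
  arena <- makeArena(c(31, 31), 29, 58, c(n, n))
  prev <- matrix(0L, n, n); prev[mkDisc(n, 12)] <- 1L
  # scatter mucus through the surroundings
  set.seed(5)
  mucus <- matrix(runif(n * n) < 0.4, n, n) & prev == 0L & arena@mask
  prev[mucus] <- 2L
  region <- expansionRegion(prev, arena, 4)
  regionIdx <- which(region)
  expected <- mean(prev[regionIdx] == 2L)
  nTrials <- 300
  obs <- numeric(nTrials)
  for (i in seq_len(nTrials)) {
    pick <- sample(regionIdx, 40)
    curr <- prev; curr[pick] <- 1L
    tm <- classifyTransitions(prev, curr, arena)
    obs[i] <- secondaryGrowthBias(tm, region, prev)[["observed"]]
  }
  se <- sd(obs) / sqrt(nTrials)
  expect_lt(abs(mean(obs) - expected), 3 * se + 1e-12)
})

test_that("accumulateGrowth: cumulative sums and exact area balance", {
  run <- quickRun(seed = 8)
  m <- accumulateGrowth(run$truth)
  expect_equal(nrow(m), nFrames(run$truth))
  # cumulative series are non-decreasing running sums; cumulative primary
  # starts from the inoculated disc's coverage at t = 0
  expect_equal(m$cum_primary,
               m$frac_slime[1] + cumsum(ifelse(is.na(m$primary), 0,
                                               m$primary)))
  expect_true(all(diff(m$cum_primary) >= 0))
  expect_true(all(diff(m$cum_secondary) >= 0))
  expect_true(all(diff(m$cum_refinement) >= 0))
  expect_true(all(m$cum_primary <= 1 + 1e-9))
  # per-interval identity: d slime = primary + secondary - refinement
  dSlime <- diff(m$frac_slime)
  bal <- (m$primary + m$secondary - m$refinement)[-1]
  expect_equal(dSlime, bal, tolerance = 1e-12)
  # cumulative primary growth = final explored (slime or mucus) fraction
  final <- m$frac_slime[nrow(m)] + m$frac_mucus[nrow(m)]
  expect_equal(m$cum_primary[nrow(m)], final, tolerance = 1e-9)
  # class fractions always sum to 1
  expect_true(all(abs(m$frac_slime + m$frac_mucus + m$frac_unexplored - 1)
                  < 1e-9))
})

test_that("without refinement the slime area is non-decreasing", {
  run <- quickRun(seed = 3, retractionProb = 0)
  m <- accumulateGrowth(run$truth)
  expect_true(all(m$refinement[-1] == 0))
  expect_true(all(m$cum_refinement == 0))
  expect_true(all(diff(m$frac_slime) >= 0))
})
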
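# The synthetic generator: geometry, determinism, mechanism switches,
# rendering statistics, and recovery of its own parameters by the pipeline.

test_that("35 h at 5-min sampling gives exactly 420 frames", {
  p <- synthParams(imagePx = 64, durationMin = 2100, intervalMin = 5,
                   growthRateMmMin = 0.1, pseudopodRate = 0)
  run <- generateSynthetic(p, render = FALSE)
  expect_equal(nFrames(run$truth), 420)
  expect_equal(max(frameTimes(run$truth)), 2095)
})

test_that("identical seeds give bit-identical output, different seeds differ", {
  p <- synthParams(imagePx = 48, durationMin = 60, seed = 7)
  a <- generateSynthetic(p)
  b <- generateSynthetic(p)
  expect_identical(a$truth@labels, b$truth@labels)
  expect_identical(a$frames@frames, b$frames@frames)
  expect_identical(a$log, b$log)
  c <- generateSynthetic(synthParams(imagePx = 48, durationMin = 60, seed = 8))
  expect_false(identical(a$truth@labels, c$truth@labels))
})

test_that("switching retraction off removes mucus and secondary growth", {
  run <- quickRun(seed = 5, retractionProb = 0)
  expect_false(any(run$truth@labels == LABELS[["MUCUS"]]))
  expect_true(all(run$log$n_secondary == 0))
  expect_true(all(run$log$n_refinement == 0))
  expect_gt(sum(run$log$n_primary), 0)
})

test_that("ground-truth labels obey the transition-legality invariant", {
  for (seed in 1:4) {
    run <- quickRun(seed = seed, mucusBias = c(1, 5, 1, 3)[seed],
                    retractionProb = c(0.3, 0.5, 0, 0.4)[seed])
    expectLegalTransitions(run$truth)
  }
})

test_that("an over-large growth rate is refused", {
  expect_error(generateSynthetic(synthParams(imagePx = 64,
                                             growthRateMmMin = 15)),
               "exit the arena")
})

test_that("renderFrame: exact class colors without noise, unbiased with noise", {
  n <- 160
  arena <- mkTestArena(n)
  lab <- matrix(LABELS[["UNEXPLORED"]], n, n)
  lab[mkDisc(n, 30)] <- LABELS[["SLIME"]]
  lab[mkDisc(n, 45) & !mkDisc(n, 30)] <- LABELS[["MUCUS"]]

  p0 <- synthParams(noiseSigma = 0)
  f0 <- renderFrame(lab, p0, arena)
  cols <- unique(matrix(f0, ncol = 3)[arena@mask, , drop = FALSE])
  expect_equal(nrow(cols), 3)

  p8 <- synthParams(noiseSigma = 8)
  set.seed(9)
  f8 <- renderFrame(lab, p8, arena)
  for (ch in 1:3) {
    sl <- f8[, , ch][lab == LABELS[["SLIME"]] & arena@mask]
    expect_gt(length(sl), 1e3)
    expect_lt(abs(mean(sl) - p8@slimeRGB[ch]), 1)
    sub <- f8[, , ch][lab == LABELS[["UNEXPLORED"]] & arena@mask]
    expect_gt(length(sub), 1e4)
    expect_lt(abs(mean(sub) - p8@substrateRGB[ch]), 1)
  }
  expect_true(all(f8 >= 0 & f8 <= 255))
})

test_that("noise-free renders are recovered exactly; sigma = 8 within 5%", {
  for (sg in c(0, 8)) {
    p <- synthParams(imagePx = 96, durationMin = 125, seed = 4, noiseSigma = sg)
    run <- generateSynthetic(p)
    stack <- segmentSequence(run$frames, run$arena,
                             initRegion = run$initRegion)
    agr <- labelAgreement(stack, run$truth)
    if (sg == 0) expect_equal(agr, 1) else expect_gte(agr, 0.95)
    expectLegalTransitions(stack)
  }
})

test_that("pipeline migration rate recovers the generator's speed", {
  v <- 0.2
  p <- synthParams(imagePx = 96, durationMin = 150, seed = 1, noiseSigma = 0,
                   growthRateMmMin = v, fillFrac = 1, retractionProb = 0,
                   pseudopodRate = 0)
  run <- generateSynthetic(p, render = FALSE)
  m <- accumulateGrowth(run$truth)
  rates <- m$migration_rate_mm_min[-1]
  pxEquiv <- run$arena@mmPerPx / intervalMin(run$truth)
  expect_true(all(abs(rates - v) <= pxEquiv))
  # and the pipeline's measured rate equals the generator's own log
  expect_equal(rates, run$log$migration_rate_mm_min, tolerance = 1e-9)
})

test_that("the spot-experiment preset closes the distance to glucose", {
  p <- synthPreset("spot-experiment", imagePx = 96, durationMin = 250,
                   seed = 2, noiseSigma = 0, retractionProb = 0)
  run <- generateSynthetic(p, render = FALSE)
  expect_s4_class(run$spots, "SpotLayout")
  arena <- run$arena
  d <- vapply(seq_len(nFrames(run$truth)), function(i)
    distanceToSpot(slimeMask(run$truth, i), run$spots, arena@mmPerPx),
    numeric(1))
  # monotone-growth fixture: distance is non-increasing and shrinks
  expect_true(all(diff(d) <= 1e-9))
  expect_lt(d[length(d)], d[1])
  # initial edge-to-edge gap is the configured 45 mm (one pixel slack)
  expect_equal(d[1], 45, tolerance = arena@mmPerPx)
})
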
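# Shape indices: closed-form anchors, invariances, erosion-based counts.

test_that("circularity hits the closed forms for disc, square, two discs", {
  disc <- mkDisc(121, 50)
  expect_equal(circularity(disc), 1, tolerance = 0.02)

  sq <- matrix(FALSE, 120, 120); sq[11:110, 11:110] <- TRUE
  expect_equal(circularity(sq), 4 / pi, tolerance = 0.02)

  two <- matrix(FALSE, 101, 220)
  two[, 1:101] <- mkDisc(101, 40)
  two[, 120:220] <- two[, 120:220] | mkDisc(101, 40)
  expect_equal(circularity(two), 2, tolerance = 0.03 * 2)

  expect_error(circularity(matrix(FALSE, 5, 5)), "empty")
})

test_that("circularity respects the isoperimetric bound on random blobs", {
  set.seed(11)
  for (i in 1:8) {
    z <- matrix(rnorm(60 * 60), 60, 60)
    z <- as.matrix(EBImage::gblur(EBImage::as.Image(z), sigma = 4))
    blob <- z > quantile(z, 0.7)
    blob <- blob & mkDisc(60, 27)
    if (sum(blob) < 20) next
    expect_gte(circularity(blob), 1 - 0.02)
  }
})

test_that("eccentricity matches ellipse closed forms and is rotation-invariant", {
  expect_lt(eccentricity(mkDisc(101, 40)), 0.02)

  ell <- mkEllipse(121, 40, 20)          # a = 2b
  expect_equal(eccentricity(ell), sqrt(3) / 2, tolerance = 0.02)

  # exact under 90 degree rotation
  rot90 <- t(ell)[, rev(seq_len(nrow(ell)))]
  expect_equal(eccentricity(ell), eccentricity(rot90), tolerance = 1e-6)

  # stable under arbitrary rotation of the underlying shape
  ell30 <- mkEllipse(121, 40, 20, thetaDeg = 30)
  expect_equal(eccentricity(ell30), sqrt(3) / 2, tolerance = 0.02)

  # single pixel: zero by convention
  one <- matrix(FALSE, 5, 5); one[3, 3] <- TRUE
  expect_equal(eccentricity(one), 0)
  expect_error(eccentricity(matrix(FALSE, 2, 2)), "empty")
})

test_that("solidity: convex shapes score 1, plus-sign scores 5/7", {
  # sub-pixel hull bias shrinks as ~0.7/r; radius 50 sits inside the 2% band
  expect_equal(solidity(mkDisc(121, 50)), 1, tolerance = 0.02)

  # plus sign of five s x s squares; its hull is the corner octagon of
  # area 7 s^2, so solidity = 5/7
  s <- 30
  plus <- matrix(FALSE, 3 * s + 2, 3 * s + 2)
  plus[(s + 1):(2 * s), 1:(3 * s)] <- TRUE
  plus[1:(3 * s), (s + 1):(2 * s)] <- TRUE
  expect_equal(solidity(plus), 5 / 7, tolerance = 0.03 * 5 / 7)

  # two discs drifting apart: solidity strictly decreases
  twoAt <- function(gap) {
    w <- 24 + gap + 24
    rr <- matrix(seq_len(45), 45, w)
    cc <- matrix(seq_len(w), 45, w, byrow = TRUE)
    ((rr - 23)^2 + (cc - 12)^2 <= 100) |
      ((rr - 23)^2 + (cc - (w - 12))^2 <= 100)
  }
  s1 <- solidity(twoAt(10)); s2 <- solidity(twoAt(40))
  expect_lt(s2, s1)
  expect_lt(s2, 0.5)
})

test_that("clusterCount matches brute-force erosion on a bridged dumbbell", {
  # two radius-10 discs joined by a 2 px wide bridge
  rr <- matrix(seq_len(41), 41, 71)
  cc <- matrix(seq_len(71), 41, 71, byrow = TRUE)
  m <- ((rr - 21)^2 + (cc - 16)^2 <= 100) |
       ((rr - 21)^2 + (cc - 56)^2 <= 100)
  m[20:21, 16:56] <- TRUE
  expect_equal(clusterCount(m, 0), 1)

  er <- bruteErode(m, 3)
  expect_equal(clusterCount(m, 3), 2)
  # the package erosion agrees pixelwise with the brute-force oracle
  inner <- EBImage::distmap(m * 1)
  expect_identical(matrix(as.numeric(inner) > 3, nrow(m), ncol(m)), er)

  expect_equal(clusterCount(mkDisc(41, 15), 3), 1)
  expect_equal(clusterCount(matrix(FALSE, 5, 5), 2), 0L)
  # erosion that wipes out everything
  expect_equal(clusterCount(mkDisc(21, 3), 8), 0)
})

test_that("shapeMetrics bundles the four indices for the initial disc", {
  n <- 129
  arena <- mkTestArena(n)
  disc <- mkDisc(n, 40)
  sm <- shapeMetrics(disc, arena)
  expect_equal(sm$circularity, 1, tolerance = 0.02)
  expect_lt(sm$eccentricity, 0.02)
  expect_equal(sm$solidity, 1, tolerance = 0.02)
  expect_equal(sm$n_clusters, 1L)
  # P, A consistency: C recomputes exactly from stored P and A
  expect_equal(sm$circularity,
               sm$perimeter_mm^2 / (4 * pi * sm$area_mm2), tolerance = 1e-12)
  # ellipse axes: a >= b and E consistent with sqrt(1 - (b/a)^2)
  expect_gte(sm$major_mm, sm$minor_mm)
  expect_equal(sm$eccentricity,
               sqrt(1 - (sm$minor_mm / sm$major_mm)^2), tolerance = 1e-12)
})
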
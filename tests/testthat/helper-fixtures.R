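# Shared fixtures and independent brute-force oracles.

# disc mask on an n x n grid, pixel-center rule
mkDisc <- function(n, r, center = c((n + 1) / 2, (n + 1) / 2)) {
  rr <- matrix(seq_len(n), n, n)
  cc <- matrix(seq_len(n), n, n, byrow = TRUE)
  (rr - center[1])^2 + (cc - center[2])^2 <= r^2
}

# axis-aligned (or rotated) ellipse mask, semi-axes a (rows) and b (cols)
mkEllipse <- function(n, a, b, thetaDeg = 0) {
  ctr <- (n + 1) / 2
  rr <- matrix(seq_len(n), n, n) - ctr
  cc <- matrix(seq_len(n), n, n, byrow = TRUE) - ctr
  th <- thetaDeg * pi / 180
  u <- rr * cos(th) + cc * sin(th)
  v <- -rr * sin(th) + cc * cos(th)
  (u / a)^2 + (v / b)^2 <= 1
}

# arena covering almost the whole n x n grid
mkTestArena <- function(n, arenaDiameterMm = 145) {
  makeArena(c((n + 1) / 2, (n + 1) / 2), n / 2 - 1, arenaDiameterMm, c(n, n))
}

# brute-force distance from each pixel to the nearest TRUE pixel (oracle
# for the distance-transform path); O(n^2), small grids only
bruteDistToSet <- function(mask) {
  pts <- which(mask, arr.ind = TRUE)
  out <- matrix(Inf, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(mask))) for (j in seq_len(ncol(mask)))
    out[i, j] <- sqrt(min((pts[, 1] - i)^2 + (pts[, 2] - j)^2))
  out
}

# brute-force Euclidean disc erosion (oracle for clusterCount's erosion):
# keep a pixel iff no in-image background pixel center lies within radius
bruteErode <- function(mask, r) {
  if (r <= 0) return(mask)
  bg <- which(!mask, arr.ind = TRUE)
  out <- mask
  fg <- which(mask, arr.ind = TRUE)
  for (k in seq_len(nrow(fg))) {
    d2 <- (bg[, 1] - fg[k, 1])^2 + (bg[, 2] - fg[k, 2])^2
    if (length(d2) && min(d2) <= r^2) out[fg[k, 1], fg[k, 2]] <- FALSE
  }
  out
}

# label-history legality: no pixel ever returns to UNEXPLORED, slime only
# appears from any class, mucus only from slime/mucus
expectLegalTransitions <- function(stack) {
  m <- stack@arena@mask
  for (t in 2:nFrames(stack)) {
    prev <- frameLabels(stack, t - 1)[m]
    curr <- frameLabels(stack, t)[m]
    # UNEXPLORED -> {UNEXPLORED, SLIME}
    expect_false(any(prev == 0 & curr == 2),
                 label = sprintf("unexplored->mucus at t=%d", t))
    # MUCUS -> {MUCUS, SLIME}: never back to unexplored
    expect_false(any(prev == 2 & curr == 0),
                 label = sprintf("mucus->unexplored at t=%d", t))
    # SLIME -> {SLIME, MUCUS}
    expect_false(any(prev == 1 & curr == 0),
                 label = sprintf("slime->unexplored at t=%d", t))
  }
  invisible(TRUE)
}

# small stochastic synthetic run (ground truth only) used across tests
quickRun <- function(seed = 1, ...) {
  generateSynthetic(synthParams(imagePx = 96, durationMin = 150, seed = seed,
                                noiseSigma = 0, ...), render = FALSE)
}

# pixelwise label agreement between two stacks, in-arena
labelAgreement <- function(a, b) {
  m <- a@arena@mask
  tot <- 0; eq <- 0
  for (i in seq_len(nFrames(a))) {
    x <- frameLabels(a, i)[m]; y <- frameLabels(b, i)[m]
    eq <- eq + sum(x == y); tot <- tot + length(x)
  }
  eq / tot
}
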
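#' Construct synthetic-generator parameters
#'
#' Builds a [SynthParams-class], starting from defaults that emulate the
#' reference experiments: a 14.5 cm circular arena containing a 2.5 cm
#' circular slime disc, photographed every 5 min for 35 h (420 frames).
#' See the class documentation for every knob.
#'
#' @param ... slot overrides, e.g. `growthRateMmMin = 0.2`, `seed = 7`.
#' @return a validated [SynthParams-class].
#' @examples
#' p <- synthParams(imagePx = 96, durationMin = 150)
#' p
#' @export
synthParams <- function(...) {
  args <- list(...)
  if ("imagePx" %in% names(args)) args$imagePx <- as.integer(args$imagePx)
  if ("seed" %in% names(args)) args$seed <- as.integer(args$seed)
  do.call(new, c(list("SynthParams"), args))
}

#' Named parameter presets for the synthetic generator
#'
#' Parameter bundles reproducing the qualitative orderings of the four
#' homogeneous-substrate conditions and the spot experiment: `control`
#' (fast exploration, frequent retraction), `nutritive` (slower, fewer
#' pseudopods), `highly-nutritive` (slowest, delayed, compact),
#' `adverse` (long initial delay, strong preference for regrowing over
#' mucus) and `spot-experiment` (chemoattraction toward a glucose spot).
#' Values are illustrative, not fitted to any measured curves.
#'
#' @param name preset name.
#' @param ... further overrides passed to [synthParams()].
#' @return a [SynthParams-class].
#' @export
synthPreset <- function(name = c("control", "nutritive", "highly-nutritive",
                                 "adverse", "spot-experiment"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    "control" = list(),
    "nutritive" = list(growthRateMmMin = 0.18, retractionProb = 0.15,
                       pseudopodRate = 0.5),
    "highly-nutritive" = list(growthRateMmMin = 0.10, retractionProb = 0.08,
                              pseudopodRate = 0.25, startDelayMin = 120),
    "adverse" = list(growthRateMmMin = 0.22, retractionProb = 0.45,
                     pseudopodRate = 0.4, mucusBias = 5, startDelayMin = 180),
    "spot-experiment" = list(spotGapMm = 45, chemoStrength = 2,
                             retractionProb = 0.2))
  do.call(synthParams, utils::modifyList(base, list(...)))
}

#' Render one synthetic frame from a ground-truth label grid
#'
#' Per-pixel class mean color plus i.i.d. Gaussian noise, clipped to
#' 0..255; outside-arena pixels get a fixed dark color (no noise).
#'
#' @param labels integer label matrix (codes of [LABELS]).
#' @param params a [SynthParams-class] (color model and noise).
#' @param arena an [ArenaMask-class].
#' @return numeric `H x W x 3` array, 0..255.
#' @export
renderFrame <- function(labels, params, arena) {
  m <- arena@mask
  H <- nrow(labels); W <- ncol(labels)
  out <- array(0, c(H, W, 3))
  for (ch in 1:3) {
    M <- matrix(params@outsideRGB[ch], H, W)
    M[m] <- params@substrateRGB[ch]
    M[m & labels == LABELS[["MUCUS"]]] <- params@mucusRGB[ch]
    M[m & labels == LABELS[["SLIME"]]] <- params@slimeRGB[ch]
    if (params@noiseSigma > 0) {
      noise <- matrix(stats::rnorm(H * W, 0, params@noiseSigma), H, W)
      noise[!m] <- 0
      M <- matrix(pmax(pmin(M + noise, 255), 0), H, W)
    }
    out[, , ch] <- M
  }
  out
}

#' Generate a synthetic slime-mold time-lapse with ground truth
#'
#' Lattice simulation of an exploring plasmodium. From an initial circular
#' slime disc, each 5-min step:
#' \enumerate{
#'   \item the reachable frontier band (non-slime arena pixels within
#'     `growthRateMmMin * intervalMin` of the slime) is computed with an
#'     exact distance transform;
#'   \item a fraction `fillFrac` of the band is claimed as new slime,
#'     sampled without replacement with weight `mucusBias` on mucus pixels
#'     vs 1 on unexplored ones (and an extra directional weight toward the
#'     glucose spot when `chemoStrength > 0`);
#'   \item stochastic pseudopod lobes (Poisson rate `pseudopodRate` per
#'     hour) grow small discs beyond the band;
#'   \item with probability `retractionProb` a peripheral patch of
#'     established slime (slime in the previous frame too, so ground truth
#'     obeys the history rule) retracts to mucus.
#' }
#' All stochastic draws consume one pseudo-random stream seeded from
#' `params@seed`, in the order above, with rendering noise drawn after the
#' simulation in frame order; identical seeds give bit-identical output.
#'
#' @param params a [SynthParams-class].
#' @param render if `FALSE`, skip rendering RGB frames (ground truth and
#'   log only) — useful when only label dynamics are needed.
#' @return list with elements `frames` (a [FrameSequence-class], or `NULL`
#'   when `render = FALSE`), `truth` (a [TrinarizedStack-class] of
#'   ground-truth labels), `log` (data.frame of per-interval true metrics:
#'   pixel counts of each growth type, the true maximum growth extent and
#'   migration rate), `arena`, `initRegion` (initial disc mask), `spots`
#'   (a [SpotLayout-class] or `NULL`) and `params`.
#' @examples
#' run <- generateSynthetic(synthParams(imagePx = 64, durationMin = 50,
#'                                      noiseSigma = 0, seed = 2))
#' nFrames(run$truth)
#' @export
generateSynthetic <- function(params, render = TRUE) {
  stopifnot(is(params, "SynthParams"))
  validObject(params)
  n <- params@imagePx
  centerPx <- c((n + 1) / 2, (n + 1) / 2)
  arenaRadiusPx <- n / 2 - 2
  arena <- makeArena(centerPx, arenaRadiusPx, params@arenaDiameterMm, c(n, n))
  mmPerPx <- arena@mmPerPx
  slimeRadiusPx <- (params@slimeDiameterMm / 2) / mmPerPx
  stepPx <- params@growthRateMmMin * params@intervalMin / mmPerPx
  if (stepPx >= arenaRadiusPx - slimeRadiusPx)
    stop("growth rate too large: slime would exit the arena in one step")
  nF <- round(params@durationMin / params@intervalMin)
  if (nF < 2) stop("duration must cover at least 2 frames")
  # same default threshold the segmentation cleanup uses
  minBlobPx <- ceiling(1e-4 * sum(arena@mask))

  # spot experiment geometry: slime and glucose spot on the horizontal
  # diameter, separated edge-to-edge by spotGapMm
  spots <- NULL
  slimeCenter <- centerPx
  if (!is.na(params@spotGapMm)) {
    spotRadiusPx <- (params@spotDiameterMm / 2) / mmPerPx
    gapPx <- params@spotGapMm / mmPerPx
    dCenters <- slimeRadiusPx + gapPx + spotRadiusPx
    slimeCenter <- c(centerPx[1], centerPx[2] - dCenters / 2)
    spotCenter <- c(centerPx[1], centerPx[2] + dCenters / 2)
    if (slimeCenter[2] - slimeRadiusPx < centerPx[2] - arenaRadiusPx ||
        spotCenter[2] + spotRadiusPx > centerPx[2] + arenaRadiusPx)
      stop("spot layout does not fit inside the arena")
    spots <- spotLayout(data.frame(
      row = spotCenter[1], col = spotCenter[2],
      radiusPx = spotRadiusPx, kind = "glucose"), arena)
  }

  init <- .discMask(c(n, n), slimeCenter, slimeRadiusPx) & arena@mask
  labels <- array(LABELS[["UNEXPLORED"]], c(n, n, nF))
  lab <- matrix(LABELS[["UNEXPLORED"]], n, n)
  lab[init] <- LABELS[["SLIME"]]
  labels[, , 1] <- lab

  log <- data.frame(interval = seq_len(nF - 1),
                    time_min = seq_len(nF - 1) * params@intervalMin,
                    n_primary = 0L, n_secondary = 0L, n_refinement = 0L,
                    max_extent_px = 0, max_extent_mm = 0,
                    migration_rate_mm_min = 0)

  # precompute chemoattraction field (distance to spot center)
  dspot <- NULL
  if (!is.null(spots) && params@chemoStrength > 0) {
    g <- spots@spots[1, ]
    rr <- matrix(seq_len(n), n, n)
    cc <- matrix(seq_len(n), n, n, byrow = TRUE)
    dspot <- sqrt((rr - g$row)^2 + (cc - g$col)^2)
  }

  sim <- function() {
    prev <- labels[, , 1]
    # sub-pixel carry: unspent front advance accumulates so the frontier
    # moves at the nominal speed even when one step is below a pixel
    carry <- 0
    for (t in 2:nF) {
      cur <- prev
      timeNow <- (t - 1) * params@intervalMin
      if (timeNow > params@startDelayMin) {
        slime <- cur == LABELS[["SLIME"]]
        d <- .distToSet(slime)
        thresh <- stepPx + carry
        band <- arena@mask & !slime & d <= thresh
        bandIdx <- which(band)
        grown <- integer(0)
        if (length(bandIdx)) {
          nGrow <- round(params@fillFrac * length(bandIdx))
          if (params@fillFrac >= 1) {
            grown <- bandIdx
          } else if (nGrow > 0) {
            w <- rep(1, length(bandIdx))
            if (params@mucusBias != 1)
              w[cur[bandIdx] == LABELS[["MUCUS"]]] <- params@mucusBias
            if (!is.null(dspot))
              w <- w * exp(params@chemoStrength *
                           (1 - dspot[bandIdx] / max(dspot[bandIdx])))
            grown <- if (all(w == w[1]))
              bandIdx[sample.int(length(bandIdx), nGrow)]
            else
              bandIdx[sample.int(length(bandIdx), nGrow, prob = w)]
          }
        }
        # pseudopod lobes extending beyond the uniform band
        nLobes <- stats::rpois(1, params@pseudopodRate * params@intervalMin / 60)
        if (nLobes > 0 && length(bandIdx)) {
          lobeR <- 2.5 * stepPx
          rr <- ((bandIdx - 1L) %% n) + 1L
          cc <- ((bandIdx - 1L) %/% n) + 1L
          for (k in seq_len(nLobes)) {
            j <- sample.int(length(bandIdx), 1)
            lobe <- .discMask(c(n, n), c(rr[j], cc[j]), lobeR) &
              arena@mask & cur != LABELS[["SLIME"]]
            grown <- union(grown, which(lobe))
          }
        }
        if (length(grown)) cur[grown] <- LABELS[["SLIME"]]
        # retraction: only established slime (slime already in prev) may
        # turn to mucus, so no pixel ever shows unexplored -> mucus
        if (params@retractionProb > 0 &&
            stats::runif(1) < params@retractionProb) {
          estab <- prev == LABELS[["SLIME"]] & cur == LABELS[["SLIME"]]
          if (any(estab)) {
            inner <- .distToSet(!(cur == LABELS[["SLIME"]]) | !arena@mask)
            peri <- estab & inner <= max(2, stepPx)
            pick <- if (any(peri)) which(peri) else which(estab)
            p <- pick[sample.int(length(pick), 1)]
            pr <- ((p - 1L) %% n) + 1L
            pc <- ((p - 1L) %/% n) + 1L
            patch <- estab &
              .discMask(c(n, n), c(pr, pc),
                        params@retractionRadiusFrac * arenaRadiusPx)
            nSlime <- sum(cur == LABELS[["SLIME"]])
            if (any(patch) && nSlime - sum(patch) >= 25)
              cur[patch] <- LABELS[["MUCUS"]]
          }
        }
        # sealing pass: the plasmodial sheet has no sub-threshold vacuoles
        # or specks at this resolution, so the truth is kept a fixed point
        # of the same speckle/hole cleanup the segmentation applies
        sl <- cur == LABELS[["SLIME"]]
        sealed <- cleanMask(sl, arena, minBlobPx)
        addIdx <- which(sealed & !sl)
        if (length(addIdx)) cur[addIdx] <- LABELS[["SLIME"]]
        dropIdx <- which(sl & !sealed)
        if (length(dropIdx)) {
          wasNew <- prev[dropIdx] == LABELS[["UNEXPLORED"]]
          cur[dropIdx[wasNew]] <- LABELS[["UNEXPLORED"]]
          cur[dropIdx[!wasNew]] <- LABELS[["MUCUS"]]
        }
        # true per-interval metrics, derived from the realized transition
        newSlime <- cur == LABELS[["SLIME"]] & prev != LABELS[["SLIME"]]
        log$n_primary[t - 1] <<-
          sum(newSlime & prev == LABELS[["UNEXPLORED"]])
        log$n_secondary[t - 1] <<- sum(newSlime & prev == LABELS[["MUCUS"]])
        log$n_refinement[t - 1] <<-
          sum(prev == LABELS[["SLIME"]] & cur == LABELS[["MUCUS"]])
        ext <- if (any(newSlime)) max(d[newSlime]) else 0
        log$max_extent_px[t - 1] <<- ext
        log$max_extent_mm[t - 1] <<- ext * mmPerPx
        log$migration_rate_mm_min[t - 1] <<- ext * mmPerPx / params@intervalMin
        carry <- min(max(0, thresh - ext), stepPx + 2)
      }
      labels[, , t] <<- cur
      prev <- cur
    }
  }

  frames <- NULL
  .withSeed(params@seed, {
    sim()
    if (render) {
      frames <- vector("list", nF)
      for (t in seq_len(nF))
        frames[[t]] <- renderFrame(labels[, , t], params, arena)
      frames <- frameSequence(frames, params@intervalMin)
    }
  })

  truth <- new("TrinarizedStack", labels = labels, arena = arena,
               intervalMin = params@intervalMin)
  list(frames = frames, truth = truth, log = log, arena = arena,
       initRegion = init, spots = spots, params = params)
}
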
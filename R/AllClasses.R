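#' @import methods
NULL

#' Label codes for the three-class (trinarized) representation
#'
#' Every in-arena pixel of a trinarized frame carries exactly one of these
#' integer codes. The codes are also the pixel values written to mask PNGs,
#' so files round-trip without a palette lookup.
#'
#' @format Named integer vector with entries `UNEXPLORED = 0`, `SLIME = 1`,
#'   `MUCUS = 2`.
#' @export
LABELS <- c(UNEXPLORED = 0L, SLIME = 1L, MUCUS = 2L)

#' Growth-event codes for per-interval transition maps
#'
#' Pixel transitions between consecutive trinarized frames:
#' `PRIMARY` = unexplored -> slime (first visit), `SECONDARY` =
#' mucus -> slime (revisit), `REFINEMENT` = slime -> mucus (withdrawal),
#' `NONE` otherwise.
#'
#' @format Named integer vector with entries `NONE = 0`, `PRIMARY = 1`,
#'   `SECONDARY = 2`, `REFINEMENT = 3`.
#' @export
EVENTS <- c(NONE = 0L, PRIMARY = 1L, SECONDARY = 2L, REFINEMENT = 3L)

#' ArenaMask: the circular analysis region
#'
#' Defines the circular petri-dish arena inside which all metrics are
#' computed, together with the physical pixel scale. The mask uses the
#' pixel-center-inside-circle rule; coordinates are (row, col) with pixel
#' centers at integer positions.
#'
#' @slot center numeric(2), (row, col) of the arena center in pixels.
#' @slot radiusPx arena radius in pixels.
#' @slot mmPerPx physical scale, millimetres per pixel.
#' @slot mask logical matrix, `TRUE` inside the circle.
#' @export
setClass("ArenaMask",
  representation(center = "numeric", radiusPx = "numeric",
                 mmPerPx = "numeric", mask = "matrix"),
  validity = function(object) {
    msg <- character()
    if (length(object@center) != 2) msg <- c(msg, "center must be (row, col)")
    if (object@radiusPx <= 0) msg <- c(msg, "radiusPx must be positive")
    if (object@mmPerPx <= 0) msg <- c(msg, "mmPerPx must be positive")
    if (!is.logical(object@mask)) msg <- c(msg, "mask must be logical")
    if (length(msg)) msg else TRUE
  })

#' FrameSequence: an ordered RGB time-lapse
#'
#' Ordered collection of RGB frames sampled at a fixed interval. Frames are
#' stored as numeric `H x W x 3` arrays with values in 0..255; timestamps are
#' derived as `(index - 1) * intervalMin`.
#'
#' @slot frames list of `H x W x 3` numeric arrays (8-bit scale).
#' @slot intervalMin sampling interval in minutes.
#' @export
setClass("FrameSequence",
  representation(frames = "list", intervalMin = "numeric"),
  validity = function(object) {
    if (length(object@frames) < 2)
      return("a FrameSequence needs at least 2 frames")
    if (object@intervalMin <= 0)
      return("intervalMin must be positive")
    d <- dim(object@frames[[1]])
    if (length(d) != 3 || d[3] != 3)
      return("frames must be H x W x 3 arrays")
    for (i in seq_along(object@frames))
      if (!identical(dim(object@frames[[i]]), d))
        return(sprintf("frame %d has mismatched dimensions", i))
    TRUE
  })

#' TrinarizedStack: the three-class labeling of a whole sequence
#'
#' Per-pixel labels in \{SLIME, MUCUS, UNEXPLORED\} for every frame,
#' restricted to the arena (outside-arena pixels are 0 and excluded from all
#' metrics). Labels obey the history rule: once a pixel has been slime or
#' mucus it can never return to unexplored.
#'
#' @slot labels integer array `H x W x T` of label codes (see [LABELS]).
#' @slot arena the [ArenaMask-class] the labels are restricted to.
#' @slot intervalMin sampling interval in minutes.
#' @export
setClass("TrinarizedStack",
  representation(labels = "array", arena = "ArenaMask",
                 intervalMin = "numeric"),
  validity = function(object) {
    if (length(dim(object@labels)) != 3)
      return("labels must be an H x W x T array")
    if (!all(object@labels %in% LABELS))
      return("labels must be in {0 = UNEXPLORED, 1 = SLIME, 2 = MUCUS}")
    if (!identical(dim(object@labels)[1:2], dim(object@arena@mask)))
      return("label grid does not match arena mask dimensions")
    TRUE
  })

#' TransitionMap: per-pixel growth events between two consecutive frames
#'
#' @slot events integer matrix of event codes (see [EVENTS]).
#' @slot intervalIndex which interval this map covers (between frames
#'   `intervalIndex` and `intervalIndex + 1`, 1-based).
#' @slot arena the [ArenaMask-class].
#' @export
setClass("TransitionMap",
  representation(events = "matrix", intervalIndex = "integer",
                 arena = "ArenaMask"),
  validity = function(object) {
    if (!all(object@events %in% EVENTS))
      return("events must be in {0 = NONE, 1 = PRIMARY, 2 = SECONDARY, 3 = REFINEMENT}")
    TRUE
  })

#' SpotLayout: attractant / repellent spots in the arena
#'
#' @slot spots data.frame with columns `row`, `col` (center, px), `radiusPx`
#'   and `kind` (one of "glucose", "salt", "origin").
#' @export
setClass("SpotLayout",
  representation(spots = "data.frame"),
  validity = function(object) {
    need <- c("row", "col", "radiusPx", "kind")
    if (!all(need %in% names(object@spots)))
      return("spots needs columns row, col, radiusPx, kind")
    if (any(object@spots$radiusPx <= 0)) return("spot radii must be positive")
    if (!all(object@spots$kind %in% c("glucose", "salt", "origin")))
      return("spot kind must be glucose, salt or origin")
    TRUE
  })

#' SynthParams: parameterization of the synthetic time-lapse generator
#'
#' Full description of a simulated exploration experiment: arena and initial
#' disc geometry (defaults follow the 14.5 cm arena with a 2.5 cm slime disc
#' sampled every 5 min for 35 h, i.e. 420 frames), lattice growth dynamics,
#' optional chemoattractant spot, and the color/noise model used to render
#' frames.
#'
#' @slot arenaDiameterMm arena diameter (mm).
#' @slot slimeDiameterMm initial slime disc diameter (mm).
#' @slot intervalMin sampling interval (min).
#' @slot durationMin total duration (min); frame count = duration / interval.
#' @slot imagePx square image side in pixels.
#' @slot growthRateMmMin frontier advance speed (mm/min).
#' @slot pseudopodRate expected new growth lobes per hour.
#' @slot retractionProb per-step probability that a peripheral region
#'   retracts to mucus.
#' @slot retractionRadiusFrac retraction patch radius, fraction of arena radius.
#' @slot mucusBias sampling weight of mucus relative to unexplored substrate
#'   when regrowth targets are drawn (1 = indifferent; > 1 models the
#'   adverse-substrate preference for previously explored area).
#' @slot fillFrac fraction of the reachable frontier band claimed per step.
#' @slot startDelayMin delay before exploration starts (min).
#' @slot chemoStrength directional bias toward the glucose spot (0 = none).
#' @slot spotGapMm edge-to-edge gap between the slime disc and the glucose
#'   spot in spot experiments (NA = no spot).
#' @slot spotDiameterMm attractant spot diameter (mm).
#' @slot slimeRGB,mucusRGB,substrateRGB,outsideRGB mean 8-bit colors per class.
#' @slot noiseSigma i.i.d. Gaussian color noise, 8-bit units.
#' @slot seed integer seed for the single pseudo-random stream.
#' @export
setClass("SynthParams",
  representation(
    arenaDiameterMm = "numeric", slimeDiameterMm = "numeric",
    intervalMin = "numeric", durationMin = "numeric", imagePx = "integer",
    growthRateMmMin = "numeric", pseudopodRate = "numeric",
    retractionProb = "numeric", retractionRadiusFrac = "numeric",
    mucusBias = "numeric", fillFrac = "numeric", startDelayMin = "numeric",
    chemoStrength = "numeric", spotGapMm = "numeric", spotDiameterMm = "numeric",
    slimeRGB = "numeric", mucusRGB = "numeric", substrateRGB = "numeric",
    outsideRGB = "numeric", noiseSigma = "numeric", seed = "integer"),
  prototype(
    arenaDiameterMm = 145, slimeDiameterMm = 25, intervalMin = 5,
    durationMin = 2100, imagePx = 256L, growthRateMmMin = 0.25,
    pseudopodRate = 1, retractionProb = 0.3, retractionRadiusFrac = 0.10,
    mucusBias = 1, fillFrac = 0.6, startDelayMin = 0, chemoStrength = 0,
    spotGapMm = NA_real_, spotDiameterMm = 25,
    slimeRGB = c(180, 150, 40), mucusRGB = c(230, 218, 182),
    substrateRGB = c(240, 240, 245), outsideRGB = c(30, 30, 30),
    noiseSigma = 4, seed = 1L),
  validity = function(object) {
    msg <- character()
    p <- function(x) length(x) == 1 && !is.na(x)
    if (object@retractionProb < 0 || object@retractionProb > 1)
      msg <- c(msg, "retractionProb must be in [0, 1]")
    if (object@fillFrac <= 0 || object@fillFrac > 1)
      msg <- c(msg, "fillFrac must be in (0, 1]")
    if (object@growthRateMmMin < 0 || object@pseudopodRate < 0 ||
        object@mucusBias < 0)
      msg <- c(msg, "rates and mucusBias must be >= 0")
    if (object@slimeDiameterMm >= object@arenaDiameterMm)
      msg <- c(msg, "slime disc must fit inside the arena")
    if (object@intervalMin <= 0 || object@durationMin <= 0)
      msg <- c(msg, "interval and duration must be positive")
    for (s in c("slimeRGB", "mucusRGB", "substrateRGB", "outsideRGB"))
      if (length(slot(object, s)) != 3) msg <- c(msg, paste(s, "must be length 3"))
    if (length(msg)) msg else TRUE
  })

setMethod("show", "ArenaMask", function(object) {
  cat(sprintf("ArenaMask: center (%.1f, %.1f) px, radius %.1f px, %.4f mm/px\n",
              object@center[1], object@center[2], object@radiusPx,
              object@mmPerPx))
  cat(sprintf("  %d x %d grid, %d in-arena pixels\n",
              nrow(object@mask), ncol(object@mask), sum(object@mask)))
})

setMethod("show", "FrameSequence", function(object) {
  d <- dim(object@frames[[1]])
  cat(sprintf("FrameSequence: %d frames of %d x %d RGB, every %g min (t = 0..%g min)\n",
              length(object@frames), d[1], d[2], object@intervalMin,
              (length(object@frames) - 1) * object@intervalMin))
})

setMethod("show", "TrinarizedStack", function(object) {
  d <- dim(object@labels)
  cat(sprintf("TrinarizedStack: %d frames of %d x %d labels, every %g min\n",
              d[3], d[1], d[2], object@intervalMin))
  n <- sum(object@arena@mask)
  last <- object@labels[, , d[3]]
  m <- object@arena@mask
  cat(sprintf("  final coverage: slime %.1f%%, mucus %.1f%%, unexplored %.1f%%\n",
              100 * sum(last[m] == LABELS["SLIME"]) / n,
              100 * sum(last[m] == LABELS["MUCUS"]) / n,
              100 * sum(last[m] == LABELS["UNEXPLORED"]) / n))
})

setMethod("show", "TransitionMap", function(object) {
  e <- object@events
  cat(sprintf(
    "TransitionMap (interval %d): %d primary, %d secondary, %d refinement\n",
    object@intervalIndex, sum(e == EVENTS["PRIMARY"]),
    sum(e == EVENTS["SECONDARY"]), sum(e == EVENTS["REFINEMENT"])))
})

setMethod("show", "SpotLayout", function(object) {
  cat("SpotLayout:\n"); print(object@spots)
})

setMethod("show", "SynthParams", function(object) {
  cat(sprintf(
    "SynthParams: %g mm arena, %g mm disc, %d frames (%g min @ %g min), %d px\n",
    object@arenaDiameterMm, object@slimeDiameterMm,
    round(object@durationMin / object@intervalMin), object@durationMin,
    object@intervalMin, object@imagePx))
  cat(sprintf(
    "  growth %.3g mm/min, pseudopods %.3g/h, retraction p=%.2g, mucus bias %.2g, seed %d\n",
    object@growthRateMmMin, object@pseudopodRate, object@retractionProb,
    object@mucusBias, object@seed))
})
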
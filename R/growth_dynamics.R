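#' Classify per-pixel growth events between two consecutive frames
#'
#' Compares two consecutive trinarized frames and maps every arena pixel to
#' a growth event: PRIMARY (unexplored -> slime, first visit), SECONDARY
#' (mucus -> slime, revisit), REFINEMENT (slime -> mucus, withdrawal) or
#' NONE. By construction the pixel counts satisfy the area balance
#' `slime(t) - slime(t-1) = primary + secondary - refinement`.
#'
#' @param prev,curr integer label matrices (codes of [LABELS]) for frames
#'   t-1 and t.
#' @param arena an [ArenaMask-class].
#' @param intervalIndex 1-based index of the interval (between frames
#'   `intervalIndex` and `intervalIndex + 1`).
#' @return a [TransitionMap-class].
#' @export
classifyTransitions <- function(prev, curr, arena,
                                intervalIndex = 1L) {
  stopifnot(is(arena, "ArenaMask"),
            identical(dim(prev), dim(curr)),
            identical(dim(prev), dim(arena@mask)))
  m <- arena@mask
  ev <- matrix(EVENTS[["NONE"]], nrow(prev), ncol(prev))
  ev[m & prev == LABELS[["UNEXPLORED"]] & curr == LABELS[["SLIME"]]] <-
    EVENTS[["PRIMARY"]]
  ev[m & prev == LABELS[["MUCUS"]] & curr == LABELS[["SLIME"]]] <-
    EVENTS[["SECONDARY"]]
  ev[m & prev == LABELS[["SLIME"]] & curr == LABELS[["MUCUS"]]] <-
    EVENTS[["REFINEMENT"]]
  new("TransitionMap", events = ev, intervalIndex = as.integer(intervalIndex),
      arena = arena)
}

#' Fractions of the arena covered by each class
#'
#' @param labels integer label matrix of one frame.
#' @param arena an [ArenaMask-class].
#' @return named numeric(3): `slime`, `mucus`, `unexplored`; sums to 1.
#' @export
coverageFractions <- function(labels, arena) {
  m <- arena@mask
  n <- sum(m)
  c(slime = sum(labels[m] == LABELS[["SLIME"]]) / n,
    mucus = sum(labels[m] == LABELS[["MUCUS"]]) / n,
    unexplored = sum(labels[m] == LABELS[["UNEXPLORED"]]) / n)
}

#' Extent of growth: distance of each growth pixel to the previous slime
#'
#' For every pixel where growth occurred in the interval (PRIMARY or
#' SECONDARY), the Euclidean distance to the closest pixel classified as
#' slime in the previous frame, computed with an exact distance transform
#' and reported in millimetres.
#'
#' @param tm a [TransitionMap-class].
#' @param prevSlime logical slime mask of the previous frame.
#' @return numeric vector of distances (mm); empty when no growth occurred.
#' @export
growthExtents <- function(tm, prevSlime) {
  stopifnot(is(tm, "TransitionMap"))
  if (!any(prevSlime)) stop("previous slime mask is empty (slime lost)")
  grown <- tm@events == EVENTS[["PRIMARY"]] | tm@events == EVENTS[["SECONDARY"]]
  if (!any(grown)) return(numeric(0))
  d <- .distToSet(prevSlime)
  d[grown] * tm@arena@mmPerPx
}

#' Migration rate of one interval
#'
#' Ratio of the maximum extent of growth to the sampling interval; 0 when
#' no growth occurred.
#'
#' @param extents numeric vector of growth distances (mm), from
#'   [growthExtents()].
#' @param intervalMin sampling interval (min).
#' @return migration rate in mm/min.
#' @export
migrationRate <- function(extents, intervalMin) {
  stopifnot(intervalMin > 0)
  if (!length(extents)) return(0)
  max(extents) / intervalMin
}

#' Expansion region reachable within one interval
#'
#' The band of non-slime arena pixels within `offsetMm` of the previous
#' slime contour — the region the cell could have explored during the
#' interval, used as the reference set for expected secondary growth. The
#' offset is normally the interval's maximum growth extent
#' (migration rate x interval).
#'
#' @param prevLabels label matrix of the previous frame.
#' @param arena an [ArenaMask-class].
#' @param offsetMm offset distance (mm), >= 0.
#' @return logical mask of the expansion region.
#' @export
expansionRegion <- function(prevLabels, arena, offsetMm) {
  stopifnot(offsetMm >= 0)
  slime <- prevLabels == LABELS[["SLIME"]] & arena@mask
  d <- .distToSet(slime)
  arena@mask & !slime & (d * arena@mmPerPx) <= offsetMm & d > 0
}

#' Observed and expected secondary-growth fractions
#'
#' `observed` is the fraction of growth pixels that are secondary growth
#' (revisits of mucus); `expected` is the fraction the interval would show
#' if growth landed uniformly at random in the expansion region, i.e. the
#' fraction of that region previously covered by mucus. Observed > expected
#' indicates a bias toward previously explored (mucus-covered) substrate.
#'
#' @param tm a [TransitionMap-class].
#' @param region logical expansion-region mask for the same interval.
#' @param prevLabels label matrix of the previous frame.
#' @return named numeric(2) `observed`, `expected`; `NA` where the
#'   denominator is zero (degenerate interval).
#' @export
secondaryGrowthBias <- function(tm, region, prevLabels) {
  nSec <- sum(tm@events == EVENTS[["SECONDARY"]])
  nPri <- sum(tm@events == EVENTS[["PRIMARY"]])
  observed <- if (nSec + nPri > 0) nSec / (nSec + nPri) else NA_real_
  nReg <- sum(region)
  expected <- if (nReg > 0)
    sum(prevLabels[region] == LABELS[["MUCUS"]]) / nReg else NA_real_
  c(observed = observed, expected = expected)
}

#' Accumulate coverage, growth and migration metrics over a whole stack
#'
#' Builds the per-frame / per-interval metrics table: coverage fractions of
#' the three classes, per-interval and cumulative areas of primary growth,
#' secondary growth and refinement (as fractions of arena area, so
#' cumulative secondary growth may exceed 1), the migration rate, and the
#' inoculated disc counted as primary coverage already present at time
#' zero — which makes cumulative primary growth equal the explored
#' (slime-or-mucus) fraction at every frame — plus the
#' observed vs expected secondary-growth fractions. Interval quantities are
#' attached to the row of the interval's later frame; the first row carries
#' `NA` for them. A sliding-window pooling of observed/expected fractions
#' (default 60 min) is appended for plotting, since single intervals can be
#' degenerate.
#'
#' @param stack a [TrinarizedStack-class].
#' @param windowMin width (min) of the pooling window for
#'   `observed_secondary_smooth` / `expected_secondary_smooth`.
#' @return data.frame with one row per frame; columns `frame`, `time_min`,
#'   `frac_slime`, `frac_mucus`, `frac_unexplored`, `primary`, `secondary`,
#'   `refinement`, `cum_primary`, `cum_secondary`, `cum_refinement`,
#'   `migration_rate_mm_min`, `observed_secondary`, `expected_secondary`,
#'   and the two smoothed columns.
#' @export
accumulateGrowth <- function(stack, windowMin = 60) {
  stopifnot(is(stack, "TrinarizedStack"))
  n <- nFrames(stack)
  arena <- arenaMask(stack)
  nAr <- sum(arena@mask)
  dt <- intervalMin(stack)
  cov <- t(vapply(seq_len(n),
                  function(i) coverageFractions(frameLabels(stack, i), arena),
                  numeric(3)))
  out <- data.frame(
    frame = seq_len(n), time_min = frameTimes(stack),
    frac_slime = cov[, 1], frac_mucus = cov[, 2], frac_unexplored = cov[, 3],
    primary = NA_real_, secondary = NA_real_, refinement = NA_real_,
    migration_rate_mm_min = NA_real_,
    observed_secondary = NA_real_, expected_secondary = NA_real_)
  nSecPix <- nPriPix <- rep(NA_real_, n)
  regMucus <- regSize <- rep(NA_real_, n)
  for (t in 2:n) {
    prev <- frameLabels(stack, t - 1)
    curr <- frameLabels(stack, t)
    tm <- classifyTransitions(prev, curr, arena, t - 1L)
    out$primary[t] <- sum(tm@events == EVENTS[["PRIMARY"]]) / nAr
    out$secondary[t] <- sum(tm@events == EVENTS[["SECONDARY"]]) / nAr
    out$refinement[t] <- sum(tm@events == EVENTS[["REFINEMENT"]]) / nAr
    prevSlime <- prev == LABELS[["SLIME"]] & arena@mask
    if (any(prevSlime)) {
      ext <- growthExtents(tm, prevSlime)
      rate <- migrationRate(ext, dt)
      out$migration_rate_mm_min[t] <- rate
      region <- expansionRegion(prev, arena, rate * dt)
      b <- secondaryGrowthBias(tm, region, prev)
      out$observed_secondary[t] <- b[["observed"]]
      out$expected_secondary[t] <- b[["expected"]]
      nSecPix[t] <- sum(tm@events == EVENTS[["SECONDARY"]])
      nPriPix[t] <- sum(tm@events == EVENTS[["PRIMARY"]])
      regSize[t] <- sum(region)
      regMucus[t] <- sum(prev[region] == LABELS[["MUCUS"]])
    }
  }
  # the inoculated disc counts as primary coverage already present at t = 0,
  # so cumulative primary growth equals the explored fraction at all times
  out$cum_primary <- out$frac_slime[1] +
    cumsum(ifelse(is.na(out$primary), 0, out$primary))
  out$cum_secondary <- cumsum(ifelse(is.na(out$secondary), 0, out$secondary))
  out$cum_refinement <- cumsum(ifelse(is.na(out$refinement), 0, out$refinement))
  # pooled fractions over a sliding window: ratio of pooled counts
  half <- max(1L, floor((windowMin / dt) / 2))
  smoothObs <- smoothExp <- rep(NA_real_, n)
  for (t in 2:n) {
    w <- max(2, t - half):min(n, t + half)
    sSec <- sum(nSecPix[w], na.rm = TRUE); sPri <- sum(nPriPix[w], na.rm = TRUE)
    sReg <- sum(regSize[w], na.rm = TRUE); sMuc <- sum(regMucus[w], na.rm = TRUE)
    if (sSec + sPri > 0) smoothObs[t] <- sSec / (sSec + sPri)
    if (sReg > 0) smoothExp[t] <- sMuc / sReg
  }
  out$observed_secondary_smooth <- smoothObs
  out$expected_secondary_smooth <- smoothExp
  out
}
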
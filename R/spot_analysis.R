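#' Define the spot layout of a spot experiment
#'
#' @param spots data.frame with columns `row`, `col` (spot centers, px),
#'   `radiusPx` and `kind` ("glucose", "salt" or "origin").
#' @param arena optional [ArenaMask-class]; when given, spots are checked to
#'   lie inside the arena.
#' @return a [SpotLayout-class].
#' @export
spotLayout <- function(spots, arena = NULL) {
  obj <- new("SpotLayout", spots = spots)
  if (!is.null(arena)) {
    d <- sqrt((spots$row - arena@center[1])^2 +
              (spots$col - arena@center[2])^2)
    if (any(d + spots$radiusPx > arena@radiusPx))
      stop("spot extends outside the arena")
  }
  obj
}

#' Minimum distance from the slime contour to the glucose spot
#'
#' Minimum over slime pixels of the Euclidean distance to the spot center
#' minus the spot radius (i.e. distance to the spot's circular edge),
#' clamped at 0 when the slime overlaps the spot; in millimetres.
#'
#' @param slimeMask logical slime mask.
#' @param layout a [SpotLayout-class] containing one glucose spot.
#' @param mmPerPx physical scale.
#' @return distance in mm (0 = contact).
#' @export
distanceToSpot <- function(slimeMask, layout, mmPerPx) {
  stopifnot(is(layout, "SpotLayout"))
  if (!any(slimeMask)) stop("empty slime mask")
  g <- layout@spots[layout@spots$kind == "glucose", , drop = FALSE]
  if (nrow(g) < 1) stop("no glucose spot in layout")
  g <- g[1, ]
  pts <- which(slimeMask, arr.ind = TRUE)
  d <- sqrt((pts[, 1] - g$row)^2 + (pts[, 2] - g$col)^2) - g$radiusPx
  max(0, min(d)) * mmPerPx
}

#' Time to first contact with the attractant
#'
#' First time at which the slime-to-spot distance drops to the threshold;
#' censored at the final observation time when contact never happens.
#'
#' @param distancesMm per-frame distances (mm).
#' @param timesMin per-frame times (min), same length.
#' @param thresholdMm contact threshold (mm), default 0.
#' @return list with `time` (min) and `censored` (logical).
#' @export
timeToContact <- function(distancesMm, timesMin, thresholdMm = 0) {
  stopifnot(length(distancesMm) == length(timesMin), thresholdMm >= 0)
  hit <- which(distancesMm <= thresholdMm)
  if (length(hit)) list(time = timesMin[hit[1]], censored = FALSE)
  else list(time = timesMin[length(timesMin)], censored = TRUE)
}

#' Empirical time-to-contact survival curve
#'
#' Step function P(t) = fraction of replicates that have not reached the
#' glucose spot by time t; censored replicates count as not-reached through
#' the horizon. With n replicates P takes values in \{0, 1/n, ..., 1\}.
#'
#' @param timesMin per-replicate contact times (min).
#' @param censored logical vector, `TRUE` where the replicate never made
#'   contact.
#' @param horizonMin end of the observation window (default: max time).
#' @return data.frame with columns `time_min` and `P` (right-continuous
#'   steps, starting at time 0); attributes `n_replicates` and `n_censored`.
#' @export
survivalCurve <- function(timesMin, censored = rep(FALSE, length(timesMin)),
                          horizonMin = max(timesMin)) {
  stopifnot(length(timesMin) >= 1, length(censored) == length(timesMin))
  n <- length(timesMin)
  ev <- sort(unique(c(0, timesMin[!censored], horizonMin)))
  ev <- ev[ev <= horizonMin]
  P <- vapply(ev, function(t)
    sum(censored | timesMin > t) / n, numeric(1))
  out <- data.frame(time_min = ev, P = P)
  attr(out, "n_replicates") <- n
  attr(out, "n_censored") <- sum(censored)
  out
}
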
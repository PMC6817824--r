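#' Convert an RGB frame to the ab* chromatic plane
#'
#' Standard sRGB -> CIELAB conversion (D65 white point) with the lightness
#' channel discarded, leaving the two chromatic coordinates a* and b*.
#' Dropping L* makes the segmentation robust to the uneven illumination of a
#' photographed dish: two pixels differing only in brightness map to the
#' same chromatic point.
#'
#' @param frame numeric `H x W x 3` array on the 0..255 scale.
#' @return numeric `H x W x 2` array holding a* and b*.
#' @examples
#' f <- array(128, c(2, 2, 3))
#' range(toAB(f))  # achromatic gray: a* = b* = 0
#' @export
toAB <- function(frame) {
  d <- dim(frame)
  if (length(d) != 3 || d[3] != 3) stop("frame must be H x W x 3")
  rgb <- matrix(as.numeric(frame), ncol = 3) / 255
  lab <- grDevices::convertColor(rgb, from = "sRGB", to = "Lab")
  array(lab[, 2:3], dim = c(d[1], d[2], 2))
}

#' Mean ab* color over a reference region
#'
#' Computes the chromatic reference used to identify the slime cluster:
#' typically the mean ab* of the known initial slime disc in frame 0.
#'
#' @param abFrame `H x W x 2` ab* array.
#' @param region logical matrix selecting the reference pixels.
#' @return numeric(2), mean (a*, b*).
#' @export
referenceColor <- function(abFrame, region) {
  if (!any(region)) stop("empty reference region")
  c(mean(abFrame[, , 1][region]), mean(abFrame[, , 2][region]))
}

#' Binarize one frame into slime / not-slime by two-cluster k-means
#'
#' All in-arena pixels' ab* values are clustered with k = 2 k-means
#' (10 restarts). The cluster whose centroid is nearer, in Euclidean ab*
#' distance, to `refColor` is labeled slime; this makes the output invariant
#' to the arbitrary permutation of k-means cluster indices and hence to the
#' seed. The raw mask is then cleaned: 8-connected foreground components
#' smaller than `minBlobPx` are removed and enclosed holes smaller than
#' `minBlobPx` are filled.
#'
#' @param abFrame `H x W x 2` ab* array (see [toAB()]).
#' @param arena an [ArenaMask-class].
#' @param refColor numeric(2), reference ab* of the initial slime disc.
#' @param seed integer seed for the k-means restarts (output does not depend
#'   on it; it only pins the iteration order).
#' @param minBlobPx speckle/hole cleanup threshold in pixels; default
#'   `ceiling(1e-4 * arena area)`.
#' @return logical matrix, `TRUE` for slime (always `FALSE` outside the
#'   arena).
#' @section Errors:
#' If the in-arena chromatic values are essentially constant, or the two
#' cluster centroids coincide (separation < 1 ab* unit), the frame carries
#' no usable color contrast and a "no chromatic contrast" error is raised.
#' @export
kmeansBinarize <- function(abFrame, arena, refColor, seed = 1L,
                           minBlobPx = NULL) {
  stopifnot(is(arena, "ArenaMask"))
  m <- arena@mask
  if (is.null(minBlobPx)) minBlobPx <- ceiling(1e-4 * sum(m))
  X <- cbind(abFrame[, , 1][m], abFrame[, , 2][m])
  if (diff(range(X[, 1])) < 0.5 && diff(range(X[, 2])) < 0.5)
    stop("no chromatic contrast in arena")
  km <- .withSeed(seed,
    stats::kmeans(X, centers = 2, nstart = 10, iter.max = 100))
  if (sqrt(sum((km$centers[1, ] - km$centers[2, ])^2)) < 1)
    stop("no chromatic contrast in arena")
  d <- rowSums((km$centers - matrix(refColor, 2, 2, byrow = TRUE))^2)
  slimeCluster <- which.min(d)
  mask <- matrix(FALSE, nrow(m), ncol(m))
  mask[m] <- km$cluster == slimeCluster
  cleanMask(mask, arena, minBlobPx)
}

#' Remove small speckles and fill small holes in a slime mask
#'
#' Foreground components (8-connected) below the threshold are deleted;
#' background components inside the arena that do not touch the arena
#' border and are below the threshold are filled.
#'
#' @param mask logical slime mask.
#' @param arena an [ArenaMask-class].
#' @param minBlobPx size threshold in pixels.
#' @return cleaned logical mask.
#' @export
cleanMask <- function(mask, arena, minBlobPx) {
  m <- arena@mask
  mask <- mask & m
  if (minBlobPx <= 1) return(mask)
  lab <- .labelComponents(mask, 8)
  if (max(lab) > 0) {
    sz <- tabulate(lab[lab > 0])
    drop <- which(sz < minBlobPx)
    if (length(drop)) mask[lab %in% drop] <- FALSE
  }
  # holes: in-arena background components not touching the arena rim
  bg <- m & !mask
  labb <- .labelComponents(bg, 4)
  if (max(labb) > 0) {
    rim <- m & !.erodeDisc(m, 1.5)
    rimLabs <- unique(labb[rim & bg])
    sz <- tabulate(labb[labb > 0])
    fill <- setdiff(which(sz < minBlobPx), rimLabs)
    if (length(fill)) mask[labb %in% fill] <- TRUE
  }
  mask
}

#' Trinarize a sequence of slime masks using pixel history
#'
#' Converts per-frame binary slime masks into the three-class labeling.
#' Frame 1 is SLIME where the mask is set and UNEXPLORED elsewhere. For
#' later frames a slime pixel is SLIME; a non-slime pixel is MUCUS if it was
#' ever slime (or mucus) before — the receding cell leaves mucus behind —
#' and UNEXPLORED otherwise. Consequently no pixel ever returns to
#' UNEXPLORED once it has left that state.
#'
#' @param masks list of logical slime masks (temporal order), or a logical
#'   `H x W x T` array.
#' @param arena an [ArenaMask-class].
#' @param intervalMin sampling interval in minutes.
#' @param initialSlime optional override for the frame-1 slime mask.
#' @return a [TrinarizedStack-class].
#' @examples
#' a <- makeArena(c(3, 3), 2, 10, c(5, 5))
#' on <- a@mask; off <- matrix(FALSE, 5, 5)
#' tri <- trinarizeSequence(list(on, off, off), a, 5)
#' frameLabels(tri, 2)[3, 3]  # 2: mucus after retraction
#' @export
trinarizeSequence <- function(masks, arena, intervalMin = 5,
                              initialSlime = NULL) {
  stopifnot(is(arena, "ArenaMask"))
  if (is.array(masks) && length(dim(masks)) == 3)
    masks <- lapply(seq_len(dim(masks)[3]), function(i) masks[, , i])
  n <- length(masks)
  if (n < 1) stop("need at least one mask")
  if (!is.null(initialSlime)) masks[[1]] <- initialSlime
  m <- arena@mask
  H <- nrow(m); W <- ncol(m)
  labels <- array(LABELS[["UNEXPLORED"]], c(H, W, n))
  ever <- masks[[1]] & m
  lab <- matrix(LABELS[["UNEXPLORED"]], H, W)
  lab[ever] <- LABELS[["SLIME"]]
  labels[, , 1] <- lab
  if (n > 1) for (t in 2:n) {
    s <- masks[[t]] & m
    lab <- matrix(LABELS[["UNEXPLORED"]], H, W)
    lab[ever & !s] <- LABELS[["MUCUS"]]
    lab[s] <- LABELS[["SLIME"]]
    labels[, , t] <- lab
    ever <- ever | s
  }
  new("TrinarizedStack", labels = labels, arena = arena,
      intervalMin = as.numeric(intervalMin))
}

#' Segment a whole frame sequence into a trinarized stack
#'
#' Runs [toAB()] and [kmeansBinarize()] on every frame independently (no
#' temporal smoothing), then [trinarizeSequence()]. The chromatic reference
#' is the mean ab* over `initRegion` in frame 1 (by default the initial
#' slime disc position must be supplied).
#'
#' @param fs a [FrameSequence-class].
#' @param arena an [ArenaMask-class].
#' @param initRegion logical matrix marking the known initial slime disc in
#'   frame 1 (used only to compute the reference color), or `NULL` if
#'   `refColor` is given.
#' @param refColor optional explicit (a*, b*) reference overriding
#'   `initRegion`.
#' @param seed k-means seed (see [kmeansBinarize()]).
#' @param minBlobFrac cleanup threshold as a fraction of arena area.
#' @return a [TrinarizedStack-class].
#' @export
segmentSequence <- function(fs, arena, initRegion = NULL, refColor = NULL,
                            seed = 1L, minBlobFrac = 1e-4) {
  stopifnot(is(fs, "FrameSequence"), is(arena, "ArenaMask"))
  minBlobPx <- ceiling(minBlobFrac * sum(arena@mask))
  if (is.null(refColor)) {
    if (is.null(initRegion))
      stop("supply initRegion or refColor")
    refColor <- referenceColor(toAB(getFrame(fs, 1)), initRegion & arena@mask)
  }
  n <- nFrames(fs)
  masks <- vector("list", n)
  for (i in seq_len(n)) {
    ab <- toAB(getFrame(fs, i))
    masks[[i]] <- tryCatch(
      kmeansBinarize(ab, arena, refColor, seed = seed, minBlobPx = minBlobPx),
      error = function(e)
        stop(sprintf("segmentation failed at frame %d: %s", i,
                     conditionMessage(e)), call. = FALSE))
  }
  trinarizeSequence(masks, arena, intervalMin(fs))
}
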
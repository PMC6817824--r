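#' Load a time-lapse image sequence
#'
#' Reads an ordered series of RGB photographs into a
#' [FrameSequence-class]. Files are taken in lexicographic order, which is
#' assumed to correspond to temporal order; an explicit character vector of
#' paths overrides that sort. Alpha channels are dropped; grayscale inputs
#' are rejected because the chromatic segmentation needs color.
#'
#' @param path a directory containing PNG/TIFF/JPEG frames, or a character
#'   vector of file paths already in temporal order.
#' @param intervalMin sampling interval between consecutive frames, minutes.
#' @return a [FrameSequence-class]; frames are `H x W x 3` arrays on the
#'   0..255 scale and timestamps are `(index - 1) * intervalMin`.
#' @examples
#' \dontrun{
#' fs <- loadSequence("frames/", intervalMin = 5)
#' frameTimes(fs)
#' }
#' @export
loadSequence <- function(path, intervalMin) {
  if (intervalMin <= 0) stop("intervalMin must be positive")
  if (length(path) == 1 && dir.exists(path)) {
    files <- list.files(path, pattern = "\\.(png|tif|tiff|jpg|jpeg)$",
                        ignore.case = TRUE, full.names = TRUE)
    files <- sort(files, method = "radix")
  } else {
    files <- path
  }
  if (length(files) < 2)
    stop("need at least 2 frames, found ", length(files))
  missing <- files[!file.exists(files)]
  if (length(missing)) stop("file not found: ", missing[1])
  frames <- vector("list", length(files))
  ref <- NULL
  for (i in seq_along(files)) {
    img <- EBImage::readImage(files[i])
    a <- EBImage::imageData(img)
    if (length(dim(a)) == 2)
      stop("grayscale frame not supported: ", files[i])
    if (dim(a)[3] == 4) a <- a[, , 1:3, drop = FALSE]
    if (dim(a)[3] != 3)
      stop("grayscale frame not supported: ", files[i])
    # EBImage stores (x, y, c); convert to (row, col, c)
    a <- aperm(a, c(2, 1, 3))
    if (is.null(ref)) ref <- dim(a)
    if (!identical(dim(a), ref))
      stop("frame dimensions differ from first frame: ", files[i])
    frames[[i]] <- a * 255
  }
  frameSequence(frames, intervalMin)
}

#' Construct a FrameSequence from in-memory frames
#'
#' @param frames list of `H x W x 3` numeric arrays, values 0..255.
#' @param intervalMin sampling interval in minutes.
#' @return a [FrameSequence-class].
#' @export
frameSequence <- function(frames, intervalMin) {
  new("FrameSequence", frames = frames, intervalMin = as.numeric(intervalMin))
}

#' Define the circular arena mask
#'
#' The arena (the petri-dish interior) is supplied explicitly, mirroring the
#' manual contour identification used in the experiments; see
#' [detectArena()] for an optional automatic helper. The mask uses the
#' pixel-center-inside-circle rule and fixes the physical scale as
#' `arenaDiameterMm / (2 * radiusPx)`.
#'
#' @param centerPx numeric(2), arena center as (row, col) in pixels.
#' @param radiusPx arena radius in pixels.
#' @param arenaDiameterMm physical arena diameter (default 145 mm, a
#'   14.5 cm dish).
#' @param imageShape integer(2), (height, width) of the frames.
#' @return an [ArenaMask-class].
#' @examples
#' arena <- makeArena(c(51, 51), 45, 145, c(101, 101))
#' arena@mmPerPx  # 145 / 90
#' @export
makeArena <- function(centerPx, radiusPx, arenaDiameterMm = 145, imageShape) {
  stopifnot(length(centerPx) == 2, length(imageShape) >= 2)
  if (radiusPx <= 0) stop("radiusPx must be positive")
  H <- imageShape[1]; W <- imageShape[2]
  # pixel centers live on [1, H] x [1, W]; the image covers [0.5, H + 0.5]
  if (centerPx[1] - radiusPx < 0.5 || centerPx[1] + radiusPx > H + 0.5 ||
      centerPx[2] - radiusPx < 0.5 || centerPx[2] + radiusPx > W + 0.5)
    stop("arena circle exceeds image bounds")
  mask <- .discMask(c(H, W), centerPx, radiusPx)
  new("ArenaMask", center = as.numeric(centerPx),
      radiusPx = as.numeric(radiusPx),
      mmPerPx = arenaDiameterMm / (2 * radiusPx), mask = mask)
}

#' Automatically detect a circular arena (helper, never the default)
#'
#' Fits a circle to the largest bright region of a frame: pixels above the
#' mid luminance are labeled, the largest component's centroid is the
#' center, and the radius is the mean centroid distance of its boundary
#' pixels. Intended only as a starting point; analyses should pass an
#' explicitly configured [makeArena()] geometry.
#'
#' @param frame an `H x W x 3` array, 0..255.
#' @param arenaDiameterMm physical arena diameter (mm).
#' @return an [ArenaMask-class].
#' @export
detectArena <- function(frame, arenaDiameterMm = 145) {
  lum <- (frame[, , 1] + frame[, , 2] + frame[, , 3]) / 3
  bw <- lum > (max(lum) + min(lum)) / 2
  lab <- .labelComponents(bw, 8)
  if (max(lab) == 0) stop("no bright region found")
  big <- which.max(tabulate(lab[lab > 0]))
  comp <- lab == big
  idx <- which(comp, arr.ind = TRUE)
  ctr <- colMeans(idx)
  inner <- .erodeDisc(comp, 1)
  edge <- which(comp & !inner, arr.ind = TRUE)
  rad <- mean(sqrt((edge[, 1] - ctr[1])^2 + (edge[, 2] - ctr[2])^2))
  makeArena(ctr, rad, arenaDiameterMm, dim(frame)[1:2])
}

#' Write trinarized label frames to disk
#'
#' One grayscale 8-bit PNG per frame with the fixed pixel codes
#' `UNEXPLORED = 0`, `SLIME = 1`, `MUCUS = 2`; outside-arena pixels are 0.
#' The encoding round-trips exactly through [readTrinarized()].
#'
#' @param stack a [TrinarizedStack-class].
#' @param outDir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return invisibly, the vector of written file paths (zero-padded frame
#'   index in the names).
#' @export
writeTrinarized <- function(stack, outDir, prefix = "frame") {
  stopifnot(is(stack, "TrinarizedStack"))
  ok <- dir.exists(outDir) ||
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  if (!ok || file.access(outDir, 2) != 0)
    stop("cannot write to ", outDir)
  n <- nFrames(stack)
  width <- max(4, nchar(as.character(n)))
  paths <- file.path(outDir, sprintf("%s_%0*d.png", prefix, width, seq_len(n)))
  for (i in seq_len(n)) {
    lab <- stack@labels[, , i]
    lab[!stack@arena@mask] <- 0L
    png::writePNG(lab / 255, paths[i])
  }
  invisible(paths)
}

#' Read trinarized label frames written by [writeTrinarized()]
#'
#' @param path directory of label PNGs, or a character vector of paths in
#'   temporal order.
#' @return integer array `H x W x T` of label codes.
#' @export
readTrinarized <- function(path) {
  if (length(path) == 1 && dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE),
                  method = "radix")
  } else files <- path
  if (!length(files)) stop("no label PNGs found in ", path)
  mats <- lapply(files, function(f) {
    m <- png::readPNG(f)
    if (length(dim(m)) == 3) m <- m[, , 1]
    m <- round(m * 255)
    storage.mode(m) <- "integer"
    m
  })
  array(unlist(mats), dim = c(dim(mats[[1]]), length(mats)))
}

#' Write a metrics table to CSV
#'
#' @param metrics data.frame as produced by [accumulateGrowth()] /
#'   [analyzeSequence()].
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
writeMetricsCSV <- function(metrics, path) {
  utils::write.csv(metrics, path, row.names = FALSE)
  invisible(path)
}
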
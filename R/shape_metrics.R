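# Per-frame morphometry of the slime mask: circularity, moment-equivalent
# ellipse eccentricity, solidity, erosion-based pseudopod (cluster) count.

# Sub-pixel perimeter: total length of the 0.5-level marching-squares
# iso-contours of the (lightly smoothed) mask. Raw marching squares on a
# hard 0/1 image systematically overestimates curved contours; a Gaussian
# pre-smoothing of sigma ~1 px removes that bias and anchors a rasterized
# disc at C = 1.
.maskPerimeterPx <- function(mask, smoothSigma = 1) {
  H <- nrow(mask); W <- ncol(mask)
  pad <- max(4, ceiling(3 * smoothSigma) + 1)
  z <- matrix(0, H + 2 * pad, W + 2 * pad)
  z[pad + seq_len(H), pad + seq_len(W)] <- mask * 1
  if (smoothSigma > 0)
    z <- as.matrix(EBImage::gblur(EBImage::as.Image(z), sigma = smoothSigma))
  cl <- grDevices::contourLines(x = seq_len(nrow(z)), y = seq_len(ncol(z)),
                                z = z, levels = 0.5)
  if (!length(cl)) return(0)
  sum(vapply(cl, function(ct)
    sum(sqrt(diff(ct$x)^2 + diff(ct$y)^2)), numeric(1)))
}

#' Circularity of a slime mask
#'
#' \eqn{C = P^2 / (4 \pi A)} with P the total contour length over all
#' connected components (sub-pixel iso-contours) and A the total foreground
#' area. C is 1 for a disc and grows as the contour becomes more convoluted
#' or the mask fragments (two equal discs give C = 2).
#'
#' @param mask logical slime mask.
#' @param mmPerPx physical scale (cancels in C; used for the returned P, A).
#' @param smoothSigma Gaussian pre-smoothing of the contour, px.
#' @param full if `TRUE` return a list with `C`, `P` (mm) and `A` (mm^2).
#' @return circularity (dimensionless), or a list when `full = TRUE`.
#' @export
circularity <- function(mask, mmPerPx = 1, smoothSigma = 1, full = FALSE) {
  if (!any(mask)) stop("empty mask")
  P <- .maskPerimeterPx(mask, smoothSigma) * mmPerPx
  A <- sum(mask) * mmPerPx^2
  C <- P^2 / (4 * pi * A)
  if (full) list(C = C, P = P, A = A) else C
}

#' Eccentricity of the moment-equivalent ellipse
#'
#' a and b are the semi-axes of the ellipse with the same normalized second
#' central moments as the full foreground pixel set (each pixel contributes
#' its unit-square extent, the usual +1/12 term);
#' \eqn{E = \sqrt{1 - (b/a)^2}}. 0 for a disc, approaching 1 for an
#' elongated shape; a single-pixel mask gives 0 by convention.
#'
#' @param mask logical slime mask.
#' @param mmPerPx physical scale.
#' @param full if `TRUE` return a list with `E`, `a`, `b` (mm).
#' @return eccentricity in \[0, 1), or a list when `full = TRUE`.
#' @export
eccentricity <- function(mask, mmPerPx = 1, full = FALSE) {
  if (!any(mask)) stop("empty mask")
  pts <- which(mask, arr.ind = TRUE)
  mu <- colMeans(pts)
  dr <- pts[, 1] - mu[1]; dc <- pts[, 2] - mu[2]
  # pixel-extent correction keeps the moments positive for thin masks
  cov <- matrix(c(mean(dr^2) + 1 / 12, mean(dr * dc),
                  mean(dr * dc), mean(dc^2) + 1 / 12), 2, 2)
  ev <- eigen(cov, symmetric = TRUE)$values
  a <- 2 * sqrt(ev[1]); b <- 2 * sqrt(ev[2])
  E <- sqrt(max(0, 1 - (b / a)^2))
  if (full) list(E = E, a = a * mmPerPx, b = b * mmPerPx) else E
}

#' Solidity of a slime mask
#'
#' Ratio of the foreground pixel count to the pixel count of the rasterized
#' convex hull of the foreground (hull of the union across components,
#' filled back onto the pixel grid). Rasterizing the hull the same way the
#' mask itself is rasterized cancels the sub-pixel hull bias, so convex
#' masks score 1 up to (tiny) chord effects.
#'
#' @param mask logical slime mask.
#' @return solidity in (0, 1\].
#' @export
solidity <- function(mask) {
  if (!any(mask)) stop("empty mask")
  A <- sum(mask)
  # boundary pixels suffice to span the hull
  inner <- .erodeDisc(mask, 1)
  edge <- which(mask & !inner, arr.ind = TRUE)
  if (!nrow(edge)) edge <- which(mask, arr.ind = TRUE)
  h <- grDevices::chull(edge)
  hp <- edge[h, , drop = FALSE]
  if (nrow(hp) < 3) return(1)  # point or line mask is its own hull
  # ensure counter-clockwise orientation (positive signed area)
  sa <- sum(hp[, 1] * c(hp[-1, 2], hp[1, 2]) -
            c(hp[-1, 1], hp[1, 1]) * hp[, 2]) / 2
  if (sa < 0) hp <- hp[rev(seq_len(nrow(hp))), , drop = FALSE]
  # rasterize: count pixel centers inside the convex polygon
  rs <- seq(ceiling(min(hp[, 1])), floor(max(hp[, 1])))
  cs <- seq(ceiling(min(hp[, 2])), floor(max(hp[, 2])))
  px <- matrix(rs, length(rs), length(cs))
  py <- matrix(cs, length(rs), length(cs), byrow = TRUE)
  insd <- matrix(TRUE, length(rs), length(cs))
  K <- nrow(hp)
  for (k in seq_len(K)) {
    p1 <- hp[k, ]; p2 <- hp[if (k == K) 1 else k + 1, ]
    cr <- (p2[1] - p1[1]) * (py - p1[2]) - (p2[2] - p1[2]) * (px - p1[1])
    insd <- insd & cr >= -1e-9
  }
  min(1, A / sum(insd))
}

#' Pseudopod (cluster) count by erosion
#'
#' Erodes the mask with a disc of the given radius (exact Euclidean
#' erosion); only the cores of high slime concentration survive, and the
#' number of remaining 8-connected components is the pseudopod / cluster
#' count. Radius 0 returns the plain component count; an erosion that
#' empties the mask returns 0.
#'
#' @param mask logical slime mask.
#' @param erosionRadiusPx erosion radius in pixels (convert from mm with
#'   the arena's scale).
#' @return non-negative integer count.
#' @export
clusterCount <- function(mask, erosionRadiusPx = 0) {
  stopifnot(erosionRadiusPx >= 0)
  if (!any(mask)) return(0L)
  er <- .erodeDisc(mask, erosionRadiusPx)
  as.integer(.countComponents(er, 8))
}

#' All four shape indices of one slime mask
#'
#' @param mask logical slime mask.
#' @param arena an [ArenaMask-class] (supplies the scale and the default
#'   erosion radius).
#' @param erosionRadiusFrac erosion radius for the cluster count, as a
#'   fraction of the arena radius (default 0.02).
#' @param smoothSigma contour smoothing for the perimeter, px.
#' @return one-row data.frame with `circularity`, `eccentricity`,
#'   `solidity`, `n_clusters`, plus `perimeter_mm`, `area_mm2`,
#'   `major_mm`, `minor_mm`.
#' @export
shapeMetrics <- function(mask, arena, erosionRadiusFrac = 0.02,
                         smoothSigma = 1) {
  stopifnot(is(arena, "ArenaMask"))
  if (!any(mask)) stop("empty mask")
  circ <- circularity(mask, arena@mmPerPx, smoothSigma, full = TRUE)
  ecc <- eccentricity(mask, arena@mmPerPx, full = TRUE)
  data.frame(
    circularity = circ$C, eccentricity = ecc$E, solidity = solidity(mask),
    n_clusters = clusterCount(mask, erosionRadiusFrac * arena@radiusPx),
    perimeter_mm = circ$P, area_mm2 = circ$A,
    major_mm = ecc$a, minor_mm = ecc$b)
}
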
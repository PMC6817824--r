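# Internal raster helpers shared across modules.

# Euclidean distance (px) from every pixel to the nearest TRUE pixel of
# `mask`; 0 on the mask itself, Inf if the mask is empty.
.distToSet <- function(mask) {
  if (!any(mask)) return(matrix(Inf, nrow(mask), ncol(mask)))
  # distmap() measures each nonzero pixel's distance to the nearest zero,
  # so invert: background of the inverted image is the target set.
  d <- EBImage::distmap(1 - mask, metric = "euclidean")
  matrix(as.numeric(d), nrow(mask), ncol(mask))
}

# Exact Euclidean erosion: keep pixels whose distance to the complement
# exceeds the radius. Matches brute-force disc erosion.
.erodeDisc <- function(mask, radiusPx) {
  if (radiusPx <= 0) return(mask)
  if (!any(mask)) return(mask)
  inner <- EBImage::distmap(mask * 1, metric = "euclidean")
  matrix(as.numeric(inner) > radiusPx, nrow(mask), ncol(mask))
}

# Connected-component labeling with 4- or 8-connectivity via igraph.
# Returns an integer matrix, 0 = background, components numbered from 1.
.labelComponents <- function(mask, connectivity = 8) {
  stopifnot(connectivity %in% c(4, 8))
  out <- matrix(0L, nrow(mask), ncol(mask))
  idx <- which(mask)
  if (!length(idx)) return(out)
  H <- nrow(mask); W <- ncol(mask)
  pos <- integer(H * W); pos[idx] <- seq_along(idx)
  r <- ((idx - 1L) %% H) + 1L
  c <- ((idx - 1L) %/% H) + 1L
  shifts <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8) shifts <- c(shifts, list(c(1L, 1L), c(1L, -1L)))
  from <- integer(0); to <- integer(0)
  for (s in shifts) {
    r2 <- r + s[1]; c2 <- c + s[2]
    ok <- r2 >= 1L & r2 <= H & c2 >= 1L & c2 <= W
    nb <- (c2[ok] - 1L) * H + r2[ok]
    hit <- pos[nb] > 0L
    from <- c(from, pos[idx[ok]][hit])
    to <- c(to, pos[nb][hit])
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(from))
    g <- igraph::add_edges(g, rbind(from, to))
  memb <- igraph::components(g)$membership
  out[idx] <- as.integer(memb)
  out
}

# Count of connected components (default 8-connectivity).
.countComponents <- function(mask, connectivity = 8) {
  lab <- .labelComponents(mask, connectivity)
  max(lab)
}

# Run `expr` with a fixed RNG seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# Boolean disc on an H x W grid, pixel-center rule.
.discMask <- function(shape, center, radiusPx) {
  H <- shape[1]; W <- shape[2]
  rr <- matrix(seq_len(H), H, W)
  cc <- matrix(seq_len(W), H, W, byrow = TRUE)
  (rr - center[1])^2 + (cc - center[2])^2 <= radiusPx^2
}
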
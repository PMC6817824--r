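#' Accessors for the core classes
#'
#' Small accessor generics so user code never touches slots directly:
#' `nFrames()` and `frameTimes()` for sequences and stacks, `intervalMin()`
#' for the sampling interval, `arenaMask()` for the arena a stack is
#' restricted to, `getFrame()` for a single RGB frame, and `frameLabels()`
#' for a single label matrix.
#'
#' @param x a [FrameSequence-class] or [TrinarizedStack-class].
#' @param i frame index (1-based).
#' @return `nFrames`: integer count. `frameTimes`: numeric vector of minutes.
#'   `intervalMin`: minutes between frames. `arenaMask`: an
#'   [ArenaMask-class]. `getFrame`: an `H x W x 3` array. `frameLabels`: an
#'   integer label matrix.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
#' @rdname accessors
#' @export
setGeneric("frameTimes", function(x) standardGeneric("frameTimes"))
#' @rdname accessors
#' @export
setGeneric("intervalMin", function(x) standardGeneric("intervalMin"))
#' @rdname accessors
#' @export
setGeneric("arenaMask", function(x) standardGeneric("arenaMask"))
#' @rdname accessors
#' @export
setGeneric("getFrame", function(x, i) standardGeneric("getFrame"))
#' @rdname accessors
#' @export
setGeneric("frameLabels", function(x, i) standardGeneric("frameLabels"))

#' @rdname accessors
setMethod("nFrames", "FrameSequence", function(x) length(x@frames))
#' @rdname accessors
setMethod("nFrames", "TrinarizedStack", function(x) dim(x@labels)[3])
#' @rdname accessors
setMethod("frameTimes", "FrameSequence",
          function(x) (seq_along(x@frames) - 1) * x@intervalMin)
#' @rdname accessors
setMethod("frameTimes", "TrinarizedStack",
          function(x) (seq_len(dim(x@labels)[3]) - 1) * x@intervalMin)
#' @rdname accessors
setMethod("intervalMin", "FrameSequence", function(x) x@intervalMin)
#' @rdname accessors
setMethod("intervalMin", "TrinarizedStack", function(x) x@intervalMin)
#' @rdname accessors
setMethod("arenaMask", "TrinarizedStack", function(x) x@arena)
#' @rdname accessors
setMethod("getFrame", "FrameSequence", function(x, i) x@frames[[i]])
#' @rdname accessors
setMethod("frameLabels", "TrinarizedStack", function(x, i) x@labels[, , i])

#' Slime mask of one frame of a trinarized stack
#'
#' @param x a [TrinarizedStack-class].
#' @param i frame index.
#' @return logical matrix, `TRUE` where the pixel is labeled slime.
#' @export
slimeMask <- function(x, i) {
  stopifnot(is(x, "TrinarizedStack"))
  x@labels[, , i] == LABELS[["SLIME"]]
}
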
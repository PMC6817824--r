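#' Run the full analysis pipeline on a frame sequence
#'
#' Orchestrates segmentation -> trinarization -> growth dynamics -> shape
#' metrics -> (optional) spot analysis and assembles everything into one
#' per-frame metrics table. Any stage failure aborts with the stage name
#' and frame index.
#'
#' @param fs a [FrameSequence-class].
#' @param arena an [ArenaMask-class].
#' @param initRegion logical matrix marking the known initial slime disc
#'   (reference color source and frame-1 sanity anchor).
#' @param refColor optional explicit (a*, b*) reference overriding
#'   `initRegion`.
#' @param spots optional [SpotLayout-class]; adds `distance_to_glucose_mm`.
#' @param seed k-means seed.
#' @param minBlobFrac segmentation cleanup threshold, fraction of arena area.
#' @param erosionRadiusFrac cluster-count erosion radius, fraction of arena
#'   radius.
#' @param windowMin pooling window for the smoothed secondary-growth
#'   fractions (min).
#' @return list with `stack` (the [TrinarizedStack-class]) and `metrics`
#'   (data.frame, one row per frame: coverage, growth, migration, shape and
#'   optionally spot distance columns).
#' @export
analyzeSequence <- function(fs, arena, initRegion = NULL, refColor = NULL,
                            spots = NULL, seed = 1L, minBlobFrac = 1e-4,
                            erosionRadiusFrac = 0.02, windowMin = 60) {
  stack <- segmentSequence(fs, arena, initRegion = initRegion,
                           refColor = refColor, seed = seed,
                           minBlobFrac = minBlobFrac)
  analyzeStack(stack, spots = spots, erosionRadiusFrac = erosionRadiusFrac,
               windowMin = windowMin)
}

#' Compute all metrics from an existing trinarized stack
#'
#' Same as [analyzeSequence()] but starting from labels (e.g. generator
#' ground truth), skipping segmentation.
#'
#' @inheritParams analyzeSequence
#' @param stack a [TrinarizedStack-class].
#' @return list with `stack` and `metrics` (see [analyzeSequence()]).
#' @export
analyzeStack <- function(stack, spots = NULL, erosionRadiusFrac = 0.02,
                         windowMin = 60) {
  stopifnot(is(stack, "TrinarizedStack"))
  arena <- arenaMask(stack)
  metrics <- tryCatch(accumulateGrowth(stack, windowMin = windowMin),
    error = function(e) stop("growth-dynamics stage failed: ",
                             conditionMessage(e), call. = FALSE))
  n <- nFrames(stack)
  shp <- vector("list", n)
  for (i in seq_len(n)) {
    msk <- slimeMask(stack, i)
    shp[[i]] <- tryCatch({
      if (any(msk)) shapeMetrics(msk, arena, erosionRadiusFrac)
      else data.frame(circularity = NA_real_, eccentricity = NA_real_,
                      solidity = NA_real_, n_clusters = 0L,
                      perimeter_mm = NA_real_, area_mm2 = 0,
                      major_mm = NA_real_, minor_mm = NA_real_)
    }, error = function(e)
      stop(sprintf("shape stage failed at frame %d: %s", i,
                   conditionMessage(e)), call. = FALSE))
  }
  metrics <- cbind(metrics, do.call(rbind, shp))
  if (!is.null(spots)) {
    dist <- vapply(seq_len(n), function(i) {
      msk <- slimeMask(stack, i)
      tryCatch(distanceToSpot(msk, spots, arena@mmPerPx),
        error = function(e)
          stop(sprintf("spot stage failed at frame %d: %s", i,
                       conditionMessage(e)), call. = FALSE))
    }, numeric(1))
    metrics$distance_to_glucose_mm <- dist
  }
  list(stack = stack, metrics = metrics)
}

#' Read and validate a YAML run configuration
#'
#' Required keys: `input` (frame directory), `interval_min`, and an `arena`
#' block with `center_row`, `center_col`, `radius_px` (plus optional
#' `diameter_mm`, default 145). Optional blocks: `init` (initial disc
#' `center_row`/`center_col`/`radius_px`; defaults to the arena center with
#' a 2.5 cm disc), `segmentation` (`seed`, `min_blob_frac`), `shape`
#' (`erosion_radius_frac`), `spots` (list of `row`/`col`/`radius_px`/
#' `kind`), and `output` (directory).
#'
#' @param path YAML file path.
#' @return validated config as a nested list.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  for (key in c("input", "interval_min"))
    if (is.null(cfg[[key]])) stop("config missing required key: ", key)
  if (is.null(cfg$arena)) stop("config missing required key: arena")
  for (key in c("center_row", "center_col", "radius_px"))
    if (is.null(cfg$arena[[key]]))
      stop("config missing required key: arena$", key)
  if (is.null(cfg$arena$diameter_mm)) cfg$arena$diameter_mm <- 145
  if (is.null(cfg$segmentation)) cfg$segmentation <- list()
  if (is.null(cfg$segmentation$seed)) cfg$segmentation$seed <- 1L
  if (is.null(cfg$segmentation$min_blob_frac))
    cfg$segmentation$min_blob_frac <- 1e-4
  if (is.null(cfg$shape)) cfg$shape <- list()
  if (is.null(cfg$shape$erosion_radius_frac))
    cfg$shape$erosion_radius_frac <- 0.02
  if (is.null(cfg$output)) cfg$output <- "slimetrace_out"
  cfg
}

#' Run a configured analysis end to end, writing all outputs
#'
#' Loads the frames named by a config (see [readRunConfig()]), runs
#' [analyzeSequence()], and writes the trinarized masks, the metrics CSV
#' and a run log (package version, effective parameters, seed) to the
#' output directory. Reruns with the same config and inputs are
#' byte-identical.
#'
#' @param configPath path to the YAML config.
#' @return invisibly, the output directory.
#' @export
runAnalysis <- function(configPath) {
  cfg <- readRunConfig(configPath)
  fs <- loadSequence(cfg$input, cfg$interval_min)
  shape <- dim(getFrame(fs, 1))[1:2]
  arena <- makeArena(c(cfg$arena$center_row, cfg$arena$center_col),
                     cfg$arena$radius_px, cfg$arena$diameter_mm, shape)
  if (is.null(cfg$init)) {
    initR <- (25 / 2) / arena@mmPerPx
    init <- .discMask(shape, arena@center, initR)
  } else {
    init <- .discMask(shape, c(cfg$init$center_row, cfg$init$center_col),
                      cfg$init$radius_px)
  }
  spots <- NULL
  if (!is.null(cfg$spots)) {
    sp <- do.call(rbind, lapply(cfg$spots, function(s)
      data.frame(row = s$row, col = s$col, radiusPx = s$radius_px,
                 kind = s$kind)))
    spots <- spotLayout(sp, arena)
  }
  res <- analyzeSequence(fs, arena, initRegion = init, spots = spots,
                         seed = cfg$segmentation$seed,
                         minBlobFrac = cfg$segmentation$min_blob_frac,
                         erosionRadiusFrac = cfg$shape$erosion_radius_frac)
  out <- cfg$output
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  writeTrinarized(res$stack, file.path(out, "masks"))
  writeMetricsCSV(res$metrics, file.path(out, "metrics.csv"))
  logLines <- c(
    paste0("slimeTrace ", as.character(utils::packageVersion("slimeTrace"))),
    paste0("config: ", normalizePath(configPath)),
    paste0("seed: ", cfg$segmentation$seed),
    paste0("min_blob_frac: ", cfg$segmentation$min_blob_frac),
    paste0("erosion_radius_frac: ", cfg$shape$erosion_radius_frac),
    paste0("frames: ", nFrames(fs)))
  writeLines(logLines, file.path(out, "run_log.txt"))
  invisible(out)
}

#' Summarize replicate metrics tables: mean and quartile bands
#'
#' Given per-replicate metrics CSVs on a common time grid, computes for
#' each metric the across-replicate mean and first/third quartiles
#' (linear-interpolation convention, `stats::quantile` type 7) at every
#' time point — the summary bands plotted for each treatment. If the
#' tables carry `distance_to_glucose_mm`, the replicate time-to-contact
#' survival curve is assembled as well.
#'
#' @param paths character vector of metrics CSV paths (>= 1), or a list of
#'   data.frames.
#' @param thresholdMm contact threshold passed to [timeToContact()].
#' @return list with `summary` (long data.frame: `time_min`, `metric`,
#'   `mean`, `q1`, `q3`) and `survival` (a [survivalCurve()] data.frame or
#'   `NULL`).
#' @export
reportReplicates <- function(paths, thresholdMm = 0) {
  tabs <- if (is.list(paths) && is.data.frame(paths[[1]])) paths
          else lapply(paths, utils::read.csv)
  if (length(tabs) < 1) stop("need at least one replicate")
  grid <- tabs[[1]]$time_min
  for (i in seq_along(tabs))
    if (!isTRUE(all.equal(tabs[[i]]$time_min, grid)))
      stop("inconsistent time grids across replicates")
  metricCols <- setdiff(names(tabs[[1]]),
                        c("frame", "time_min"))
  metricCols <- metricCols[vapply(metricCols, function(cn)
    is.numeric(tabs[[1]][[cn]]), logical(1))]
  rows <- lapply(metricCols, function(cn) {
    M <- vapply(tabs, function(tb) as.numeric(tb[[cn]]),
                numeric(length(grid)))
    M <- matrix(M, nrow = length(grid))
    data.frame(time_min = grid, metric = cn,
               mean = rowMeans(M, na.rm = TRUE),
               q1 = apply(M, 1, stats::quantile, 0.25, na.rm = TRUE,
                          names = FALSE, type = 7),
               q3 = apply(M, 1, stats::quantile, 0.75, na.rm = TRUE,
                          names = FALSE, type = 7))
  })
  surv <- NULL
  if ("distance_to_glucose_mm" %in% names(tabs[[1]])) {
    tc <- lapply(tabs, function(tb)
      timeToContact(tb$distance_to_glucose_mm, tb$time_min, thresholdMm))
    surv <- survivalCurve(vapply(tc, `[[`, numeric(1), "time"),
                          vapply(tc, `[[`, logical(1), "censored"),
                          horizonMin = max(grid))
  }
  list(summary = do.call(rbind, rows), survival = surv)
}
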
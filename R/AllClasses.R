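#' @import methods
NULL

#' RasterGrid: a single north-up raster band
#'
#' The universal currency of the pipeline: one 2-D band of values on a
#' regular grid, with an affine georeference (origin and cell size), a
#' nodata mask (encoded as `NA` in `values`), free-text units and a CRS tag.
#' Row 1 of the value matrix is the northernmost row.
#'
#' All arithmetic between grids requires identical shape and geotransform;
#' nothing is ever resampled silently (see [resampleMean()] for the explicit
#' aggregation utility).  Nodata propagates as a union: any operation whose
#' input is nodata at a pixel yields nodata there.
#'
#' @slot values numeric matrix; `NA` marks nodata.
#' @slot xmin,ymax numeric scalars, coordinates of the outer corner of the
#'   top-left cell (north-up convention).
#' @slot cellsize numeric length-2 `(dx, dy)`, both strictly positive.
#' @slot units free-text unit string.
#' @slot crs free-text CRS identifier (synthetic scenarios use a planar
#'   metric CRS, tagged `"local-metric"`).
#' @seealso [rasterGrid()], [gridValues()], [normalizeMinMax()]
#' @export
setClass("RasterGrid",
  representation(
    values   = "matrix",
    xmin     = "numeric",
    ymax     = "numeric",
    cellsize = "numeric",
    units    = "character",
    crs      = "character"
  ),
  prototype(
    xmin = 0, ymax = 0, cellsize = c(1, 1), units = "", crs = "local-metric"
  )
)

setValidity("RasterGrid", function(object) {
  msg <- character()
  if (!is.numeric(object@values) && !is.logical(object@values))
    msg <- c(msg, "values must be a numeric matrix")
  if (length(object@cellsize) != 2L)
    msg <- c(msg, "cellsize must have length 2 (dx, dy)")
  else if (any(!is.finite(object@cellsize)) || any(object@cellsize <= 0))
    msg <- c(msg, "cell sizes must be strictly positive")
  if (length(object@xmin) != 1L || length(object@ymax) != 1L)
    msg <- c(msg, "xmin and ymax must be scalars")
  if (length(msg)) msg else TRUE
})

#' GridStack: a set of aligned bands
#'
#' A named list of [RasterGrid-class] objects sharing one geotransform,
#' typically the 12 monthly bands of a climate variable (names `"1"` to
#' `"12"`).
#'
#' @slot grids list of aligned `RasterGrid` objects.
#' @slot temporal logical; `TRUE` when the bands are calendar months, in
#'   which case there must be exactly 12, named 1..12.
#' @export
setClass("GridStack",
  representation(grids = "list", temporal = "logical"),
  prototype(temporal = FALSE)
)

setValidity("GridStack", function(object) {
  gs <- object@grids
  if (!length(gs)) return("a GridStack needs at least one band")
  if (!all(vapply(gs, is, logical(1), "RasterGrid")))
    return("all members must be RasterGrid objects")
  for (g in gs[-1]) if (!isAligned(gs[[1]], g))
    return("all member grids must share shape and geotransform")
  if (isTRUE(object@temporal)) {
    if (length(gs) != 12L || !identical(names(gs), as.character(1:12)))
      return("temporal stacks must have 12 bands named 1..12")
  }
  TRUE
})

#' SoilProfileStack: depth-interval layers of one soil property
#'
#' Ordered layers of a property reported on fixed depth intervals (the soil
#' grids used here report seven intervals spanning 0--200 cm).  Intervals
#' must be contiguous, non-overlapping and start at 0 cm.
#'
#' @slot layers list of aligned `RasterGrid` objects, one per interval.
#' @slot intervals numeric matrix with columns `top_cm`, `bottom_cm`.
#' @seealso [depthWeightedAverage()]
#' @export
setClass("SoilProfileStack",
  representation(layers = "list", intervals = "matrix")
)

setValidity("SoilProfileStack", function(object) {
  iv <- object@intervals
  if (ncol(iv) != 2L) return("intervals must have two columns (top, bottom)")
  if (nrow(iv) != length(object@layers))
    return("layer count must equal interval count")
  if (nrow(iv) == 0L) return("at least one layer is required")
  if (iv[1, 1] != 0) return("intervals must start at 0 cm")
  if (any(iv[, 2] <= iv[, 1])) return("interval bottoms must exceed tops")
  if (nrow(iv) > 1L && any(abs(iv[-1, 1] - iv[-nrow(iv), 2]) > 1e-9))
    return("intervals must be contiguous and non-overlapping")
  if (!all(vapply(object@layers, is, logical(1), "RasterGrid")))
    return("layers must be RasterGrid objects")
  for (g in object@layers[-1]) if (!isAligned(object@layers[[1]], g))
    return("layers must be aligned")
  TRUE
})

#' FlowField: D8 drainage structure derived from a DEM
#'
#' Per-pixel D8 flow directions, flow accumulation (drained cell count,
#' counting the cell itself), and the stream mask (accumulation at or above
#' a threshold).  Direction codes are 0 for a pit/outlet and 1--8 for the
#' neighbours in the fixed order E, SE, S, SW, W, NW, N, NE (ties broken by
#' this order for determinism).
#'
#' @slot directions integer matrix of D8 codes (`NA` = nodata).
#' @slot accumulation numeric matrix of drained cell counts (>= 1).
#' @slot streamMask logical matrix.
#' @slot streamThreshold numeric, the accumulation threshold used.
#' @slot spill numeric matrix: the epsilon-drained spill surface used to
#'   order cells; strictly decreasing along every flow path (guarantees
#'   acyclicity).
#' @slot xmin,ymax,cellsize georeference, as in [RasterGrid-class].
#' @seealso [d8Flow()], [delineateWatersheds()]
#' @export
setClass("FlowField",
  representation(
    directions = "matrix", accumulation = "matrix", streamMask = "matrix",
    streamThreshold = "numeric", spill = "matrix",
    xmin = "numeric", ymax = "numeric", cellsize = "numeric"
  )
)

setValidity("FlowField", function(object) {
  d <- dim(object@directions)
  if (!identical(d, dim(object@accumulation)) ||
      !identical(d, dim(object@streamMask)))
    return("directions, accumulation and streamMask must share one shape")
  v <- object@directions[!is.na(object@directions)]
  if (length(v) && (any(v < 0) || any(v > 8)))
    return("direction codes must be 0 (pit/outlet) or 1..8")
  a <- object@accumulation[!is.na(object@accumulation)]
  if (length(a) && any(a < 1)) return("accumulation must be >= 1 where valid")
  TRUE
})

#' WatershedPartition: labelled subcatchments
#'
#' Every valid cell is labelled by the stream segment (reach between
#' confluences) its flow path first reaches.  Cells whose path leaves the
#' grid without touching a stream are collected under label 0
#' ("unchanneled"), so the labels still partition the valid extent.
#'
#' @slot labels integer matrix; `NA` = nodata, 0 = unchanneled.
#' @slot records data.frame with one row per watershed: `id`, `cells`,
#'   `area_m2`, `stream_cells`, `stream_length_m`, `mean_slope`,
#'   `mean_slope_area_term`, `velocity_scale` (the last three `NA` unless a
#'   slope grid was supplied to [delineateWatersheds()]).
#' @slot unchanneled integer, number of label-0 cells.
#' @slot xmin,ymax,cellsize georeference.
#' @export
setClass("WatershedPartition",
  representation(
    labels = "matrix", records = "data.frame", unchanneled = "integer",
    xmin = "numeric", ymax = "numeric", cellsize = "numeric"
  )
)

setValidity("WatershedPartition", function(object) {
  lab <- object@labels[!is.na(object@labels)]
  ids <- sort(unique(lab[lab > 0]))
  if (!all(ids %in% object@records$id))
    return("every positive label must have a watershed record")
  TRUE
})

#' ProcessMap: a normalized vulnerability map
#'
#' A [RasterGrid-class] whose valid values lie in [0, 1], tagged with the
#' fate process it describes and the provenance of its inputs.  These are
#' the end products of the pipeline: relative spatial variation in a
#' process, not an absolute measurement of it.
#'
#' @slot process short process name (e.g. `"leaching"`).
#' @slot provenance character vector naming the input layers used.
#' @export
setClass("ProcessMap",
  contains = "RasterGrid",
  representation(process = "character", provenance = "character"),
  prototype(process = "", provenance = character())
)

setValidity("ProcessMap", function(object) {
  v <- object@values[!is.na(object@values)]
  if (length(v) && (min(v) < -1e-9 || max(v) > 1 + 1e-9))
    return("ProcessMap values must lie in [0, 1]")
  TRUE
})

#' ResidueDatabase: insecticide-residue observations
#'
#' A validated table of residue observations (study, sampling time,
#' substrate, methods, limits, compound, concentration, coordinates).  Rows
#' violating hard invariants are kept in `rejected` with a reason, never
#' silently dropped.  Georeferencing is judged against a latitude/longitude
#' bounding box (default: continental Africa, lat -35..38, lon -26..64).
#'
#' @slot data data.frame of accepted observations.
#' @slot rejected data.frame of rejected rows with a `reason` column.
#' @slot bbox numeric length-4: `lat_min`, `lat_max`, `lon_min`, `lon_max`.
#' @seealso [readResidueCsv()], [residueFunnel()]
#' @export
setClass("ResidueDatabase",
  representation(data = "data.frame", rejected = "data.frame",
                 bbox = "numeric")
)

setValidity("ResidueDatabase", function(object) {
  if (length(object@bbox) != 4L)
    return("bbox must be (lat_min, lat_max, lon_min, lon_max)")
  need <- residueColumns()
  if (nrow(object@data) && !all(need %in% names(object@data)))
    return("data is missing mandatory residue columns")
  TRUE
})

#' ScenarioSpec: parameters of a synthetic study scenario
#'
#' Defines the statistical structure of a synthetic input set: grid shape
#' and cell size, spatial correlation length, terrain relief, soil property
#' ranges, seasonal amplitude and phase per climate variable, land-use
#' class proportions and the nodata fraction.  One global seed fans out to
#' per-variable subseeds by stable hashing, so every output is reproducible
#' bit-for-bit and adding a generator never perturbs existing ones.
#'
#' @slot nrow,ncol grid shape (at least 16 x 16).
#' @slot cellsize cell size in metres (square cells, planar CRS).
#' @slot seed integer master seed.
#' @slot corLen spatial correlation length, in cells.
#' @slot relief terrain relief amplitude, metres.
#' @slot soilRanges named list of `c(min, max)` ranges per soil variable.
#' @slot seasonalAmplitude,seasonalPhase named numeric vectors per monthly
#'   climate variable (amplitude in the variable's units; phase in months).
#' @slot landuseProportions named numeric vector over the five land-use
#'   classes, summing to 1.
#' @slot nodataFraction fraction of the grid masked as nodata.
#' @seealso [scenarioSpec()], [synthScenario()]
#' @export
setClass("ScenarioSpec",
  representation(
    nrow = "integer", ncol = "integer", cellsize = "numeric",
    seed = "integer", corLen = "numeric", relief = "numeric",
    soilRanges = "list", seasonalAmplitude = "numeric",
    seasonalPhase = "numeric", landuseProportions = "numeric",
    nodataFraction = "numeric"
  )
)

setValidity("ScenarioSpec", function(object) {
  if (object@nrow < 16L || object@ncol < 16L)
    return("scenario grids must be at least 16 x 16")
  p <- object@landuseProportions
  if (abs(sum(p) - 1) > 1e-9) return("land-use proportions must sum to 1")
  if (any(p < 0)) return("land-use proportions must be non-negative")
  if (object@nodataFraction < 0 || object@nodataFraction >= 1)
    return("nodataFraction must be in [0, 1)")
  if (object@corLen >= min(object@nrow, object@ncol))
    return("correlation length must be smaller than the grid extent")
  TRUE
})
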
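#' Construct a RasterGrid
#'
#' @param values numeric matrix (row 1 = northernmost row); `NA` is nodata.
#' @param xmin,ymax coordinates of the top-left outer corner.  `ymax`
#'   defaults so the lower-left corner sits at y = 0.
#' @param cellsize cell size: a scalar for square cells or `c(dx, dy)`.
#' @param units free-text unit string.
#' @param crs free-text CRS tag.
#' @return a [RasterGrid-class].
#' @examples
#' g <- rasterGrid(matrix(1:12, 3, 4), cellsize = 100)
#' gridValues(g)
#' @export
rasterGrid <- function(values, xmin = 0, ymax = NULL, cellsize = 1,
                       units = "", crs = "local-metric") {
  if (is.vector(values)) values <- matrix(values, nrow = 1)
  storage.mode(values) <- "double"
  if (length(cellsize) == 1L) cellsize <- c(cellsize, cellsize)
  if (is.null(ymax)) ymax <- nrow(values) * cellsize[2]
  new("RasterGrid", values = values, xmin = xmin, ymax = ymax,
      cellsize = as.numeric(cellsize), units = units, crs = crs)
}

#' @describeIn rasterGrid value matrix accessor.
#' @param x a `RasterGrid`.
#' @export
setMethod("gridValues", "RasterGrid", function(x) x@values)

#' @describeIn rasterGrid replace the value matrix (shape must be kept).
#' @param value replacement matrix.
#' @export
setMethod("gridValues<-", "RasterGrid", function(x, value) {
  if (is.vector(value)) value <- matrix(value, nrow(x@values), ncol(x@values))
  stopifnot(identical(dim(value), dim(x@values)))
  storage.mode(value) <- "double"
  x@values <- value
  validObject(x)
  x
})

#' @describeIn rasterGrid logical nodata mask (TRUE = nodata).
#' @export
setMethod("nodataMask", "RasterGrid", function(x) is.na(x@values))

#' @describeIn rasterGrid cell size `(dx, dy)`.
#' @export
setMethod("cellSize", "RasterGrid", function(x) x@cellsize)

#' @describeIn rasterGrid unit string.
#' @export
setMethod("gridUnits", "RasterGrid", function(x) x@units)

setMethod("show", "RasterGrid", function(object) {
  v <- object@values
  ok <- !is.na(v)
  cat(sprintf("%s: %d x %d cells (%g x %g), %d valid",
              class(object), nrow(v), ncol(v),
              object@cellsize[1], object@cellsize[2], sum(ok)))
  if (nzchar(object@units)) cat(" [", object@units, "]", sep = "")
  cat("\n")
  if (any(ok))
    cat(sprintf("  range: %.6g .. %.6g\n", min(v[ok]), max(v[ok])))
})

setMethod("show", "ProcessMap", function(object) {
  cat(sprintf("ProcessMap <%s>\n", object@process))
  callNextMethod()
  if (length(object@provenance))
    cat("  inputs:", paste(object@provenance, collapse = ", "), "\n")
})

#' @describeIn processMap the process tag of a vulnerability map.
#' @export
setMethod("processName", "ProcessMap", function(x) x@process)

#' @describeIn processMap provenance (names of the input layers used).
#' @export
setMethod("provenance", "ProcessMap", function(x) x@provenance)

#' Tag a normalized grid as a process-vulnerability map
#'
#' @param g a [RasterGrid-class] with valid values in [0, 1].
#' @param process short process name.
#' @param provenance character vector naming the inputs it was built from.
#' @return a [ProcessMap-class].
#' @export
processMap <- function(g, process, provenance = character()) {
  new("ProcessMap", g, process = process, provenance = provenance)
}

#' Strip a ProcessMap back to its plain grid
#' @param x a `ProcessMap` or `RasterGrid`.
#' @return a [RasterGrid-class].
#' @export
asGrid <- function(x) {
  stopifnot(is(x, "RasterGrid"))
  new("RasterGrid", values = x@values, xmin = x@xmin, ymax = x@ymax,
      cellsize = x@cellsize, units = x@units, crs = x@crs)
}

#' Test or assert grid alignment
#'
#' Two grids are aligned when they share shape, cell size and origin (to
#' 1e-9 of a cell).  Arithmetic between unaligned grids is an error, never
#' a silent resample.
#' @param a,b `RasterGrid` objects.
#' @return `isAligned` returns a logical; `assertAligned` errors.
#' @export
isAligned <- function(a, b) {
  identical(dim(a@values), dim(b@values)) &&
    all(abs(a@cellsize - b@cellsize) < 1e-9 * a@cellsize) &&
    abs(a@xmin - b@xmin) < 1e-9 * a@cellsize[1] &&
    abs(a@ymax - b@ymax) < 1e-9 * a@cellsize[2]
}

#' @rdname isAligned
#' @param ... grids to check against the first.
#' @export
assertAligned <- function(...) {
  gs <- list(...)
  if (length(gs) == 1L && is.list(gs[[1]])) gs <- gs[[1]]
  for (g in gs[-1]) {
    if (!isAligned(gs[[1]], g))
      stop("grids are not aligned (shape/cellsize/origin differ); ",
           "inputs must be pre-aligned, resampling is never implicit",
           call. = FALSE)
  }
  invisible(TRUE)
}

## Elementwise arithmetic between aligned grids (NA = nodata propagates
## as a union automatically).
setMethod("Ops", signature("RasterGrid", "RasterGrid"), function(e1, e2) {
  assertAligned(e1, e2)
  out <- asGrid(e1)
  out@values <- callGeneric(e1@values, e2@values)
  out@units <- ""
  out
})

setMethod("Ops", signature("RasterGrid", "numeric"), function(e1, e2) {
  out <- asGrid(e1)
  out@values <- callGeneric(e1@values, e2)
  out
})

setMethod("Ops", signature("numeric", "RasterGrid"), function(e1, e2) {
  out <- asGrid(e2)
  out@values <- callGeneric(e1, e2@values)
  out
})

#' Min--max normalization over the valid extent
#'
#' Rescales valid pixels by `(x - min)/(max - min)`, computed over the full
#' valid extent of the map (the continental maps this emulates are
#' normalized continent-wide).  Nodata is preserved.  A constant map is
#' mapped to 0 everywhere (documented degenerate rule).
#'
#' `bounds` fixes the normalization constants instead of recomputing them
#' from the grid — used by the sensitivity analysis, where a perturbed
#' input is rescaled with the baseline bounds (recomputing the bounds
#' would absorb a pure scaling entirely, min--max being affine-invariant)
#' and `clip = TRUE` truncates the result back into [0, 1].
#'
#' @param x a [RasterGrid-class].
#' @param bounds optional fixed `c(min, max)` normalization constants.
#' @param clip truncate the output into [0, 1] (only meaningful with
#'   `bounds`).
#' @param ... unused.
#' @return a dimensionless `RasterGrid` in [0, 1].
#' @examples
#' g <- rasterGrid(matrix(c(2, 4, 6), 1))
#' gridValues(normalizeMinMax(g))   # 0, 0.5, 1
#' @name normalizeMinMax
#' @export
setMethod("normalizeMinMax", "RasterGrid",
          function(x, bounds = NULL, clip = FALSE, ...) {
  v <- x@values
  ok <- !is.na(v)
  if (!any(ok)) stop("cannot normalize an all-nodata grid", call. = FALSE)
  if (is.null(bounds)) {
    lo <- min(v[ok]); hi <- max(v[ok])
  } else {
    lo <- bounds[1]; hi <- bounds[2]
  }
  out <- asGrid(x)
  if (hi == lo) {
    v[ok] <- 0
  } else {
    v[ok] <- (v[ok] - lo) / (hi - lo)
  }
  if (clip) v[ok] <- pmin(pmax(v[ok], 0), 1)
  out@values <- v
  out@units <- "1"
  out
})

#' @describeIn normalizeMinMax a `GridStack` is normalized jointly across
#'   all its bands (one min and max for the whole stack), so e.g. months
#'   stay mutually comparable.
#' @export
setMethod("normalizeMinMax", "GridStack", function(x, ...) {
  all_v <- unlist(lapply(x@grids, function(g) g@values[!is.na(g@values)]))
  if (!length(all_v)) stop("cannot normalize an all-nodata stack", call. = FALSE)
  lo <- min(all_v); hi <- max(all_v)
  out <- x
  out@grids <- lapply(x@grids, function(g) {
    v <- g@values
    ok <- !is.na(v)
    v[ok] <- if (hi == lo) 0 else (v[ok] - lo) / (hi - lo)
    g@values <- v
    g@units <- "1"
    g
  })
  out
})

#' Complement of a normalized grid
#'
#' Per-pixel `1 - x` for grids already normalized to [0, 1]; the `(1 - x)`
#' terms of the weighted-index models (e.g. shallow water table implies
#' more leaching).  Values outside [0, 1] are an error.
#' @param x a [RasterGrid-class] in [0, 1].
#' @return a `RasterGrid` in [0, 1].
#' @export
setMethod("gridComplement", "RasterGrid", function(x) {
  v <- x@values[!is.na(x@values)]
  if (length(v) && (min(v) < -1e-9 || max(v) > 1 + 1e-9))
    stop("gridComplement expects a grid normalized to [0, 1]", call. = FALSE)
  out <- asGrid(x)
  out@values <- 1 - x@values
  out
})

#' Weighted linear combination of aligned grids
#'
#' The shared evaluator behind the weighted-index models: per-pixel
#' `sum(w_i * g_i)`.  Nodata propagates as a union (any nodata input makes
#' the output pixel nodata).
#'
#' @param grids list of aligned [RasterGrid-class] objects.
#' @param weights numeric vector, one weight per grid.
#' @return a `RasterGrid`.
#' @examples
#' g <- rasterGrid(matrix(1, 2, 2))
#' gridValues(combineLinear(list(g, g, g, g, g), c(5, 5, 2, 1, 5)))  # all 18
#' @export
combineLinear <- function(grids, weights) {
  if (!length(grids)) stop("combineLinear needs at least one term", call. = FALSE)
  if (length(weights) != length(grids))
    stop("one weight per grid is required", call. = FALSE)
  assertAligned(grids)
  acc <- weights[1] * grids[[1]]@values
  if (length(grids) > 1L)
    for (i in 2:length(grids)) acc <- acc + weights[i] * grids[[i]]@values
  out <- asGrid(grids[[1]])
  out@values <- acc
  out@units <- ""
  out
}

#' Build a soil-profile stack
#'
#' @param layers list of aligned [RasterGrid-class] objects, one per depth
#'   interval, shallowest first.
#' @param intervals numeric matrix (or 2-column data.frame) of
#'   `(top_cm, bottom_cm)` rows, contiguous and starting at 0.
#' @return a [SoilProfileStack-class].
#' @export
soilProfileStack <- function(layers, intervals) {
  iv <- as.matrix(intervals)
  colnames(iv) <- c("top_cm", "bottom_cm")
  new("SoilProfileStack", layers = layers, intervals = iv)
}

#' Depth-weighted profile average
#'
#' Collapses a multi-layer soil property to a single grid using the layer
#' thicknesses as weights: `sum(thickness_i * value_i) / sum(thickness_i)`.
#' A pixel is nodata if any layer is nodata there.
#'
#' @param p a [SoilProfileStack-class].
#' @return a [RasterGrid-class].
#' @examples
#' l <- lapply(c(10, 20, 40), function(v) rasterGrid(matrix(v, 2, 2)))
#' p <- soilProfileStack(l, rbind(c(0, 5), c(5, 15), c(15, 30)))
#' gridValues(depthWeightedAverage(p))[1, 1]  # 850/30
#' @export
depthWeightedAverage <- function(p) {
  stopifnot(is(p, "SoilProfileStack"))
  validObject(p)
  th <- p@intervals[, 2] - p@intervals[, 1]
  if (sum(th) <= 0) stop("zero total profile thickness", call. = FALSE)
  acc <- th[1] * p@layers[[1]]@values
  if (length(th) > 1L)
    for (i in 2:length(th)) acc <- acc + th[i] * p@layers[[i]]@values
  out <- asGrid(p@layers[[1]])
  out@values <- acc / sum(th)
  out
}

#' Build a grid stack
#'
#' @param grids named list of aligned grids; for monthly stacks use names
#'   `"1"` to `"12"` and `temporal = TRUE`.
#' @param temporal logical.
#' @return a [GridStack-class].
#' @export
gridStack <- function(grids, temporal = FALSE) {
  if (is.null(names(grids)) && temporal) names(grids) <- as.character(seq_along(grids))
  new("GridStack", grids = grids, temporal = temporal)
}

#' @describeIn gridStack extract one band by name or index.
#' @param x a `GridStack`; @param i band name or index.
#' @export
setMethod("[[", "GridStack", function(x, i) x@grids[[i]])

setMethod("show", "GridStack", function(object) {
  cat(sprintf("GridStack: %d band(s)%s\n", length(object@grids),
              if (object@temporal) " (monthly)" else ""))
  show(object@grids[[1]])
})

#' Explicit mean aggregation to a coarser grid
#'
#' Block-averages a grid by an integer factor (mirroring the averaging of
#' finer products to the working resolution).  Provided as an explicit
#' utility only; nothing in the pipeline ever resamples implicitly.
#' Blocks that are entirely nodata stay nodata; otherwise the mean of the
#' valid cells is used.
#'
#' @param x a [RasterGrid-class] whose dimensions are divisible by `factor`.
#' @param factor integer aggregation factor (>= 1).
#' @return a coarser `RasterGrid`.
#' @export
setMethod("resampleMean", "RasterGrid", function(x, factor) {
  f <- as.integer(factor)
  stopifnot(f >= 1L)
  if (f == 1L) return(x)
  v <- x@values
  if (nrow(v) %% f || ncol(v) %% f)
    stop("grid dimensions must be divisible by the aggregation factor",
         call. = FALSE)
  nr <- nrow(v) %/% f; nc <- ncol(v) %/% f
  out <- matrix(NA_real_, nr, nc)
  ri <- (seq_len(nrow(v)) - 1L) %/% f + 1L
  ci <- (seq_len(ncol(v)) - 1L) %/% f + 1L
  idx <- (rep(ci, each = nrow(v)) - 1L) * nr + rep(ri, ncol(v))
  sums <- tapply(as.vector(v), idx, function(z) {
    z <- z[!is.na(z)]
    if (length(z)) mean(z) else NA_real_
  })
  out[as.integer(names(sums))] <- as.numeric(sums)
  rasterGrid(out, xmin = x@xmin, ymax = x@ymax, cellsize = x@cellsize * f,
             units = x@units, crs = x@crs)
})

#' Metric cell width of a geographic grid row
#'
#' For rasters in geographic coordinates the east--west cell width shrinks
#' with latitude: `width_deg * 111320 * cos(latitude)` metres.  Synthetic
#' scenarios use a planar CRS with square metric cells and never need this.
#'
#' @param latitude_deg latitude in degrees.
#' @param width_deg cell width in degrees.
#' @return metres.
#' @export
degreeCellWidth <- function(latitude_deg, width_deg) {
  width_deg * 111320 * cos(latitude_deg * pi / 180)
}
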
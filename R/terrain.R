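## D8 neighbour geometry, fixed order E, SE, S, SW, W, NW, N, NE.
## The order doubles as the deterministic tie-break for flow directions.
.d8_dr   <- c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L)
.d8_dc   <- c(1L, 1L, 0L, -1L, -1L, -1L, 0L, 1L)
.d8_dist <- c(1, sqrt(2), 1, sqrt(2), 1, sqrt(2), 1, sqrt(2))

## out[r, c] = m[r + dr, c + dc], `fill` outside the grid.
.shiftMat <- function(m, dr, dc, fill = NA) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  r0 <- max(1L, 1L - dr); r1 <- min(nr, nr - dr)
  c0 <- max(1L, 1L - dc); c1 <- min(nc, nc - dc)
  if (r0 > r1 || c0 > c1) return(out)
  rs <- r0:r1; cs <- c0:c1
  out[rs, cs] <- m[rs + dr, cs + dc]
  out
}

## Pad by one ring of linearly extrapolated values so border gradients
## reduce to one-sided differences.
.padExtrap <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  p <- rbind(2 * m[1, ] - m[2, ], m, 2 * m[nr, ] - m[nr - 1, ])
  cbind(2 * p[, 1] - p[, 2], p, 2 * p[, nc] - p[, nc - 1])
}

#' Terrain slope from a DEM
#'
#' 3x3 finite-difference gradient magnitude (Horn weights); border pixels
#' use one-sided differences via linear edge extrapolation.  Neighbours
#' that are nodata are treated as equal to the centre cell (they
#' contribute no gradient); the output is nodata wherever the DEM is.
#'
#' @param dem a [RasterGrid-class] of elevations (m) with at least 2 rows
#'   and 2 columns.
#' @param mode `"degrees"` or `"percent"`.
#' @return a `RasterGrid` of slope (>= 0).
#' @export
terrainSlope <- function(dem, mode = c("degrees", "percent")) {
  mode <- match.arg(mode)
  v <- dem@values
  if (nrow(v) < 2L || ncol(v) < 2L)
    stop("slope needs at least a 2 x 2 DEM", call. = FALSE)
  p <- .padExtrap(v)
  ctr <- v
  rows <- 2:(nrow(v) + 1L); cols <- 2:(ncol(v) + 1L)
  nb <- function(dr, dc) {
    z <- p[rows + dr, cols + dc]
    bad <- is.na(z)
    z[bad] <- ctr[bad]   # missing neighbour contributes zero gradient
    z
  }
  e  <- nb(0, 1);  w  <- nb(0, -1)
  n  <- nb(-1, 0); s  <- nb(1, 0)
  ne <- nb(-1, 1); nw <- nb(-1, -1)
  se <- nb(1, 1);  sw <- nb(1, -1)
  dx <- dem@cellsize[1]; dy <- dem@cellsize[2]
  gx <- ((ne + 2 * e + se) - (nw + 2 * w + sw)) / (8 * dx)
  gy <- ((sw + 2 * s + se) - (nw + 2 * n + ne)) / (8 * dy)
  tanb <- sqrt(gx^2 + gy^2)
  tanb[is.na(v)] <- NA_real_
  out <- asGrid(dem)
  if (mode == "degrees") {
    out@values <- atan(tanb) * 180 / pi
    out@units <- "degrees"
  } else {
    out@values <- 100 * tanb
    out@units <- "percent"
  }
  out
}

## Planchon-Darboux drainage surface.  eps = 0 gives the classical pit
## fill; eps > 0 adds a tiny per-step increment so every flat drains
## strictly toward its spill path.  Cells on the grid edge or adjacent to
## nodata act as drains.
.pdSurface <- function(v, eps = 0) {
  nr <- nrow(v); nc <- ncol(v)
  valid <- !is.na(v)
  if (!any(valid)) stop("DEM has no valid cells", call. = FALSE)
  drain <- matrix(FALSE, nr, nc)
  drain[c(1L, nr), ] <- TRUE
  drain[, c(1L, nc)] <- TRUE
  for (k in 1:8)
    drain <- drain | !.shiftMat(valid, .d8_dr[k], .d8_dc[k], fill = FALSE)
  seed <- valid & drain
  W <- matrix(Inf, nr, nc)
  W[seed] <- v[seed]
  W[!valid] <- NA_real_
  maxit <- 8L * (nr + nc) + 16L
  delta <- Inf
  for (it in seq_len(maxit)) {
    nmin <- matrix(Inf, nr, nc)
    for (k in 1:8) {
      nb <- .shiftMat(W, .d8_dr[k], .d8_dc[k], fill = Inf)
      nb[is.na(nb)] <- Inf
      nmin <- pmin(nmin, nb + eps * .d8_dist[k])
    }
    Wn <- pmax(v, pmin(W, nmin))
    Wn[seed] <- v[seed]
    Wn[!valid] <- NA_real_
    delta <- if (any(is.infinite(Wn[valid])) || any(is.infinite(W[valid])))
      Inf else max(abs(Wn - W)[valid], 0)
    W <- Wn
    if (delta == 0) break
  }
  if (delta != 0)
    stop("pit filling did not converge; DEM drainage structure is degenerate",
         call. = FALSE)
  W
}

#' Fill closed depressions in a DEM
#'
#' Raises every pit to its lowest spill elevation so that each interior
#' cell has a monotone non-ascending path to the grid edge (or to a nodata
#' hole, which acts as a drain).  The output is everywhere >= the input,
#' and a pit-free DEM is returned unchanged.
#'
#' @param dem a [RasterGrid-class].
#' @return the filled `RasterGrid`.
#' @export
fillPits <- function(dem) {
  out <- asGrid(dem)
  out@values <- .pdSurface(dem@values, eps = 0)
  out
}

#' D8 flow directions, accumulation and streams
#'
#' Routes each cell to its steepest-descent neighbour (drop divided by
#' distance, diagonals by sqrt(2)); remaining flats are drained by an
#' epsilon gradient toward the filled-DEM spill path, and exact ties are
#' broken by the fixed neighbour order E, SE, S, SW, W, NW, N, NE.  Flow
#' accumulation counts the cells draining through each cell, counting the
#' cell itself, so it is >= 1 everywhere valid.  Cells with no lower
#' neighbour are pits/outlets (direction code 0).
#'
#' @param dem_filled a pit-filled DEM (see [fillPits()]).
#' @param streamThreshold accumulation (cell count) at or above which a
#'   cell is a stream (default 50).
#' @return a [FlowField-class].
#' @export
d8Flow <- function(dem_filled, streamThreshold = 50) {
  v <- dem_filled@values
  nr <- nrow(v); nc <- ncol(v)
  valid <- !is.na(v)
  W <- .pdSurface(v, eps = 1e-6)
  best <- matrix(-Inf, nr, nc)
  dirs <- matrix(0L, nr, nc)
  for (k in 1:8) {
    nb <- .shiftMat(W, .d8_dr[k], .d8_dc[k], fill = Inf)
    nb[is.na(nb)] <- Inf
    drop <- (W - nb) / .d8_dist[k]
    better <- drop > best & valid
    best[better] <- drop[better]
    dirs[better] <- k
  }
  dirs[best <= 0 & valid] <- 0L
  dirs[!valid] <- NA_integer_
  ## receiver linear indices (column-major)
  lin <- matrix(seq_len(nr * nc), nr, nc)
  recv <- matrix(NA_integer_, nr, nc)
  has <- !is.na(dirs) & dirs > 0L
  recv[has] <- lin[has] + .d8_dr[dirs[has]] + .d8_dc[dirs[has]] * nr
  ## accumulation: sweep cells from high to low on the spill surface
  acc <- matrix(NA_real_, nr, nc)
  acc[valid] <- 1
  ord <- order(W, decreasing = TRUE, na.last = NA)
  dv <- as.vector(dirs); rv <- as.vector(recv)
  av <- as.vector(acc)
  for (i in ord) {
    d <- dv[i]
    if (!is.na(d) && d > 0L) {
      j <- rv[i]
      av[j] <- av[j] + av[i]
    }
  }
  acc <- matrix(av, nr, nc)
  sm <- !is.na(acc) & acc >= streamThreshold
  new("FlowField", directions = dirs, accumulation = acc, streamMask = sm,
      streamThreshold = streamThreshold, spill = W,
      xmin = dem_filled@xmin, ymax = dem_filled@ymax,
      cellsize = dem_filled@cellsize)
}

setMethod("show", "FlowField", function(object) {
  ok <- !is.na(object@directions)
  cat(sprintf(
    "FlowField: %d x %d, %d valid cells, %d outlets, %d stream cells (threshold %g)\n",
    nrow(object@directions), ncol(object@directions), sum(ok),
    sum(object@directions == 0L, na.rm = TRUE), sum(object@streamMask),
    object@streamThreshold))
})

#' Flow accumulation as a grid
#' @param flow a [FlowField-class].
#' @return a [RasterGrid-class] of drained cell counts.
#' @export
accumulationGrid <- function(flow) {
  rasterGrid(flow@accumulation, xmin = flow@xmin, ymax = flow@ymax,
             cellsize = flow@cellsize, units = "cells")
}

## receiver linear index matrix for a FlowField
.receivers <- function(flow) {
  d <- flow@directions
  nr <- nrow(d)
  lin <- matrix(seq_along(d), nr, ncol(d))
  recv <- matrix(NA_integer_, nr, ncol(d))
  has <- !is.na(d) & d > 0L
  recv[has] <- lin[has] + .d8_dr[d[has]] + .d8_dc[d[has]] * nr
  recv
}

#' Topographic wetness index
#'
#' `TWI = ln(a / tan(beta))` with `a` the specific catchment area
#' (accumulation x cell size, m) and `tan(beta)` from the slope in
#' degrees, floored at 0.001 so flat pixels stay finite.
#'
#' @param slope_g slope grid in degrees.
#' @param acc_g flow-accumulation grid (cell counts).
#' @param cell_m cell size in metres.
#' @return a [RasterGrid-class].
#' @export
twi <- function(slope_g, acc_g, cell_m) {
  assertAligned(slope_g, acc_g)
  tanb <- pmax(tan(slope_g@values * pi / 180), 0.001)
  a <- acc_g@values * cell_m
  out <- asGrid(slope_g)
  out@values <- log(a / tanb)
  out@units <- "1"
  out
}

#' Delineate subwatersheds from the stream network
#'
#' Splits the stream network into segments between confluences and labels
#' every valid cell by the segment its flow path first reaches.  A stream
#' cell starts a new segment when it is a channel head (no stream donors)
#' or a confluence (two or more stream donors).  Segment stream length is
#' the sum of flow steps along the segment (cell size, x sqrt(2) for
#' diagonal steps), including the outflow step into the next segment.
#' Cells draining off the grid without touching a stream are grouped under
#' label 0 ("unchanneled") so the labels partition the valid extent.
#'
#' @param flow a [FlowField-class] with a non-empty stream mask.
#' @param slope_n optional normalized slope grid; when given, per-watershed
#'   mean slope, the mean slope-area term over stream cells and the
#'   velocity scale `V_m` (watershed mean normalized slope) are recorded
#'   for [streamVelocity()].
#' @param b,c exponents of the slope-area term `s^b A^c` (both 0.5).
#' @param slope_floor lower bound applied to slope in the slope-area term.
#' @return a [WatershedPartition-class].
#' @export
delineateWatersheds <- function(flow, slope_n = NULL, b = 0.5, c = 0.5,
                                slope_floor = 1e-4) {
  sm <- flow@streamMask
  if (!any(sm))
    stop("no stream cells at accumulation threshold ", flow@streamThreshold,
         "; lower the stream threshold", call. = FALSE)
  dirs <- flow@directions
  valid <- !is.na(dirs)
  nr <- nrow(dirs); nc <- ncol(dirs)
  recv <- .receivers(flow)
  W <- flow@spill
  smv <- as.vector(sm); dv <- as.vector(dirs); rv <- as.vector(recv)
  ## stream donor counts
  donors <- integer(nr * nc)
  sidx <- which(smv)
  for (i in sidx) {
    if (dv[i] > 0L) donors[rv[i]] <- donors[rv[i]] + 1L
  }
  ## segment ids, sweeping streams from upstream to downstream
  sord <- sidx[order(W[sidx], decreasing = TRUE)]
  segv <- integer(nr * nc)
  nseg <- 0L
  for (i in sord) {
    if (segv[i] == 0L) {
      nseg <- nseg + 1L
      segv[i] <- nseg
    }
    if (dv[i] > 0L) {
      j <- rv[i]
      if (smv[j] && donors[j] == 1L) segv[j] <- segv[i]
    }
  }
  ## label every cell by the first stream segment its path reaches
  labv <- rep(NA_integer_, nr * nc)
  ordAsc <- order(W, decreasing = FALSE, na.last = NA)
  for (i in ordAsc) {
    if (smv[i]) {
      labv[i] <- segv[i]
    } else if (dv[i] > 0L) {
      labv[i] <- labv[rv[i]]
    } else {
      labv[i] <- 0L
    }
  }
  ## stream length per segment (internal steps + outflow step)
  len <- numeric(nseg)
  dx <- flow@cellsize[1]
  for (i in sidx) {
    if (dv[i] > 0L) len[segv[i]] <- len[segv[i]] + .d8_dist[dv[i]] * dx
  }
  ## a reach occupying a single terminal cell still spans that cell
  len <- pmax(len, dx)
  cells <- tabulate(labv[labv > 0L & !is.na(labv)], nbins = nseg)
  streamCells <- tabulate(segv[segv > 0L], nbins = nseg)
  rec <- data.frame(
    id = seq_len(nseg), cells = cells,
    area_m2 = cells * flow@cellsize[1] * flow@cellsize[2],
    stream_cells = streamCells, stream_length_m = len,
    mean_slope = NA_real_, mean_slope_area_term = NA_real_,
    velocity_scale = NA_real_
  )
  if (!is.null(slope_n)) {
    sv <- as.vector(slope_n@values)
    ws_mean <- tapply(sv[labv > 0L & !is.na(labv)],
                      labv[labv > 0L & !is.na(labv)], mean)
    rec$mean_slope[as.integer(names(ws_mean))] <- as.numeric(ws_mean)
    s <- pmax(sv[sidx], slope_floor)
    term <- s^b * flow@accumulation[sidx]^c
    tm <- tapply(term, segv[sidx], mean)
    rec$mean_slope_area_term[as.integer(names(tm))] <- as.numeric(tm)
    rec$velocity_scale <- rec$mean_slope
  }
  new("WatershedPartition",
      labels = matrix(labv, nr, nc), records = rec,
      unchanneled = sum(labv == 0L, na.rm = TRUE),
      xmin = flow@xmin, ymax = flow@ymax, cellsize = flow@cellsize)
}

setMethod("show", "WatershedPartition", function(object) {
  cat(sprintf("WatershedPartition: %d watershed(s), %d unchanneled cell(s)\n",
              nrow(object@records), object@unchanneled))
  print(utils::head(object@records, 5))
})

#' Broadcast per-watershed values onto the grid
#'
#' @param ws a [WatershedPartition-class].
#' @param values numeric vector indexed by watershed id (one per record).
#' @param units unit tag for the result.
#' @return a [RasterGrid-class]; unchanneled and nodata cells are nodata.
#' @export
wsField <- function(ws, values, units = "") {
  stopifnot(length(values) == nrow(ws@records))
  lab <- ws@labels
  out <- matrix(NA_real_, nrow(lab), ncol(lab))
  pos <- !is.na(lab) & lab > 0L
  out[pos] <- values[lab[pos]]
  rasterGrid(out, xmin = ws@xmin, ymax = ws@ymax, cellsize = ws@cellsize,
             units = units)
}

#' Horton form factor per watershed
#'
#' Catchment-shape descriptor used as the "catchment capacity" indicator
#' of runoff transfer: the ratio of watershed area to stream length
#' (default), or the classical area / length^2 behind the dialect flag.
#'
#' @param ws a [WatershedPartition-class] with positive stream lengths.
#' @param dialect `"area_over_length"` (as used here, metres) or
#'   `"area_over_length_squared"` (dimensionless, Horton's classical form).
#' @return a data.frame with columns `id`, `form_factor`; broadcast with
#'   [wsField()].
#' @export
hortonFormFactor <- function(ws,
                             dialect = c("area_over_length",
                                         "area_over_length_squared")) {
  dialect <- match.arg(dialect)
  len <- ws@records$stream_length_m
  if (any(len <= 0))
    stop("watershed with zero stream length", call. = FALSE)
  ff <- switch(dialect,
    area_over_length = ws@records$area_m2 / len,
    area_over_length_squared = ws@records$area_m2 / len^2
  )
  data.frame(id = ws@records$id, form_factor = ff)
}
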
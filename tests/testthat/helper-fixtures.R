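## Shared fixture builders; everything is generated in code.

mkGrid <- function(v, nrow = NULL, cellsize = 1, units = "") {
  if (is(v, "RasterGrid")) return(v)
  if (is.null(dim(v)) && !is.null(nrow)) v <- matrix(v, nrow = nrow)
  if (is.null(dim(v))) v <- matrix(v, nrow = 1)
  rasterGrid(v, cellsize = cellsize, units = units)
}

## seeded random grid in [lo, hi], optionally with nodata holes
randGrid <- function(nr, nc, seed, lo = 0, hi = 1, na_frac = 0) {
  set.seed(seed)
  v <- matrix(runif(nr * nc, lo, hi), nr, nc)
  if (na_frac > 0) v[sample(nr * nc, round(na_frac * nr * nc))] <- NA_real_
  rasterGrid(v)
}

smallSpec <- function(seed = 1, n = 48, ...) {
  scenarioSpec(nrow = n, ncol = n, cellsize = 500, seed = seed,
               corLen = 5, nodataFraction = 0, ...)
}

## Build a FlowField by hand from a direction-code matrix (codes 0..8 in
## the package's E,SE,S,SW,W,NW,N,NE order).  Accumulation and a
## consistent spill surface are derived by explicit path-following -- an
## oracle independent of d8Flow.
flowFromDirections <- function(dirs, streamMask, cellsize = 100,
                               threshold = 1) {
  dr <- c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L)
  dc <- c(1L, 1L, 0L, -1L, -1L, -1L, 0L, 1L)
  nr <- nrow(dirs); nc <- ncol(dirs)
  recv <- function(i) {
    r <- (i - 1L) %% nr + 1L; cc <- (i - 1L) %/% nr + 1L
    d <- dirs[r, cc]
    if (is.na(d) || d == 0L) return(NA_integer_)
    (cc + dc[d] - 1L) * nr + (r + dr[d])
  }
  n <- nr * nc
  acc <- matrix(0, nr, nc)
  depth <- matrix(NA_real_, nr, nc)   # steps to the outlet
  for (i in seq_len(n)) {
    if (is.na(dirs[i])) next
    j <- i; steps <- 0L
    repeat {
      acc[j] <- acc[j] + 1
      jn <- recv(j)
      if (is.na(jn)) break
      j <- jn; steps <- steps + 1L
      stopifnot(steps <= n)  # acyclicity of the hand-built field
    }
  }
  for (i in seq_len(n)) {
    if (is.na(dirs[i])) next
    j <- i; d <- 0L
    repeat {
      jn <- recv(j)
      if (is.na(jn)) break
      j <- jn; d <- d + 1L
    }
    depth[i] <- d
  }
  acc[is.na(dirs)] <- NA_real_
  new("FlowField", directions = dirs, accumulation = acc,
      streamMask = streamMask & !is.na(dirs), streamThreshold = threshold,
      spill = depth,    # strictly decreasing along flow: works as spill
      xmin = 0, ymax = nr * cellsize, cellsize = c(cellsize, cellsize))
}

## follow D8 directions from every cell; returns max path length (cells)
## or stops if a cycle is found -- independent acyclicity check
followAll <- function(flow) {
  dirs <- flow@directions
  dr <- c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L)
  dc <- c(1L, 1L, 0L, -1L, -1L, -1L, 0L, 1L)
  nr <- nrow(dirs); n <- length(dirs)
  maxlen <- 0L
  for (i in seq_len(n)) {
    if (is.na(dirs[i])) next
    j <- i; steps <- 0L
    repeat {
      r <- (j - 1L) %% nr + 1L; cc <- (j - 1L) %/% nr + 1L
      d <- dirs[r, cc]
      if (d == 0L) break
      j <- (cc + dc[d] - 1L) * nr + (r + dr[d])
      steps <- steps + 1L
      if (steps > n) stop("cycle detected in flow directions")
    }
    maxlen <- max(maxlen, steps)
  }
  maxlen
}
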
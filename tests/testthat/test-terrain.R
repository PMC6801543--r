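test_that("slope is zero on flat terrain and exact on an inclined plane", {
  flat <- mkGrid(matrix(100, 6, 6), cellsize = 50)
  expect_true(all(gridValues(terrainSlope(flat)) == 0))

  ## z = 0.1 x on metric cells: 10% slope = atan(0.1) degrees everywhere,
  ## border pixels included (one-sided differences)
  nr <- 8; nc <- 10; cs <- 30
  x <- matrix(rep((seq_len(nc) - 1) * cs, each = nr), nr, nc)
  plane <- mkGrid(0.1 * x, cellsize = cs)
  pct <- gridValues(terrainSlope(plane, "percent"))
  expect_equal(pct, matrix(10, nr, nc), tolerance = 1e-9)
  deg <- gridValues(terrainSlope(plane, "degrees"))
  expect_equal(unique(round(as.vector(deg), 6)), round(atan(0.1) * 180 / pi, 6))

  rough <- randGrid(12, 12, seed = 4, lo = 0, hi = 100)
  expect_true(all(gridValues(terrainSlope(rough)) >= 0))
  expect_error(terrainSlope(mkGrid(1:5)), "2 x 2")
})

test_that("pit filling raises depressions to their spill and nothing else", {
  ## pit-free: an inclined plane is unchanged
  nr <- 5; nc <- 5
  plane <- mkGrid(matrix(rep(1:nc, each = nr), nr, nc), cellsize = 10)
  expect_equal(gridValues(fillPits(plane)), gridValues(plane))

  ## single-cell depression: the pit must rise exactly to the lowest
  ## elevation on its rim, and nothing else may move.  The outer ring is
  ## lower than the rim so the rim itself drains freely.
  v <- matrix(6, 5, 5)
  v[2:4, 2:4] <- c(8, 8, 8, 8, 1, 8, 7.5, 8, 8)  # centre cell is a pit
  rim <- v[2:4, 2:4][-5]
  dem <- mkGrid(v, cellsize = 10)
  filled <- gridValues(fillPits(dem))
  expect_equal(filled[3, 3], min(rim))  # lowest rim cell: 7.5
  expect_true(all(filled - v >= 0))
  expect_equal(filled[v != 1], v[v != 1])  # only the pit moved

  ## brute-force flood oracle: water level = the minimax elevation over
  ## all 8-connected paths from the pit to the border
  paths_minimax <- function(v, start) {
    n <- length(v)
    best <- rep(Inf, n)
    best[start] <- v[start]
    repeat {
      changed <- FALSE
      for (i in seq_len(n)) {
        r <- (i - 1) %% 5 + 1; cc <- (i - 1) %/% 5 + 1
        for (dr in -1:1) for (dc in -1:1) {
          r2 <- r + dr; c2 <- cc + dc
          if (r2 < 1 || r2 > 5 || c2 < 1 || c2 > 5) next
          j <- (c2 - 1) * 5 + r2
          cand <- max(best[i], v[j])
          if (cand < best[j]) { best[j] <- cand; changed <- TRUE }
        }
      }
      if (!changed) break
    }
    border <- c(1:5, seq(5, 25, 5), seq(1, 21, 5), 21:25)
    min(best[border])
  }
  expect_equal(filled[3, 3], paths_minimax(as.vector(v), start = 13))

  set.seed(9)
  rnd <- randGrid(20, 20, seed = 9, lo = 0, hi = 50)
  expect_true(all(gridValues(fillPits(rnd)) - gridValues(rnd) >= -1e-12))
})

test_that("D8 routing accumulates correctly on a descending line", {
  row <- mkGrid(matrix(c(5, 4, 3, 2, 1), 1), cellsize = 10)
  flow <- d8Flow(fillPits(row), streamThreshold = 3)
  expect_equal(as.vector(flow@accumulation), 1:5)
  expect_equal(as.vector(flow@directions), c(1L, 1L, 1L, 1L, 0L))
  expect_equal(as.vector(flow@streamMask), c(FALSE, FALSE, TRUE, TRUE, TRUE))
})

test_that("a V-shaped valley drains both slopes onto its axis", {
  ## valley along column 4 of a 7 x 7, deepening southwards; checked
  ## against explicit path-following (independent oracle)
  nr <- 7; nc <- 7
  col <- matrix(rep(1:nc, each = nr), nr, nc)
  rowm <- matrix(rep(1:nr, nc), nr, nc)
  v <- abs(col - 4) * 10 + (nr - rowm)
  dem <- mkGrid(v, cellsize = 10)
  flow <- d8Flow(fillPits(dem), streamThreshold = 10)
  oracle <- flowFromDirections(flow@directions,
                               flow@streamMask, cellsize = 10)
  expect_equal(flow@accumulation, oracle@accumulation)
  ## the axis collects increasingly from both sides; outlet drains all
  expect_equal(flow@accumulation[7, 4], 49)
  expect_true(all(diff(flow@accumulation[, 4]) > 0))
})

test_that("flow accumulation is conserved and directions are acyclic", {
  spec <- smallSpec(seed = 3, n = 48)
  dem <- synthDem(spec)
  flow <- d8Flow(fillPits(dem))
  outlets <- !is.na(flow@directions) & flow@directions == 0L
  expect_identical(sum(flow@accumulation[outlets]),
                   sum(!is.na(flow@directions)) * 1)
  expect_true(all(flow@accumulation[!is.na(flow@accumulation)] >= 1))
  expect_lt(followAll(flow), length(flow@directions))  # terminates, no cycle
})

test_that("TWI follows ln(a/tan(beta)) with a floored gradient", {
  ## a = 1000 m, tan(beta) = 0.1  =>  ln(10000)
  slope_deg <- mkGrid(atan(0.1) * 180 / pi)
  acc <- mkGrid(10)
  got <- gridValues(twi(slope_deg, acc, cell_m = 100))[1, 1]
  expect_equal(got, log(10000), tolerance = 1e-9)

  flat <- gridValues(twi(mkGrid(0), mkGrid(1), cell_m = 100))[1, 1]
  expect_true(is.finite(flat))
  expect_equal(flat, log(100 / 0.001))

  ## monotone in accumulation at fixed slope
  t1 <- gridValues(twi(slope_deg, mkGrid(10), 100))[1, 1]
  t2 <- gridValues(twi(slope_deg, mkGrid(20), 100))[1, 1]
  expect_gt(t2, t1)
})

test_that("a single straight stream yields one watershed covering all cells", {
  row <- mkGrid(matrix(c(5, 4, 3, 2, 1), 1), cellsize = 100)
  flow <- d8Flow(fillPits(row), streamThreshold = 1)
  ws <- delineateWatersheds(flow)
  expect_equal(nrow(ws@records), 1L)
  expect_equal(ws@records$cells, 5L)
  ## 5-cell straight reach at 100 m cells: 4 flow steps
  expect_equal(ws@records$stream_length_m, 400)
  expect_equal(ws@unchanneled, 0L)
})

test_that("a Y-confluence gives three segments partitioning the grid", {
  ## hand-built 5 x 5 flow field: two arms meeting at (3,3), trunk south
  dirs <- matrix(NA_integer_, 5, 5)
  ## E=1 SE=2 S=3 SW=4 W=5 NW=6 N=7 NE=8; 0 = outlet
  dirs[1, ] <- c(2L, 3L, 3L, 3L, 4L)
  dirs[2, ] <- c(2L, 2L, 3L, 4L, 4L)
  dirs[3, ] <- c(1L, 1L, 3L, 5L, 5L)
  dirs[4, ] <- c(1L, 1L, 3L, 5L, 5L)
  dirs[5, ] <- c(1L, 1L, 0L, 5L, 5L)
  ## arms: (1,2)->(2,2)... wait for the stream mask choose the heavy cells
  stream <- matrix(FALSE, 5, 5)
  stream[2, 2] <- TRUE; stream[2, 4] <- TRUE   # two arms
  stream[3, 3] <- TRUE                         # confluence
  stream[4, 3] <- TRUE; stream[5, 3] <- TRUE   # trunk
  flow <- flowFromDirections(dirs, stream, cellsize = 100)
  ws <- delineateWatersheds(flow)
  expect_equal(nrow(ws@records), 3L)
  expect_equal(sum(ws@records$cells) + ws@unchanneled,
               sum(!is.na(dirs)))
  ## every stream cell belongs to exactly one watershed
  expect_true(all(!is.na(ws@labels[stream]) & ws@labels[stream] > 0))
})

test_that("watershed labels partition the valid extent on synthetic terrain", {
  spec <- smallSpec(seed = 5, n = 48)
  flow <- d8Flow(fillPits(synthDem(spec)))
  ws <- delineateWatersheds(flow)
  expect_gte(nrow(ws@records), 1L)
  expect_identical(sum(ws@records$cells) + ws@unchanneled,
                   sum(!is.na(flow@directions)))
  expect_error(delineateWatersheds(d8Flow(fillPits(synthDem(spec)),
                                          streamThreshold = 1e9)),
               "threshold")
})

test_that("Horton form factor divides area by stream length (both dialects)", {
  rec <- data.frame(id = 1L, cells = 1L, area_m2 = 10000,
                    stream_cells = 5L, stream_length_m = 500,
                    mean_slope = NA_real_, mean_slope_area_term = NA_real_,
                    velocity_scale = NA_real_)
  ws <- new("WatershedPartition", labels = matrix(1L, 1, 1), records = rec,
            unchanneled = 0L, xmin = 0, ymax = 100, cellsize = c(100, 100))
  expect_equal(hortonFormFactor(ws)$form_factor, 20)
  expect_equal(hortonFormFactor(ws, "area_over_length_squared")$form_factor,
               0.04)
  rec2 <- rec; rec2$area_m2 <- 20000
  ws2 <- ws; ws2@records <- rec2
  expect_equal(hortonFormFactor(ws2)$form_factor, 40)  # doubling area doubles
  rec3 <- rec; rec3$stream_length_m <- 0
  ws3 <- ws; ws3@records <- rec3
  expect_error(hortonFormFactor(ws3), "zero stream length")
})
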
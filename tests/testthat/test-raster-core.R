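test_that("min-max normalization rescales, preserves nodata, handles degenerate maps", {
  g <- mkGrid(c(2, 4, 6))
  expect_equal(as.vector(gridValues(normalizeMinMax(g))), c(0, 0.5, 1))

  expect_equal(as.vector(gridValues(normalizeMinMax(mkGrid(c(7, 7, 7))))),
               c(0, 0, 0))

  ## index range 0..18 rescaled by the direct per-pixel formula
  v <- seq(0, 18, by = 0.5)
  got <- gridValues(normalizeMinMax(mkGrid(v)))
  expect_equal(as.vector(got), (v - 0) / 18, tolerance = 1e-12)

  withna <- mkGrid(c(1, NA, 3))
  n <- normalizeMinMax(withna)
  expect_true(is.na(gridValues(n)[1, 2]))
  expect_equal(gridValues(n)[1, 3], 1)

  expect_error(normalizeMinMax(mkGrid(c(NA_real_, NA_real_))), "nodata")
})

test_that("normalization is idempotent on [0,1]-spanning grids and bounded", {
  for (s in 1:5) {
    g <- randGrid(16, 16, seed = s, na_frac = 0.1)
    n1 <- normalizeMinMax(g)
    v <- gridValues(n1)[!nodataMask(n1)]
    expect_true(all(v >= 0 & v <= 1))
    n2 <- normalizeMinMax(n1)
    expect_equal(gridValues(n2), gridValues(n1), tolerance = 1e-12)
  }
})

test_that("fixed-bounds normalization uses the given constants and clips", {
  g <- mkGrid(c(0, 5, 10, 12))
  n <- normalizeMinMax(g, bounds = c(0, 10), clip = TRUE)
  expect_equal(as.vector(gridValues(n)), c(0, 0.5, 1, 1))
  n2 <- normalizeMinMax(g, bounds = c(0, 10), clip = FALSE)
  expect_equal(gridValues(n2)[1, 4], 1.2)
})

test_that("complement is the involution 1 - x on normalized grids only", {
  g <- mkGrid(c(0, 0.3, 1))
  expect_equal(as.vector(gridValues(gridComplement(g))), c(1, 0.7, 0))
  expect_equal(gridValues(gridComplement(gridComplement(g))), gridValues(g))
  expect_error(gridComplement(mkGrid(c(0, 2))), "normalized")
})

test_that("depth-weighted averaging weights layers by thickness", {
  layers <- lapply(c(10, 20, 40), function(x) mkGrid(matrix(x, 2, 2)))
  p <- soilProfileStack(layers, rbind(c(0, 5), c(5, 15), c(15, 30)))
  expect_equal(gridValues(depthWeightedAverage(p))[1, 1], 850 / 30)

  same <- soilProfileStack(lapply(1:3, function(i) mkGrid(matrix(7, 2, 2))),
                           rbind(c(0, 5), c(5, 15), c(15, 30)))
  expect_equal(unique(as.vector(gridValues(depthWeightedAverage(same)))), 7)

  one <- soilProfileStack(list(mkGrid(matrix(1:4, 2, 2))), rbind(c(0, 30)))
  expect_equal(gridValues(depthWeightedAverage(one)), matrix(1:4, 2, 2))

  ## any-layer nodata makes the pixel nodata
  l2 <- layers
  v <- gridValues(l2[[2]]); v[1, 1] <- NA; gridValues(l2[[2]]) <- v
  p2 <- soilProfileStack(l2, rbind(c(0, 5), c(5, 15), c(15, 30)))
  expect_true(is.na(gridValues(depthWeightedAverage(p2))[1, 1]))
  expect_false(is.na(gridValues(depthWeightedAverage(p2))[2, 2]))

  ## invalid intervals are rejected at construction
  expect_error(soilProfileStack(layers, rbind(c(0, 5), c(6, 15), c(15, 30))),
               "contiguous")
  expect_error(soilProfileStack(list(mkGrid(1)), rbind(c(5, 10))), "0 cm")
})

test_that("combineLinear matches a per-pixel scalar loop and propagates nodata", {
  ones <- lapply(1:5, function(i) mkGrid(matrix(1, 2, 2)))
  expect_equal(unique(as.vector(gridValues(
    combineLinear(ones, c(5, 5, 2, 1, 5))))), 18)
  expect_error(combineLinear(list(), numeric(0)), "at least one")
  g <- randGrid(4, 4, seed = 2)
  expect_equal(gridValues(combineLinear(list(g), 1)), gridValues(g))

  set.seed(11)
  gs <- lapply(1:4, function(i) randGrid(32, 32, seed = 100 + i,
                                         na_frac = 0.05))
  w <- rnorm(4)
  got <- gridValues(combineLinear(gs, w))
  ref <- matrix(NA_real_, 32, 32)
  for (r in 1:32) for (cc in 1:32) {
    s <- 0
    for (k in 1:4) s <- s + w[k] * gridValues(gs[[k]])[r, cc]
    ref[r, cc] <- s
  }
  expect_equal(got, ref, tolerance = 1e-10)

  ## nodata union
  na_ref <- Reduce(`|`, lapply(gs, nodataMask))
  expect_identical(is.na(got), na_ref)
})

test_that("grid arithmetic requires alignment", {
  a <- randGrid(4, 4, seed = 1)
  b <- randGrid(4, 5, seed = 2)
  expect_error(a + b, "not aligned")
  c2 <- rasterGrid(gridValues(a), cellsize = 2)
  expect_error(a * c2, "not aligned")
})

test_that("mean aggregation averages valid cells per block", {
  v <- matrix(1:16, 4, 4)
  g <- mkGrid(v)
  agg <- resampleMean(g, 2)
  expect_equal(gridValues(agg)[1, 1], mean(v[1:2, 1:2]))
  expect_equal(cellSize(agg), c(2, 2))
  v[1, 1] <- NA
  g2 <- mkGrid(v)
  expect_equal(gridValues(resampleMean(g2, 2))[1, 1], mean(v[1:2, 1:2],
                                                           na.rm = TRUE))
  expect_error(resampleMean(mkGrid(matrix(1, 3, 3)), 2), "divisible")
})

test_that("ASCII grid I/O round-trips values, georeference and nodata", {
  g <- randGrid(7, 5, seed = 3, na_frac = 0.2)
  p <- withr::local_tempfile(fileext = ".asc")
  writeAsciiGrid(g, p)
  g2 <- readAsciiGrid(p)
  expect_equal(gridValues(g2), gridValues(g), tolerance = 1e-9)
  expect_equal(cellSize(g2), cellSize(g))
  expect_equal(g2@xmin, g@xmin)
  expect_equal(g2@ymax, g@ymax)
  expect_error(readAsciiGrid(file.path(tempdir(), "nope.asc")), "no such")
})
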
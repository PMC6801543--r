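test_that("textural factor M evaluates both dialects on worked values", {
  expect_equal(texturalFactorM(30, 40, 20), (30 + 8) * 80)   # 3040
  expect_equal(texturalFactorM(30, 40, 20, "as_printed"), 30 + 8 * 80)  # 670
  expect_equal(texturalFactorM(30, 40, 100), 0)
  expect_error(texturalFactorM(-1, 40, 20), "non-negative")
  ## grid form agrees with scalar form
  g <- texturalFactorM(mkGrid(c(30, 10)), mkGrid(c(40, 20)),
                       mkGrid(c(20, 50)))
  expect_equal(as.vector(gridValues(g)),
               c(texturalFactorM(30, 40, 20), texturalFactorM(10, 20, 50)))
})

test_that("erodibility K reproduces the nomograph worked value and floors at 0", {
  expect_equal(erodibilityK(3040, 2, 2, 3), 0.0258, tolerance = 2e-3)
  expect_equal(erodibilityK(0, 12, 2, 3), 0)
  ## monotone decreasing in OM at fixed M
  Ks <- vapply(0:12, function(om) erodibilityK(3040, om, 2, 3), numeric(1))
  expect_true(all(diff(Ks) <= 0))
  ## negative nomograph output floored
  expect_equal(erodibilityK(0, 12, 1, 1), 0)
  expect_error(erodibilityK(100, 2, 5, 3), "structure class")
})

test_that("slope factor S has the documented two-branch form", {
  expect_equal(slopeFactorS(0), 0.03)
  expect_equal(slopeFactorS(5), 10.8 * sin(5 * pi / 180) + 0.03)  # ~0.971
  th20 <- atan(0.2) * 180 / pi
  expect_equal(slopeFactorS(th20), 16.8 * sin(atan(0.2)) - 0.5)   # ~2.795
  ## jump at the 9% breakpoint is below 0.01
  thb <- atan(0.09) * 180 / pi
  jump <- abs((10.8 * sin(atan(0.09)) + 0.03) -
                (16.8 * sin(atan(0.09)) - 0.5))
  expect_lt(jump, 0.01)
  expect_equal(abs(slopeFactorS(thb + 1e-9) - slopeFactorS(thb - 1e-9)),
               jump, tolerance = 1e-6)
  expect_error(slopeFactorS(91), "degrees")
})

test_that("cover factor complements the vegetation index within [0,1]", {
  expect_equal(coverFactorC(1), 0)
  expect_equal(coverFactorC(0), 1)
  expect_equal(coverFactorC(0.25), 0.75)
})

test_that("USLE erosion is the non-negative product of its factors", {
  expect_equal(usleErosion(0, 0.03, 0.5, 1), 0)
  expect_equal(usleErosion(2000, erodibilityK(3040, 2, 2, 3), 0.5,
                           slopeFactorS(5)),
               25.1, tolerance = 2e-3)
  expect_equal(usleErosion(4000, 0.02, 0.5, 1),
               2 * usleErosion(2000, 0.02, 0.5, 1))
  expect_error(usleErosion(-1, 0.02, 0.5, 1), "non-negative")
})

test_that("vectorized USLE chain matches a scalar per-pixel oracle", {
  set.seed(91)
  silt <- randGrid(32, 32, 91, 5, 60); sand <- randGrid(32, 32, 92, 10, 80)
  clay <- randGrid(32, 32, 93, 5, 50); om <- randGrid(32, 32, 94, 0.3, 6)
  s_cls <- mkGrid(matrix(sample(1:4, 32 * 32, TRUE), 32, 32))
  p_cls <- mkGrid(matrix(sample(1:3, 32 * 32, TRUE), 32, 32))
  R <- randGrid(32, 32, 95, 200, 12000)
  evi <- randGrid(32, 32, 96)
  th <- randGrid(32, 32, 97, 0, 35)
  M <- texturalFactorM(silt, sand, clay)
  K <- erodibilityK(M, om, s_cls, p_cls)
  E <- usleErosion(R, K, coverFactorC(evi), slopeFactorS(th))
  ref <- matrix(NA_real_, 32, 32)
  for (r in 1:32) for (cc in 1:32) {
    mm <- (gridValues(silt)[r, cc] + 0.2 * gridValues(sand)[r, cc]) *
      (100 - gridValues(clay)[r, cc])
    kk <- max(((2.1e-4 * mm^1.14 * (12 - gridValues(om)[r, cc]) +
                  3.25 * (gridValues(s_cls)[r, cc] - 2) +
                  2.5 * (gridValues(p_cls)[r, cc] - 3)) / 100) * 0.1317, 0)
    rad <- gridValues(th)[r, cc] * pi / 180
    ss <- if (tan(rad) < 0.09) 10.8 * sin(rad) + 0.03
          else 16.8 * sin(rad) - 0.5
    ref[r, cc] <- gridValues(R)[r, cc] * kk *
      (1 - gridValues(evi)[r, cc]) * ss
  }
  expect_equal(gridValues(E), ref, tolerance = 1e-10)
  expect_true(all(gridValues(E) >= 0))
})

test_that("sediment load sums erosion over watersheds and is additive", {
  lab <- matrix(1L, 10, 10); lab[, 6:10] <- 2L
  rec <- data.frame(id = 1:2, cells = c(50L, 50L), area_m2 = c(5e5, 5e5),
                    stream_cells = c(5L, 5L), stream_length_m = c(500, 500),
                    mean_slope = NA_real_, mean_slope_area_term = NA_real_,
                    velocity_scale = NA_real_)
  ws <- new("WatershedPartition", labels = lab, records = rec,
            unchanneled = 0L, xmin = 0, ymax = 1000,
            cellsize = c(100, 100))
  E1 <- mkGrid(matrix(1, 10, 10), cellsize = 100)
  load <- sedimentLoad(E1, ws, cell_area_ha = 1)
  expect_equal(load$load_t_yr, c(50, 50))  # 50 cells x 1 t/ha/yr x 1 ha
  expect_equal(sum(load$load_t_yr), sum(gridValues(E1)))
  expect_equal(sedimentLoad(E1 * 0, ws, 1)$load_t_yr, c(0, 0))
})

test_that("stream velocity scales the slope-area term to the watershed mean", {
  ## two stream cells with s^b A^c = {2, 4} and V_m = 1:
  ## V = {2/3, 4/3}, watershed mean of V = V_m
  dirs <- matrix(c(1L, 1L, 0L), 1, 3)
  stream <- matrix(c(FALSE, TRUE, TRUE), 1, 3)
  flow <- flowFromDirections(dirs, stream, cellsize = 100)
  flow@accumulation[1, 2] <- 4; flow@accumulation[1, 3] <- 16
  ws <- delineateWatersheds(flow, slope_n = mkGrid(matrix(1, 1, 3),
                                                   cellsize = 100))
  V <- streamVelocity(mkGrid(matrix(1, 1, 3), cellsize = 100), flow, ws)
  expect_equal(as.vector(gridValues(V))[2:3], c(2 / 3, 4 / 3),
               tolerance = 1e-12)
  expect_true(is.na(gridValues(V)[1, 1]))
  expect_equal(mean(gridValues(V)[stream]), 1, tolerance = 1e-12)

  ## uniform slope and accumulation: V = V_m everywhere on the stream
  flow2 <- flowFromDirections(dirs, stream, cellsize = 100)
  flow2@accumulation[stream] <- 9
  ws2 <- delineateWatersheds(flow2, slope_n = mkGrid(matrix(0.5, 1, 3),
                                                     cellsize = 100))
  V2 <- streamVelocity(mkGrid(matrix(0.5, 1, 3), cellsize = 100), flow2, ws2)
  expect_equal(unique(gridValues(V2)[stream]), 0.5)
})

test_that("the watershed-mean velocity identity holds on synthetic terrain", {
  spec <- smallSpec(seed = 8, n = 48)
  terr <- terrainDerivatives(synthDem(spec))
  V <- streamVelocity(terr$slope_n, terr$flow, terr$ws)
  lab <- terr$ws@labels[terr$flow@streamMask]
  vms <- tapply(gridValues(V)[terr$flow@streamMask], lab, mean)
  ## scalar oracle for V_m: watershed mean of normalized slope
  for (id in names(vms)) {
    cells <- !is.na(terr$ws@labels) & terr$ws@labels == as.integer(id)
    expect_equal(unname(vms[id]), mean(gridValues(terr$slope_n)[cells]),
                 tolerance = 1e-9)
  }
})

test_that("sedimentation index is the load x slack-water product", {
  ## grids already spanning [0,1] so the internal normalizations are
  ## identities; include the (1,0) endpoint so renormalization is too
  load <- mkGrid(c(1, 0, 0.8, 0.5))
  vel <- mkGrid(c(0, 1, 0.5, 1))
  idx <- sedimentationIndex(load, vel)
  expect_s4_class(idx, "ProcessMap")
  expect_equal(as.vector(gridValues(idx)), c(1, 0, 0.4, 0))
  expect_equal(gridValues(idx)[1, 2], 0)  # no load, no deposition
})
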
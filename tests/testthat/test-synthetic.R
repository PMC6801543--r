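test_that("generators are bit-for-bit deterministic under a fixed seed", {
  spec <- smallSpec(seed = 42, n = 32)
  expect_identical(gridValues(randomField(spec, "x")),
                   gridValues(randomField(spec, "x")))
  expect_identical(gridValues(synthDem(spec)), gridValues(synthDem(spec)))
  s1 <- synthClimateStack(spec, "temp"); s2 <- synthClimateStack(spec, "temp")
  expect_identical(gridValues(s1[["4"]]), gridValues(s2[["4"]]))
  counts <- data.frame(compound = "pp'DDD", substrate = "soil", n = 20)
  expect_identical(synthResidueDb(counts, seed = 5)@data,
                   synthResidueDb(counts, seed = 5)@data)
  ## different variable names give different fields
  expect_false(identical(gridValues(randomField(spec, "x")),
                         gridValues(randomField(spec, "y"))))
})

test_that("random fields honour the requested range and correlation", {
  spec <- smallSpec(seed = 3, n = 32)
  f <- randomField(spec, "rng", range = c(5, 9))
  expect_equal(range(gridValues(f)), c(5, 9))

  ## corLen -> 0 recovers white noise: mean lag-1 autocorrelation near 0
  lag1 <- function(m) {
    v1 <- as.vector(m[, -ncol(m)]); v2 <- as.vector(m[, -1])
    stats::cor(v1, v2)
  }
  acs <- vapply(1:100, function(i) {
    f <- randomField(spec, paste0("wn", i), corLen = 0)
    lag1(gridValues(f))
  }, numeric(1))
  expect_lt(abs(mean(acs)), 0.05)
  ## smoothing induces strong positive lag-1 correlation
  sm <- vapply(1:20, function(i)
    lag1(gridValues(randomField(spec, paste0("sm", i), corLen = 4))),
    numeric(1))
  expect_gt(mean(sm), 0.5)
})

test_that("synthetic DEM modes produce the advertised drainage structure", {
  spec <- smallSpec(seed = 2, n = 32)
  flat <- synthDem(spec, "flat")
  expect_equal(length(unique(as.vector(gridValues(flat)))), 1L)

  ## inclined plane: single outlet at the low (north-west) corner
  plane <- synthDem(spec, "plane")
  flow <- d8Flow(fillPits(plane))
  outlets <- which(!is.na(flow@directions) & flow@directions == 0L)
  expect_equal(outlets, 1L)
  expect_equal(flow@accumulation[[1L]], 32 * 32)

  ## default 128 x 128 scenario drains into several watersheds
  spec128 <- scenarioSpec(seed = 1, nodataFraction = 0)
  terr <- terrainDerivatives(synthDem(spec128))
  expect_gte(nrow(terr$ws@records), 3L)
})

test_that("climate stacks have sinusoidal seasonality around the base field", {
  spec <- smallSpec(seed = 6, n = 32)

  ## zero amplitude: twelve identical months, so seasonal SD is zero
  spec0 <- smallSpec(seed = 6, n = 32,
                     seasonalAmplitude = c(wind = 0, srad = 0, temp = 0,
                                           rh = 0))
  stk <- synthClimateStack(spec0, "temp")
  s <- annualSummary(stk@grids)
  expect_true(all(gridValues(s$sd) == 0))

  ## phase shift by 6 months flips the warmest month
  stk1 <- synthClimateStack(spec, "temp")
  spec_sh <- smallSpec(seed = 6, n = 32,
                       seasonalPhase = c(wind = 0, srad = 3, temp = 8,
                                         rh = 8))
  stk2 <- synthClimateStack(spec_sh, "temp")
  m1 <- vapply(1:12, function(i) mean(gridValues(stk1[[as.character(i)]])),
               numeric(1))
  m2 <- vapply(1:12, function(i) mean(gridValues(stk2[[as.character(i)]])),
               numeric(1))
  expect_equal((which.max(m1) + 6 - 1) %% 12 + 1, which.max(m2))

  ## monthly mean tracks the base field within the CLT noise bound
  base <- gridValues(randomField(spec, "climate_temp",
                                 spec@soilRanges$temp))
  mean_stack <- Reduce(`+`, lapply(stk1@grids, gridValues)) / 12
  amp <- spec@seasonalAmplitude[["temp"]]
  bound <- 3 * (0.1 * amp) / sqrt(12)
  expect_lt(mean(abs(mean_stack - base)), bound)
})

test_that("texture fractions sum to 100% everywhere", {
  spec <- smallSpec(seed = 4, n = 32)
  tex <- synthTexture(spec)
  tot <- gridValues(tex$silt) + gridValues(tex$sand) + gridValues(tex$clay)
  expect_equal(tot, matrix(100, 32, 32), tolerance = 1e-9)
  expect_true(all(gridValues(tex$clay) > 0))
})

test_that("categorical generators respect vocabularies and proportions", {
  spec <- smallSpec(seed = 12, n = 48)
  lu <- synthLanduse(spec)
  expect_true(all(gridValues(lu) %in% 1:5))
  props <- tabulate(gridValues(lu), 5) / (48 * 48)
  expect_equal(props, unname(spec@landuseProportions), tolerance = 0.05)
  dc <- synthDrainageClass(spec)
  expect_true(all(gridValues(dc) %in% 1:3))
})

test_that("scenario validity rules reject malformed specifications", {
  expect_error(scenarioSpec(nrow = 15), "16 x 16")
  expect_error(scenarioSpec(landuseProportions = c(a = 0.5, b = 0.4)),
               "sum to 1")
  expect_error(scenarioSpec(nodataFraction = 1), "nodataFraction")
  expect_error(randomField(smallSpec(n = 32), "x", corLen = 40),
               "correlation length")
})

test_that("residue generator delivers the requested counts and georeferencing", {
  counts <- data.frame(compound = "deltamethrin", substrate = "water", n = 50)
  db <- synthResidueDb(counts, georefFraction = 0.94, seed = 9)
  expect_equal(nrow(db@data), 50L)
  f <- residueFunnel(db)
  expect_equal(f$georeferenced, 47L)  # round(0.94 * 50)

  ## closed loop with the funnel at controlled location count
  counts2 <- data.frame(compound = c("pp'DDD", "pp'DDD"),
                        substrate = c("soil", "sediment"),
                        n = c(169L, 216L))
  db2 <- synthResidueDb(counts2, georefFraction = 1, seed = 10,
                        nLocations = 100)
  f2 <- residueFunnel(db2, compound = "pp'DDD",
                      substrates = c("soil", "sediment"))
  expect_equal(unname(f2$selected_by_substrate[c("soil", "sediment")]),
               c(169L, 216L))
  expect_equal(f2$selected_locations, 100L)

  ## degenerate requests
  empty <- synthResidueDb(data.frame(compound = character(0),
                                     substrate = character(0),
                                     n = integer(0)))
  expect_equal(nrow(empty@data), 0L)
  expect_error(synthResidueDb(data.frame(compound = "x", substrate = "soil",
                                         n = -1)), "negative")
})

test_that("a full synthetic scenario feeds every downstream stage", {
  spec <- smallSpec(seed = 19, n = 32)
  inp <- synthScenario(spec)
  ## every raster aligned, classes in vocabulary, normalizable
  expect_true(all(gridValues(inp$drainage_class) %in% c(1:3, NA)))
  expect_true(all(gridValues(inp$structure_class) %in% c(1:4, NA)))
  expect_silent(normalizeMinMax(inp$groundwater_depth))
  expect_true(isAligned(inp$dem, inp$evi))
  expect_true(isAligned(inp$dem, inp$wind[["1"]]))
  expect_s4_class(inp$oc_profile, "SoilProfileStack")
  expect_equal(nrow(inp$oc_profile@intervals), 7L)
  expect_equal(max(inp$oc_profile@intervals), 200)
})
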
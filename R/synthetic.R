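## Seeded generators for every pipeline input.  The emulation is
## statistical only (value ranges, spatial autocorrelation, seasonality,
## class mixtures); no geographic realism is claimed.

## evaluate expr under a temporary RNG state; global stream untouched
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

## stable per-variable subseed below 2^31: one master seed fans out so
## adding a generator never perturbs existing outputs
.subseed <- function(seed, name) {
  h <- as.double(seed %% 2147483647)
  for (k in utf8ToInt(name)) h <- (h * 31 + k) %% 2147483629
  as.integer(h)
}

#' Define a synthetic study scenario
#'
#' @param nrow,ncol grid shape (>= 16 each; default 128 x 128).
#' @param cellsize cell size in metres (planar CRS, square cells).
#' @param seed master seed; fixes every generated raster and table
#'   bit-for-bit.
#' @param corLen spatial correlation length in cells.
#' @param relief terrain relief amplitude in metres.
#' @param soilRanges named list of `c(min, max)` overrides for soil and
#'   surface variables (see defaults in the implementation).
#' @param seasonalAmplitude,seasonalPhase named numeric per monthly
#'   climate variable (`wind`, `srad`, `temp`, `rh`); amplitude in the
#'   variable's units, phase in months.
#' @param landuseProportions named proportions over the five land-use
#'   classes (must sum to 1).
#' @param nodataFraction fraction of the grid masked out (shared mask
#'   across all layers).
#' @return a [ScenarioSpec-class].
#' @export
scenarioSpec <- function(nrow = 128, ncol = 128, cellsize = 1000, seed = 1,
                         corLen = 8, relief = 400,
                         soilRanges = list(),
                         seasonalAmplitude = c(wind = 1, srad = 2000,
                                               temp = 5, rh = 12),
                         seasonalPhase = c(wind = 0, srad = 3, temp = 2,
                                           rh = 8),
                         landuseProportions = c(
                           "Forest" = 0.25,
                           "Grass/scrub/woodland" = 0.30,
                           "Barren/very sparsely vegetated land" = 0.12,
                           "Irrigated and rain-fed cultivated land" = 0.28,
                           "Built-up land" = 0.05),
                         nodataFraction = 0.02) {
  defaults <- list(
    groundwater_depth = c(0.5, 80),      # m
    depth_to_bedrock  = c(20, 5000),     # cm
    soil_moisture     = c(2, 40),        # % vol
    soil_thickness    = c(10, 200),      # cm
    organic_matter    = c(0.3, 6),       # %
    organic_carbon    = c(1, 60),        # g/kg
    pH                = c(4.5, 8.5),
    CEC               = c(2, 40),        # cmol(+)/kg
    erosivity         = c(200, 12000),   # MJ.mm/(ha.h.yr)
    evi               = c(0.02, 0.8),
    pet               = c(800, 2200),    # mm/yr
    wind              = c(0.5, 6),       # m/s
    srad              = c(12000, 24000), # kJ/m2/day
    temp              = c(15, 42),       # deg C
    rh                = c(20, 85)        # %
  )
  soilRanges <- utils::modifyList(defaults, soilRanges)
  new("ScenarioSpec",
      nrow = as.integer(nrow), ncol = as.integer(ncol),
      cellsize = cellsize, seed = as.integer(seed), corLen = corLen,
      relief = relief, soilRanges = soilRanges,
      seasonalAmplitude = seasonalAmplitude, seasonalPhase = seasonalPhase,
      landuseProportions = landuseProportions,
      nodataFraction = nodataFraction)
}

setMethod("show", "ScenarioSpec", function(object) {
  cat(sprintf(
    "ScenarioSpec: %d x %d cells of %g m, seed %d, corLen %g, relief %g m\n",
    object@nrow, object@ncol, object@cellsize, object@seed, object@corLen,
    object@relief))
})

## Gaussian-kernel smoothed white noise, rescaled so that the output
## min/max hit the requested range endpoints exactly.
.gaussianField <- function(nr, nc, corLen, seed, range = c(0, 1)) {
  z <- .withSeed(seed, matrix(stats::rnorm(nr * nc), nr, nc))
  if (corLen > 0.5) {
    smoother <- function(n) {
      S <- exp(-outer(seq_len(n), seq_len(n), `-`)^2 / (2 * corLen^2))
      S / rowSums(S)
    }
    z <- smoother(nr) %*% z %*% t(smoother(nc))
  }
  lo <- min(z); hi <- max(z)
  if (hi > lo) z <- (z - lo) / (hi - lo) * (range[2] - range[1]) + range[1]
  else z[] <- range[1]
  z
}

#' Spatially autocorrelated random field
#'
#' Kernel-smoothed Gaussian noise rescaled to a stated range;
#' deterministic per scenario seed and variable name.  A correlation
#' length of 0 recovers white noise.
#'
#' @param spec a [ScenarioSpec-class].
#' @param name variable name (drives the subseed).
#' @param range output range endpoints.
#' @param corLen correlation length override (default: the scenario's).
#' @param mask optional logical matrix of nodata cells to apply.
#' @return a [RasterGrid-class].
#' @export
randomField <- function(spec, name, range = c(0, 1), corLen = spec@corLen,
                        mask = NULL) {
  if (corLen >= min(spec@nrow, spec@ncol))
    stop("correlation length must be smaller than the grid extent",
         call. = FALSE)
  v <- .gaussianField(spec@nrow, spec@ncol, corLen,
                      .subseed(spec@seed, name), range)
  if (!is.null(mask)) v[mask] <- NA_real_
  rasterGrid(v, cellsize = spec@cellsize)
}

#' Shared nodata mask of a scenario
#'
#' A contiguous-blob mask covering about `nodataFraction` of the grid,
#' derived from a smoothed field threshold; shared by every layer of the
#' scenario.
#' @param spec a [ScenarioSpec-class].
#' @return logical matrix (TRUE = nodata).
#' @export
scenarioMask <- function(spec) {
  if (spec@nodataFraction <= 0)
    return(matrix(FALSE, spec@nrow, spec@ncol))
  f <- .gaussianField(spec@nrow, spec@ncol, spec@corLen,
                      .subseed(spec@seed, "nodata_mask"))
  f <= stats::quantile(f, spec@nodataFraction)
}

#' Synthetic digital elevation model
#'
#' `"ridged"` (default): a superposition of a broad-scale correlated
#' surface (ridges and valleys), finer correlated roughness and a gentle
#' regional tilt, scaled to the scenario's relief amplitude; its D8
#' network at the default stream threshold yields several watersheds on a
#' 128 x 128 grid.  `"plane"`: an inclined plane draining to one corner.
#' `"flat"`: constant elevation.
#'
#' @param spec a [ScenarioSpec-class].
#' @param mode `"ridged"`, `"plane"` or `"flat"`.
#' @param mask optional nodata mask.
#' @return a [RasterGrid-class] of elevations (m).
#' @export
synthDem <- function(spec, mode = c("ridged", "plane", "flat"), mask = NULL) {
  mode <- match.arg(mode)
  nr <- spec@nrow; nc <- spec@ncol
  v <- switch(mode,
    flat = matrix(100, nr, nc),
    plane = {
      x <- matrix(rep(seq_len(nc), each = nr), nr, nc)
      y <- matrix(rep(seq_len(nr), nc), nr, nc)
      0.01 * spec@cellsize * (x + 0.5 * y)
    },
    ridged = {
      broad <- .gaussianField(nr, nc, max(spec@corLen * 2.5, 6),
                              .subseed(spec@seed, "dem_broad"))
      fine <- .gaussianField(nr, nc, spec@corLen,
                             .subseed(spec@seed, "dem_fine"))
      tilt <- matrix(rep(seq_len(nc) / nc, each = nr), nr, nc)
      spec@relief * (0.7 * broad + 0.2 * fine + 0.1 * tilt)
    })
  if (!is.null(mask)) v[mask] <- NA_real_
  rasterGrid(v, cellsize = spec@cellsize, units = "m")
}

#' Synthetic monthly climate stack
#'
#' 12 monthly grids: a spatial base field plus a seasonal sinusoid
#' (amplitude and phase from the scenario) plus month-specific noise
#' (SD = 10% of the amplitude).  The sinusoid sums to zero over the
#' twelve months, so the stack's monthly mean equals the base field up to
#' the noise.
#'
#' @param spec a [ScenarioSpec-class].
#' @param variable `"wind"`, `"srad"`, `"temp"` or `"rh"`.
#' @param mask optional nodata mask.
#' @return a temporal [GridStack-class] in the variable's units.
#' @export
synthClimateStack <- function(spec, variable = c("wind", "srad", "temp", "rh"),
                              mask = NULL) {
  variable <- match.arg(variable)
  rng <- spec@soilRanges[[variable]]
  amp <- spec@seasonalAmplitude[[variable]]
  phase <- spec@seasonalPhase[[variable]]
  base <- .gaussianField(spec@nrow, spec@ncol, spec@corLen,
                         .subseed(spec@seed, paste0("climate_", variable)),
                         rng)
  gs <- lapply(1:12, function(i) {
    season <- amp * sin(2 * pi * (i - phase) / 12)
    noise <- .withSeed(
      .subseed(spec@seed, sprintf("climate_%s_noise_%02d", variable, i)),
      matrix(stats::rnorm(spec@nrow * spec@ncol, sd = 0.1 * abs(amp)),
             spec@nrow, spec@ncol))
    v <- base + season + noise
    if (!is.null(mask)) v[mask] <- NA_real_
    rasterGrid(v, cellsize = spec@cellsize, units = variable)
  })
  names(gs) <- as.character(1:12)
  gridStack(gs, temporal = TRUE)
}

## categorical field: latent smoothed field cut at the class proportions
.categoricalField <- function(spec, name, proportions, mask = NULL) {
  f <- .gaussianField(spec@nrow, spec@ncol, spec@corLen,
                      .subseed(spec@seed, name))
  br <- stats::quantile(f, cumsum(proportions))
  br[length(br)] <- Inf
  v <- matrix(findInterval(f, c(-Inf, br[-length(br)])), spec@nrow, spec@ncol)
  if (!is.null(mask)) v[mask] <- NA_real_
  rasterGrid(v, cellsize = spec@cellsize, units = "class")
}

#' Synthetic land-use class grid
#'
#' Categorical classes drawn from a latent correlated field cut at the
#' scenario's class proportions; codes index the five-class vocabulary of
#' [defaultLanduseWeights()].
#' @param spec a [ScenarioSpec-class].
#' @param mask optional nodata mask.
#' @return a [RasterGrid-class] of class codes 1..5.
#' @export
synthLanduse <- function(spec, mask = NULL) {
  .categoricalField(spec, "landuse", spec@landuseProportions, mask)
}

#' Synthetic soil drainage class grid
#'
#' Three infiltration classes (low / moderate / high) from a latent field;
#' default mixture 30/45/25%.
#' @param spec a [ScenarioSpec-class].
#' @param proportions class proportions (sum 1).
#' @param mask optional nodata mask.
#' @return a [RasterGrid-class] of class codes 1..3.
#' @export
synthDrainageClass <- function(spec, proportions = c(0.30, 0.45, 0.25),
                               mask = NULL) {
  .categoricalField(spec, "drainage_class", proportions, mask)
}

#' Synthetic soil-property profile stack
#'
#' Seven depth intervals spanning 0--200 cm, each a correlated field in
#' the variable's range, with a multiplicative depth trend (organic
#' carbon declines with depth; pH drifts slightly upward; other
#' properties stay flat).
#'
#' @param spec a [ScenarioSpec-class].
#' @param variable `"organic_carbon"`, `"clay"`, `"pH"` or `"CEC"`.
#' @param mask optional nodata mask.
#' @return a [SoilProfileStack-class] with 7 layers.
#' @export
synthSoilProfile <- function(spec,
                             variable = c("organic_carbon", "clay", "pH",
                                          "CEC"),
                             mask = NULL) {
  variable <- match.arg(variable)
  iv <- rbind(c(0, 5), c(5, 15), c(15, 30), c(30, 60), c(60, 100),
              c(100, 150), c(150, 200))
  rng <- if (variable == "clay") c(5, 60) else spec@soilRanges[[variable]]
  base <- .gaussianField(spec@nrow, spec@ncol, spec@corLen,
                         .subseed(spec@seed, paste0("profile_", variable)),
                         rng)
  depth_mid <- rowMeans(iv)
  trend <- switch(variable,
    organic_carbon = exp(-depth_mid / 80),
    pH = 1 + 0.02 * depth_mid / 100,
    rep(1, nrow(iv)))
  layers <- lapply(seq_len(nrow(iv)), function(k) {
    wig <- .gaussianField(spec@nrow, spec@ncol, spec@corLen,
                          .subseed(spec@seed,
                                   sprintf("profile_%s_%d", variable, k)),
                          c(0.9, 1.1))
    v <- base * trend[k] * wig
    if (!is.null(mask)) v[mask] <- NA_real_
    rasterGrid(v, cellsize = spec@cellsize, units = variable)
  })
  soilProfileStack(layers, iv)
}

#' Synthetic soil texture fractions
#'
#' Silt, sand and clay percentages from a softmax of three latent fields,
#' so the three fractions sum to exactly 100% at every pixel.
#' @param spec a [ScenarioSpec-class].
#' @param mask optional nodata mask.
#' @return named list of grids `silt`, `sand`, `clay` (%).
#' @export
synthTexture <- function(spec, mask = NULL) {
  parts <- lapply(c("silt", "sand", "clay"), function(nm)
    exp(2 * .gaussianField(spec@nrow, spec@ncol, spec@corLen,
                           .subseed(spec@seed, paste0("texture_", nm)))))
  tot <- Reduce(`+`, parts)
  out <- lapply(parts, function(p) {
    v <- 100 * p / tot
    if (!is.null(mask)) v[mask] <- NA_real_
    rasterGrid(v, cellsize = spec@cellsize, units = "%")
  })
  names(out) <- c("silt", "sand", "clay")
  out
}

#' Generate the full synthetic input set of a scenario
#'
#' Every input raster of the pipeline on one shared grid and nodata mask:
#' DEM, drainage class, groundwater depth, depth to bedrock, soil
#' moisture, soil thickness, texture fractions, organic matter, structure
#' class, soil-profile stacks (organic carbon, clay, pH, CEC), rainfall
#' erosivity, EVI, land use, monthly climate stacks and PET — plus a
#' synthetic residue table.  All outputs are deterministic in the
#' scenario seed.
#'
#' @param spec a [ScenarioSpec-class].
#' @param residueCounts per-(compound, substrate) request for the residue
#'   table (see [synthResidueDb()]); a small default mixture is used when
#'   omitted.
#' @return named list of inputs.
#' @export
synthScenario <- function(spec, residueCounts = NULL) {
  m <- scenarioMask(spec)
  sr <- spec@soilRanges
  tex <- synthTexture(spec, m)
  if (is.null(residueCounts))
    residueCounts <- data.frame(
      compound = c("pp'DDD", "pp'DDD", "endosulfan", "chlorpyrifos"),
      substrate = c("soil", "sediment", "water", "soil"),
      n = c(30, 40, 25, 15))
  list(
    spec = spec,
    mask = m,
    dem = synthDem(spec, "ridged", m),
    drainage_class = synthDrainageClass(spec, mask = m),
    groundwater_depth = randomField(spec, "groundwater_depth",
                                    sr$groundwater_depth, mask = m),
    depth_to_bedrock = randomField(spec, "depth_to_bedrock",
                                   sr$depth_to_bedrock, mask = m),
    soil_moisture = randomField(spec, "soil_moisture", sr$soil_moisture,
                                mask = m),
    soil_thickness = randomField(spec, "soil_thickness", sr$soil_thickness,
                                 mask = m),
    silt = tex$silt, sand = tex$sand, clay = tex$clay,
    organic_matter = randomField(spec, "organic_matter", sr$organic_matter,
                                 mask = m),
    structure_class = .categoricalField(spec, "structure_class",
                                        c(0.2, 0.35, 0.3, 0.15), m),
    oc_profile = synthSoilProfile(spec, "organic_carbon", m),
    clay_profile = synthSoilProfile(spec, "clay", m),
    ph_profile = synthSoilProfile(spec, "pH", m),
    cec_profile = synthSoilProfile(spec, "CEC", m),
    erosivity = randomField(spec, "erosivity", sr$erosivity, mask = m),
    evi = randomField(spec, "evi", sr$evi, mask = m),
    landuse = synthLanduse(spec, m),
    wind = synthClimateStack(spec, "wind", m),
    srad = synthClimateStack(spec, "srad", m),
    temp = synthClimateStack(spec, "temp", m),
    rh = synthClimateStack(spec, "rh", m),
    pet = randomField(spec, "pet", sr$pet, mask = m),
    residues = synthResidueDb(residueCounts, georefFraction = 0.94,
                              seed = .subseed(spec@seed, "residues"))
  )
}

#' Synthetic insecticide-residue table
#'
#' Builds a [ResidueDatabase-class] with exactly the requested number of
#' observations per (compound, substrate) pair.  `round(georefFraction *
#' n)` rows receive coordinates, drawn from `nLocations` distinct sites
#' inside the bounding box (every site is used at least once when enough
#' georeferenced rows exist).  All other schema columns are filled from
#' small realistic vocabularies; a few observations fall below the
#' detection limit and are flagged.
#'
#' @param counts data.frame with columns `compound`, `substrate`, `n`
#'   (non-negative).
#' @param georefFraction fraction of rows with coordinates.
#' @param seed integer seed.
#' @param nLocations number of distinct sampling sites (default about one
#'   per three georeferenced rows; must not exceed their count).
#' @param nStudies size of the source-study vocabulary.
#' @param bbox `(lat_min, lat_max, lon_min, lon_max)`, default continental
#'   Africa.
#' @return a [ResidueDatabase-class].
#' @export
synthResidueDb <- function(counts, georefFraction = 0.94, seed = 1,
                           nLocations = NULL, nStudies = 17,
                           bbox = c(-35, 38, -26, 64)) {
  stopifnot(all(c("compound", "substrate", "n") %in% names(counts)))
  if (any(counts$n < 0)) stop("negative observation counts", call. = FALSE)
  total <- sum(counts$n)
  if (total == 0)
    return(new("ResidueDatabase", data = emptyResidueTable(),
               rejected = cbind(emptyResidueTable(), reason = character(0)),
               bbox = bbox))
  .withSeed(seed, {
    compound <- rep(counts$compound, counts$n)
    substrate <- rep(counts$substrate, counts$n)
    n_geo <- round(georefFraction * total)
    if (is.null(nLocations)) nLocations <- max(1L, round(n_geo / 3))
    if (nLocations > n_geo && n_geo > 0)
      stop("more locations requested than georeferenced rows", call. = FALSE)
    lat <- rep(NA_real_, total); lon <- rep(NA_real_, total)
    if (n_geo > 0) {
      site_lat <- round(stats::runif(nLocations, bbox[1], bbox[2]), 4)
      site_lon <- round(stats::runif(nLocations, bbox[3], bbox[4]), 4)
      geo_rows <- sample(total, n_geo)
      site_of <- c(seq_len(nLocations),
                   sample(nLocations, n_geo - nLocations, replace = TRUE))
      lat[geo_rows] <- site_lat[site_of]
      lon[geo_rows] <- site_lon[site_of]
    }
    cls <- c("pp'DDD" = "organochlorine", "endosulfan" = "organochlorine",
             "chlorpyrifos" = "organophosphate")
    bdl <- stats::runif(total) < 0.05
    conc <- signif(stats::rlnorm(total, meanlog = 1, sdlog = 1.2), 4)
    conc[bdl] <- 0
    df <- data.frame(
      ## every study in the vocabulary contributes at least one row (when
      ## enough rows exist), so the distinct-study count is exact
      study_id = sprintf("study_%02d", if (total >= nStudies)
        sample(c(seq_len(nStudies),
                 sample.int(nStudies, total - nStudies, replace = TRUE)))
        else sample.int(nStudies, total)),
      year = sample(1992:2016, total, replace = TRUE),
      months = sample(c("1-3", "4-6", "7-9", "10-12"), total, replace = TRUE),
      substrate = substrate,
      collection_method = sample(c("grab", "core", "composite"), total,
                                 replace = TRUE),
      depth_cm = sample(c(0, 5, 10, 20), total, replace = TRUE),
      extraction_method = sample(c("soxhlet", "QuEChERS", "LLE"), total,
                                 replace = TRUE),
      quantification_method = sample(c("GC-ECD", "GC-MS", "HPLC"), total,
                                     replace = TRUE),
      detection_limit = 0.001,
      quantification_limit = 0.005,
      compound = compound,
      compound_class = ifelse(compound %in% names(cls), cls[compound],
                              "other"),
      concentration = conc,
      concentration_units = "ug/kg",
      below_detection = bdl,
      latitude = lat,
      longitude = lon,
      stringsAsFactors = FALSE
    )
  })
  new("ResidueDatabase", data = df,
      rejected = cbind(df[0, ], reason = character(0)), bbox = bbox)
}
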
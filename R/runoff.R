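#' Default land-use runoff weights
#'
#' The five-class land-use weighting used by the runoff-generation
#' indicator, expressing how impervious the surface under each class is:
#' Forest 0, Grass/scrub/woodland 0.2, Barren/very sparsely vegetated land
#' 0.6, Irrigated and rain-fed cultivated land 0.8, Built-up land 1.
#'
#' @return named numeric vector of weights in [0, 1].
#' @export
defaultLanduseWeights <- function() {
  c("Forest" = 0,
    "Grass/scrub/woodland" = 0.2,
    "Barren/very sparsely vegetated land" = 0.6,
    "Irrigated and rain-fed cultivated land" = 0.8,
    "Built-up land" = 1)
}

#' Look up land-use runoff weights
#'
#' Per-pixel lookup of the class weight.  The default table covers the
#' five regrouped classes; a 17-class product is first reduced to these
#' five via the editable regrouping config shipped in
#' `inst/extdata/modis17_to_5.yaml`.
#'
#' @param classes a [RasterGrid-class] of integer class codes (indices
#'   into `levels`).
#' @param levels character vector of class names for the codes.
#' @param table named weights per class (default
#'   [defaultLanduseWeights()]).
#' @return a `RasterGrid` in [0, 1].
#' @export
landuseWeights <- function(classes, levels = names(defaultLanduseWeights()),
                           table = defaultLanduseWeights()) {
  missing_cls <- setdiff(levels, names(table))
  if (length(missing_cls))
    stop("land-use class(es) not in weight table: ",
         paste(missing_cls, collapse = ", "), call. = FALSE)
  v <- classes@values
  codes <- v[!is.na(v)]
  if (length(codes) && (any(codes < 1) || any(codes > length(levels))))
    stop("land-use class code outside the level vocabulary", call. = FALSE)
  out <- asGrid(classes)
  sv <- matrix(NA_real_, nrow(v), ncol(v))
  sv[!is.na(v)] <- unname(table[levels[codes]])
  out@values <- sv
  out@units <- "1"
  out
}

#' Topography indicator for runoff generation
#'
#' The arithmetic mean of the normalized slope and the normalized
#' topographic wetness index.
#'
#' @param slope_n,twi_n aligned normalized grids.
#' @return a `RasterGrid` in [0, 1].
#' @export
topographyIndicator <- function(slope_n, twi_n) {
  assertAligned(slope_n, twi_n)
  out <- combineLinear(list(slope_n, twi_n), c(0.5, 0.5))
  out@units <- "1"
  out
}

.check_unit <- function(g, nm) {
  v <- g@values[!is.na(g@values)]
  if (length(v) && (min(v) < -1e-9 || max(v) > 1 + 1e-9))
    stop("runoff indicator '", nm, "' is not normalized to [0, 1]",
         call. = FALSE)
}

## mean of normalized indicators, optionally renormalized; the continuous
## analogue of summing binary susceptibility indicators
.indicatorScore <- function(grids, rescale, process, provenance) {
  for (nm in names(grids)) .check_unit(grids[[nm]], nm)
  ## sum first, divide once: exactly rounded, so binary indicators give
  ## score * count == classical integer score bit-for-bit
  score <- combineLinear(unname(grids), rep(1, length(grids)))
  score@values <- score@values / length(grids)
  if (rescale) score <- normalizeMinMax(score)
  score@units <- "1"
  processMap(score, process, provenance = provenance)
}

#' Surface-runoff generation susceptibility
#'
#' Mean of five normalized indicators: complemented drainage score
#' (impermeable soil generates runoff), complemented soil thickness (thin
#' soil saturates quickly), soil erodibility, the topography indicator and
#' the land-use weight.  Continuous [0, 1] indicators replace the binary
#' indicators of the classical susceptibility scoring: with binary inputs
#' the score times the indicator count recovers the classical integer
#' score exactly.
#'
#' @param drainage_score,soil_thickness_n,erodibility_n,topo_n,landuse_w
#'   aligned normalized grids.
#' @param rescale renormalize the mean to span [0, 1] (default `TRUE`).
#' @return a [ProcessMap-class] tagged `"runoff_generation"`.
#' @export
runoffGeneration <- function(drainage_score, soil_thickness_n, erodibility_n,
                             topo_n, landuse_w, rescale = TRUE) {
  .indicatorScore(
    list(drainage = gridComplement(drainage_score),
         thickness = gridComplement(soil_thickness_n),
         erodibility = erodibility_n, topography = topo_n,
         landuse = landuse_w),
    rescale, "runoff_generation",
    c("drainage class", "soil thickness", "erodibility", "slope+TWI",
      "land use"))
}

#' Surface-runoff transfer susceptibility
#'
#' Mean of the three indicators available at continental extent:
#' generation susceptibility, normalized slope (steep slopes transfer) and
#' the normalized catchment form factor (compact catchments transfer,
#' configurable orientation).  Break of slope and artificial linear axes
#' are not modelled.
#'
#' @param gen a `"runoff_generation"` [ProcessMap-class].
#' @param slope_n,form_factor_n aligned normalized grids.
#' @param rescale renormalize to span [0, 1].
#' @return a [ProcessMap-class] tagged `"runoff_transfer"`.
#' @export
runoffTransfer <- function(gen, slope_n, form_factor_n, rescale = TRUE) {
  .indicatorScore(
    list(generation = asGrid(gen), slope = slope_n,
         form_factor = form_factor_n),
    rescale, "runoff_transfer",
    c("runoff generation", "slope", "Horton form factor"))
}

#' Surface-runoff accumulation susceptibility
#'
#' Mean of four indicators: generation susceptibility, complemented slope
#' (runoff accumulates where the terrain flattens), normalized TWI and
#' normalized flow accumulation.  Break of slope is not modelled.
#'
#' @param gen a `"runoff_generation"` [ProcessMap-class].
#' @param slope_n,twi_n,flow_acc_n aligned normalized grids.
#' @param rescale renormalize to span [0, 1].
#' @return a [ProcessMap-class] tagged `"runoff_accumulation"`.
#' @export
runoffAccumulation <- function(gen, slope_n, twi_n, flow_acc_n,
                               rescale = TRUE) {
  .indicatorScore(
    list(generation = asGrid(gen), flat = gridComplement(slope_n),
         twi = twi_n, accumulation = flow_acc_n),
    rescale, "runoff_accumulation",
    c("runoff generation", "slope", "TWI", "flow accumulation"))
}

#' Read a land-cover regrouping table
#'
#' Maps the classes of a finer land-cover product onto the five runoff
#' weight classes.  The shipped default regroups the 17 IGBP-style classes.
#'
#' @param path YAML file `original_class: target_class`; default the
#'   packaged table.
#' @return named character vector.
#' @export
readLanduseRegrouping <- function(path = system.file("extdata",
                                                     "modis17_to_5.yaml",
                                                     package = "pestfate")) {
  map <- yaml::read_yaml(path)
  targets <- names(defaultLanduseWeights())
  bad <- setdiff(unique(unlist(map)), targets)
  if (length(bad))
    stop("regrouping targets unknown to the weight table: ",
         paste(bad, collapse = ", "), call. = FALSE)
  unlist(map)
}
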
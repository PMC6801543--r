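## USLE-based erosion, watershed sediment load, stream velocity and the
## combined sedimentation-vulnerability map.

## apply an elementwise function over numerics and/or aligned grids
.elementwise <- function(f, args, units = "") {
  gs <- Filter(function(a) is(a, "RasterGrid"), args)
  if (!length(gs)) return(do.call(f, args))
  assertAligned(gs)
  vals <- lapply(args, function(a) if (is(a, "RasterGrid")) a@values else a)
  out <- asGrid(gs[[1]])
  out@values <- do.call(f, vals)
  out@units <- units
  out
}

#' USLE textural factor M
#'
#' From the silt, sand and clay percentages, with the very fine sand
#' fraction taken as 20% of the sand fraction.  The default dialect is the
#' standard nomograph form `M = (msilt + mvfs) * (100 - mclay)`; the
#' alternative `as_printed` dialect evaluates
#' `msilt + mvfs * (100 - mclay)` (a parenthesization that circulates in
#' some sources).
#'
#' @param msilt,msand,mclay texture percentages (numerics or aligned
#'   [RasterGrid-class] objects).
#' @param dialect `"standard"` or `"as_printed"`.
#' @return same shape as the inputs.
#' @examples
#' texturalFactorM(30, 40, 20)                 # (30 + 8) * 80 = 3040
#' texturalFactorM(30, 40, 20, "as_printed")   # 30 + 8 * 80 = 670
#' @export
texturalFactorM <- function(msilt, msand, mclay,
                            dialect = c("standard", "as_printed")) {
  dialect <- match.arg(dialect)
  .elementwise(function(si, sa, cl) {
    if (any(si < 0 | sa < 0 | cl < 0, na.rm = TRUE))
      stop("texture fractions must be non-negative", call. = FALSE)
    mvfs <- 0.2 * sa
    if (dialect == "standard") (si + mvfs) * (100 - cl)
    else si + mvfs * (100 - cl)
  }, list(msilt, msand, mclay))
}

#' USLE soil erodibility K
#'
#' Wischmeier--Smith nomograph:
#' `K = ((2.1e-4 * M^1.14 * (12 - OM) + 3.25 * (s - 2) + 2.5 * (p - 3)) / 100) * 0.1317`
#' in (t ha h)/(ha MJ mm), floored at 0 (the nomograph can go negative for
#' extreme inputs).
#'
#' @param M textural factor (see [texturalFactorM()]).
#' @param OM organic matter content, %.
#' @param s_class soil structure class 1--4 (1 very fine granular ...
#'   4 blocky/platy/massive).
#' @param p_class soil drainage (permeability) class.
#' @return erodibility, same shape as the inputs.
#' @examples
#' erodibilityK(3040, 2, 2, 3)   # ~0.0259
#' @export
erodibilityK <- function(M, OM, s_class, p_class) {
  .elementwise(function(M, OM, s, p) {
    if (any(M < 0, na.rm = TRUE)) stop("M must be non-negative", call. = FALSE)
    if (any(!(s %in% 1:4) & !is.na(s)))
      stop("structure class must be in 1..4", call. = FALSE)
    K <- ((2.1e-4 * M^1.14 * (12 - OM) + 3.25 * (s - 2) + 2.5 * (p - 3)) / 100) *
      0.1317
    pmax(K, 0)
  }, list(M, OM, s_class, p_class), units = "t.ha.h/(ha.MJ.mm)")
}

#' USLE slope-steepness factor S
#'
#' Two-branch form with the break at a 9% slope, tested on `tan(theta)`:
#' `S = 10.8 sin(theta) + 0.03` below 9%, `16.8 sin(theta) - 0.5` at or
#' above.  The jump at the breakpoint is below 0.01.  Slope length is not
#' modelled (it acts at much finer resolution than the working grid), so
#' the topographic factor reduces to S.
#'
#' @param theta_deg slope in degrees (0--90).
#' @return S, same shape as the input.
#' @examples
#' slopeFactorS(5)            # 10.8 * sin(5 deg) + 0.03
#' slopeFactorS(atan(0.2) * 180 / pi)   # 20% slope, steep branch
#' @export
slopeFactorS <- function(theta_deg) {
  .elementwise(function(th) {
    if (any(th < 0 | th > 90, na.rm = TRUE))
      stop("slope must be within 0..90 degrees", call. = FALSE)
    rad <- th * pi / 180
    ifelse(tan(rad) < 0.09, 10.8 * sin(rad) + 0.03, 16.8 * sin(rad) - 0.5)
  }, list(theta_deg))
}

#' Cover-management factor C from vegetation index
#'
#' The enhanced vegetation index is used as a proxy for cover management:
#' dense vegetation protects the soil, so `C = 1 - EVI_n`, clipped to
#' [0, 1].
#'
#' @param evi_n normalized vegetation index (grid or numeric, [0, 1]).
#' @return C, same shape as the input.
#' @export
coverFactorC <- function(evi_n) {
  .elementwise(function(e) pmin(pmax(1 - e, 0), 1), list(evi_n), units = "1")
}

#' USLE erosion rate
#'
#' `E = R * K * C * S` in t/ha/yr.  The support-practice factor is
#' excluded (no spatial data exist for it, so P = 1), and the topographic
#' factor is the slope-steepness factor S alone.
#'
#' @param R rainfall erosivity (MJ mm / (ha h yr)).
#' @param K erodibility (see [erodibilityK()]).
#' @param C cover factor (see [coverFactorC()]).
#' @param S slope factor (see [slopeFactorS()]).
#' @return erosion rate, non-negative, same shape as the inputs.
#' @export
usleErosion <- function(R, K, C, S) {
  .elementwise(function(R, K, C, S) {
    if (any(R < 0 | K < 0 | C < 0 | S < 0, na.rm = TRUE))
      stop("USLE factors must be non-negative", call. = FALSE)
    R * K * C * S
  }, list(R, K, C, S), units = "t/ha/yr")
}

#' Watershed sediment load
#'
#' The sediment load of a watershed is the sum of erosion over its cells:
#' `sum(E * cell_area_ha)` in t/yr.
#'
#' @param E erosion grid (t/ha/yr), aligned with the partition.
#' @param ws a [WatershedPartition-class].
#' @param cell_area_ha cell area in hectares.
#' @return data.frame with columns `id`, `load_t_yr`.
#' @export
sedimentLoad <- function(E, ws, cell_area_ha) {
  stopifnot(identical(dim(E@values), dim(ws@labels)))
  lab <- as.vector(ws@labels)
  ev <- as.vector(E@values) * cell_area_ha
  keep <- !is.na(lab) & lab > 0L & !is.na(ev)
  sums <- tapply(ev[keep], lab[keep], sum)
  load <- numeric(nrow(ws@records))
  load[as.integer(names(sums))] <- as.numeric(sums)
  data.frame(id = ws@records$id, load_t_yr = load)
}

#' Stream velocity within watersheds
#'
#' On stream cells, `V = V_m * s^b * A^c / mean(s^b * A^c)`, where the
#' mean is taken over the watershed's stream cells, `A` is the flow
#' accumulation, `s` the normalized slope floored at 1e-4, and `V_m` the
#' watershed's velocity scale (its mean normalized slope).  By
#' construction, the watershed mean of V equals `V_m`.  Off-stream cells
#' are nodata (sedimentation takes place in the streams).
#'
#' @param slope_n normalized slope grid.
#' @param flow a [FlowField-class].
#' @param ws a [WatershedPartition-class].
#' @param b,c slope-area exponents (both 0.5).
#' @param slope_floor lower bound on slope.
#' @return a [RasterGrid-class], valid on stream cells only.
#' @export
streamVelocity <- function(slope_n, flow, ws, b = 0.5, c = 0.5,
                           slope_floor = 1e-4) {
  stopifnot(identical(dim(slope_n@values), dim(ws@labels)))
  sidx <- which(flow@streamMask)
  if (!length(sidx)) stop("flow field has no stream cells", call. = FALSE)
  seg <- ws@labels[sidx]
  if (any(is.na(seg) | seg <= 0L))
    stop("stream cells must belong to a watershed", call. = FALSE)
  sv <- as.vector(slope_n@values)
  lab <- as.vector(ws@labels)
  keep <- !is.na(lab) & lab > 0L & !is.na(sv)
  vm_tab <- tapply(sv[keep], lab[keep], mean)
  Vm <- numeric(nrow(ws@records))
  Vm[as.integer(names(vm_tab))] <- as.numeric(vm_tab)
  s <- pmax(sv[sidx], slope_floor)
  term <- s^b * flow@accumulation[sidx]^c
  tm_tab <- tapply(term, seg, mean)
  tmean <- numeric(nrow(ws@records))
  tmean[as.integer(names(tm_tab))] <- as.numeric(tm_tab)
  out <- matrix(NA_real_, nrow(ws@labels), ncol(ws@labels))
  out[sidx] <- Vm[seg] * term / tmean[seg]
  rasterGrid(out, xmin = ws@xmin, ymax = ws@ymax, cellsize = ws@cellsize,
             units = "1")
}

#' Sedimentation vulnerability index
#'
#' Sedimentation is favoured where the sediment load is high and the
#' stream velocity low: per-pixel `load_n * (1 - V_n)` over the min--max
#' normalized load and velocity maps, renormalized to [0, 1].
#'
#' @param load_g sediment-load grid (e.g. the per-watershed load broadcast
#'   with [wsField()]).
#' @param V velocity grid (see [streamVelocity()]; off-stream cells may
#'   carry the watershed velocity scale so the map covers the full
#'   extent).
#' @return a [ProcessMap-class] tagged `"sedimentation"`.
#' @export
sedimentationIndex <- function(load_g, V) {
  assertAligned(load_g, V)
  ln <- normalizeMinMax(load_g)
  vn <- normalizeMinMax(V)
  raw <- ln * gridComplement(vn)
  processMap(normalizeMinMax(raw), "sedimentation",
             provenance = c("USLE erosion", "watershed sediment load",
                            "stream velocity"))
}
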
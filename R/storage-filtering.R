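#' Soil storage and filtering capacity
#'
#' The unweighted linear index `SFC = OC + clay + (1 - pH) + CEC` over
#' normalized inputs, min--max normalized to [0, 1].  Each input is a soil
#' property collapsed from its depth intervals with
#' [depthWeightedAverage()] and then normalized (depth aggregation
#' precedes normalization).  Low SFC flags areas more susceptible to
#' pesticide fate: such soils hold and filter little.
#'
#' @param x named list of aligned [RasterGrid-class] inputs `OC` (organic
#'   carbon), `clay`, `pH`, `CEC`, all in [0, 1].
#' @param rescale if `FALSE`, return the raw sum (0..4) as a plain
#'   `RasterGrid`.
#' @return a [ProcessMap-class] tagged `"storage_filtering"` (or a
#'   `RasterGrid` when `rescale = FALSE`).
#' @export
storageFilteringCapacity <- function(x, rescale = TRUE) {
  need <- c("OC", "clay", "pH", "CEC")
  if (!all(need %in% names(x)))
    stop("storage/filtering inputs must include ",
         paste(need, collapse = ", "), call. = FALSE)
  for (nm in need) {
    v <- x[[nm]]@values[!is.na(x[[nm]]@values)]
    if (length(v) && (min(v) < -1e-9 || max(v) > 1 + 1e-9))
      stop("input '", nm, "' is not normalized to [0, 1]", call. = FALSE)
  }
  raw <- combineLinear(
    list(x$OC, x$clay, gridComplement(x$pH), x$CEC),
    c(1, 1, 1, 1)
  )
  if (!rescale) return(raw)
  processMap(normalizeMinMax(raw), "storage_filtering",
             provenance = c("organic carbon", "clay", "pH", "CEC"))
}
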
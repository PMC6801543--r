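#' Default leaching index weights
#'
#' The weights of the DRASTIC-style leaching index, in order: drainage
#' score (5), complemented groundwater depth (5), complemented depth to
#' bedrock (2), complemented slope (1), soil moisture (5).  Read-only;
#' alternative weights enter only through the `weights` argument of
#' [leachingVulnerability()] (used by the sensitivity analysis).
#'
#' @return named numeric vector `c(D = 5, GW = 5, DB = 2, SL = 1, SM = 5)`.
#' @export
leachingWeights <- function() {
  c(D = 5, GW = 5, DB = 2, SL = 1, SM = 5)
}

#' Score the ordinal soil drainage class
#'
#' Maps the three infiltration-rate classes (low < 15 mm/h, moderate
#' 15--50 mm/h, high > 50 mm/h) to an equally spaced [0, 1] score: higher
#' infiltration means higher leaching propensity.  The class bounds are
#' physical but carry no numeric coding, so the spacing is configurable.
#'
#' @param classes a [RasterGrid-class] of integer class codes (indices
#'   into `levels`).
#' @param levels class vocabulary, default `c("low", "moderate", "high")`.
#' @param scores named numeric scores per level.
#' @return a `RasterGrid` in [0, 1].
#' @export
drainageClassScore <- function(classes,
                               levels = c("low", "moderate", "high"),
                               scores = c(low = 0, moderate = 0.5, high = 1)) {
  if (!all(levels %in% names(scores)))
    stop("scores must name every class level", call. = FALSE)
  v <- classes@values
  codes <- v[!is.na(v)]
  if (length(codes) && (any(codes < 1) || any(codes > length(levels)) ||
                        any(codes != round(codes))))
    stop("unknown drainage class code(s): ",
         paste(unique(codes[codes < 1 | codes > length(levels) |
                              codes != round(codes)]), collapse = ", "),
         call. = FALSE)
  out <- asGrid(classes)
  sv <- matrix(NA_real_, nrow(v), ncol(v))
  sv[!is.na(v)] <- unname(scores[levels[codes]])
  out@values <- sv
  out@units <- "1"
  out
}

#' Leaching vulnerability (DRASTIC-weighted index)
#'
#' The weighted index
#' `L = 5 D + 5 (1 - GW) + 2 (1 - DB) + (1 - SL) + 5 SM`
#' over normalized inputs: drainage score `D`, groundwater depth `GW`,
#' depth to bedrock `DB`, slope `SL` and mean soil moisture `SM`.  Raw
#' depths and slope are normalized first and complemented inside the index
#' (a shallow water table means more leaching).  The result is min--max
#' normalized to [0, 1] over the valid extent.
#'
#' @param x named list of aligned [RasterGrid-class] inputs `D`, `GW`,
#'   `DB`, `SL`, `SM`, all in [0, 1].
#' @param weights index weights (default [leachingWeights()]).
#' @param rescale if `FALSE`, return the raw weighted sum (range 0 to
#'   `sum(weights)`) as a plain `RasterGrid` instead of a normalized
#'   [ProcessMap-class].
#' @return a `ProcessMap` tagged `"leaching"` (or a `RasterGrid` when
#'   `rescale = FALSE`).
#' @export
leachingVulnerability <- function(x, weights = leachingWeights(),
                                  rescale = TRUE) {
  need <- c("D", "GW", "DB", "SL", "SM")
  if (!all(need %in% names(x)))
    stop("leaching inputs must include ", paste(need, collapse = ", "),
         call. = FALSE)
  for (nm in need) {
    v <- x[[nm]]@values[!is.na(x[[nm]]@values)]
    if (length(v) && (min(v) < -1e-9 || max(v) > 1 + 1e-9))
      stop("leaching input '", nm, "' is not normalized to [0, 1]",
           call. = FALSE)
  }
  stopifnot(length(weights) == 5L)
  raw <- combineLinear(
    list(x$D, gridComplement(x$GW), gridComplement(x$DB),
         gridComplement(x$SL), x$SM),
    unname(weights)
  )
  if (!rescale) return(raw)
  processMap(normalizeMinMax(raw), "leaching",
             provenance = c("drainage class", "groundwater depth",
                            "depth to bedrock", "slope", "soil moisture"))
}
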
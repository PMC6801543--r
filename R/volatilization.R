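#' Monthly volatilization-associated variable
#'
#' For month `i`,
#' `V_i = WV_i + Srad_i + T_i + PET + (1 - RH_i)`
#' over normalized inputs: wind velocity, solar radiation, day-time
#' surface temperature and relative humidity as monthly stacks, and the
#' long-term annual potential evapotranspiration entering every month
#' identically (it is an annual-only product).  Monthly stacks should be
#' normalized across the whole 12-band stack (see
#' [normalizeMinMax()][normalizeMinMax,GridStack-method]) so months remain
#' comparable.  The result ranges over [0, 5] and is not yet normalized.
#'
#' @param x named list with temporal [GridStack-class] members `WV`,
#'   `Srad`, `T`, `RH` (12 normalized bands each) and a [RasterGrid-class]
#'   `PET` (normalized), all aligned.
#' @param month month index 1--12.
#' @return a `RasterGrid` (range 0..5).
#' @export
monthlyVolatilization <- function(x, month) {
  need <- c("WV", "Srad", "T", "RH", "PET")
  if (!all(need %in% names(x)))
    stop("volatilization inputs must include ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!(length(month) == 1L && month %in% 1:12))
    stop("month must be a single integer in 1..12", call. = FALSE)
  for (nm in c("WV", "Srad", "T", "RH")) {
    stk <- x[[nm]]
    if (!is(stk, "GridStack") || !stk@temporal)
      stop("input '", nm, "' must be a 12-month GridStack", call. = FALSE)
  }
  m <- as.character(month)
  combineLinear(
    list(x$WV[[m]], x$Srad[[m]], x$T[[m]], x$PET,
         gridComplement(x$RH[[m]])),
    c(1, 1, 1, 1, 1)
  )
}

#' Annual mean and seasonal dispersion of monthly maps
#'
#' Per-pixel mean of the 12 monthly values (min--max normalized into a
#' [ProcessMap-class]) and their population standard deviation (divisor
#' 12, since the 12 months are the complete seasonal cycle, not a sample
#' from it).  The SD is 0 exactly where the seasonal cycle is constant.
#'
#' @param months a temporal [GridStack-class] (or list of 12 aligned
#'   grids) of monthly values.
#' @param process process tag for the mean map (default
#'   `"volatilization"`).
#' @return list with members `mean` (a `ProcessMap`) and `sd` (a
#'   `RasterGrid`).
#' @export
annualSummary <- function(months, process = "volatilization") {
  gs <- if (is(months, "GridStack")) months@grids else months
  if (length(gs) != 12L)
    stop("an annual summary needs exactly 12 monthly grids", call. = FALSE)
  assertAligned(gs)
  mean_g <- combineLinear(gs, rep(1, 12))
  mean_g@values <- mean_g@values / 12
  sq <- lapply(gs, function(g) {
    d <- g@values - mean_g@values
    d * d
  })
  var_v <- Reduce(`+`, sq) / 12
  ## a seasonally constant pixel has SD exactly 0 (guard against the
  ## rounding of sum/12 leaving ~1e-17 residues)
  mn <- Reduce(pmin, lapply(gs, function(g) g@values))
  mx <- Reduce(pmax, lapply(gs, function(g) g@values))
  var_v[!is.na(mn) & mn == mx] <- 0
  sd_g <- asGrid(gs[[1]])
  sd_g@values <- sqrt(var_v)
  sd_g@units <- ""
  list(
    mean = processMap(normalizeMinMax(mean_g), process,
                      provenance = c("wind velocity", "solar radiation",
                                     "surface temperature", "PET",
                                     "relative humidity")),
    sd = sd_g
  )
}
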
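## One-at-a-time sensitivity analysis: perturb each raw input by +/-5%
## (before any normalization), re-run the full pipeline, and report the
## mean pixel-relative output change and its dispersion.

.scaleInput <- function(x, fac) {
  if (is(x, "GridStack")) {
    x@grids <- lapply(x@grids, function(g) { g@values <- g@values * fac; g })
    x
  } else if (is(x, "SoilProfileStack")) {
    x@layers <- lapply(x@layers, function(g) { g@values <- g@values * fac; g })
    x
  } else if (is(x, "RasterGrid")) {
    x@values <- x@values * fac
    x
  } else if (is.numeric(x)) {
    x * fac
  } else {
    stop("cannot perturb input of class ", class(x)[1], call. = FALSE)
  }
}

.pixelChanges <- function(base, pert, eps = 1e-9) {
  b <- if (is(base, "RasterGrid")) as.vector(base@values) else as.numeric(base)
  p <- if (is(pert, "RasterGrid")) as.vector(pert@values) else as.numeric(pert)
  keep <- !is.na(b) & !is.na(p) & abs(b) >= eps
  100 * abs(p[keep] - b[keep]) / abs(b[keep])
}

#' One-at-a-time sensitivity to an input variable
#'
#' Scales the named raw input by `(1 + delta)`, re-runs the full model
#' pipeline (including any re-normalization inside it), and summarizes the
#' per-pixel relative change `100 * |out' - out| / out` over valid pixels
#' (pixels where the baseline output is below 1e-9 are excluded).  Because
#' the perturbation is applied to the raw input before normalization, the
#' response of a renormalized index can be asymmetric between `+delta`
#' and `-delta`.
#'
#' @param model a function taking the input list and returning a grid (or
#'   `ProcessMap`).
#' @param inputs named list of raw model inputs (grids, stacks, profile
#'   stacks or numerics).
#' @param variable name of the input to perturb; must exist in `inputs`.
#' @param delta signed relative perturbation (default +0.05).
#' @param process optional process label for the record.
#' @return one-row data.frame: `process`, `variable`, `delta`,
#'   `mean_change_pct`, `change_dispersion` (pixel SD of the relative
#'   change).
#' @export
oatVariable <- function(model, inputs, variable, delta = 0.05,
                        process = "") {
  if (!variable %in% names(inputs))
    stop("unknown model variable: ", variable, call. = FALSE)
  base <- model(inputs)
  inputs2 <- inputs
  inputs2[[variable]] <- .scaleInput(inputs2[[variable]], 1 + delta)
  pert <- model(inputs2)
  ch <- .pixelChanges(base, pert)
  data.frame(
    process = process, variable = variable, delta = delta,
    mean_change_pct = if (length(ch)) mean(ch) else NA_real_,
    change_dispersion = if (length(ch) > 1L) stats::sd(ch) else 0
  )
}

#' Sensitivity table over all variables of a model
#'
#' Runs [oatVariable()] for every named input at each `delta` and binds
#' the records into one table, one row per (variable, delta).
#'
#' @inheritParams oatVariable
#' @param variables which inputs to perturb (default: all).
#' @param deltas perturbations (default `c(-0.05, +0.05)`).
#' @return data.frame of sensitivity records.
#' @export
sensitivityTable <- function(model, inputs, variables = names(inputs),
                             deltas = c(-0.05, 0.05), process = "") {
  rows <- list()
  for (v in variables)
    for (d in deltas)
      rows[[length(rows) + 1L]] <- oatVariable(model, inputs, v, d, process)
  do.call(rbind, rows)
}

#' Sensitivity of the leaching index to its weights
#'
#' Shifts each of the five leaching weights one at a time by
#' `+/- deviation` points, keeping only shifts that stay within the
#' weights' 1--5 range (shifts that would leave it are excluded from the
#' average, so every applied shift has magnitude exactly `deviation`).
#' The full pipeline, including the final renormalization, is re-run for
#' each shifted weight vector and the per-pixel relative changes are
#' pooled over all applied shifts.  On synthetic inputs the response is
#' near-proportional to the deviation.
#'
#' @param inputs named list of normalized leaching inputs (see
#'   [leachingVulnerability()]).
#' @param deviation integer number of points, 0--4 (the weights live on a
#'   1--5 scale, so a deviation of 5 or more is an error).
#' @param weights baseline weights (default [leachingWeights()]).
#' @return one-row data.frame: `process`, `variable`, `delta`,
#'   `mean_change_pct`, `change_dispersion`, plus `n_shifts`, the number
#'   of in-range shifts averaged over.
#' @export
oatLeachingWeights <- function(inputs, deviation,
                               weights = leachingWeights()) {
  if (length(deviation) != 1L || deviation != round(deviation) ||
      deviation < 0)
    stop("deviation must be a single non-negative integer", call. = FALSE)
  if (deviation >= 5)
    stop("deviation must stay below the 1..5 weight range width",
         call. = FALSE)
  base <- leachingVulnerability(inputs, weights = weights)
  changes <- list()
  n_shifts <- 0L
  if (deviation > 0) {
    for (j in seq_along(weights)) {
      for (sgn in c(-1, 1)) {
        w2 <- weights
        w2[j] <- w2[j] + sgn * deviation
        if (w2[j] < 1 || w2[j] > 5) next
        n_shifts <- n_shifts + 1L
        pert <- leachingVulnerability(inputs, weights = w2)
        changes[[n_shifts]] <- .pixelChanges(base, pert)
      }
    }
  }
  ch <- unlist(changes)
  data.frame(
    process = "leaching", variable = "weights", delta = deviation,
    mean_change_pct = if (length(ch)) mean(ch) else 0,
    change_dispersion = if (length(ch) > 1L) stats::sd(ch) else 0,
    n_shifts = n_shifts
  )
}
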
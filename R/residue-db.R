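## Insecticide-residue observation database: load, validate, summarize.

#' Mandatory residue-table columns
#'
#' The schema systematically extracted from residue studies: study,
#' sampling year and months, sample collection method and depth,
#' extraction and quantification methods, their limits, compound and
#' compound class, measured concentration with units, a below-detection
#' flag and coordinates.
#' @return character vector of column names.
#' @export
residueColumns <- function() {
  c("study_id", "year", "months", "substrate", "collection_method",
    "depth_cm", "extraction_method", "quantification_method",
    "detection_limit", "quantification_limit", "compound",
    "compound_class", "concentration", "concentration_units",
    "below_detection", "latitude", "longitude")
}

#' @rdname residueColumns
#' @export
emptyResidueTable <- function() {
  df <- data.frame(
    study_id = character(0), year = integer(0), months = character(0),
    substrate = character(0), collection_method = character(0),
    depth_cm = numeric(0), extraction_method = character(0),
    quantification_method = character(0), detection_limit = numeric(0),
    quantification_limit = numeric(0), compound = character(0),
    compound_class = character(0), concentration = numeric(0),
    concentration_units = character(0), below_detection = logical(0),
    latitude = numeric(0), longitude = numeric(0),
    stringsAsFactors = FALSE)
  df
}

.substrates <- c("soil", "sediment", "water", "air")

#' Load and validate a residue CSV
#'
#' Reads the observation table, applies an optional column-name
#' normalization map (deposited files vary in their headers), and
#' validates every row against the hard invariants: substrate from the
#' four-term vocabulary (soil, sediment, water, air) and concentration
#' non-negative unless flagged below detection.  Violating rows are
#' rejected into a side table with a reason, never silently dropped.
#' Coordinates outside the bounding box do not reject a row; the row is
#' simply not georeferenced for the funnel counts.
#'
#' @param path CSV file with a header.
#' @param bbox georeferencing bounding box
#'   `(lat_min, lat_max, lon_min, lon_max)`; default continental Africa
#'   (-35..38, -26..64).
#' @param column_map optional named character vector `file_header ->
#'   canonical_name`.
#' @param quiet suppress the accepted/rejected message.
#' @return a [ResidueDatabase-class].
#' @export
readResidueCsv <- function(path, bbox = c(-35, 38, -26, 64),
                           column_map = NULL, quiet = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(column_map)) {
    hit <- names(df) %in% names(column_map)
    names(df)[hit] <- unname(column_map[names(df)[hit]])
  }
  missing_cols <- setdiff(residueColumns(), names(df))
  if (length(missing_cols))
    stop("residue table is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  df <- df[residueColumns()]
  reason <- rep(NA_character_, nrow(df))
  bad_sub <- !(df$substrate %in% .substrates)
  reason[bad_sub] <- paste0("substrate not in {",
                            paste(.substrates, collapse = ", "), "}: ",
                            df$substrate[bad_sub])
  bad_conc <- !is.na(df$concentration) & df$concentration < 0 &
    !isTRUE_vec(df$below_detection)
  reason[is.na(reason) & bad_conc] <- "negative concentration"
  ok <- is.na(reason)
  db <- new("ResidueDatabase",
            data = df[ok, , drop = FALSE],
            rejected = cbind(df[!ok, , drop = FALSE],
                             reason = reason[!ok]),
            bbox = bbox)
  if (!quiet)
    message(sum(ok), " observation(s) accepted, ", sum(!ok), " rejected")
  db
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

#' Write the accepted observations back to CSV
#'
#' Round-trips losslessly through [readResidueCsv()].
#' @param db a [ResidueDatabase-class].
#' @param path output CSV path.
#' @export
writeResidueCsv <- function(db, path) {
  utils::write.csv(db@data, path, row.names = FALSE, na = "")
  invisible(path)
}

## georeferenced = coordinates present and inside the bounding box
.isGeoref <- function(df, bbox) {
  !is.na(df$latitude) & !is.na(df$longitude) &
    df$latitude >= bbox[1] & df$latitude <= bbox[2] &
    df$longitude >= bbox[3] & df$longitude <= bbox[4]
}

#' Residue extraction funnel
#'
#' Counts observations, georeferenced observations, per-substrate counts
#' (among georeferenced observations, which is why they may sum to less
#' than the total), distinct compounds, distinct studies, and — for the
#' (optionally filtered) selection — observations and unique sampling
#' locations.
#' Unique locations are distinct (latitude, longitude) pairs at full
#' stored precision among georeferenced rows (set `location_digits` to
#' round before pairing).  Filtering by an unknown compound yields an
#' all-zero report, not an error.
#'
#' @param db a [ResidueDatabase-class].
#' @param compound optional compound filter.
#' @param substrates optional substrate filter.
#' @param location_digits optional rounding (decimal places) applied to
#'   coordinates before counting unique locations.
#' @return a list of class `"residueFunnel"`: `total_observations`,
#'   `georeferenced`, `substrate_counts`, `distinct_compounds`,
#'   `distinct_studies`, `selected_observations`,
#'   `selected_by_substrate`, `selected_locations`.
#' @export
residueFunnel <- function(db, compound = NULL, substrates = NULL,
                          location_digits = NULL) {
  df <- db@data
  geo <- .isGeoref(df, db@bbox)
  sel <- rep(TRUE, nrow(df))
  if (!is.null(compound)) sel <- sel & df$compound %in% compound
  if (!is.null(substrates)) sel <- sel & df$substrate %in% substrates
  sub_counts <- vapply(.substrates,
                       function(s) sum(df$substrate == s & geo), integer(1))
  sdf <- df[sel, , drop = FALSE]
  sgeo <- geo[sel]
  lat <- sdf$latitude[sgeo]; lon <- sdf$longitude[sgeo]
  if (!is.null(location_digits)) {
    lat <- round(lat, location_digits); lon <- round(lon, location_digits)
  }
  out <- list(
    total_observations = nrow(df),
    georeferenced = sum(geo),
    substrate_counts = sub_counts,
    distinct_compounds = length(unique(df$compound)),
    distinct_studies = length(unique(df$study_id)),
    selected_observations = nrow(sdf),
    selected_by_substrate = vapply(.substrates,
                                   function(s) sum(sdf$substrate == s),
                                   integer(1)),
    selected_locations = nrow(unique(cbind(lat, lon)))
  )
  class(out) <- "residueFunnel"
  out
}

#' @export
print.residueFunnel <- function(x, ...) {
  cat("Residue funnel\n")
  cat(sprintf("  observations:    %d (%d georeferenced)\n",
              x$total_observations, x$georeferenced))
  cat(sprintf("  substrates:      %s\n",
              paste(sprintf("%s %d", names(x$substrate_counts),
                            x$substrate_counts), collapse = ", ")))
  cat(sprintf("  compounds:       %d distinct, studies: %d\n",
              x$distinct_compounds, x$distinct_studies))
  cat(sprintf("  selection:       %d observation(s) at %d unique location(s)\n",
              x$selected_observations, x$selected_locations))
  invisible(x)
}

#' Combine residue databases
#'
#' Binds the accepted and rejected tables of several databases (which
#' must share a bounding box).
#' @param ... [ResidueDatabase-class] objects.
#' @return a [ResidueDatabase-class].
#' @export
combineResidueDb <- function(...) {
  dbs <- list(...)
  stopifnot(length(dbs) >= 1L)
  for (d in dbs[-1])
    if (!isTRUE(all.equal(d@bbox, dbs[[1]]@bbox)))
      stop("databases use different bounding boxes", call. = FALSE)
  new("ResidueDatabase",
      data = do.call(rbind, lapply(dbs, function(d) d@data)),
      rejected = do.call(rbind, lapply(dbs, function(d) d@rejected)),
      bbox = dbs[[1]]@bbox)
}

setMethod("show", "ResidueDatabase", function(object) {
  cat(sprintf("ResidueDatabase: %d accepted, %d rejected observation(s)\n",
              nrow(object@data), nrow(object@rejected)))
  geo <- if (nrow(object@data)) sum(.isGeoref(object@data, object@bbox)) else 0L
  cat(sprintf("  georeferenced: %d; bbox lat %g..%g lon %g..%g\n",
              geo, object@bbox[1], object@bbox[2], object@bbox[3],
              object@bbox[4]))
})
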
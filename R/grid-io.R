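## Raster interchange: ESRI ASCII grid (.asc), the plain-text raster format
## understood by every GIS.  Square cells only (the format has a single
## `cellsize` field); the nodata tag is honored on read and write.

#' Read an ESRI ASCII grid
#'
#' @param path path to a `.asc` file.
#' @param units,crs optional metadata to attach (the format itself carries
#'   none).
#' @return a [RasterGrid-class].
#' @export
readAsciiGrid <- function(path, units = "", crs = "local-metric") {
  if (!file.exists(path)) stop("no such raster file: ", path, call. = FALSE)
  con <- file(path, "r")
  on.exit(close(con))
  hdr <- list()
  n_hdr <- 0L
  repeat {
    pos <- seek(con)
    line <- readLines(con, n = 1L)
    parts <- strsplit(trimws(line), "\\s+")[[1]]
    if (length(parts) == 2L && grepl("^[A-Za-z_]", parts[1])) {
      hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
      n_hdr <- n_hdr + 1L
    } else {
      seek(con, pos)
      break
    }
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("malformed ASCII grid header in ", path, call. = FALSE)
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  vals <- scan(con, what = double(), n = nr * nc, quiet = TRUE)
  if (length(vals) != nr * nc)
    stop("raster body has ", length(vals), " values, expected ", nr * nc,
         call. = FALSE)
  if (!is.null(hdr$nodata_value)) vals[vals == hdr$nodata_value] <- NA_real_
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  xll <- if (!is.null(hdr$xllcorner)) hdr$xllcorner else 0
  yll <- if (!is.null(hdr$yllcorner)) hdr$yllcorner else 0
  rasterGrid(m, xmin = xll, ymax = yll + nr * hdr$cellsize,
             cellsize = hdr$cellsize, units = units, crs = crs)
}

#' Write an ESRI ASCII grid
#'
#' @param g a [RasterGrid-class] with square cells.
#' @param path output path.
#' @param nodata numeric nodata sentinel written for `NA` pixels.
#' @return `path`, invisibly.
#' @export
writeAsciiGrid <- function(g, path, nodata = -9999) {
  stopifnot(is(g, "RasterGrid"))
  if (abs(g@cellsize[1] - g@cellsize[2]) > 1e-9 * g@cellsize[1])
    stop("ASCII grids support square cells only", call. = FALSE)
  v <- g@values
  if (any(v == nodata, na.rm = TRUE))
    stop("nodata sentinel ", nodata, " collides with data values", call. = FALSE)
  v[is.na(v)] <- nodata
  hdr <- c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10g", g@xmin),
    sprintf("yllcorner %.10g", g@ymax - nrow(v) * g@cellsize[2]),
    sprintf("cellsize %.10g", g@cellsize[1]),
    sprintf("NODATA_value %.10g", nodata)
  )
  body <- apply(v, 1L, function(row) paste(sprintf("%.10g", row), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read or write a monthly stack as 12 numbered ASCII grids
#'
#' Band `i` of variable `prefix` lives in `<prefix>_<i>.asc` next to
#' `prefix`.
#' @param prefix path prefix (without `_i.asc`).
#' @param units,crs metadata passed to [readAsciiGrid()].
#' @return `readGridStack12`: a temporal [GridStack-class].
#' @export
readGridStack12 <- function(prefix, units = "", crs = "local-metric") {
  gs <- lapply(1:12, function(i)
    readAsciiGrid(sprintf("%s_%02d.asc", prefix, i), units = units, crs = crs))
  names(gs) <- as.character(1:12)
  gridStack(gs, temporal = TRUE)
}

#' @rdname readGridStack12
#' @param s a temporal `GridStack`.
#' @export
writeGridStack12 <- function(s, prefix) {
  stopifnot(is(s, "GridStack"), s@temporal)
  for (i in 1:12)
    writeAsciiGrid(s@grids[[as.character(i)]], sprintf("%s_%02d.asc", prefix, i))
  invisible(prefix)
}

#' Read a pipeline run configuration
#'
#' A YAML file naming the input rasters by their role in the pipeline,
#' plus the free parameters and dialect flags.  Recognized top-level keys:
#' `seed`, `out_dir`, `stream_threshold`, `scenario` (synthetic-grid
#' parameters: `nrow`, `ncol`, `cellsize`, `nodata_fraction`, ...),
#' `dialects` (`eq4_form`: `standard` | `as_printed`; `horton`:
#' `area_over_length` | `area_over_length_squared`), and `inputs` (role ->
#' file path, for running on pre-existing rasters instead of synthetic
#' ones).
#'
#' @param path YAML file.
#' @return a named list with defaults filled in.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- list(
    seed = 1L, out_dir = ".", stream_threshold = 50,
    dialects = list(eq4_form = "standard", horton = "area_over_length"),
    scenario = list(), inputs = list()
  )
  cfg <- utils::modifyList(defaults, cfg)
  cfg$dialects$eq4_form <- match.arg(cfg$dialects$eq4_form,
                                     c("standard", "as_printed"))
  cfg$dialects$horton <- match.arg(cfg$dialects$horton,
                                   c("area_over_length", "area_over_length_squared"))
  for (p in unlist(cfg$inputs))
    if (!file.exists(p)) stop("configured input does not exist: ", p, call. = FALSE)
  cfg
}
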
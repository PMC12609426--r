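# Plain-text formats: ESRI ASCII grids for rasters, tab-delimited tables for
# footprints and training data.  ASCII grid keeps the package free of binary
# raster dependencies while remaining readable by GDAL, QGIS and friends.

#' Write a raster as an ESRI ASCII grid
#'
#' Writes a [sif_grid()] to the plain-text ESRI ASCII grid format (`.asc`):
#' a six-line header (`ncols`, `nrows`, `xllcorner`, `yllcorner`, `cellsize`,
#' `NODATA_value`) followed by rows of values from north to south.
#' Coordinates are geographic (EPSG:4326).  Values are written with 17
#' significant digits so a write/read round trip preserves doubles exactly.
#'
#' @param grid A `sif_grid`.
#' @param path Output file path.
#' @param nodata Sentinel written for `NA` cells (default `-9999`).
#' @return `path`, invisibly.
#' @export
write_raster <- function(grid, path, nodata = -9999) {
  stopifnot(inherits(grid, "sif_grid"))
  v <- grid$values
  v[!is.finite(v)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", ncol(v)),
    paste("nrows", nrow(v)),
    paste("xllcorner", formatC(grid$extent[1], format = "g", digits = 17)),
    paste("yllcorner", formatC(grid$extent[3], format = "g", digits = 17)),
    paste("cellsize", formatC(grid$cellsize, format = "g", digits = 17)),
    paste("NODATA_value", nodata)), con)
  for (i in seq_len(nrow(v)))
    writeLines(paste(formatC(v[i, ], format = "g", digits = 17),
                     collapse = " "), con)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' Inverse of [write_raster()].  `NODATA_value` cells come back as `NA`.
#'
#' @param path File path.
#' @param date,units Optional metadata to attach (the format itself carries
#'   only geometry).
#' @return A [sif_grid()].
#' @export
read_raster <- function(path, date = NULL, units = "W m-2 um-1 sr-1") {
  lines <- readLines(path)
  hdr <- list()
  for (i in 1:6) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
            "nodata_value")
  if (!all(need %in% names(hdr)))
    stop("not an ESRI ASCII grid: missing header field(s) ",
         paste(setdiff(need, names(hdr)), collapse = ", "))
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  v <- matrix(scan(text = lines[-(1:6)], quiet = TRUE), nrow = nr,
              ncol = nc, byrow = TRUE)
  v[v == hdr$nodata_value] <- NA_real_
  extent <- c(hdr$xllcorner, hdr$xllcorner + nc * hdr$cellsize,
              hdr$yllcorner, hdr$yllcorner + nr * hdr$cellsize)
  sif_grid(v, extent, hdr$cellsize, date = date, units = units)
}

#' Write / read a 7-band reflectance stack
#'
#' One ASCII grid per band, at `<prefix>_b1.asc` .. `<prefix>_b7.asc`.
#'
#' @param stack A [refl_stack()].
#' @param prefix Path prefix (directory must exist).
#' @return For the writer, the vector of paths, invisibly; for the reader, a
#'   `refl_stack`.
#' @export
write_reflectance <- function(stack, prefix) {
  stopifnot(inherits(stack, "refl_stack"))
  paths <- paste0(prefix, "_b", 1:7, ".asc")
  for (b in 1:7) write_raster(band_grid(stack, b), paths[b])
  invisible(paths)
}

#' @rdname write_reflectance
#' @param date Optional date metadata for the reader.
#' @export
read_reflectance <- function(prefix, date = NULL) {
  grids <- lapply(paste0(prefix, "_b", 1:7, ".asc"), read_raster)
  for (b in 2:7) check_same_geometry(grids[[1]], grids[[b]], "bands")
  bands <- array(NA_real_, c(dim(grids[[1]]$values), 7))
  for (b in 1:7) bands[, , b] <- grids[[b]]$values
  refl_stack(bands, grids[[1]]$extent, grids[[1]]$cellsize, date = date)
}

footprint_columns <- c("id", "date", "lat", "lon", "sif_757", "sif_771",
                       "qc_flag")

#' Read a footprint table
#'
#' Reads a tab-delimited table of SIF soundings with columns `id`, `date`
#' (ISO-8601), `lat`, `lon`, `sif_757`, `sif_771`, `qc_flag`.  Rows violating
#' the schema (unparseable date, latitude outside \[-90, 90\], longitude
#' outside \[-180, 180), non-finite SIF, non-integer flag) are rejected and
#' reported, with line numbers, in the `"rejected"` attribute of the result.
#' A header-only file yields an empty table.  A missing required column is an
#' error naming the column.
#'
#' @param path File path.
#' @return A `data.frame` of valid soundings; attribute `rejected` holds a
#'   `data.frame` with columns `line` and `reason` (zero rows when clean).
#' @export
read_footprint_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = "character")
  missing <- setdiff(footprint_columns, names(df))
  if (length(missing))
    stop("footprint table is missing required column(s): ",
         paste(missing, collapse = ", "))
  if (nrow(df) == 0) {
    out <- data.frame(id = character(), date = as.Date(character()),
                      lat = numeric(), lon = numeric(), sif_757 = numeric(),
                      sif_771 = numeric(), qc_flag = integer())
    attr(out, "rejected") <- data.frame(line = integer(), reason = character())
    return(out)
  }
  date <- suppressWarnings(as.Date(df$date, format = "%Y-%m-%d"))
  lat <- suppressWarnings(as.numeric(df$lat))
  lon <- suppressWarnings(as.numeric(df$lon))
  s757 <- suppressWarnings(as.numeric(df$sif_757))
  s771 <- suppressWarnings(as.numeric(df$sif_771))
  qc <- suppressWarnings(as.integer(df$qc_flag))
  reason <- rep(NA_character_, nrow(df))
  flag <- function(bad, msg) reason[is.na(reason) & bad] <<- msg
  flag(is.na(date), "unparseable date")
  flag(!is.finite(lat) | lat < -90 | lat > 90, "latitude outside [-90, 90]")
  flag(!is.finite(lon) | lon < -180 | lon >= 180,
       "longitude outside [-180, 180)")
  flag(!is.finite(s757) | !is.finite(s771), "non-finite SIF value")
  flag(is.na(qc), "non-integer qc_flag")
  keep <- is.na(reason)
  out <- data.frame(id = df$id[keep], date = date[keep], lat = lat[keep],
                    lon = lon[keep], sif_757 = s757[keep],
                    sif_771 = s771[keep], qc_flag = qc[keep],
                    stringsAsFactors = FALSE)
  # line numbers in the file: +1 for the header
  attr(out, "rejected") <- data.frame(line = which(!keep) + 1L,
                                      reason = reason[!keep])
  out
}

#' Write a footprint (or processed/training) table
#'
#' Tab-delimited, ISO-8601 dates, full double precision.  Round trips through
#' [read_footprint_table()] losslessly for the core columns; extra columns
#' (e.g. `sif_daily`, `sif_smoothed`, `b1`..`b7`, `doy`, `stratum`) are
#' written as-is.
#'
#' @param df Table to write.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_footprint_table <- function(df, path) {
  out <- df
  if (inherits(out$date, "Date")) out$date <- format(out$date, "%Y-%m-%d")
  num <- vapply(out, is.double, logical(1))
  out[num] <- lapply(out[num], function(x) formatC(x, format = "g", digits = 17))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# generic delimited table used for metrics/audit artifacts
write_delim_table <- function(df, path) {
  out <- df
  if (inherits(out$date, "Date")) out$date <- format(out$date, "%Y-%m-%d")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_delim_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
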
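# Regular geographic grids (EPSG:4326, north-up, cell-edge registration at
# the configured NW corner).  Matrix row 1 is the northernmost row; columns
# run west to east.  Cell intervals are half-open: a point on a cell's
# southern/eastern edge belongs to the next cell.

#' Create a gridded SIF raster
#'
#' A `sif_grid` holds one band of values on a regular lat/lon lattice in
#' geographic coordinates (EPSG:4326).  Row 1 of the value matrix is the
#' northernmost row of cells; cells are registered to the edges of the extent
#' (the NW corner of the grid coincides with the NW corner of the extent).
#' `NA` cells are nodata.
#'
#' @param values Numeric matrix, `nrow = nlat`, `ncol = nlon`.
#' @param extent Numeric length-4 vector `c(lon_min, lon_max, lat_min, lat_max)`
#'   in degrees.
#' @param cellsize Cell size in degrees; must divide both extent spans evenly.
#' @param date Optional `Date` the layer refers to.
#' @param units Character unit string stored as metadata
#'   (default `"W m-2 um-1 sr-1"`, the SIF radiance unit).
#' @return An object of class `sif_grid`.
#' @export
sif_grid <- function(values, extent, cellsize, date = NULL,
                     units = "W m-2 um-1 sr-1") {
  dims <- grid_dims(extent, cellsize)
  values <- as.matrix(values)
  if (!identical(dim(values), dims))
    stop("value matrix is ", nrow(values), "x", ncol(values),
         " but extent/cellsize imply ", dims[1], "x", dims[2])
  structure(list(values = values, extent = as.numeric(extent),
                 cellsize = cellsize, date = date, units = units),
            class = "sif_grid")
}

#' @export
print.sif_grid <- function(x, ...) {
  cat("<sif_grid> ", nrow(x$values), "x", ncol(x$values),
      " cells, ", x$cellsize, "deg, extent [",
      paste(format(x$extent), collapse = ", "), "]",
      if (!is.null(x$date)) paste0(", date ", format(x$date)), "\n", sep = "")
  cat("  values: ", sum(is.finite(x$values)), " finite / ",
      length(x$values), " (", x$units, ")\n", sep = "")
  invisible(x)
}

# nrow/ncol implied by extent and cellsize; errors unless cellsize divides
# the extent evenly (within floating tolerance).
grid_dims <- function(extent, cellsize) {
  if (length(extent) != 4 || extent[2] <= extent[1] || extent[4] <= extent[3])
    stop("extent must be c(lon_min, lon_max, lat_min, lat_max) with positive spans")
  if (!is.finite(cellsize) || cellsize <= 0) stop("cellsize must be positive")
  spans <- c(extent[4] - extent[3], extent[2] - extent[1])
  n <- spans / cellsize
  if (any(abs(n - round(n)) > 1e-6))
    stop("cellsize ", cellsize, " does not divide the extent evenly")
  as.integer(round(n))
}

# cell-centre coordinates; latitudes descend (row 1 = north)
grid_lats <- function(g) {
  n <- nrow(g$values)
  g$extent[4] - g$cellsize / 2 - (seq_len(n) - 1L) * g$cellsize
}

grid_lons <- function(g) {
  n <- ncol(g$values)
  g$extent[1] + g$cellsize / 2 + (seq_len(n) - 1L) * g$cellsize
}

# Map points to (row, col); NA outside the extent.  Half-open cells: a point
# exactly on the shared edge of two cells belongs to the southern/eastern one,
# except on the outermost S/E boundary which is closed so the extent maps
# entirely onto the grid.
cell_rowcol <- function(g, lat, lon) {
  nr <- nrow(g$values); nc <- ncol(g$values)
  row <- floor((g$extent[4] - lat) / g$cellsize) + 1
  col <- floor((lon - g$extent[1]) / g$cellsize) + 1
  row[lat == g$extent[3]] <- nr
  col[lon == g$extent[2]] <- nc
  bad <- !is.finite(lat) | !is.finite(lon) |
    lat > g$extent[4] | lat < g$extent[3] |
    lon < g$extent[1] | lon > g$extent[2]
  row[bad] <- NA_integer_; col[bad] <- NA_integer_
  cbind(row = as.integer(row), col = as.integer(col))
}

same_geometry <- function(a, b, tol = 1e-9) {
  all(abs(a$extent - b$extent) < tol) && abs(a$cellsize - b$cellsize) < tol
}

# Errors with both geometries printed when two layers do not align.
check_same_geometry <- function(a, b, what = "rasters") {
  if (!same_geometry(a, b))
    stop(what, " have mismatched geometry:\n  a: extent [",
         paste(format(a$extent), collapse = ", "), "], cellsize ", a$cellsize,
         "\n  b: extent [", paste(format(b$extent), collapse = ", "),
         "], cellsize ", b$cellsize)
  invisible(TRUE)
}

#' Seven-band reflectance stack
#'
#' Container for BRDF-corrected style surface reflectance on the same lattice
#' convention as [sif_grid()]: an `nlat x nlon x 7` array with values in
#' \[0, 1\] (band order b1..b7).
#'
#' @param bands Numeric array `nlat x nlon x 7`.
#' @param extent,cellsize,date As in [sif_grid()].
#' @return An object of class `refl_stack`.
#' @export
refl_stack <- function(bands, extent, cellsize, date = NULL) {
  dims <- grid_dims(extent, cellsize)
  if (length(dim(bands)) != 3 || !identical(dim(bands)[1:2], dims) ||
      dim(bands)[3] != 7L)
    stop("bands must be an array of dim c(", dims[1], ", ", dims[2], ", 7)")
  structure(list(bands = bands, extent = as.numeric(extent),
                 cellsize = cellsize, date = date),
            class = "refl_stack")
}

#' @export
print.refl_stack <- function(x, ...) {
  cat("<refl_stack> ", dim(x$bands)[1], "x", dim(x$bands)[2],
      " cells x 7 bands, ", x$cellsize, "deg",
      if (!is.null(x$date)) paste0(", date ", format(x$date)), "\n", sep = "")
  invisible(x)
}

# view one band of a stack as a sif_grid (for geometry checks / export)
band_grid <- function(stack, band) {
  sif_grid(stack$bands[, , band], stack$extent, stack$cellsize,
           date = stack$date, units = "reflectance")
}
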
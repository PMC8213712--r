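#' The six-class LULC codebook
#'
#' Integer codes for the land-use/land-cover classes of a subsiding
#' coal-mining landscape: farmland, other agricultural land, urban and rural
#' construction land, subsided seeper area (mining-induced subsidence with
#' water accumulation), water area, and tidal wetland.
#'
#' @return Named character vector; names are the codes "1".."6".
#' @export
lulc_codebook <- function() {
  c(`1` = "farmland",
    `2` = "other agricultural land",
    `3` = "urban and rural construction land",
    `4` = "subsided seeper area",
    `5` = "water area",
    `6` = "tidal wetland")
}

N_CLASSES <- 6L

#' Construct a raster grid
#'
#' A minimal single-band raster: a numeric matrix with square-cell geometry
#' metadata. Row 1 is the northernmost row. Missing cells are stored as `NA`
#' internally and written with the `nodata_value` sentinel on disk.
#'
#' @param values Numeric matrix (row 1 = north).
#' @param cellsize Cell side length in meters (> 0).
#' @param xllcorner,yllcorner Coordinates of the lower-left corner (meters).
#' @param nodata_value Sentinel written for `NA` cells (default -9999).
#' @return An object of class `lulc_grid`.
#' @export
new_grid <- function(values, cellsize, xllcorner = 0, yllcorner = 0,
                     nodata_value = -9999) {
  if (!is.matrix(values)) values <- as.matrix(values)
  g <- structure(list(
    nrows = nrow(values), ncols = ncol(values),
    cellsize = as.numeric(cellsize),
    xllcorner = as.numeric(xllcorner), yllcorner = as.numeric(yllcorner),
    nodata_value = as.numeric(nodata_value),
    values = values
  ), class = "lulc_grid")
  validate_grid(g)
  g
}

#' @export
validate_grid <- function(g) {
  stopifnot(inherits(g, "lulc_grid"))
  if (g$nrows < 1L || g$ncols < 1L) stop("grid must have at least one row and column")
  if (!is.finite(g$cellsize) || g$cellsize <= 0) stop("cellsize must be positive")
  if (nrow(g$values) != g$nrows || ncol(g$values) != g$ncols)
    stop("values dimensions do not match nrows/ncols")
  v <- g$values[!is.na(g$values)]
  if (length(v) && any(!is.finite(v))) stop("non-nodata values must be finite")
  invisible(g)
}

#' @export
print.lulc_grid <- function(x, ...) {
  cat(sprintf("<lulc_grid> %d x %d @ %g m  origin (%g, %g)  nodata %g\n",
              x$nrows, x$ncols, x$cellsize, x$xllcorner, x$yllcorner,
              x$nodata_value))
  v <- x$values[!is.na(x$values)]
  if (length(v)) cat(sprintf("  values: [%g, %g], %d valid / %d cells\n",
                             min(v), max(v), length(v), length(x$values)))
  invisible(x)
}

#' Test geometric identity of two grids
#' @param a,b Grids.
#' @return Logical.
#' @export
same_geometry <- function(a, b) {
  a$nrows == b$nrows && a$ncols == b$ncols &&
    isTRUE(all.equal(a$cellsize, b$cellsize)) &&
    isTRUE(all.equal(a$xllcorner, b$xllcorner)) &&
    isTRUE(all.equal(a$yllcorner, b$yllcorner))
}

stop_if_geometry_mismatch <- function(a, b) {
  if (!same_geometry(a, b)) stop("grids do not share the same geometry")
  invisible(TRUE)
}

#' Construct an LULC map
#'
#' A categorical grid over the six-class codebook. Every valid cell must hold
#' an integer code in 1..6.
#'
#' @param grid A `lulc_grid` with integer-valued cells.
#' @return An object of classes `lulc_map` and `lulc_grid`.
#' @export
new_lulc_map <- function(grid) {
  validate_grid(grid)
  v <- grid$values[!is.na(grid$values)]
  if (length(v) && (any(v != round(v)) || any(v < 1 | v > N_CLASSES)))
    stop("LULC map cells must hold integer codes in 1..6")
  grid$values <- round(grid$values)
  class(grid) <- c("lulc_map", "lulc_grid")
  grid
}

#' Per-class areas of an LULC map in hectares
#'
#' Cell counts times cellsize^2 / 10,000. The six areas always sum exactly to
#' the total valid area.
#'
#' @param map An `lulc_map`.
#' @return Named numeric vector of length 6 (ha), names = class codes.
#' @export
class_areas <- function(map) {
  counts <- tabulate(map$values[!is.na(map$values)], nbins = N_CLASSES)
  areas <- counts * cell_area_ha(map)
  names(areas) <- as.character(seq_len(N_CLASSES))
  areas
}

cell_area_ha <- function(g) g$cellsize^2 / 1e4

#' A stack of geometry-aligned driver rasters
#'
#' Bundles the seven driving-factor layers used by the suitability models:
#' five accessibility distances (meters to the nearest residential area,
#' mine, road, river and ditch) plus elevation (m) and slope (degrees).
#'
#' @param layers Named list of `lulc_grid`s sharing one geometry.
#' @param standardized Set to `TRUE` for stacks on the zero-mean scale, where
#'   the raw-scale nonnegativity check on distance layers does not apply.
#' @return Object of class `driver_stack` (a named list of grids).
#' @export
new_driver_stack <- function(layers, standardized = FALSE) {
  stopifnot(is.list(layers), length(layers) >= 1, !is.null(names(layers)))
  if (any(names(layers) == "")) stop("all driver layers must be named")
  for (g in layers) validate_grid(g)
  ref <- layers[[1]]
  for (nm in names(layers)) {
    if (!same_geometry(ref, layers[[nm]]))
      stop("driver layer '", nm, "' does not share the stack geometry")
  }
  if (!standardized) {
    for (nm in grep("^dist_", names(layers), value = TRUE)) {
      v <- layers[[nm]]$values
      if (any(v[!is.na(v)] < 0)) stop("distance layer '", nm, "' has negative values")
    }
  }
  structure(layers, class = "driver_stack")
}

#' Canonical driver names
#' @return Character vector of the seven driver layer names.
#' @export
driver_names <- function() {
  c("dist_residential", "dist_mines", "dist_roads", "dist_rivers",
    "dist_ditches", "elevation", "slope")
}

#' @export
print.driver_stack <- function(x, ...) {
  cat(sprintf("<driver_stack> %d layers: %s\n", length(x),
              paste(names(x), collapse = ", ")))
  invisible(x)
}

# matrix of valid-cell driver values (cells x drivers), plus the cell index
driver_matrix <- function(drivers) {
  m <- vapply(drivers, function(g) as.vector(g$values),
              numeric(drivers[[1]]$nrows * drivers[[1]]$ncols))
  colnames(m) <- names(drivers)
  m
}
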
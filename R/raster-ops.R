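#' Majority-resample a categorical map to a coarser grid
#'
#' Aggregates `factor` x `factor` blocks of cells; each output cell takes the
#' majority class of its source block, excluding nodata cells from the vote.
#' Ties are broken by the smallest class code; an all-nodata block stays
#' nodata. Trailing partial blocks are allowed, so `factor` need not divide
#' the map dimensions. Output cellsize is the input cellsize times `factor`.
#'
#' @param map An `lulc_map`.
#' @param factor Positive integer aggregation factor.
#' @return An `lulc_map` on the coarser grid.
#' @export
resample_categorical <- function(map, factor) {
  stopifnot(inherits(map, "lulc_map"))
  factor <- check_factor(factor)
  dims <- block_dims(map, factor)
  id <- block_ids(map, factor, dims)
  v <- as.vector(map$values)
  keep <- !is.na(v)
  nblk <- dims$nr * dims$nc
  # counts[block, code]
  counts <- matrix(0L, nblk, N_CLASSES)
  if (any(keep)) {
    tab <- tabulate((v[keep] - 1) * nblk + id[keep], nbins = nblk * N_CLASSES)
    counts <- matrix(tab, nblk, N_CLASSES)
  }
  out <- max.col(counts, ties.method = "first")   # ties -> smallest code
  out[rowSums(counts) == 0L] <- NA_integer_
  new_lulc_map(new_grid(matrix(out, dims$nr, dims$nc),
                        cellsize = map$cellsize * factor,
                        xllcorner = map$xllcorner,
                        yllcorner = yll_after_blocking(map, factor, dims),
                        nodata_value = map$nodata_value))
}

#' Mean-resample a continuous grid to a coarser grid
#'
#' Each output cell is the arithmetic mean of the valid cells in its source
#' block; an all-nodata block stays nodata.
#'
#' @param grid A `lulc_grid`.
#' @param factor Positive integer aggregation factor.
#' @return A `lulc_grid` on the coarser grid.
#' @export
resample_continuous <- function(grid, factor) {
  validate_grid(grid)
  factor <- check_factor(factor)
  dims <- block_dims(grid, factor)
  id <- block_ids(grid, factor, dims)
  v <- as.vector(grid$values)
  keep <- !is.na(v)
  nblk <- dims$nr * dims$nc
  sums <- counts <- numeric(nblk)
  if (any(keep)) {
    present <- sort(unique(id[keep]))
    sums[present] <- rowsum(v[keep], id[keep])[, 1]
    counts <- tabulate(id[keep], nbins = nblk)
  }
  out <- ifelse(counts > 0, sums / pmax(counts, 1), NA_real_)
  new_grid(matrix(out, dims$nr, dims$nc),
           cellsize = grid$cellsize * factor,
           xllcorner = grid$xllcorner,
           yllcorner = yll_after_blocking(grid, factor, dims),
           nodata_value = grid$nodata_value)
}

check_factor <- function(factor) {
  if (length(factor) != 1L || is.na(factor) || factor < 1 || factor != round(factor))
    stop("resampling factor must be a positive integer")
  as.integer(factor)
}

block_dims <- function(g, f) list(nr = ceiling(g$nrows / f), nc = ceiling(g$ncols / f))

# column-major block id for each cell of g under factor f
block_ids <- function(g, f, dims) {
  r <- (seq_len(g$nrows) - 1L) %/% f + 1L
  c_ <- (seq_len(g$ncols) - 1L) %/% f + 1L
  as.vector(outer(r, c_, function(i, j) (j - 1L) * dims$nr + i))
}

# keep the NW corner anchored: the y origin moves down if blocks overhang south
yll_after_blocking <- function(g, f, dims) {
  top <- g$yllcorner + g$nrows * g$cellsize
  top - dims$nr * (g$cellsize * f)
}

#' Euclidean distance to the nearest feature cell
#'
#' For every cell, the minimum center-to-center Euclidean distance in meters
#' to any feature cell of a binary mask. Feature cells get distance 0. Uses
#' an exact Euclidean distance transform.
#'
#' @param features `lulc_grid` mask: nonzero = feature. Must contain at least
#'   one feature cell.
#' @param cellsize Cell size in meters; defaults to the mask's own.
#' @return `lulc_grid` of distances (meters); nodata cells stay nodata.
#' @export
euclidean_distance <- function(features, cellsize = features$cellsize) {
  validate_grid(features)
  m <- features$values
  feat <- !is.na(m) & m != 0
  if (!any(feat)) stop("empty feature mask: distance is undefined")
  # distmap: distance of foreground (non-feature) pixels to nearest background
  d <- EBImage::distmap(matrix(as.numeric(!feat), nrow(m), ncol(m)),
                        metric = "euclidean")
  d <- as.matrix(d) * cellsize
  d[is.na(m)] <- NA_real_
  new_grid(d, cellsize = features$cellsize, xllcorner = features$xllcorner,
           yllcorner = features$yllcorner, nodata_value = features$nodata_value)
}

#' Slope in degrees from a DEM
#'
#' Horn's 3x3 finite-difference gradient, the standard GIS slope operator.
#' Border cells are handled by linear-extrapolation padding, which reduces to
#' one-sided differences at the edges.
#'
#' @param dem `lulc_grid` of elevations (meters), at least 3x3.
#' @return `lulc_grid` of slope in degrees (>= 0).
#' @export
slope_from_dem <- function(dem) {
  validate_grid(dem)
  if (dem$nrows < 3L || dem$ncols < 3L) stop("DEM must be at least 3x3")
  z <- pad_extrapolate(dem$values)
  nr <- dem$nrows; nc <- dem$ncols
  ri <- 2:(nr + 1); ci <- 2:(nc + 1)
  # Horn weights: dz/dx = ((c + 2f + i) - (a + 2d + g)) / (8 * cellsize)
  dzdx <- ((z[ri - 1, ci + 1] + 2 * z[ri, ci + 1] + z[ri + 1, ci + 1]) -
           (z[ri - 1, ci - 1] + 2 * z[ri, ci - 1] + z[ri + 1, ci - 1])) /
    (8 * dem$cellsize)
  # row index grows southwards; dz/dy is positive northwards
  dzdy <- ((z[ri - 1, ci - 1] + 2 * z[ri - 1, ci] + z[ri - 1, ci + 1]) -
           (z[ri + 1, ci - 1] + 2 * z[ri + 1, ci] + z[ri + 1, ci + 1])) /
    (8 * dem$cellsize)
  slope <- atan(sqrt(dzdx^2 + dzdy^2)) * 180 / pi
  new_grid(slope, cellsize = dem$cellsize, xllcorner = dem$xllcorner,
           yllcorner = dem$yllcorner, nodata_value = dem$nodata_value)
}

# pad by one cell of linear extrapolation (2*edge - inner) on each side
pad_extrapolate <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  p <- matrix(NA_real_, nr + 2, nc + 2)
  p[2:(nr + 1), 2:(nc + 1)] <- m
  p[1, 2:(nc + 1)] <- 2 * m[1, ] - m[2, ]
  p[nr + 2, 2:(nc + 1)] <- 2 * m[nr, ] - m[nr - 1, ]
  p[, 1] <- 2 * p[, 2] - p[, 3]
  p[, nc + 2] <- 2 * p[, nc + 1] - p[, nc]
  p
}

#' Cross-tabulate two aligned LULC maps
#'
#' Entry (u, v) counts cells coded u in `a` and v in `b`; cells nodata in
#' either map are skipped.
#'
#' @param a,b Aligned `lulc_map`s.
#' @return 6x6 integer matrix with class-code dimnames.
#' @export
cross_tabulate <- function(a, b) {
  stop_if_geometry_mismatch(a, b)
  va <- as.vector(a$values); vb <- as.vector(b$values)
  keep <- !is.na(va) & !is.na(vb)
  tab <- table(factor(va[keep], levels = 1:N_CLASSES),
               factor(vb[keep], levels = 1:N_CLASSES))
  m <- matrix(as.integer(tab), N_CLASSES, N_CLASSES,
              dimnames = list(a = as.character(1:N_CLASSES),
                              b = as.character(1:N_CLASSES)))
  m
}

#' One pass of a 3x3 majority filter over an LULC map
#'
#' Each cell takes the modal class of its 3x3 neighbourhood (edge-replicated).
#' Ties retain the current class when it is among the modes, otherwise the
#' smallest class code wins. Used by the synthetic generator to turn
#' salt-and-pepper samples into patch structure.
#'
#' @param map An `lulc_map` without nodata cells.
#' @return Filtered `lulc_map`.
#' @export
majority_filter <- function(map) {
  stopifnot(inherits(map, "lulc_map"))
  v <- map$values
  if (anyNA(v)) stop("majority_filter expects a fully valid map")
  nr <- nrow(v); nc <- ncol(v)
  pr <- c(1, seq_len(nr), nr); pc <- c(1, seq_len(nc), nc)
  p <- v[pr, pc]
  counts <- array(0L, c(nr, nc, N_CLASSES))
  for (dr in 0:2) for (dc in 0:2) {
    w <- p[dr + seq_len(nr), dc + seq_len(nc)]
    for (k in seq_len(N_CLASSES)) counts[, , k] <- counts[, , k] + (w == k)
  }
  cmax <- pmax(counts[, , 1], counts[, , 2], counts[, , 3],
               counts[, , 4], counts[, , 5], counts[, , 6])
  out <- matrix(0L, nr, nc)
  for (k in N_CLASSES:1) out[counts[, , k] == cmax] <- k   # smallest code wins ties
  keep_cur <- counts[cbind(rep(seq_len(nr), nc), rep(seq_len(nc), each = nr),
                           as.vector(v))] == as.vector(cmax)
  out[matrix(keep_cur, nr, nc)] <- v[matrix(keep_cur, nr, nc)]
  map$values <- out
  map
}
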
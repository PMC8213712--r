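#' Read an ESRI ASCII grid
#'
#' Parses the six-line header (`ncols`, `nrows`, `xllcorner`, `yllcorner`,
#' `cellsize`, `NODATA_value`; the last is optional and defaults to -9999)
#' followed by `nrows` rows of `ncols` whitespace-separated values ordered
#' north to south. Cells equal to the nodata sentinel become `NA`.
#'
#' @param path Path to a `.asc` file.
#' @return A `lulc_grid`.
#' @export
read_ascii_grid <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- list()
  i <- 1L
  while (i <= length(lines)) {
    toks <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    key <- tolower(toks[1])
    if (!key %in% c("ncols", "nrows", "xllcorner", "yllcorner",
                    "cellsize", "nodata_value")) break
    if (length(toks) != 2L)
      stop("malformed header at line ", i, ": '", lines[i], "'")
    val <- suppressWarnings(as.numeric(toks[2]))
    if (is.na(val)) stop("non-numeric header value at line ", i, ": '", toks[2], "'")
    hdr[[key]] <- val
    i <- i + 1L
  }
  for (key in c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")) {
    if (is.null(hdr[[key]])) stop("missing header key '", key, "'")
  }
  nodata <- if (is.null(hdr$nodata_value)) -9999 else hdr$nodata_value
  nrows <- as.integer(hdr$nrows); ncols <- as.integer(hdr$ncols)
  body <- lines[seq(i, length.out = length(lines) - i + 1L)]
  if (length(body) != nrows)
    stop("expected ", nrows, " data rows, found ", length(body))
  vals <- matrix(NA_real_, nrows, ncols)
  for (r in seq_len(nrows)) {
    toks <- strsplit(trimws(body[r]), "\\s+")[[1]]
    if (length(toks) != ncols)
      stop("row length mismatch at line ", i + r - 1L, ": expected ",
           ncols, " values, found ", length(toks))
    v <- suppressWarnings(as.numeric(toks))
    if (anyNA(v))
      stop("non-numeric token at line ", i + r - 1L, ": '",
           toks[which(is.na(v))[1]], "'")
    vals[r, ] <- v
  }
  vals[vals == nodata] <- NA_real_
  new_grid(vals, cellsize = hdr$cellsize, xllcorner = hdr$xllcorner,
           yllcorner = hdr$yllcorner, nodata_value = nodata)
}

#' Write an ESRI ASCII grid
#'
#' Headers are written in the canonical key order. Integer-valued grids are
#' written without a decimal point; other values with at most 6 significant
#' digits. `NA` cells are written as the grid's nodata sentinel.
#'
#' @param grid A `lulc_grid`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_ascii_grid <- function(grid, path) {
  validate_grid(grid)
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot open '", path, "' for writing: ", conditionMessage(e)))
  on.exit(close(con))
  hdr <- c(
    sprintf("ncols        %s", fmt_asc(grid$ncols)),
    sprintf("nrows        %s", fmt_asc(grid$nrows)),
    sprintf("xllcorner    %s", fmt_asc(grid$xllcorner)),
    sprintf("yllcorner    %s", fmt_asc(grid$yllcorner)),
    sprintf("cellsize     %s", fmt_asc(grid$cellsize)),
    sprintf("NODATA_value %s", fmt_asc(grid$nodata_value))
  )
  writeLines(hdr, con)
  v <- grid$values
  v[is.na(v)] <- grid$nodata_value
  for (r in seq_len(grid$nrows)) {
    writeLines(paste(vapply(v[r, ], fmt_asc, character(1)), collapse = " "), con)
  }
  invisible(path)
}

# one numeric token: integers bare, reals with <= 6 significant digits
fmt_asc <- function(x) {
  if (is.na(x)) stop("internal: NA reached the ASCII formatter")
  if (abs(x - round(x)) < 1e-9 && abs(x) < 1e15) {
    sprintf("%.0f", round(x))
  } else {
    sprintf("%g", signif(x, 6))
  }
}
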
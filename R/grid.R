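#' Elevation grid container
#'
#' A minimal square-cell raster of elevations in metres. Rows run north to
#' south (row 1 is the northernmost), columns west to east, matching the
#' usual raster layout. Georeferencing is a lower-left corner plus a cell
#' size; `NA` cells are nodata.
#'
#' @param z Numeric matrix of elevations (m); row 1 = north.
#' @param cell_size Cell edge length in metres (> 0).
#' @param xll,yll Map coordinates of the grid's lower-left corner (m).
#' @param nodata Value written to file for `NA` cells.
#' @return An object of class `elevation_grid`.
#' @examples
#' g <- elevation_grid(matrix(1:12, 3, 4), cell_size = 10)
#' dim(g$z)
#' @export
elevation_grid <- function(z, cell_size, xll = 0, yll = 0, nodata = -9999) {
  if (!is.matrix(z) || !is.numeric(z)) {
    stop("`z` must be a numeric matrix", call. = FALSE)
  }
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0) {
    stop("`cell_size` must be a single positive number", call. = FALSE)
  }
  structure(
    list(z = z, cell_size = as.numeric(cell_size),
         xll = as.numeric(xll), yll = as.numeric(yll),
         nodata = as.numeric(nodata)),
    class = "elevation_grid"
  )
}

#' @export
print.elevation_grid <- function(x, ...) {
  cat(sprintf("<elevation_grid> %d x %d cells, %g m cells\n",
              nrow(x$z), ncol(x$z), x$cell_size))
  rng <- range(x$z, na.rm = TRUE)
  cat(sprintf("  elevation: %.1f .. %.1f m; origin (%g, %g)\n",
              rng[1], rng[2], x$xll, x$yll))
  invisible(x)
}

#' Map extent of a grid
#'
#' @param grid An [elevation_grid()].
#' @return Named numeric vector `c(xmin, ymin, xmax, ymax)` in map metres.
#' @export
grid_extent <- function(grid) {
  stopifnot(inherits(grid, "elevation_grid"))
  c(xmin = grid$xll, ymin = grid$yll,
    xmax = grid$xll + ncol(grid$z) * grid$cell_size,
    ymax = grid$yll + nrow(grid$z) * grid$cell_size)
}

# Column/row index of the cell containing map point (x, y); NA outside.
cell_index <- function(grid, x, y) {
  col <- floor((x - grid$xll) / grid$cell_size) + 1L
  row <- nrow(grid$z) - floor((y - grid$yll) / grid$cell_size)
  bad <- col < 1L | col > ncol(grid$z) | row < 1L | row > nrow(grid$z)
  col[bad] <- NA_integer_
  row[bad] <- NA_integer_
  list(row = as.integer(row), col = as.integer(col))
}

# Cell-centre coordinates for every cell, in matrix (row-major per column)
# order matching as.vector(z).
cell_centers <- function(grid) {
  nr <- nrow(grid$z); nc <- ncol(grid$z); cs <- grid$cell_size
  list(
    x = rep(grid$xll + (seq_len(nc) - 0.5) * cs, each = nr),
    y = rep(grid$yll + (nr - seq_len(nr) + 0.5) * cs, times = nc)
  )
}

#' Read and write Esri ASCII grids
#'
#' Plain-text raster exchange format: a six-line header (`ncols`, `nrows`,
#' `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`) followed by rows of
#' whitespace-separated values, northernmost row first.
#'
#' @param grid An [elevation_grid()].
#' @param path File path.
#' @return `read_ascii_grid` returns an [elevation_grid()];
#'   `write_ascii_grid` returns `path` invisibly.
#' @export
write_ascii_grid <- function(grid, path) {
  stopifnot(inherits(grid, "elevation_grid"))
  z <- grid$z
  z[is.na(z)] <- grid$nodata
  hdr <- c(
    sprintf("ncols %d", ncol(z)),
    sprintf("nrows %d", nrow(z)),
    sprintf("xllcorner %.10g", grid$xll),
    sprintf("yllcorner %.10g", grid$yll),
    sprintf("cellsize %.10g", grid$cell_size),
    sprintf("NODATA_value %.10g", grid$nodata)
  )
  rows <- apply(z, 1L, function(r) paste(format(r, trim = TRUE), collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1:6]
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  vals <- stats::setNames(as.numeric(kv[, 2]), tolower(kv[, 1]))
  nc <- as.integer(vals[["ncols"]]); nr <- as.integer(vals[["nrows"]])
  body <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  if (length(body) != nr * nc) {
    stop(sprintf("grid body has %d values, expected %d", length(body), nr * nc),
         call. = FALSE)
  }
  z <- matrix(body, nrow = nr, ncol = nc, byrow = TRUE)
  z[z == vals[["nodata_value"]]] <- NA_real_
  elevation_grid(z, cell_size = vals[["cellsize"]],
                 xll = vals[["xllcorner"]], yll = vals[["yllcorner"]],
                 nodata = vals[["nodata_value"]])
}
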
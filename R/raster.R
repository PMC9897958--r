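#' Lightweight in-memory grid raster
#'
#' A minimal regular-grid raster: a numeric or integer matrix plus an origin
#' and a cell size in projected meters.  Row 1 is the *southernmost* row, so
#' `values[i, j]` is the cell whose centre is at
#' `(xmin + (j - 0.5) res, ymin + (i - 0.5) res)`.
#'
#' @param values matrix of cell values (row 1 = south).
#' @param xmin,ymin coordinates of the grid's lower-left corner (m).
#' @param res cell size (m), square cells.
#' @return an object of class `grid_raster`.
#' @export
grid_raster <- function(values, xmin = 0, ymin = 0, res = 30) {
  stopifnot(is.matrix(values), res > 0)
  structure(list(values = values, xmin = xmin, ymin = ymin, res = res),
            class = "grid_raster")
}

#' @export
print.grid_raster <- function(x, ...) {
  cat(sprintf("grid_raster: %d rows x %d cols, res %g m, origin (%g, %g)\n",
              nrow(x$values), ncol(x$values), x$res, x$xmin, x$ymin))
  invisible(x)
}

#' @export
dim.grid_raster <- function(x) dim(x$values)

raster_xmax <- function(r) r$xmin + ncol(r$values) * r$res
raster_ymax <- function(r) r$ymin + nrow(r$values) * r$res

#' Cell index of point coordinates
#'
#' Maps points to cells by nearest cell centre.  Points exactly on a vertical
#' cell edge belong to the west cell and points on a horizontal edge to the
#' north cell (the northwest-most cell wins on a corner).  Points outside the
#' extent get `NA`.
#'
#' @param r a [grid_raster].
#' @param x,y point coordinates (m).
#' @return data.frame with columns `row`, `col` (NA off-extent).
#' @export
cell_of <- function(r, x, y) {
  eps <- 1e-9
  fx <- (x - r$xmin) / r$res
  fy <- (y - r$ymin) / r$res
  nr <- nrow(r$values); nc <- ncol(r$values)
  col <- floor(fx + eps) + 1
  on_edge_x <- abs(fx - round(fx)) < eps & round(fx) > 0
  col[on_edge_x] <- round(fx[on_edge_x])
  row <- floor(fy + eps) + 1
  row[row > nr & fy < nr + eps] <- nr
  off <- fx < -eps | fy < -eps | fx > nc + eps | fy > nr + eps
  col[off | col < 1 | col > nc] <- NA_integer_
  row[off | row < 1 | row > nr] <- NA_integer_
  row[is.na(col)] <- NA_integer_
  col[is.na(row)] <- NA_integer_
  data.frame(row = row, col = col)
}

#' Coordinates of cell centres
#' @param r a [grid_raster].
#' @param row,col cell indices (row 1 = south).
#' @return data.frame with columns `x`, `y`.
#' @export
cell_center <- function(r, row, col) {
  data.frame(x = r$xmin + (col - 0.5) * r$res,
             y = r$ymin + (row - 0.5) * r$res)
}

#' Extract raster values at point coordinates
#'
#' Nearest-cell lookup with the northwest tie-break of [cell_of()].
#'
#' @param r a [grid_raster] or a named list of them (shared grid).
#' @param x,y point coordinates.
#' @return vector of values, or a data.frame (one column per raster) for a
#'   list input; `NA` for off-extent points or undefined cells.
#' @export
raster_extract <- function(r, x, y) {
  if (is.list(r) && !inherits(r, "grid_raster")) {
    idx <- cell_of(r[[1]], x, y)
    out <- lapply(r, function(b) b$values[cbind(idx$row, idx$col)])
    return(as.data.frame(out, optional = TRUE))
  }
  idx <- cell_of(r, x, y)
  r$values[cbind(idx$row, idx$col)]
}

#' Write / read a grid raster as Esri ASCII grid
#'
#' Plain-text interchange format readable by standard GIS tools.
#'
#' @param r a [grid_raster].
#' @param path file path (conventionally `.asc`).
#' @param digits significant digits written.
#' @return `read_ascii_grid` returns a [grid_raster]; `write_ascii_grid`
#'   returns `path` invisibly.
#' @export
write_ascii_grid <- function(r, path, digits = 7) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(r$values)),
    sprintf("nrows %d", nrow(r$values)),
    sprintf("xllcorner %.6f", r$xmin),
    sprintf("yllcorner %.6f", r$ymin),
    sprintf("cellsize %.6f", r$res),
    "NODATA_value -9999"), con)
  v <- r$values
  v[is.na(v)] <- -9999
  # ASCII grids are written north to south
  for (i in nrow(v):1)
    writeLines(paste(signif(v[i, ], digits), collapse = " "), con)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path) {
  hdr <- readLines(path, n = 6)
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  get <- function(k) as.numeric(kv[match(k, tolower(kv[, 1])), 2])
  nc <- get("ncols"); nr <- get("nrows")
  vals <- scan(path, skip = 6, quiet = TRUE)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == get("nodata_value")] <- NA
  m <- m[nr:1, , drop = FALSE]  # back to row 1 = south
  grid_raster(m, xmin = get("xllcorner"), ymin = get("yllcorner"),
              res = get("cellsize"))
}
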
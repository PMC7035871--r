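# Light raster containers: a categorical land-cover grid and a multi-band
# reflectance stack, with plain-text (ESRI ASCII grid) I/O through sp.
# Coordinates are planar; the CRS linear unit must be metres for any
# distance-based operation (buffers).

#' Categorical land-cover raster
#'
#' Wraps an integer matrix of class codes with grid geometry. Row 1 is the
#' top (northernmost) row; \code{NA} cells are nodata. Coordinates refer to
#' a projected CRS with linear units of metres (e.g. UTM); geographic
#' degree-unit grids are rejected by distance-based operations.
#'
#' @param values integer matrix of class codes (\code{NA} = nodata).
#' @param cellsize cell edge length in CRS units.
#' @param xmin,ymin coordinates of the lower-left corner of the grid.
#' @param crs_units linear unit of the CRS ("m" or "degree").
#' @param crs_name free-text CRS description kept as metadata.
#' @return an \code{lc_raster} object.
#' @export
lc_raster <- function(values, cellsize, xmin = 0, ymin = 0,
                      crs_units = "m", crs_name = "local metric grid") {
  stop_if(!is.matrix(values), "values must be a matrix")
  stop_if(!(is.numeric(values) || is.integer(values)), "values must be numeric")
  stop_if(!is.numeric(cellsize) || length(cellsize) != 1 || cellsize <= 0,
          "cellsize must be a single positive number")
  storage.mode(values) <- "integer"
  structure(list(values = values, cellsize = as.numeric(cellsize),
                 xmin = as.numeric(xmin), ymin = as.numeric(ymin),
                 crs_units = crs_units, crs_name = crs_name),
            class = "lc_raster")
}

#' @export
print.lc_raster <- function(x, ...) {
  cat(sprintf("<lc_raster> %d x %d cells, cellsize %g %s\n",
              nrow(x$values), ncol(x$values), x$cellsize, x$crs_units))
  cat(sprintf("  extent x [%g, %g]  y [%g, %g]  (%s)\n",
              x$xmin, x$xmin + ncol(x$values) * x$cellsize,
              x$ymin, x$ymin + nrow(x$values) * x$cellsize, x$crs_name))
  p <- class_proportions(x)
  cat("  classes:", paste(sprintf("%s=%.1f%%", names(p), p), collapse = " "),
      "\n")
  invisible(x)
}

#' @export
dim.lc_raster <- function(x) dim(x$values)

# pixel-centre coordinates of every cell, as vectors aligned with
# as.vector(values) (column-major)
pixel_centres <- function(r) {
  nr <- nrow(r$values); nc <- ncol(r$values)
  cx <- r$xmin + (seq_len(nc) - 0.5) * r$cellsize
  cy <- r$ymin + (nr - seq_len(nr) + 0.5) * r$cellsize
  list(x = rep(cx, each = nr), y = rep(cy, times = nc))
}

# row/col of the cell containing point (x, y); NA if off-grid
cell_index <- function(r, x, y) {
  col <- floor((x - r$xmin) / r$cellsize) + 1
  row <- nrow(r$values) - floor((y - r$ymin) / r$cellsize)
  bad <- col < 1 | col > ncol(r$values) | row < 1 | row > nrow(r$values) |
    !is.finite(x) | !is.finite(y)
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  list(row = as.integer(row), col = as.integer(col))
}

#' Global class proportions of a land-cover raster
#'
#' @param r an \code{\link{lc_raster}}.
#' @return named numeric vector of percentages over valid (non-nodata)
#'   cells, named by class code.
#' @export
class_proportions <- function(r) {
  v <- r$values[!is.na(r$values)]
  stop_if(length(v) == 0, "raster has no valid cells")
  100 * table(v) / length(v)
}

#' Read / write a land-cover raster as an ESRI ASCII grid
#'
#' Plain-text single-band raster exchange format, handled through
#' \pkg{sp}. Nodata cells are stored as the format's NODATA value.
#'
#' @param r an \code{\link{lc_raster}}.
#' @param path file path (conventionally \code{.asc}).
#' @param crs_units,crs_name CRS metadata to attach on read (the ASCII grid
#'   header does not carry a CRS).
#' @return \code{write_lc_raster} returns \code{path} invisibly;
#'   \code{read_lc_raster} returns an \code{lc_raster}.
#' @export
write_lc_raster <- function(r, path) {
  nr <- nrow(r$values); nc <- ncol(r$values)
  grid <- sp::GridTopology(
    cellcentre.offset = c(r$xmin + r$cellsize / 2, r$ymin + r$cellsize / 2),
    cellsize = c(r$cellsize, r$cellsize), cells.dim = c(nc, nr))
  # sp grids store values row-wise from the top-left cell
  vals <- as.vector(t(r$values))
  sgdf <- sp::SpatialGridDataFrame(grid, data.frame(band1 = vals))
  sp::write.asciigrid(sgdf, path, na.value = -9999)
  invisible(path)
}

#' @rdname write_lc_raster
#' @export
read_lc_raster <- function(path, crs_units = "m",
                           crs_name = "local metric grid") {
  sgdf <- sp::read.asciigrid(path, as.image = FALSE)
  gp <- sp::gridparameters(sgdf)
  nc <- gp$cells.dim[1]; nr <- gp$cells.dim[2]
  stop_if(abs(gp$cellsize[1] - gp$cellsize[2]) > 1e-9,
          "non-square cells are not supported")
  vals <- matrix(sgdf@data[[1]], nrow = nr, ncol = nc, byrow = TRUE)
  lc_raster(vals, cellsize = gp$cellsize[1],
            xmin = gp$cellcentre.offset[1] - gp$cellsize[1] / 2,
            ymin = gp$cellcentre.offset[2] - gp$cellsize[2] / 2,
            crs_units = crs_units, crs_name = crs_name)
}

#' Multi-band reflectance stack
#'
#' A stack of co-registered bands on one grid, with a shared validity mask
#' (FALSE = masked, e.g. cloud or cloud shadow). Used as input to
#' \code{\link{build_composite}} and the classifier.
#'
#' @param bands 3-d numeric array (rows x cols x bands).
#' @param band_names character vector naming each band.
#' @param mask logical matrix, TRUE where the pixel is valid; defaults to
#'   all-valid.
#' @param cellsize,xmin,ymin,crs_units,crs_name grid geometry as in
#'   \code{\link{lc_raster}}.
#' @return a \code{reflectance_stack}.
#' @export
reflectance_stack <- function(bands, band_names = NULL, mask = NULL,
                              cellsize = 30, xmin = 0, ymin = 0,
                              crs_units = "m",
                              crs_name = "local metric grid") {
  stop_if(length(dim(bands)) != 3, "bands must be a 3-d array")
  if (is.null(band_names))
    band_names <- sprintf("b%d", seq_len(dim(bands)[3]))
  stop_if(length(band_names) != dim(bands)[3],
          "band_names length must match band count")
  if (is.null(mask)) mask <- matrix(TRUE, dim(bands)[1], dim(bands)[2])
  stop_if(!identical(dim(mask), dim(bands)[1:2]),
          "mask geometry must match bands")
  structure(list(bands = bands, band_names = band_names, mask = mask,
                 cellsize = cellsize, xmin = xmin, ymin = ymin,
                 crs_units = crs_units, crs_name = crs_name),
            class = "reflectance_stack")
}

same_geometry <- function(a, b) {
  identical(dim(a$bands)[1:2], dim(b$bands)[1:2]) &&
    isTRUE(all.equal(c(a$cellsize, a$xmin, a$ymin),
                     c(b$cellsize, b$xmin, b$ymin)))
}

#' Read / write a reflectance stack as per-band ASCII grids
#'
#' Each band goes to \code{<prefix>_<band>.asc}; masked pixels are stored as
#' nodata in every band.
#'
#' @param stack a \code{\link{reflectance_stack}}.
#' @param prefix path prefix for the band files.
#' @param paths on read: band files in band order.
#' @return \code{write_stack} returns the file paths invisibly;
#'   \code{read_stack} a \code{reflectance_stack}.
#' @export
write_stack <- function(stack, prefix) {
  paths <- character(0)
  for (k in seq_along(stack$band_names)) {
    v <- stack$bands[, , k]
    v[!stack$mask] <- NA
    p <- sprintf("%s_%s.asc", prefix, stack$band_names[k])
    r <- lc_raster(matrix(0L, nrow(v), ncol(v)), stack$cellsize,
                   stack$xmin, stack$ymin)
    # reuse the grid writer with float payload
    nrc <- dim(v)
    grid <- sp::GridTopology(
      c(stack$xmin + stack$cellsize / 2, stack$ymin + stack$cellsize / 2),
      c(stack$cellsize, stack$cellsize), c(nrc[2], nrc[1]))
    sgdf <- sp::SpatialGridDataFrame(grid, data.frame(b = as.vector(t(v))))
    sp::write.asciigrid(sgdf, p, na.value = -9999)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' @rdname write_stack
#' @export
read_stack <- function(paths, band_names = NULL) {
  stop_if(length(paths) < 1, "no band files given")
  grids <- lapply(paths, sp::read.asciigrid)
  gp <- sp::gridparameters(grids[[1]])
  nc <- gp$cells.dim[1]; nr <- gp$cells.dim[2]
  arr <- array(NA_real_, c(nr, nc, length(paths)))
  for (k in seq_along(grids))
    arr[, , k] <- matrix(grids[[k]]@data[[1]], nr, nc, byrow = TRUE)
  mask <- !apply(is.na(arr), c(1, 2), any)
  arr[is.na(arr)] <- 0
  reflectance_stack(arr, band_names %||%
                      sub("\\.asc$", "", basename(paths)),
                    mask = mask, cellsize = gp$cellsize[1],
                    xmin = gp$cellcentre.offset[1] - gp$cellsize[1] / 2,
                    ymin = gp$cellcentre.offset[2] - gp$cellsize[2] / 2)
}
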
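# Matrix-backed grid raster. Rows index northing (row 1 = northernmost),
# columns index easting; cell centres sit at ((col - 0.5) * cell_size,
# (row - 0.5) * cell_size) in planar metres. All layers of a scene share one
# grid geometry, so a plain matrix plus the cell size is the whole state.

#' Create a grid raster
#'
#' A lightweight georeferenced square-cell raster: a matrix of values
#' (numeric, logical, integer or character) plus the cell edge length in
#' metres. Row 1 is the northernmost row; cell centres are at
#' `((col - 0.5) * cell_size, (row - 0.5) * cell_size)`.
#'
#' @param values A matrix.
#' @param cell_size Cell edge length in metres (default 10, the resolution of
#'   the national land-cover and submerged-vegetation products the analysis
#'   is designed around).
#' @return An object of class `bc_raster`.
#' @examples
#' r <- bc_raster(matrix(runif(100), 10, 10))
#' dim(r)
#' @export
bc_raster <- function(values, cell_size = 10) {
  if (!is.matrix(values)) stop("`values` must be a matrix")
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("`cell_size` must be a single positive number")
  structure(list(values = values, cell_size = as.numeric(cell_size)),
            class = "bc_raster")
}

#' @export
dim.bc_raster <- function(x) dim(x$values)

#' @export
print.bc_raster <- function(x, ...) {
  cat(sprintf("<bc_raster> %d x %d cells, %.1f m resolution (%s)\n",
              nrow(x$values), ncol(x$values), x$cell_size,
              typeof(x$values)))
  invisible(x)
}

is_bc_raster <- function(x) inherits(x, "bc_raster")

#' Cell area in square kilometres
#' @param x A [bc_raster] or a cell size in metres.
#' @return Area of one cell in km^2.
#' @export
cell_area_km2 <- function(x) {
  cs <- if (is_bc_raster(x)) x$cell_size else x
  (cs / 1000)^2
}

#' Area covered by a boolean mask
#' @param mask A logical [bc_raster].
#' @return Area in km^2 of the TRUE cells.
#' @export
mask_area_km2 <- function(mask) {
  stopifnot(is_bc_raster(mask), is.logical(mask$values))
  sum(mask$values, na.rm = TRUE) * cell_area_km2(mask)
}

# Error unless all rasters share one grid geometry. NULL entries are skipped.
check_same_grid <- function(...) {
  rs <- Filter(Negate(is.null), list(...))
  if (!length(rs)) return(invisible(TRUE))
  ref <- rs[[1]]
  for (r in rs) {
    if (!is_bc_raster(r)) stop("expected bc_raster inputs")
    if (!identical(dim(r$values), dim(ref$values)) ||
        !isTRUE(all.equal(r$cell_size, ref$cell_size)))
      stop("rasters do not share one grid geometry")
  }
  invisible(TRUE)
}

#' Euclidean distance to the nearest TRUE cell
#'
#' Exact Euclidean distance transform between cell centres. Cells where the
#' mask is TRUE get distance 0; if the mask has no TRUE cell every distance
#' is `Inf`.
#'
#' @param mask A logical [bc_raster].
#' @return A numeric [bc_raster] of distances in metres.
#' @export
distance_to <- function(mask) {
  stopifnot(is_bc_raster(mask), is.logical(mask$values))
  v <- mask$values
  v[is.na(v)] <- FALSE
  bc_raster(cpp_edt(v) * mask$cell_size, mask$cell_size)
}

# x/y coordinates (metres) of cell centres for linear indices into the grid.
cell_xy <- function(idx, nr, cell_size) {
  row <- ((idx - 1L) %% nr) + 1L
  col <- ((idx - 1L) %/% nr) + 1L
  list(row = row, col = col,
       x = (col - 0.5) * cell_size, y = (row - 0.5) * cell_size)
}

# Linear index of the cell containing planar point (x, y); NA outside grid.
point_cell <- function(x, y, nr, nc, cell_size) {
  col <- floor(x / cell_size) + 1L
  row <- floor(y / cell_size) + 1L
  ok <- col >= 1L & col <= nc & row >= 1L & row <= nr
  idx <- ifelse(ok, (col - 1L) * nr + row, NA_integer_)
  as.integer(idx)
}
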
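# Concentration rasters and the exact polyline-per-cell length primitive that
# underpins length-weighted extraction of grid concentrations along a route.

#' Construct a concentration grid
#'
#' A georeferenced annual-mean raster in planar metres. Cell `(i, j)`
#' (0-based column i, row j) covers the half-open square
#' `[x0 + i*c, x0 + (i+1)*c) x [y0 + j*c, y0 + (j+1)*c)`; points on the exact
#' top/right domain boundary belong to the last cell.
#'
#' @param origin `c(x0, y0)`, lower-left corner in metres.
#' @param cell_size cell edge length in metres (> 0).
#' @param values numeric matrix, `nrows x ncols`, row 1 the southernmost row;
#'   all values must be >= 0 (annual-mean concentrations).
#' @param model_name label of the air pollution model the raster emulates.
#' @return object of class `concentration_grid`.
#' @export
concentration_grid <- function(origin, cell_size, values,
                               model_name = "model") {
  stopifnot(length(origin) == 2L, is.numeric(origin))
  abort_if(cell_size <= 0, "cell_size must be > 0")
  values <- as.matrix(values)
  abort_if(any(values < 0, na.rm = TRUE),
           "concentration values must be >= 0")
  structure(list(origin = as.numeric(origin), cell_size = cell_size,
                 ncols = ncol(values), nrows = nrow(values),
                 values = values, model_name = model_name),
            class = "concentration_grid")
}

#' @export
print.concentration_grid <- function(x, ...) {
  cat(sprintf(
    "<concentration_grid> %s: %d x %d cells of %g m, origin (%g, %g)\n",
    x$model_name, x$ncols, x$nrows, x$cell_size, x$origin[1], x$origin[2]))
  cat(sprintf("  values: %.2f - %.2f ug/m3\n", min(x$values), max(x$values)))
  invisible(x)
}

#' Grid extent as c(xmin, ymin, xmax, ymax)
#' @keywords internal
grid_extent <- function(grid) {
  c(grid$origin[1L], grid$origin[2L],
    grid$origin[1L] + grid$ncols * grid$cell_size,
    grid$origin[2L] + grid$nrows * grid$cell_size)
}

#' 0-based cell indices of points (half-open cells, boundary-clamped)
#' @keywords internal
cell_index <- function(grid, x, y) {
  ix <- floor((x - grid$origin[1L]) / grid$cell_size)
  iy <- floor((y - grid$origin[2L]) / grid$cell_size)
  # exact top/right boundary belongs to the last cell
  ix <- pmin(pmax(ix, 0), grid$ncols - 1L)
  iy <- pmin(pmax(iy, 0), grid$nrows - 1L)
  cbind(ix = as.integer(ix), iy = as.integer(iy))
}

#' Raster value at point locations
#'
#' @param grid a [concentration_grid()]
#' @param x,y point coordinates in metres (must lie inside the grid extent)
#' @return concentrations in ug/m3
#' @export
grid_value_at <- function(grid, x, y) {
  ext <- grid_extent(grid)
  if (any(x < ext[1L] | x > ext[3L] | y < ext[2L] | y > ext[4L])) {
    stop("point outside grid extent", call. = FALSE)
  }
  idx <- cell_index(grid, x, y)
  grid$values[cbind(idx[, "iy"] + 1L, idx[, "ix"] + 1L)]
}

#' Exact per-cell path lengths of a polyline across a raster
#'
#' Clips every polyline piece to the grid cells it traverses by computing the
#' parametric crossings with the cell edge lines, so the returned lengths are
#' exact (up to floating point) and sum to the polyline length. This is the
#' support for length-weighted extraction of grid concentrations along a
#' commuter leg.
#'
#' @param polyline n x 2 matrix of (x, y) in metres, entirely inside the grid
#'   extent; a vertex outside raises a "leg outside grid" error rather than
#'   silently clamping.
#' @param grid a [concentration_grid()].
#' @return data.frame with 0-based cell columns `ix`, `iy` and the in-cell
#'   `length` in metres, one row per traversed cell (aggregated).
#' @export
#' @examples
#' g <- concentration_grid(c(0, 0), 1, matrix(1, 2, 2))
#' cell_path_lengths(rbind(c(0, 0), c(2, 2)), g)  # two cells, sqrt(2) each
cell_path_lengths <- function(polyline, grid) {
  polyline <- as_polyline(polyline)
  ext <- grid_extent(grid)
  if (any(polyline[, 1L] < ext[1L] | polyline[, 1L] > ext[3L] |
          polyline[, 2L] < ext[2L] | polyline[, 2L] > ext[4L])) {
    stop("leg outside grid extent", call. = FALSE)
  }
  cs <- grid$cell_size
  x0 <- grid$origin[1L]
  y0 <- grid$origin[2L]
  keys <- numeric(0)
  lens <- numeric(0)
  for (k in seq_len(max(nrow(polyline) - 1L, 0L))) {
    px <- polyline[k, 1L]; py <- polyline[k, 2L]
    qx <- polyline[k + 1L, 1L]; qy <- polyline[k + 1L, 2L]
    dx <- qx - px; dy <- qy - py
    seg_len <- sqrt(dx * dx + dy * dy)
    if (seg_len == 0) next
    ts <- c(0, 1)
    if (dx != 0) {
      i_rng <- sort(c(ceiling((min(px, qx) - x0) / cs),
                      floor((max(px, qx) - x0) / cs)))
      ii <- seq(i_rng[1L], i_rng[2L])
      tx <- (x0 + ii * cs - px) / dx
      ts <- c(ts, tx[tx > 0 & tx < 1])
    }
    if (dy != 0) {
      j_rng <- sort(c(ceiling((min(py, qy) - y0) / cs),
                      floor((max(py, qy) - y0) / cs)))
      jj <- seq(j_rng[1L], j_rng[2L])
      ty <- (y0 + jj * cs - py) / dy
      ts <- c(ts, ty[ty > 0 & ty < 1])
    }
    ts <- sort(unique(ts))
    mid_t <- (ts[-length(ts)] + ts[-1L]) / 2
    piece <- (ts[-1L] - ts[-length(ts)]) * seg_len
    idx <- cell_index(grid, px + mid_t * dx, py + mid_t * dy)
    keys <- c(keys, idx[, "iy"] * grid$ncols + idx[, "ix"])
    lens <- c(lens, piece)
  }
  if (!length(keys)) {
    # degenerate (single point / zero length): report containing cell, length 0
    idx <- cell_index(grid, polyline[1L, 1L], polyline[1L, 2L])
    return(data.frame(ix = idx[1L, "ix"], iy = idx[1L, "iy"], length = 0))
  }
  agg <- rowsum(lens, group = keys)
  key <- as.numeric(rownames(agg))
  data.frame(ix = as.integer(key %% grid$ncols),
             iy = as.integer(key %/% grid$ncols),
             length = as.numeric(agg))
}
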
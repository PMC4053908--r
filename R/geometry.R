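# Planar geometry primitives used throughout the package.
# All coordinates are planar metres; polylines are n x 2 matrices (x, y).

#' Arc length of a polyline
#'
#' @param polyline numeric matrix with two columns (x, y) and at least one row.
#' @return total length in metres (0 for a single point).
#' @keywords internal
polyline_length <- function(polyline) {
  polyline <- as_polyline(polyline)
  if (nrow(polyline) < 2L) return(0)
  dx <- diff(polyline[, 1L])
  dy <- diff(polyline[, 2L])
  sum(sqrt(dx * dx + dy * dy))
}

#' Coerce to a polyline matrix
#' @keywords internal
as_polyline <- function(x) {
  m <- as.matrix(x)
  if (!is.numeric(m) || ncol(m) != 2L) {
    stop("polyline must be a numeric matrix with columns (x, y)", call. = FALSE)
  }
  storage.mode(m) <- "double"
  m
}

#' Distance from points to a single line segment
#'
#' Vectorised over points: perpendicular distance where the projection falls
#' inside the segment, endpoint distance otherwise.
#'
#' @param px,py point coordinates (equal-length vectors)
#' @param ax,ay,bx,by segment endpoints (scalars)
#' @keywords internal
point_segment_distance <- function(px, py, ax, ay, bx, by) {
  vx <- bx - ax
  vy <- by - ay
  len2 <- vx * vx + vy * vy
  if (len2 == 0) return(sqrt((px - ax)^2 + (py - ay)^2))
  t <- pmin(1, pmax(0, ((px - ax) * vx + (py - ay) * vy) / len2))
  qx <- ax + t * vx
  qy <- ay + t * vy
  sqrt((px - qx)^2 + (py - qy)^2)
}

#' Minimum distance from points to a polyline
#'
#' @param px,py point coordinates
#' @param polyline n x 2 matrix
#' @return vector of distances, one per point
#' @keywords internal
point_polyline_distance <- function(px, py, polyline) {
  polyline <- as_polyline(polyline)
  n <- nrow(polyline)
  if (n == 1L) return(sqrt((px - polyline[1, 1])^2 + (py - polyline[1, 2])^2))
  d <- rep(Inf, length(px))
  for (i in seq_len(n - 1L)) {
    d <- pmin(d, point_segment_distance(
      px, py,
      polyline[i, 1], polyline[i, 2], polyline[i + 1L, 1], polyline[i + 1L, 2]
    ))
  }
  d
}

#' Minimum distance from points to the nearest of many segments
#'
#' @param px,py point coordinates
#' @param seg_coords matrix with columns ax, ay, bx, by (one row per segment)
#' @return vector of distances, one per point
#' @keywords internal
point_segments_distance <- function(px, py, seg_coords) {
  d <- rep(Inf, length(px))
  for (i in seq_len(nrow(seg_coords))) {
    d <- pmin(d, point_segment_distance(
      px, py,
      seg_coords[i, 1], seg_coords[i, 2], seg_coords[i, 3], seg_coords[i, 4]
    ))
  }
  d
}

#' Sample points at approximately regular arc-length spacing along a polyline
#'
#' Used by the classification buffer rule and by test oracles; midpoint
#' positions of `n` equal arc-length slices, so each point represents
#' length/n metres of the line.
#'
#' @param polyline n x 2 matrix
#' @param n number of sample points (>= 1)
#' @return n x 2 matrix of points
#' @keywords internal
sample_polyline <- function(polyline, n) {
  polyline <- as_polyline(polyline)
  if (nrow(polyline) < 2L) {
    return(matrix(rep(polyline[1L, ], each = n), ncol = 2L))
  }
  seg_len <- sqrt(diff(polyline[, 1L])^2 + diff(polyline[, 2L])^2)
  total <- sum(seg_len)
  if (total == 0) return(matrix(rep(polyline[1L, ], each = n), ncol = 2L))
  s <- (seq_len(n) - 0.5) / n * total
  cum <- c(0, cumsum(seg_len))
  idx <- findInterval(s, cum, rightmost.closed = TRUE)
  idx[idx >= nrow(polyline)] <- nrow(polyline) - 1L
  frac <- (s - cum[idx]) / seg_len[idx]
  frac[!is.finite(frac)] <- 0
  cbind(
    polyline[idx, 1L] + frac * (polyline[idx + 1L, 1L] - polyline[idx, 1L]),
    polyline[idx, 2L] + frac * (polyline[idx + 1L, 2L] - polyline[idx, 2L])
  )
}

#' Reverse a polyline
#' @keywords internal
reverse_polyline <- function(polyline) {
  polyline <- as_polyline(polyline)
  polyline[rev(seq_len(nrow(polyline))), , drop = FALSE]
}
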
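# Synthetic road network: a jittered grid of streets with main/side classes.

#' Construct a road network object
#'
#' @param nodes data.frame with columns `id` (integer), `x`, `y` (metres).
#' @param segments data.frame with columns `id`, `from`, `to` (node ids) and
#'   `road_class` ("main" or "side").
#' @return object of class `road_network`. Segment lengths are computed from
#'   node coordinates; geometry is stored as straight 2-point polylines.
#' @export
road_network <- function(nodes, segments) {
  stopifnot(all(c("id", "x", "y") %in% names(nodes)),
            all(c("id", "from", "to", "road_class") %in% names(segments)))
  if (!all(segments$road_class %in% c("main", "side"))) {
    stop("road_class must be 'main' or 'side'", call. = FALSE)
  }
  if (!all(c(segments$from, segments$to) %in% nodes$id)) {
    stop("segment endpoints must reference node ids", call. = FALSE)
  }
  nodes <- nodes[order(nodes$id), c("id", "x", "y")]
  rownames(nodes) <- NULL
  xi <- match(segments$from, nodes$id)
  yi <- match(segments$to, nodes$id)
  geometry <- lapply(seq_len(nrow(segments)), function(k) {
    rbind(c(nodes$x[xi[k]], nodes$y[xi[k]]),
          c(nodes$x[yi[k]], nodes$y[yi[k]]))
  })
  segments$length <- vapply(geometry, polyline_length, numeric(1))
  if (any(segments$length <= 0)) {
    stop("zero-length road segment (from == to?)", call. = FALSE)
  }
  rownames(segments) <- NULL
  structure(list(nodes = nodes,
                 segments = segments[, c("id", "from", "to", "road_class",
                                         "length")],
                 geometry = geometry),
            class = "road_network")
}

#' @export
print.road_network <- function(x, ...) {
  cat(sprintf("<road_network> %d nodes, %d segments (%d main / %d side)\n",
              nrow(x$nodes), nrow(x$segments),
              sum(x$segments$road_class == "main"),
              sum(x$segments$road_class == "side")))
  invisible(x)
}

#' Segment endpoint coordinates as a matrix (ax, ay, bx, by)
#' @keywords internal
network_segment_coords <- function(network) {
  n <- network$nodes
  s <- network$segments
  i <- match(s$from, n$id)
  j <- match(s$to, n$id)
  cbind(ax = n$x[i], ay = n$y[i], bx = n$x[j], by = n$y[j])
}

#' Is every node reachable from every other?
#' @keywords internal
network_is_connected <- function(network) {
  ids <- network$nodes$id
  if (length(ids) <= 1L) return(TRUE)
  adj <- split(c(network$segments$to, network$segments$from),
               c(network$segments$from, network$segments$to))
  seen <- ids[1L]
  frontier <- ids[1L]
  while (length(frontier)) {
    nxt <- setdiff(unique(unlist(adj[as.character(frontier)])), seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  length(seen) == length(ids)
}

#' Nearest network node to a point
#'
#' @param network a `road_network`
#' @param x,y point coordinates in metres
#' @param max_dist maximum snapping distance; `NA` beyond it.
#' @return node id, or `NA_integer_` if no node lies within `max_dist`.
#' @export
nearest_node <- function(network, x, y, max_dist = Inf) {
  d2 <- (network$nodes$x - x)^2 + (network$nodes$y - y)^2
  k <- which.min(d2)
  if (sqrt(d2[k]) > max_dist) return(NA_integer_)
  network$nodes$id[k]
}

#' Generate a synthetic street network
#'
#' Lays out a grid of `n_blocks` x `n_blocks` city blocks inside the scenario
#' domain: `n_blocks + 1` street lines per axis, interior line positions
#' jittered so block sizes vary as in a real street plan (and length ties
#' between alternative routes are rare). Each line is drawn as a side street
#' with probability `p_side`, otherwise a main road; all segments of a line
#' inherit its class. The resulting planar graph is always connected.
#'
#' @param config a [scenario_config()].
#' @return a [road_network()] with `(n_blocks + 1)^2` nodes and
#'   `2 * n_blocks * (n_blocks + 1)` segments.
#' @export
#' @examples
#' net <- generate_network(scenario_config(n_blocks = 2, seed = 1))
#' nrow(net$segments)  # 12
generate_network <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  ext <- config$domain_extent
  nb <- config$n_blocks
  nl <- nb + 1L            # street lines per axis
  rng <- local_seed(config$seed, "network")
  on.exit(rng(), add = TRUE)

  line_pos <- function(lo, hi) {
    span <- hi - lo
    margin <- span / (2 * nl)
    p <- seq(lo + margin, hi - margin, length.out = nl)
    if (nl > 2L) {
      spacing <- (span - 2 * margin) / nb
      jit <- stats::runif(nl - 2L, -0.2, 0.2) * spacing
      p[2:(nl - 1L)] <- p[2:(nl - 1L)] + jit
    }
    p
  }
  vx <- line_pos(ext[1L], ext[3L])   # vertical line x positions
  hy <- line_pos(ext[2L], ext[4L])   # horizontal line y positions

  # class per line: verticals then horizontals
  is_side <- stats::runif(2L * nl) < config$p_side
  v_class <- ifelse(is_side[seq_len(nl)], "side", "main")
  h_class <- ifelse(is_side[nl + seq_len(nl)], "side", "main")

  # nodes: row-major by (y, x); id = (iy - 1) * nl + ix
  nodes <- data.frame(
    id = seq_len(nl * nl),
    x = rep(vx, times = nl),
    y = rep(hy, each = nl)
  )
  node_id <- function(ix, iy) (iy - 1L) * nl + ix

  seg_from <- integer(0); seg_to <- integer(0); seg_class <- character(0)
  for (ix in seq_len(nl)) {          # vertical lines: connect along y
    for (iy in seq_len(nl - 1L)) {
      seg_from <- c(seg_from, node_id(ix, iy))
      seg_to <- c(seg_to, node_id(ix, iy + 1L))
      seg_class <- c(seg_class, v_class[ix])
    }
  }
  for (iy in seq_len(nl)) {          # horizontal lines: connect along x
    for (ix in seq_len(nl - 1L)) {
      seg_from <- c(seg_from, node_id(ix, iy))
      seg_to <- c(seg_to, node_id(ix + 1L, iy))
      seg_class <- c(seg_class, h_class[iy])
    }
  }
  segments <- data.frame(id = seq_along(seg_from), from = seg_from,
                         to = seg_to, road_class = seg_class)
  net <- road_network(nodes, segments)
  if (!network_is_connected(net)) {
    stop("generated network is not connected; check n_blocks", call. = FALSE)
  }
  net
}
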
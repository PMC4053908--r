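# Shared fixtures and independent oracles. Everything is built in code;
# oracles are deliberately naive (enumeration, dense sampling) and never
# share code paths with the implementation they check.

tiny_config <- function(...) {
  args <- list(...)
  defaults <- list(domain_extent = c(0, 0, 600, 600), n_blocks = 2L,
                   n_subjects = 6L, n_weekdays = 10L, seed = 42L)
  do.call(scenario_config, utils::modifyList(defaults, args))
}

# straight two-node network segment helper
hand_network <- function(nodes_xy, edges) {
  nodes <- data.frame(id = seq_len(nrow(nodes_xy)),
                      x = nodes_xy[, 1], y = nodes_xy[, 2])
  segments <- data.frame(id = seq_len(nrow(edges)),
                         from = edges[, 1], to = edges[, 2],
                         road_class = edges[, 3])
  segments$from <- as.integer(segments$from)
  segments$to <- as.integer(segments$to)
  road_network(nodes, segments)
}

# --- routing oracle: exhaustive simple-path enumeration -------------------

enumerate_paths <- function(edges, origin, destination, nodes) {
  # edges: data.frame(from, to, length); returns list of node-id paths
  out <- list()
  recurse <- function(path, visited) {
    last <- path[length(path)]
    if (last == destination) {
      out[[length(out) + 1L]] <<- path
      return(invisible(NULL))
    }
    nbr <- unique(c(edges$to[edges$from == last], edges$from[edges$to == last]))
    for (v in setdiff(nbr, visited)) {
      recurse(c(path, v), c(visited, v))
    }
  }
  recurse(origin, origin)
  out
}

path_len <- function(path, edges) {
  total <- 0
  for (i in seq_len(length(path) - 1L)) {
    m <- (edges$from == path[i] & edges$to == path[i + 1L]) |
      (edges$to == path[i] & edges$from == path[i + 1L])
    total <- total + min(edges$length[m])
  }
  total
}

oracle_shortest <- function(network, origin, destination) {
  edges <- network$segments
  paths <- enumerate_paths(edges, origin, destination, network$nodes$id)
  if (!length(paths)) return(NULL)
  lens <- vapply(paths, path_len, numeric(1), edges = edges)
  best <- which(lens <= min(lens) + 1e-9)
  # lexicographically smallest node sequence among ties
  cand <- paths[best]
  ord <- order(vapply(cand, function(p) paste(sprintf("%06d", p),
                                              collapse = ","), ""))
  list(length = min(lens), path = cand[[ord[1L]]])
}

random_connected_network <- function(n_nodes, extra_edges = 2L) {
  # random spanning tree plus extra edges; random positive lengths via coords
  xy <- matrix(runif(n_nodes * 2, 0, 100), ncol = 2)
  edges <- NULL
  for (v in 2:n_nodes) {
    u <- sample(seq_len(v - 1L), 1L)
    edges <- rbind(edges, c(u, v))
  }
  for (k in seq_len(extra_edges)) {
    uv <- sample(n_nodes, 2L)
    if (!any((edges[, 1] == uv[1] & edges[, 2] == uv[2]) |
             (edges[, 1] == uv[2] & edges[, 2] == uv[1]))) {
      edges <- rbind(edges, uv)
    }
  }
  hand_network(xy, data.frame(from = edges[, 1], to = edges[, 2],
                              road_class = "main"))
}

# --- leg concentration oracle: dense arc-length sampling ------------------

oracle_leg_concentration <- function(polyline, grid, n = 1e4) {
  pts <- no2commute:::sample_polyline(polyline, n)
  mean(grid_value_at(grid, pts[, 1], pts[, 2]))
}

random_grid <- function(ncols, nrows, cell_size, origin = c(0, 0)) {
  concentration_grid(origin, cell_size,
                     matrix(runif(ncols * nrows, 10, 80), nrows, ncols))
}

random_polyline <- function(extent, n_vertices = 4L) {
  cbind(runif(n_vertices, extent[1], extent[3]),
        runif(n_vertices, extent[2], extent[4]))
}

# a subject with explicitly chosen legs/waits, for hand-arithmetic tests
hand_subject <- function(legs, waits = list(), id = 1L) {
  make_subject(id = id, home = 1L, work = 2L, home_xy = c(0, 0),
               work_xy = c(1, 1),
               trips = list(list(direction = "out", start_min = 480,
                                 legs = legs, waits = waits)))
}
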
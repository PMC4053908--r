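# Route simulation: shortest path by distance on the road network, with a
# deterministic lexicographic tie-break, plus the study's trip-completion and
# subject-inclusion rules.

#' Lexicographic comparison of integer node sequences
#' @keywords internal
lex_less <- function(a, b) {
  n <- min(length(a), length(b))
  for (i in seq_len(n)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  length(a) < length(b)
}

#' Single-source shortest paths with lexicographic tie-breaking
#'
#' Plain O(n^2) Dijkstra, adequate for the street networks used here
#' (tens to hundreds of nodes). Among equal-length paths the one with the
#' lexicographically smallest node-id sequence wins, making routing
#' deterministic and independent of edge insertion order.
#' @keywords internal
dijkstra_paths <- function(network, origin) {
  nodes <- network$nodes$id
  n <- length(nodes)
  pos <- match(origin, nodes)
  if (is.na(pos)) stop("origin node not on network", call. = FALSE)
  segs <- network$segments
  fi <- match(segs$from, nodes)
  ti <- match(segs$to, nodes)
  adj <- vector("list", n)
  for (k in seq_len(nrow(segs))) {
    adj[[fi[k]]] <- rbind(adj[[fi[k]]], c(ti[k], segs$length[k], k))
    adj[[ti[k]]] <- rbind(adj[[ti[k]]], c(fi[k], segs$length[k], k))
  }
  dist <- rep(Inf, n)
  done <- rep(FALSE, n)
  paths <- vector("list", n)       # node-id sequences
  segpaths <- vector("list", n)    # segment-id sequences
  dist[pos] <- 0
  paths[[pos]] <- nodes[pos]
  segpaths[[pos]] <- integer(0)
  eps <- 1e-9
  for (iter in seq_len(n)) {
    # pick unfinished node with min dist; tie -> lexicographically least path
    u <- 0L
    for (v in seq_len(n)) {
      if (done[v] || is.infinite(dist[v])) next
      if (u == 0L || dist[v] < dist[u] - eps ||
          (dist[v] <= dist[u] + eps && lex_less(paths[[v]], paths[[u]]))) {
        u <- v
      }
    }
    if (u == 0L) break
    done[u] <- TRUE
    if (is.null(adj[[u]])) next
    for (r in seq_len(nrow(adj[[u]]))) {
      v <- adj[[u]][r, 1L]
      if (done[v]) next
      nd <- dist[u] + adj[[u]][r, 2L]
      cand <- c(paths[[u]], nodes[v])
      if (nd < dist[v] - eps ||
          (nd <= dist[v] + eps && lex_less(cand, paths[[v]]))) {
        dist[v] <- min(nd, dist[v])
        paths[[v]] <- cand
        segpaths[[v]] <- c(segpaths[[u]], segs$id[adj[[u]][r, 3L]])
      }
    }
  }
  list(dist = dist, paths = paths, segpaths = segpaths, nodes = nodes)
}

#' Shortest route between two network nodes
#'
#' Minimises total road-segment length (distance as the cost factor). Ties
#' are broken deterministically: the lexicographically smallest node-id
#' sequence among all minimum-length paths is returned.
#'
#' @param network a [road_network()].
#' @param origin,destination node ids; must differ (a commute between
#'   identical locations is excluded by design) and both lie on the network.
#' @return object of class `route`: list with `node_path`, `segment_ids`,
#'   `total_length` (m) and `polyline`.
#' @export
#' @examples
#' net <- generate_network(scenario_config(n_blocks = 2, seed = 1))
#' r <- shortest_route(net, 1, 9)
#' r$total_length
shortest_route <- function(network, origin, destination) {
  if (identical(origin, destination)) {
    stop("degenerate trip: origin and destination are the same place",
         call. = FALSE)
  }
  if (!origin %in% network$nodes$id || !destination %in% network$nodes$id) {
    stop("origin/destination must be network node ids", call. = FALSE)
  }
  sp <- dijkstra_paths(network, origin)
  di <- match(destination, sp$nodes)
  if (is.infinite(sp$dist[di])) {
    stop("disconnected: no path between origin and destination",
         call. = FALSE)
  }
  node_path <- sp$paths[[di]]
  idx <- match(node_path, network$nodes$id)
  structure(list(node_path = node_path,
                 segment_ids = sp$segpaths[[di]],
                 total_length = sp$dist[di],
                 polyline = cbind(network$nodes$x[idx],
                                  network$nodes$y[idx])),
            class = "route")
}

#' @export
print.route <- function(x, ...) {
  cat(sprintf("<route> %d nodes, %d segments, %.1f m\n",
              length(x$node_path), length(x$segment_ids), x$total_length))
  invisible(x)
}

#' Mirror a trip (reverse direction)
#' @keywords internal
mirror_trip <- function(trip, start_min) {
  legs <- rev(trip$legs)
  legs <- lapply(legs, function(l) {
    l$polyline <- reverse_polyline(l$polyline)
    l
  })
  waits <- rev(trip$waits)
  retime_trip(list(
    direction = if (identical(trip$direction, "out")) "return" else "out",
    start_min = start_min,
    legs = legs,
    waits = waits,
    mirrored = TRUE
  ))
}

#' Recompute leg and wait clock times cumulatively from the trip start
#' @keywords internal
retime_trip <- function(trip) {
  t <- trip$start_min
  nw <- length(trip$waits)
  for (i in seq_along(trip$legs)) {
    # a wait (mode change) precedes legs 2..n when present
    if (i > 1L && nw >= i - 1L && !is.null(trip$waits[[i - 1L]])) {
      trip$waits[[i - 1L]]$start_min <- t %% 1440
      t <- t + trip$waits[[i - 1L]]$duration_min
    }
    trip$legs[[i]]$start_min <- t %% 1440
    t <- t + trip$legs[[i]]$duration_min
  }
  trip
}

#' Complete a subject's uneven trip set by duplication
#'
#' A subject reporting an odd number of trips between home and work/school is
#' missing one direction; the unmatched trip is duplicated as its mirror
#' image (geometry reversed, leg order reversed, modes and durations
#' preserved). The mirrored trip starts at the subject's reported leave time
#' for the opposite location when available, otherwise nine hours after the
#' original trip. Idempotent on even trip counts.
#'
#' @param subject a subject (see [generate_population()]).
#' @return the subject with an even trip count.
#' @export
complete_trips <- function(subject) {
  abort_if(length(subject$trips) < 1L, "subject reports no trips")
  if (length(subject$trips) %% 2L == 0L) return(subject)
  n_out <- sum(vapply(subject$trips, function(t) t$direction == "out",
                      logical(1)))
  n_ret <- length(subject$trips) - n_out
  # mirror a trip of the overrepresented direction
  want <- if (n_out > n_ret) "out" else "return"
  src <- Find(function(t) t$direction == want, rev(subject$trips))
  leave <- if (want == "out") subject$reported_leave["work"]
           else subject$reported_leave["home"]
  if (is.null(leave) || length(leave) == 0L || is.na(leave)) {
    leave <- (src$start_min + 540) %% 1440
  }
  subject$trips <- c(subject$trips, list(mirror_trip(src, as.numeric(leave))))
  subject
}

#' Apply the study's subject-inclusion criteria
#'
#' Retains subjects (a) living AND working/attending school inside the study
#' extent, with the two locations not being the same place, (b) reporting at
#' least one home-work trip, and (c) whose geocode quality is house- or
#' street-level. Each rejected subject is counted under the first failed
#' criterion.
#'
#' @param subjects list of subjects.
#' @param extent study area rectangle `c(xmin, ymin, xmax, ymax)` in metres.
#' @return list with elements `subjects` (retained), `rejections` (named
#'   counts by reason: outside_area, same_place, no_trips, poor_geocode) and
#'   `reason` (per-input character, NA when retained).
#' @export
filter_subjects <- function(subjects, extent) {
  reasons <- rep(NA_character_, length(subjects))
  inside <- function(p) {
    p[1L] >= extent[1L] && p[1L] <= extent[3L] &&
      p[2L] >= extent[2L] && p[2L] <= extent[4L]
  }
  for (i in seq_along(subjects)) {
    s <- subjects[[i]]
    if (!inside(s$home_xy) || !inside(s$work_xy)) {
      reasons[i] <- "outside_area"
    } else if (isTRUE(s$home == s$work) ||
               isTRUE(all(abs(s$home_xy - s$work_xy) < 1e-9))) {
      reasons[i] <- "same_place"
    } else if (length(s$trips) < 1L) {
      reasons[i] <- "no_trips"
    } else if (!is.null(s$geocode_quality) &&
               !s$geocode_quality %in% c("house", "street")) {
      reasons[i] <- "poor_geocode"
    }
  }
  keep <- is.na(reasons)
  counts <- table(factor(reasons[!keep],
                         levels = c("outside_area", "same_place", "no_trips",
                                    "poor_geocode")))
  list(subjects = subjects[keep],
       rejections = stats::setNames(as.integer(counts), names(counts)),
       reason = reasons)
}

#' Agreement between reported and routed distances
#'
#' Unadjusted coefficient of determination of a simple linear regression of
#' routed on reported distance, the quality check guarding against large
#' routing detours.
#'
#' @param reported,routed equal-length numeric vectors of distances in
#'   metres, n >= 3.
#' @return R-squared in `[0, 1]`.
#' @export
distance_agreement <- function(reported, routed) {
  abort_if(length(reported) != length(routed) || length(reported) < 3L,
           "need equal-length vectors with n >= 3")
  abort_if(stats::var(reported) == 0,
           "reported distances have zero variance; R^2 undefined")
  fit <- stats::lm(routed ~ reported)
  summary(fit)$r.squared
}
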
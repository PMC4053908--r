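# Road classification of commuter legs: main vs side street by overlapped
# length, with a 15 m buffer fallback for legs off the network (e.g. tram
# tracks).

#' Classify a leg as main or side street
#'
#' The leg polyline is cut into short arc-length slices; each slice is
#' attributed to the nearest network segment within `snap_tol` metres, and
#' the class with the greatest total overlapped length wins (ties go to
#' main). If no part of the leg lies within `snap_tol` of the network the
#' 15 m buffer rule of [classify_offnetwork_leg()] applies.
#'
#' @param leg a [make_leg()] object (or any list with a `polyline`).
#' @param network a [road_network()].
#' @param snap_tol on-network projection tolerance in metres; routed legs
#'   coincide with the network exactly, so this only absorbs numeric noise.
#' @param buffer_m buffer for the off-network fallback.
#' @return "main" or "side".
#' @export
classify_leg <- function(leg, network, snap_tol = 5, buffer_m = 15) {
  polyline <- as_polyline(leg$polyline)
  len <- polyline_length(polyline)
  abort_if(len <= 0, "cannot classify a zero-length leg")
  n <- max(20L, as.integer(ceiling(len / 2)))
  pts <- sample_polyline(polyline, n)
  slice <- len / n

  seg <- network_segment_coords(network)
  best_d <- rep(Inf, n)
  best_k <- rep(NA_integer_, n)
  for (k in seq_len(nrow(seg))) {
    d <- point_segment_distance(pts[, 1L], pts[, 2L],
                                seg[k, 1L], seg[k, 2L], seg[k, 3L], seg[k, 4L])
    upd <- d < best_d
    best_d[upd] <- d[upd]
    best_k[upd] <- k
  }
  on_net <- best_d <= snap_tol
  if (!any(on_net)) {
    return(classify_offnetwork_leg(leg, network, buffer_m = buffer_m))
  }
  cls <- network$segments$road_class[best_k[on_net]]
  main_len <- sum(cls == "main") * slice
  side_len <- sum(cls == "side") * slice
  if (main_len >= side_len) "main" else "side"
}

#' Classify an off-network leg via a buffer around its polyline
#'
#' Considers every road segment intersecting the `buffer_m` buffer of the leg
#' and compares the total in-buffer segment length per class; the larger
#' class wins, ties go to main. Used for public-transport legs (tram, train)
#' that do not coincide with the road network.
#'
#' @param leg a leg-like list with a `polyline`.
#' @param network a [road_network()].
#' @param buffer_m buffer radius in metres (study rule: 15 m).
#' @return "main" or "side"; error "unclassifiable" when the buffer contains
#'   no road segment.
#' @export
classify_offnetwork_leg <- function(leg, network, buffer_m = 15) {
  polyline <- as_polyline(leg$polyline)
  seg <- network_segment_coords(network)
  cls <- network$segments$road_class
  in_buffer <- c(main = 0, side = 0)
  for (k in seq_len(nrow(seg))) {
    seg_poly <- rbind(seg[k, 1:2], seg[k, 3:4])
    slen <- polyline_length(seg_poly)
    m <- max(10L, as.integer(ceiling(slen / 0.5)))
    pts <- sample_polyline(seg_poly, m)
    d <- point_polyline_distance(pts[, 1L], pts[, 2L], polyline)
    frac <- mean(d <= buffer_m)
    in_buffer[[cls[k]]] <- in_buffer[[cls[k]]] + frac * slen
  }
  if (sum(in_buffer) == 0) {
    stop("unclassifiable: no road segment within the buffer", call. = FALSE)
  }
  if (in_buffer[["main"]] >= in_buffer[["side"]]) "main" else "side"
}

#' Class of the nearest road segment to a point (for waiting locations)
#'
#' @param network a [road_network()].
#' @param x,y location in metres.
#' @param max_dist search radius; "side" is returned when no segment lies
#'   within it (a waiting area away from any road).
#' @return "main" or "side".
#' @export
classify_point <- function(network, x, y, max_dist = 15) {
  seg <- network_segment_coords(network)
  d <- vapply(seq_len(nrow(seg)), function(k) {
    point_segment_distance(x, y, seg[k, 1L], seg[k, 2L],
                           seg[k, 3L], seg[k, 4L])
  }, numeric(1))
  k <- which.min(d)
  if (d[k] > max_dist) "side" else network$segments$road_class[k]
}

#' Classify every leg and wait of a population
#'
#' @param subjects list of subjects with routed legs.
#' @param network a [road_network()].
#' @param snap_tol,buffer_m see [classify_leg()].
#' @return the subjects with `road_class` set on all legs and waits.
#' @export
classify_population <- function(subjects, network, snap_tol = 5,
                                buffer_m = 15) {
  lapply(subjects, function(s) {
    s$trips <- lapply(s$trips, function(tr) {
      tr$legs <- lapply(tr$legs, function(l) {
        l$road_class <- classify_leg(l, network, snap_tol, buffer_m)
        l
      })
      tr$waits <- lapply(tr$waits, function(w) {
        w$road_class <- classify_point(network, w$x, w$y, max_dist = buffer_m)
        w
      })
      tr
    })
    s
  })
}
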
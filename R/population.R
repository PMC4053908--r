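# Synthetic commuter population: travel-diary hierarchy (subject > trip >
# leg/wait) with modes, clock times and routed geometries.

# assumed travel speeds by mode, km/h (durations follow from routed length)
MODE_SPEED_KMH <- c(walking = 5, bicycle = 15, motorized = 30, public = 20,
                    other = 5)

# ventilation ratios relative to motorized/public transport
VENTILATION_RATIO <- c(walking = 1.7, bicycle = 2.0, motorized = 1.0,
                       public = 1.0, other = 1.0)

#' Construct a commuter leg
#'
#' @param id leg identifier.
#' @param subject_id owning subject.
#' @param mode travel mode: walking, bicycle, motorized, public or other.
#' @param polyline leg geometry, n x 2 matrix in metres.
#' @param start_min clock time of leg start, minutes since midnight.
#' @param duration_min leg duration in minutes (> 0); derived from length and
#'   the mode's assumed speed when `NULL`.
#' @param road_class "main", "side" or "unset".
#' @return object of class `leg`.
#' @export
make_leg <- function(id, subject_id, mode, polyline, start_min,
                     duration_min = NULL, road_class = "unset") {
  abort_if(!mode %in% names(MODE_SPEED_KMH), paste("unknown mode:", mode))
  polyline <- as_polyline(polyline)
  len <- polyline_length(polyline)
  abort_if(len <= 0, "leg polyline must have positive length")
  if (is.null(duration_min)) {
    duration_min <- len / (MODE_SPEED_KMH[[mode]] * 1000 / 60)
  }
  abort_if(duration_min <= 0, "leg duration must be > 0")
  structure(list(id = id, subject_id = subject_id, mode = mode,
                 polyline = polyline, length_m = len,
                 start_min = start_min %% 1440,
                 duration_min = duration_min, road_class = road_class),
            class = "leg")
}

#' Hour of day (0-23) of a clock time in minutes
#' @keywords internal
clock_hour <- function(start_min) as.integer(floor(start_min / 60)) %% 24L

#' Construct a waiting episode between two legs
#'
#' @param x,y waiting location in metres (e.g. a public transport stop).
#' @param start_min clock time, minutes since midnight.
#' @param duration_min waiting duration in minutes (>= 0).
#' @param road_class class of the nearest road, or "unset" to classify later.
#' @return object of class `wait`.
#' @export
make_wait <- function(x, y, start_min, duration_min, road_class = "unset") {
  abort_if(duration_min < 0, "wait duration must be >= 0")
  structure(list(x = x, y = y, start_min = start_min %% 1440,
                 duration_min = duration_min, road_class = road_class),
            class = "wait")
}

#' Construct a subject
#'
#' @param id subject identifier.
#' @param home,work network node ids of home and work/school.
#' @param home_xy,work_xy geocoded coordinates in metres.
#' @param geocode_quality "house", "street" or "poor".
#' @param trips list of trips (each a list with `direction`, `start_min`,
#'   `legs`, `waits`).
#' @param reported_leave named vector `c(home = , work = )` of reported leave
#'   times in minutes since midnight (used when duplicating uneven trips).
#' @param reported_distance_m self-reported daily one-way commute distance.
#' @return object of class `subject`.
#' @export
make_subject <- function(id, home, work, home_xy, work_xy,
                         geocode_quality = "house", trips = list(),
                         reported_leave = c(home = NA_real_, work = NA_real_),
                         reported_distance_m = NA_real_) {
  structure(list(id = id, home = home, work = work,
                 home_xy = as.numeric(home_xy), work_xy = as.numeric(work_xy),
                 geocode_quality = geocode_quality, trips = trips,
                 reported_leave = reported_leave,
                 reported_distance_m = reported_distance_m),
            class = "subject")
}

#' Split a routed node path into public-transport trip legs
#'
#' walk (first edge) -> wait -> public (middle) -> wait -> walk (last edge);
#' falls back to a single public leg when the path is too short to split.
#' @keywords internal
split_public_trip <- function(route, network, subject_id, leg_id0) {
  np <- route$node_path
  coords <- route$polyline
  if (length(np) < 4L) {
    return(list(legs = list(make_leg(leg_id0, subject_id, "public", coords,
                                     start_min = 0)),
                waits = list(NULL)))
  }
  l1 <- make_leg(leg_id0, subject_id, "walking",
                 coords[1:2, , drop = FALSE], start_min = 0)
  l2 <- make_leg(leg_id0 + 1L, subject_id, "public",
                 coords[2:(nrow(coords) - 1L), , drop = FALSE], start_min = 0)
  l3 <- make_leg(leg_id0 + 2L, subject_id, "walking",
                 coords[(nrow(coords) - 1L):nrow(coords), , drop = FALSE],
                 start_min = 0)
  w1 <- make_wait(coords[2L, 1L], coords[2L, 2L], 0,
                  duration_min = stats::runif(1, 0, 10))
  w2 <- make_wait(coords[nrow(coords) - 1L, 1L],
                  coords[nrow(coords) - 1L, 2L], 0,
                  duration_min = stats::runif(1, 0, 10))
  list(legs = list(l1, l2, l3), waits = list(w1, w2))
}

#' Generate a synthetic commuter population
#'
#' Each subject gets distinct home and work nodes, a main travel mode drawn
#' from the configured shares, and two trips per day (about 16% get four,
#' with a midday return), starting in the morning (6-8 am) and late-afternoon
#' (4-6 pm) rush hours. Routes are shortest-by-distance on the network;
#' public-transport trips are split into walk/public/walk legs with waiting
#' episodes at the interchange nodes. Leg durations follow from routed length
#' and assumed mode speeds (walk 5, bicycle 15, motorized 30, public
#' 20 km/h). With a positive `uneven_fraction` the matching fraction of
#' subjects has its final return trip removed (to be restored by
#' [complete_trips()]), emulating travel diaries reporting only one
#' direction.
#'
#' @param config a [scenario_config()].
#' @param network a [road_network()] with at least two nodes.
#' @return list of `subject` objects, length `config$n_subjects`.
#' @export
generate_population <- function(config, network) {
  stopifnot(inherits(config, "scenario_config"))
  abort_if(nrow(network$nodes) < 2L,
           "network has fewer than 2 nodes; cannot place commuters")
  rng <- local_seed(config$seed, "population")
  on.exit(rng(), add = TRUE)
  ids <- network$nodes$id
  modes <- names(config$mode_shares)

  subjects <- vector("list", config$n_subjects)
  leg_counter <- 0L
  for (i in seq_len(config$n_subjects)) {
    hw <- sample(ids, 2L)
    route_out <- shortest_route(network, hw[1L], hw[2L])
    mode <- sample(modes, 1L, prob = config$mode_shares)
    four_trips <- stats::runif(1) < 0.16

    t_morning <- round(pmin(pmax(stats::rnorm(1, 420, 40), 330), 600))
    t_evening <- round(pmin(pmax(stats::rnorm(1, 1020, 40), 870), 1230))
    starts <- if (four_trips) {
      t_mid1 <- round(stats::runif(1, 690, 750))   # midday return
      t_mid2 <- round(t_mid1 + stats::runif(1, 45, 90))
      list(c("out", t_morning), c("return", t_mid1),
           c("out", t_mid2), c("return", t_evening))
    } else {
      list(c("out", t_morning), c("return", t_evening))
    }

    build_trip <- function(direction, start_min) {
      if (mode == "public") {
        parts <- split_public_trip(route_out, network, i, leg_counter + 1L)
      } else {
        parts <- list(legs = list(make_leg(leg_counter + 1L, i, mode,
                                           route_out$polyline, 0)),
                      waits = list(NULL))
      }
      leg_counter <<- leg_counter + length(parts$legs)
      trip <- list(direction = direction, start_min = as.numeric(start_min),
                   legs = parts$legs,
                   waits = Filter(Negate(is.null), parts$waits))
      if (direction == "return") {
        trip$legs <- lapply(rev(trip$legs), function(l) {
          l$polyline <- reverse_polyline(l$polyline)
          l
        })
        trip$waits <- rev(trip$waits)
      }
      retime_trip(trip)
    }
    trips <- lapply(starts, function(s) build_trip(s[1L], as.numeric(s[2L])))

    reported_leave <- c(home = t_morning, work = t_evening)
    if (config$uneven_fraction > 0 &&
        stats::runif(1) < config$uneven_fraction) {
      trips <- trips[-length(trips)]   # final return trip goes unreported
    }
    reported <- route_out$total_length * exp(stats::rnorm(1, 0, 0.2))

    idx <- match(hw, ids)
    subjects[[i]] <- make_subject(
      id = i, home = hw[1L], work = hw[2L],
      home_xy = c(network$nodes$x[idx[1L]], network$nodes$y[idx[1L]]),
      work_xy = c(network$nodes$x[idx[2L]], network$nodes$y[idx[2L]]),
      trips = trips, reported_leave = reported_leave,
      reported_distance_m = reported
    )
  }
  subjects
}

#' Flatten subjects to a per-leg table
#'
#' @param subjects list of subjects.
#' @return data.frame with one row per leg: subject_id, trip index,
#'   direction, leg id, mode, road_class, start_min, start_hour,
#'   duration_min, length_m.
#' @export
legs_table <- function(subjects) {
  rows <- list()
  for (s in subjects) {
    for (ti in seq_along(s$trips)) {
      tr <- s$trips[[ti]]
      for (l in tr$legs) {
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = s$id, trip = ti, direction = tr$direction,
          leg_id = l$id, mode = l$mode, road_class = l$road_class,
          start_min = l$start_min, start_hour = clock_hour(l$start_min),
          duration_min = l$duration_min, length_m = l$length_m
        )
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(subject_id = integer(0), trip = integer(0),
                      direction = character(0), leg_id = integer(0),
                      mode = character(0), road_class = character(0),
                      start_min = numeric(0), start_hour = integer(0),
                      duration_min = numeric(0), length_m = numeric(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
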
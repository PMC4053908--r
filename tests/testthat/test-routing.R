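# Shortest routes, trip completion, inclusion filters, distance agreement.

test_that("shortest_route handles the trivial and triangle cases", {
  two <- hand_network(rbind(c(0, 0), c(7, 0)),
                      data.frame(from = 1, to = 2, road_class = "main"))
  r <- shortest_route(two, 1L, 2L)
  expect_equal(r$total_length, 7)
  expect_equal(r$node_path, c(1L, 2L))

  # 3-4-5 triangle: direct 5-edge beats the 3+4 detour
  tri <- hand_network(rbind(c(0, 0), c(3, 0), c(3, 4)),
                      data.frame(from = c(1, 2, 1), to = c(2, 3, 3),
                                 road_class = "main"))
  r <- shortest_route(tri, 1L, 3L)
  expect_equal(r$total_length, 5)
  expect_equal(r$node_path, c(1L, 3L))
})

test_that("shortest_route errors on degenerate and disconnected requests", {
  two <- hand_network(rbind(c(0, 0), c(7, 0)),
                      data.frame(from = 1, to = 2, road_class = "main"))
  expect_error(shortest_route(two, 1L, 1L), "degenerate trip")
  four <- hand_network(rbind(c(0, 0), c(1, 0), c(5, 5), c(6, 5)),
                       data.frame(from = c(1, 3), to = c(2, 4),
                                  road_class = "main"))
  expect_error(shortest_route(four, 1L, 4L), "disconnected")
})

test_that("shortest_route matches exhaustive enumeration on random graphs", {
  set.seed(101)
  for (k in 1:40) {
    net <- random_connected_network(sample(4:8, 1), extra_edges = 3L)
    od <- sample(net$nodes$id, 2L)
    got <- shortest_route(net, od[1], od[2])
    want <- oracle_shortest(net, od[1], od[2])
    expect_equal(got$total_length, want$length, tolerance = 1e-9)
    expect_equal(got$node_path, want$path)
  }
})

test_that("length ties break to the lexicographically smallest node path", {
  # unit square: 1-2-4 and 1-3-4 both length 2; 1,2,4 is lexicographic min
  sq <- hand_network(rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1)),
                     data.frame(from = c(1, 1, 2, 3), to = c(2, 3, 4, 4),
                                road_class = "main"))
  r <- shortest_route(sq, 1L, 4L)
  expect_equal(r$node_path, c(1L, 2L, 4L))
  expect_equal(r$total_length, 2)
})

test_that("route lengths agree with igraph on a generated network", {
  skip_if_not_installed("igraph")
  net <- generate_network(tiny_config(n_blocks = 3, seed = 5))
  g <- igraph::graph_from_data_frame(
    net$segments[, c("from", "to")], directed = FALSE,
    vertices = data.frame(name = net$nodes$id))
  dmat <- igraph::distances(g, weights = net$segments$length)
  set.seed(2)
  for (k in 1:10) {
    od <- sample(net$nodes$id, 2L)
    r <- shortest_route(net, od[1], od[2])
    expect_equal(r$total_length,
                 dmat[as.character(od[1]), as.character(od[2])],
                 tolerance = 1e-9)
  }
})

make_trip_subject <- function(n_trips, start = 450) {
  leg <- make_leg(1L, 1L, "walking", rbind(c(0, 0), c(1000, 0)),
                  start_min = start)
  trips <- lapply(seq_len(n_trips), function(i) {
    dir <- if (i %% 2L == 1L) "out" else "return"
    poly <- if (dir == "out") leg$polyline else
      no2commute:::reverse_polyline(leg$polyline)
    l <- make_leg(i, 1L, "walking", poly, start_min = start + 60 * i)
    list(direction = dir, start_min = start + 60 * i, legs = list(l),
         waits = list())
  })
  make_subject(1L, 1L, 2L, c(0, 0), c(1000, 0), trips = trips,
               reported_leave = c(home = 430, work = 1020))
}

test_that("complete_trips duplicates the unmatched direction, mirrored", {
  s1 <- make_trip_subject(1L)
  done <- complete_trips(s1)
  expect_length(done$trips, 2L)
  expect_equal(done$trips[[2]]$direction, "return")
  expect_true(isTRUE(done$trips[[2]]$mirrored))
  expect_equal(done$trips[[2]]$legs[[1]]$polyline,
               no2commute:::reverse_polyline(s1$trips[[1]]$legs[[1]]$polyline))
  expect_equal(done$trips[[2]]$legs[[1]]$mode, "walking")
  # start time taken from the reported work leave time
  expect_equal(done$trips[[2]]$start_min, 1020)

  s3 <- make_trip_subject(3L)
  done3 <- complete_trips(s3)
  expect_length(done3$trips, 4L)
  expect_equal(sum(vapply(done3$trips, function(t) isTRUE(t$mirrored),
                          logical(1))), 1L)
  n_out <- sum(vapply(done3$trips, function(t) t$direction == "out",
                      logical(1)))
  expect_equal(n_out, 2L)
})

test_that("complete_trips is idempotent on even trip counts", {
  s2 <- make_trip_subject(2L)
  expect_identical(complete_trips(s2), s2)
  s1done <- complete_trips(make_trip_subject(1L))
  expect_identical(complete_trips(s1done), s1done)
})

test_that("filter_subjects applies the inclusion criteria and partitions rejects", {
  extent <- c(0, 0, 100, 100)
  ok <- make_subject(1L, 1L, 2L, c(10, 10), c(90, 90),
                     trips = list(list(direction = "out", start_min = 420,
                                       legs = list(), waits = list())))
  outside <- make_subject(2L, 1L, 2L, c(-5, 10), c(90, 90),
                          trips = ok$trips)
  same <- make_subject(3L, 1L, 1L, c(10, 10), c(10, 10), trips = ok$trips)
  tripless <- make_subject(4L, 1L, 2L, c(10, 10), c(90, 90))
  poor <- make_subject(5L, 1L, 2L, c(10, 10), c(90, 90),
                       geocode_quality = "poor", trips = ok$trips)
  res <- filter_subjects(list(ok, outside, same, tripless, poor), extent)
  expect_length(res$subjects, 1L)
  expect_equal(res$subjects[[1]]$id, 1L)
  expect_equal(unname(res$rejections),
               c(1L, 1L, 1L, 1L))
  expect_equal(res$reason[2], "outside_area")
  expect_equal(res$reason[3], "same_place")
  # rejection reasons partition the removed set
  expect_equal(sum(res$rejections), 5L - length(res$subjects))
  expect_identical(filter_subjects(list(), extent)$subjects, list())
})

test_that("distance_agreement computes the unadjusted R-squared", {
  # exact fits trigger summary.lm's perfect-fit warning; irrelevant here
  expect_equal(suppressWarnings(
    distance_agreement(c(10, 20, 30), c(10, 20, 30))), 1)
  expect_equal(suppressWarnings(
    distance_agreement(c(10, 20, 30), 2 * c(10, 20, 30) + 5)), 1)
  # hand normal equations for {(10,12),(20,18),(30,33)}:
  # slope 210/200, intercept 0 -> SSE 13.5, SST 234
  expect_equal(distance_agreement(c(10, 20, 30), c(12, 18, 33)),
               1 - 13.5 / 234, tolerance = 1e-12)
  expect_error(distance_agreement(c(5, 5, 5), c(1, 2, 3)), "zero variance")
  expect_error(distance_agreement(c(1, 2), c(1, 2)), "n >= 3")
})
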
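# Synthetic scenario generators: network, rasters, population, stations.

test_that("scenario_config validates its invariants", {
  expect_s3_class(tiny_config(), "scenario_config")
  expect_error(tiny_config(mode_shares = c(walking = 0.5, bicycle = 0.5,
                                           motorized = 0.1, public = 0.1)),
               "sum to 1")
  expect_error(tiny_config(grid_sizes = c(25, 70)), "does not divide")
  expect_error(tiny_config(background_level = -1), "> 0")
  expect_error(tiny_config(domain_extent = c(0, 0, 0, 600)), "degenerate")
})

test_that("a 2x2 block network has 9 nodes, 12 segments, and is connected", {
  net <- generate_network(tiny_config(n_blocks = 2))
  expect_equal(nrow(net$nodes), 9L)
  expect_equal(nrow(net$segments), 12L)
  expect_true(no2commute:::network_is_connected(net))
  # segment length equals polyline arc length
  lens <- vapply(net$geometry, no2commute:::polyline_length, numeric(1))
  expect_equal(net$segments$length, lens, tolerance = 1e-9)
})

test_that("zero side-street density gives an all-main network; seeds reproduce", {
  net <- generate_network(tiny_config(p_side = 0))
  expect_true(all(net$segments$road_class == "main"))
  a <- generate_network(tiny_config(seed = 7))
  b <- generate_network(tiny_config(seed = 7))
  expect_identical(a, b)
  c <- generate_network(tiny_config(seed = 8))
  expect_false(identical(a$nodes, c$nodes))
})

test_that("rasters: uniform field when road increment is zero", {
  cfg <- tiny_config(road_increment = 0)
  grids <- generate_rasters(cfg, generate_network(cfg))
  for (g in grids) {
    expect_equal(as.numeric(g$values),
                 rep(cfg$background_level, length(g$values)),
                 tolerance = 1e-12)
  }
})

test_that("cells far from any road sit within 1% of background", {
  cfg <- scenario_config(domain_extent = c(0, 0, 2000, 2000),
                         decay_length = 40, seed = 1)
  # a single short road in the SW corner; the NE corner is ~2500 m away
  net <- hand_network(rbind(c(10, 10), c(110, 10)),
                      data.frame(from = 1, to = 2, road_class = "main"))
  grids <- generate_rasters(cfg, net)
  g <- grids[["model_100m"]]
  ne_corner <- g$values[g$nrows, g$ncols]
  expect_lt(abs(ne_corner - cfg$background_level) / cfg$background_level,
            0.01)
})

test_that("raster nesting: coarse cells equal the mean of their fine cells", {
  cfg <- tiny_config()
  net <- generate_network(cfg)
  grids <- generate_rasters(cfg, net)
  g25 <- grids[["model_25m"]]; g50 <- grids[["model_50m"]]
  g100 <- grids[["model_100m"]]
  # every 100 m cell = mean of its 4 50 m cells = mean of its 16 25 m cells
  for (i in seq_len(g100$ncols)) {
    for (j in seq_len(g100$nrows)) {
      sub50 <- g50$values[(2 * j - 1):(2 * j), (2 * i - 1):(2 * i)]
      sub25 <- g25$values[(4 * j - 3):(4 * j), (4 * i - 3):(4 * i)]
      expect_equal(g100$values[j, i], mean(sub50), tolerance = 1e-9)
      expect_equal(g100$values[j, i], mean(sub25), tolerance = 1e-6)
    }
  }
})

test_that("model bias shifts one raster additively", {
  cfg <- tiny_config(model_bias = c(0, 0, 2.5))
  cfg0 <- tiny_config(model_bias = 0)
  net <- generate_network(cfg)
  gb <- generate_rasters(cfg, net)
  g0 <- generate_rasters(cfg0, net)
  expect_equal(gb[["model_100m"]]$values,
               g0[["model_100m"]]$values + 2.5, tolerance = 1e-12)
  expect_equal(gb[["model_25m"]]$values, g0[["model_25m"]]$values)
})

test_that("population: determinism, structure, degenerate mode share", {
  cfg <- tiny_config(n_subjects = 5)
  net <- generate_network(cfg)
  p1 <- generate_population(cfg, net)
  p2 <- generate_population(cfg, net)
  expect_identical(p1, p2)
  for (s in p1) {
    expect_true(s$home != s$work)
    expect_true(length(s$trips) %in% c(2L, 4L))
    for (tr in s$trips) {
      for (l in tr$legs) {
        expect_gt(l$duration_min, 0)
        expect_gt(l$length_m, 0)
        expect_true(l$mode %in% c("walking", "bicycle", "motorized",
                                  "public"))
      }
    }
  }
  walk_only <- tiny_config(n_subjects = 4,
                           mode_shares = c(walking = 1, bicycle = 0,
                                           motorized = 0, public = 0))
  pw <- generate_population(walk_only, net)
  modes <- unlist(lapply(pw, function(s)
    lapply(s$trips, function(tr) vapply(tr$legs, `[[`, "", "mode"))))
  expect_true(all(modes == "walking"))
  one_node <- list(nodes = data.frame(id = 1L, x = 0, y = 0))
  expect_error(generate_population(cfg, one_node), "fewer than 2 nodes")
})

test_that("trip-count and mode-share targets hit their binomial 99% CI at n = 1000", {
  cfg <- scenario_config(domain_extent = c(0, 0, 600, 600), n_blocks = 3L,
                         n_subjects = 1000L, seed = 11L)
  net <- generate_network(cfg)
  pop <- generate_population(cfg, net)
  two_trip <- mean(vapply(pop, function(s) length(s$trips) == 2L,
                          logical(1)))
  # spec band [0.80, 0.88] around the 84% reported share
  expect_gte(two_trip, 0.80)
  expect_lte(two_trip, 0.88)
  # per-subject main mode within binomial 99% CI of its configured share
  main_mode <- vapply(pop, function(s) {
    ms <- vapply(s$trips[[1]]$legs, `[[`, "", "mode")
    if ("public" %in% ms) "public" else ms[1L]
  }, "")
  for (m in names(cfg$mode_shares)) {
    p <- cfg$mode_shares[[m]]
    half <- 2.576 * sqrt(p * (1 - p) / 1000)
    expect_gte(mean(main_mode == m), p - half)
    expect_lte(mean(main_mode == m), p + half)
  }
})

test_that("station series: constant, closed-form hourly means, determinism", {
  flat <- tiny_config(noise_sd = 0,
                      diurnal_profile = list(main = rep(1, 24),
                                             side = rep(1, 24)))
  s <- generate_station_series(flat)
  expect_equal(stats::sd(s$street$value), 0)
  expect_equal(unique(s$background$value), flat$background_level)

  prof <- rep(1, 24); prof[9] <- 1.5    # hour 8 multiplier 1.5
  cfg <- tiny_config(noise_sd = 0,
                     diurnal_profile = list(main = prof, side = prof))
  s <- generate_station_series(cfg)
  hour8 <- mean(s$street$value[s$street$hour == 8])
  expect_equal(hour8 / mean(s$street$value), 1.5 / mean(prof),
               tolerance = 1e-12)

  a <- generate_station_series(tiny_config(seed = 3))
  b <- generate_station_series(tiny_config(seed = 3))
  expect_identical(a, b)
  expect_true(all(a$street$value >= 0))
})

test_that("generated concentrations, durations and distances are positive", {
  cfg <- tiny_config(n_subjects = 8)
  net <- generate_network(cfg)
  grids <- generate_rasters(cfg, net)
  pop <- generate_population(cfg, net)
  expect_true(all(vapply(grids, function(g) all(g$values > 0), logical(1))))
  lt <- legs_table(pop)
  expect_true(all(lt$duration_min > 0))
  expect_true(all(lt$length_m > 0))
})
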
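# Exposure engine: per-cell path lengths, leg concentration, subject
# concentration/exposure, ventilation-adjusted dose.

test_that("cell_path_lengths: single cell, diagonal, boundary handling", {
  g <- concentration_grid(c(0, 0), 10, matrix(1, 3, 3))
  one <- cell_path_lengths(rbind(c(2, 2), c(7, 2)), g)
  expect_equal(nrow(one), 1L)
  expect_equal(one$ix, 0L); expect_equal(one$iy, 0L)
  expect_equal(one$length, 5)

  g1 <- concentration_grid(c(0, 0), 1, matrix(1, 2, 2))
  diag2 <- cell_path_lengths(rbind(c(0, 0), c(2, 2)), g1)
  diag2 <- diag2[order(diag2$ix), ]
  expect_equal(diag2$ix, c(0L, 1L))
  expect_equal(diag2$iy, c(0L, 1L))
  expect_equal(diag2$length, c(sqrt(2), sqrt(2)), tolerance = 1e-12)

  # exact top/right boundary belongs to the last cell, no error
  top <- cell_path_lengths(rbind(c(1.5, 2), c(2, 2)), g1)
  expect_equal(sum(top$length), 0.5, tolerance = 1e-12)
  expect_true(all(top$iy == 1L))

  expect_error(cell_path_lengths(rbind(c(0, 0), c(3, 1)), g1),
               "outside grid")
})

test_that("per-cell lengths always sum to the polyline length", {
  set.seed(7)
  g <- random_grid(12, 9, 25)
  for (k in 1:50) {
    poly <- random_polyline(c(0, 0, 300, 225), n_vertices = sample(2:6, 1))
    cpl <- cell_path_lengths(poly, g)
    expect_equal(sum(cpl$length), no2commute:::polyline_length(poly),
                 tolerance = 1e-9 * max(1, no2commute:::polyline_length(poly)))
  }
})

test_that("leg_concentration: uniform grid, hand weighting, point legs", {
  gu <- concentration_grid(c(0, 0), 10, matrix(40, 4, 4))
  leg <- list(polyline = rbind(c(3, 3), c(37, 31)))
  expect_equal(leg_concentration(leg, gu), 40, tolerance = 1e-12)

  g2 <- concentration_grid(c(0, 0), 1, matrix(c(20, 60), 1, 2))
  half <- list(polyline = rbind(c(0, 0.5), c(2, 0.5)))
  expect_equal(leg_concentration(half, g2), 40, tolerance = 1e-12)

  pt <- list(polyline = rbind(c(1.5, 0.5)))
  expect_equal(leg_concentration(pt, g2), 60)
})

test_that("leg_concentration matches the dense-sampling oracle", {
  set.seed(12)
  for (k in 1:25) {
    g <- random_grid(8, 8, 12.5)
    poly <- random_polyline(c(0, 0, 100, 100), n_vertices = 4)
    got <- leg_concentration(list(polyline = poly), g)
    want <- oracle_leg_concentration(poly, g, n = 2e4)
    expect_lt(abs(got - want) / want, 0.005)
  }
})

# fixture for the hand-arithmetic subject: three 100 m cells valued 40/30/25
hand_world <- function() {
  g <- concentration_grid(c(0, 0), 100, matrix(c(40, 30, 25), 1, 3))
  rm_ <- rep(1, 24); rm_[9] <- 1.2
  rt <- ratio_table(rm_, rep(1, 24))
  leg1 <- make_leg(1L, 1L, "motorized", rbind(c(10, 50), c(90, 50)),
                   start_min = 8 * 60, duration_min = 10,
                   road_class = "main")
  leg2 <- make_leg(2L, 1L, "motorized", rbind(c(110, 50), c(190, 50)),
                   start_min = 8 * 60, duration_min = 5, road_class = "side")
  wait <- make_wait(250, 50, start_min = 8 * 60, duration_min = 3,
                    road_class = "side")
  list(grid = g, ratios = rt,
       subject = hand_subject(list(leg1, leg2), list(wait)))
}

test_that("subject concentration and exposure match hand arithmetic", {
  w <- hand_world()
  # (40*1.2*10 + 30*1*5 + 25*1*3) / 18 = 705/18
  expect_equal(subject_concentration(w$subject, w$ratios, w$grid), 705 / 18,
               tolerance = 1e-12)
  e <- subject_exposure(w$subject, w$ratios, w$grid)
  expect_equal(e$E_subject, 705, tolerance = 1e-12)
  expect_equal(e$time_weighted, 705 / 18, tolerance = 1e-12)
  expect_equal(e$time_weighted,
               subject_concentration(w$subject, w$ratios, w$grid))
})

test_that("single leg with unit ratio reduces to the leg concentration; equal durations give the simple mean", {
  g <- concentration_grid(c(0, 0), 100, matrix(c(40, 30, 25), 1, 3))
  idt <- identity_ratio_table()
  l1 <- make_leg(1L, 1L, "walking", rbind(c(10, 50), c(90, 50)),
                 start_min = 420, duration_min = 7, road_class = "main")
  s1 <- hand_subject(list(l1))
  expect_equal(subject_concentration(s1, idt, g),
               leg_concentration(l1, g))
  l2 <- make_leg(2L, 1L, "walking", rbind(c(110, 50), c(190, 50)),
                 start_min = 420, duration_min = 7, road_class = "side")
  s2 <- hand_subject(list(l1, l2))
  expect_equal(subject_concentration(s2, idt, g), mean(c(40, 30)),
               tolerance = 1e-12)
})

test_that("doubling durations doubles E and leaves time-weighted unchanged", {
  w <- hand_world()
  doubled <- w$subject
  doubled$trips[[1]]$legs <- lapply(doubled$trips[[1]]$legs, function(l) {
    l$duration_min <- 2 * l$duration_min; l
  })
  doubled$trips[[1]]$waits <- lapply(doubled$trips[[1]]$waits, function(x) {
    x$duration_min <- 2 * x$duration_min; x
  })
  e1 <- subject_exposure(w$subject, w$ratios, w$grid)
  e2 <- subject_exposure(doubled, w$ratios, w$grid)
  expect_equal(e2$E_subject, 2 * e1$E_subject, tolerance = 1e-12)
  expect_equal(e2$time_weighted, e1$time_weighted, tolerance = 1e-12)
})

test_that("a zero-duration wait changes nothing", {
  w <- hand_world()
  with0 <- w$subject
  with0$trips[[1]]$waits <- c(with0$trips[[1]]$waits,
                              list(make_wait(50, 50, 480, 0, "main")))
  expect_equal(subject_exposure(with0, w$ratios, w$grid)$E_subject,
               subject_exposure(w$subject, w$ratios, w$grid)$E_subject,
               tolerance = 1e-12)
})

test_that("leg_dose applies the mode-specific ventilation ratios", {
  expect_equal(leg_dose(468, "motorized"), 468)
  expect_equal(leg_dose(468, "public"), 468)
  expect_equal(leg_dose(100, "walking"), 170)
  expect_equal(leg_dose(414, "bicycle") / 414, 2.0)
  expect_error(leg_dose(10, "rocket"), "unknown travel mode")
  expect_equal(unname(ventilation_ratios()[c("walking", "bicycle")]),
               c(1.7, 2.0))
})

test_that("median dose / median exposure per mode equals the ventilation ratio exactly", {
  cfg <- tiny_config(n_subjects = 20, seed = 2)
  net <- generate_network(cfg)
  pop <- classify_population(generate_population(cfg, net), net)
  grids <- generate_rasters(cfg, net)
  legs <- compute_leg_exposure(pop, identity_ratio_table(),
                               grids[["model_50m"]])
  vr <- ventilation_ratios()
  for (m in unique(legs$mode)) {
    sub <- legs[legs$mode == m, ]
    expect_equal(stats::median(sub$dose) / stats::median(sub$exposure),
                 unname(vr[[m]]), tolerance = 1e-12)
  }
})

test_that("uniform latent field makes C_subject identical across resolutions", {
  cfg <- tiny_config(road_increment = 0, n_subjects = 6, seed = 3)
  net <- generate_network(cfg)
  pop <- classify_population(generate_population(cfg, net), net)
  grids <- generate_rasters(cfg, net)
  rt <- identity_ratio_table()
  cs <- sapply(grids, function(g) {
    vapply(pop, subject_concentration, numeric(1), ratios = rt, grid = g)
  })
  expect_lt(max(abs(cs[, 1] - cs[, 2])), 1e-9)
  expect_lt(max(abs(cs[, 1] - cs[, 3])), 1e-9)
})

test_that("E_subject is additive over trips", {
  w <- hand_world()
  s <- w$subject
  # split the single trip into two single-leg trips plus the wait
  t1 <- list(direction = "out", start_min = 480,
             legs = s$trips[[1]]$legs[1], waits = s$trips[[1]]$waits)
  t2 <- list(direction = "return", start_min = 1020,
             legs = s$trips[[1]]$legs[2], waits = list())
  split <- s; split$trips <- list(t1, t2)
  expect_equal(subject_exposure(split, w$ratios, w$grid)$E_subject,
               subject_exposure(s, w$ratios, w$grid)$E_subject,
               tolerance = 1e-12)
})
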
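test_that("stress periods break at supply-well start and replacement years", {
  wells <- rbind(
    well_spec("w53", 1, 1, 1, 1000, 1953, 1993),
    well_spec("w61", 1, 1, 2, 1000, 1961, 1984),
    well_spec("w70", 1, 1, 3, 1000, 1970, 1993),
    well_spec("w84", 1, 1, 4, 1000, 1984, 1993),
    well_spec("src", 1, 1, 5, 500, 1937, 1993, role = "effluent_source"))
  periods <- build_stress_periods(wells, c(1937, 1993))
  expect_length(periods, 5)
  bounds <- t(vapply(periods, function(p) c(p$start_year, p$end_year),
                     numeric(2)))
  expect_equal(bounds[, 1], c(1937, 1953, 1961, 1970, 1984))
  expect_equal(bounds[, 2], c(1953, 1961, 1970, 1984, 1993))
  # contiguity and well activity per period
  expect_equal(bounds[-1, 1], bounds[-5, 2])
  ids <- lapply(periods, function(p) sort(p$active_wells$well_id))
  expect_equal(ids[[1]], "src")
  expect_equal(ids[[4]], c("src", "w53", "w61", "w70"))
  # the 1984 replacement supersedes the 1961 well in the last period
  expect_equal(ids[[5]], c("src", "w53", "w70", "w84"))
  # supply wells withdraw, sources inject
  p4 <- periods[[4]]$active_wells
  expect_true(all(p4$rate[p4$well_id != "src"] < 0))
  expect_true(p4$rate[p4$well_id == "src"] > 0)

  expect_length(build_stress_periods(NULL, c(1937, 1993)), 1)
  one <- build_stress_periods(well_spec("w", 1, 1, 1, 10, 1937, 1993),
                              c(1937, 1993))
  expect_length(one, 1)  # breakpoint coincides with the horizon start
  expect_error(build_stress_periods(NULL, c(1993, 1993)), "horizon")
})

test_that("interblock conductance is the harmonic mean times area over distance", {
  g <- grid_spec(n_rows = 1, n_cols = 3, dx = 10, dy = 10,
                 layer_top = 10, layer_bottom = 0)
  con <- function(K) {
    pr <- aquifer_props(g, array(K, dim = c(1, 1, 3)), 0.3)
    plumetrace:::interblock_conductances(g, pr)$cx
  }
  # equal K: C = K A / L = 10 * 100 / 10
  expect_equal(as.vector(con(c(10, 10, 10))), c(100, 100))
  # zero-K neighbour: no-flow contact
  expect_equal(as.vector(con(c(10, 0, 10))), c(0, 0))
  # harmonic mean 2 / (1/10 + 1/40) = 16 ft/day -> C = 16 * 100 / 10
  expect_equal(as.vector(con(c(10, 40, 10)))[1], 160)
})

test_that("steady state reproduces 1-D Laplace and constant-head solutions", {
  g <- grid_spec(n_rows = 1, n_cols = 10, dx = 10, dy = 10,
                 layer_top = 10, layer_bottom = 0)
  pr <- aquifer_props(g, 10, 0.25)
  per <- build_stress_periods(NULL, c(1900, 1901))[[1]]
  bc <- boundary_conditions(
    data.frame(layer = 1, row = 1, col = c(1, 10), head = c(10, 0)))
  h <- solve_steady_state(assemble_system(g, pr, bc, per))
  expect_equal(as.vector(h$head[1, 1, ]), seq(10, 0, length.out = 10),
               tolerance = 1e-10)
  # all boundary heads equal -> constant field; velocities all zero
  bc0 <- boundary_conditions(
    data.frame(layer = 1, row = 1, col = c(1, 10), head = 7))
  h0 <- solve_steady_state(assemble_system(g, pr, bc0, per))
  expect_equal(as.vector(h0$head[1, 1, ]), rep(7, 10), tolerance = 1e-12)
  v0 <- cell_velocities(h0)
  expect_equal(max(abs(v0$fx)), 0, tolerance = 1e-12)
})

test_that("Darcy seepage velocity is K i / n and faces are single-valued", {
  # uniform gradient 0.01 with K = 100, porosity 0.25 -> 4 ft/day
  g <- grid_spec(n_rows = 1, n_cols = 11, dx = 10, dy = 10,
                 layer_top = 10, layer_bottom = 0)
  pr <- aquifer_props(g, 100, 0.25)
  per <- build_stress_periods(NULL, c(1900, 1901))[[1]]
  bc <- boundary_conditions(
    data.frame(layer = 1, row = 1, col = c(1, 11), head = c(1, 0)))
  v <- cell_velocities(solve_steady_state(assemble_system(g, pr, bc, per)))
  inner <- v$fx[1, 1, 2:11] / 0.25
  expect_equal(inner, rep(4, 10), tolerance = 1e-10)
  # an interior face has one stored value shared by both neighbours
  expect_equal(dim(v$fx), c(1, 1, 12))
  expect_error(aquifer_props(g, 100, 0), "porosity")
})

test_that("missing constant-head cells and wells in fixed cells are rejected", {
  g <- grid_spec(n_rows = 2, n_cols = 2, dx = 10, dy = 10,
                 layer_top = 10, layer_bottom = 0)
  pr <- aquifer_props(g, 10, 0.3)
  expect_error(
    boundary_conditions(data.frame(layer = integer(0), row = integer(0),
                                   col = integer(0), head = numeric(0))),
    "constant-head")
  bc <- boundary_conditions(data.frame(layer = 1, row = 1, col = 1,
                                       head = 5))
  per <- build_stress_periods(well_spec("w", 1, 1, 1, 100, 1900, 1910),
                              c(1900, 1910))[[1]]
  expect_error(assemble_system(g, pr, bc, per), "constant-head cell")
})

test_that("global mass balance closes on the synthetic fixture", {
  sc <- fixture_scenario("high")
  for (pf in sc$period_fields) {
    wb <- water_budget(pf$heads)
    expect_lte(abs(wb$imbalance), 1e-6 * wb$inflow)
  }
})

test_that("solutions are linear in the stresses and preserve symmetry", {
  n <- 15
  g <- grid_spec(n_rows = n, n_cols = n, dx = 50, dy = 50,
                 layer_top = 20, layer_bottom = 0)
  pr <- aquifer_props(g, 80, 0.3)
  edge <- unique(rbind(expand.grid(layer = 1, row = c(1, n), col = 1:n),
                       expand.grid(layer = 1, row = 1:n, col = c(1, n))))
  edge$head <- 0  # zero-offset boundary
  ctr <- (n + 1) / 2
  solve_q <- function(mult) {
    bc <- boundary_conditions(edge, recharge = 0.002 * mult)
    w <- well_spec("w", 1, ctr, ctr, 5000 * mult, 1900, 1910)
    per <- build_stress_periods(w, c(1900, 1910))[[1]]
    solve_steady_state(assemble_system(g, pr, bc, per))$head
  }
  h1 <- solve_q(1); h2 <- solve_q(2)
  expect_equal(h2, 2 * h1, tolerance = 1e-8)
  # symmetric aquifer and stresses: symmetric under row/col reflection
  hh <- h1[1, , ]
  expect_equal(hh, hh[n:1, ], tolerance = 1e-9)
  expect_equal(hh, hh[, n:1], tolerance = 1e-9)
})

test_that("Thiem drawdown error shrinks monotonically under grid refinement", {
  errs <- vapply(c(21, 41), thiem_rel_error, numeric(1))
  expect_lt(errs[2], errs[1])
  expect_lt(errs[2], 0.02)
})
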
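# shared fixtures, built once per test run and cached

.fixture_cache <- new.env(parent = emptyenv())

fixture_model <- function() {
  if (is.null(.fixture_cache$model)) {
    .fixture_cache$model <- generate_aquifer()
  }
  .fixture_cache$model
}

fixture_scenario <- function(id = "high") {
  key <- paste0("scen_", id)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- simulate_scenario(fixture_model(), id,
                                               n_particles = 25, seed = 1)
  }
  .fixture_cache[[key]]
}

fixture_cohort <- function(seed = 11, true_or = 1.5) {
  key <- sprintf("cohort_%d_%g", seed, true_or)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- generate_cohort(
      cohort_config(true_or = true_or, seed = seed),
      fixture_model(), fixture_scenario("high"))
  }
  .fixture_cache[[key]]
}

fixture_records <- function(latency = 0, id = "high", seed = 11) {
  ch <- fixture_cohort(seed)
  sc <- fixture_scenario(id)
  compute_exposure(ch$subjects, ch$residences, sc$schedule, ch$systems,
                   latency = latency,
                   private_arrivals = sc$private_arrivals,
                   grid = fixture_model()$grid)
}

# hand-built single-layer velocity field with given face seepage
# velocities (ft/day) on a 1-cell grid; porosity 0.25
one_cell_grid <- function(dx = 10, dy = 10, top = 10, bottom = 0) {
  grid_spec(n_rows = 1, n_cols = 1, dx = dx, dy = dy,
            layer_top = top, layer_bottom = bottom)
}

one_cell_field <- function(grid, vx = c(0, 0), vy = c(0, 0),
                           vz = c(0, 0), porosity = 0.25) {
  structure(list(
    fx = array(vx * porosity, dim = c(1, 1, 2)),
    fy = array(vy * porosity, dim = c(1, 2, 1)),
    # fz[1] is the top face, fz[2] the bottom face; vz given bottom, top
    fz = array(c(vz[2], vz[1]) * porosity, dim = c(2, 1, 1)),
    porosity = array(porosity, dim = c(1, 1, 1)),
    grid = grid, inactive = NULL), class = "velocity_field")
}

make_particle <- function(position, cell = c(1, 1, 1), clock = 0,
                          release_year = 1937) {
  structure(list(position = position, cell = cell, clock = clock,
                 release_year = release_year), class = "particle")
}

# uniform +x flow across an n-col strip, built through the real solver;
# the first and last columns hold the fixed heads, so release particles
# from column 2 onward
uniform_strip <- function(n_cols = 12, dx = 100, v = 100,
                          porosity = 0.25, K = 250) {
  # head gradient i chosen so K * i / porosity = v
  i <- v * porosity / K
  g <- grid_spec(n_rows = 3, n_cols = n_cols, dx = dx, dy = dx,
                 layer_top = 50, layer_bottom = 0)
  pr <- aquifer_props(g, K, porosity)
  drop <- i * dx * (n_cols - 1)
  ch <- rbind(
    data.frame(layer = 1, row = 1:3, col = 1, head = 100),
    data.frame(layer = 1, row = 1:3, col = n_cols, head = 100 - drop))
  bc <- boundary_conditions(ch)
  per <- build_stress_periods(NULL, c(1937, 1993))[[1]]
  h <- solve_steady_state(assemble_system(g, pr, bc, per))
  list(grid = g, field = cell_velocities(h), period = per)
}

thiem_rel_error <- function(n, L = 3050, K = 50, b = 50, Q = 10000) {
  dx <- L / n
  g <- grid_spec(n_rows = n, n_cols = n, dx = dx, dy = dx,
                 layer_top = b, layer_bottom = 0)
  pr <- aquifer_props(g, K, 0.3)
  edge <- unique(rbind(expand.grid(layer = 1, row = c(1, n), col = 1:n),
                       expand.grid(layer = 1, row = 1:n, col = c(1, n))))
  edge$head <- 100
  bc <- boundary_conditions(edge)
  ctr <- (n + 1) / 2
  per <- build_stress_periods(well_spec("p", 1, ctr, ctr, Q, 1900, 1910),
                              c(1900, 1910))[[1]]
  h <- solve_steady_state(assemble_system(g, pr, bc, per))$head[1, , ]
  r1 <- max(2, round(200 / dx)); r2 <- round(600 / dx)
  obs <- mean(c(h[ctr, ctr + r2] - h[ctr, ctr + r1],
                h[ctr, ctr - r2] - h[ctr, ctr - r1],
                h[ctr + r2, ctr] - h[ctr + r1, ctr],
                h[ctr - r2, ctr] - h[ctr - r1, ctr]))
  expected <- Q / (2 * pi * K * b) * log(r2 / r1)
  abs(obs - expected) / expected
}
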
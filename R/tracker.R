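#' Seed particles in effluent source cells
#'
#' Places `n_per_cell` particles in each source cell on a deterministic
#' stratified lattice in the horizontal plane (strata are fixed by
#' `n_per_cell`; the RNG only jitters positions within their strata), at
#' mid-layer depth with a small vertical jitter. The same seed always
#' reproduces the same particles.
#'
#' @param grid a [grid_spec()].
#' @param source_cells data frame with columns `layer`, `row`, `col`.
#' @param n_per_cell particles per source cell (>= 1).
#' @param release_year calendar year of release.
#' @param rng_seed integer seed controlling the within-stratum jitter.
#' @return A list of `particle` objects with fields `position` (x, y, z,
#'   feet), `cell` (layer, row, col), `clock` (elapsed days, 0) and
#'   `release_year`.
#' @export
seed_particles <- function(grid, source_cells, n_per_cell = 25,
                           release_year, rng_seed = 1L) {
  source_cells <- as.data.frame(source_cells)
  if (nrow(source_cells) == 0) stop("empty source cell set")
  if (n_per_cell < 1) stop("n_per_cell must be >= 1")
  xe <- x_edges(grid); ye <- y_edges(grid)
  k <- ceiling(sqrt(n_per_cell))
  strata <- expand.grid(i = seq_len(k), j = seq_len(k))[seq_len(n_per_cell), ]
  with_seed(rng_seed, {
    out <- vector("list", nrow(source_cells) * n_per_cell)
    m <- 0L
    for (s in seq_len(nrow(source_cells))) {
      l <- source_cells$layer[s]; r <- source_cells$row[s]
      c <- source_cells$col[s]
      wx <- (xe[c + 1] - xe[c]) / k
      wy <- (ye[r + 1] - ye[r]) / k
      zmid <- (grid$layer_top[l] + grid$layer_bottom[l]) / 2
      dz <- grid$layer_top[l] - grid$layer_bottom[l]
      for (p in seq_len(n_per_cell)) {
        jit <- runif(3, -0.4, 0.4)
        m <- m + 1L
        out[[m]] <- structure(list(
          position = c(
            xe[c] + (strata$i[p] - 0.5 + jit[1]) * wx,
            ye[r] + (strata$j[p] - 0.5 + jit[2]) * wy,
            zmid + jit[3] * dz / 2),
          cell = c(l, r, c), clock = 0,
          release_year = release_year), class = "particle")
      }
    }
    out
  })
}

# per-axis data for the semi-analytical cell-transit solution:
# entry/exit coordinates and face seepage velocities of the current cell
cell_axis_data <- function(p, v, grid) {
  l <- p$cell[1]; r <- p$cell[2]; c <- p$cell[3]
  n <- v$porosity[l, r, c]
  xe <- x_edges(grid); ye <- y_edges(grid)
  list(
    x = list(xp = p$position[1], x1 = xe[c], x2 = xe[c + 1],
             v1 = v$fx[l, r, c] / n, v2 = v$fx[l, r, c + 1] / n),
    y = list(xp = p$position[2], x1 = ye[r], x2 = ye[r + 1],
             v1 = v$fy[l, r, c] / n, v2 = v$fy[l, r + 1, c] / n),
    z = list(xp = p$position[3], x1 = grid$layer_bottom[l],
             x2 = grid$layer_top[l],
             v1 = v$fz[l + 1, r, c] / n, v2 = v$fz[l, r, c] / n))
}

# exit time along one axis under a linearly varying velocity
# v(x) = v1 + A (x - x1); te = (1/A) log(v_exit / v_p), limit (x_e - x_p)/v
axis_exit <- function(a) {
  dxc <- a$x2 - a$x1
  A <- (a$v2 - a$v1) / dxc
  vmax <- max(abs(a$v1), abs(a$v2))
  if (vmax <= 0) return(list(te = Inf, side = NA_integer_))
  vp <- a$v1 + A * (a$xp - a$x1)
  if (abs(a$v2 - a$v1) <= 1e-10 * vmax) {
    v <- (a$v1 + a$v2) / 2
    if (v > 0) return(list(te = (a$x2 - a$xp) / v, side = 2L))
    if (v < 0) return(list(te = (a$x1 - a$xp) / v, side = 1L))
    return(list(te = Inf, side = NA_integer_))
  }
  if (vp > 0 && a$v2 > 0) {
    list(te = log(a$v2 / vp) / A, side = 2L)
  } else if (vp < 0 && a$v1 < 0) {
    list(te = log(a$v1 / vp) / A, side = 1L)
  } else {
    # the particle runs into an internal stagnation point on this axis
    list(te = Inf, side = NA_integer_)
  }
}

# closed-form axis position after time t (t <= exit time)
axis_position <- function(a, t) {
  dxc <- a$x2 - a$x1
  A <- (a$v2 - a$v1) / dxc
  vmax <- max(abs(a$v1), abs(a$v2))
  pos <- if (vmax <= 0 || abs(a$v2 - a$v1) <= 1e-10 * vmax) {
    a$xp + (a$v1 + a$v2) / 2 * t
  } else {
    vp <- a$v1 + A * (a$xp - a$x1)
    a$x1 + (vp * exp(A * t) - a$v1) / A
  }
  min(max(pos, a$x1), a$x2)
}

#' Semi-analytical transit of a particle across its current cell
#'
#' Within a cell each velocity component varies linearly along its own
#' axis, so the transit time to each candidate exit face has a closed
#' form; the exit face is the axis with the smallest positive transit
#' time and the other coordinates follow from the same closed form.
#'
#' @param p a `particle`.
#' @param v a `velocity_field` from [cell_velocities()].
#' @param grid the [grid_spec()].
#' @return A list with `status` (`"moved"` or `"stagnant"`), `exit_point`
#'   (x, y, z), `exit_time` (days spent in the cell) and `next_cell`
#'   (layer, row, col, or `NULL` when the particle leaves the domain).
#' @export
pollock_step <- function(p, v, grid) {
  ax <- cell_axis_data(p, v, grid)
  ex <- lapply(ax, axis_exit)
  te <- vapply(ex, `[[`, numeric(1), "te")
  te[te <= 0] <- Inf
  if (all(!is.finite(te))) {
    return(list(status = "stagnant", exit_point = p$position,
                exit_time = Inf, next_cell = NULL))
  }
  k <- which.min(te)
  t_exit <- te[[k]]
  side <- ex[[k]]$side
  pos <- c(axis_position(ax$x, t_exit),
           axis_position(ax$y, t_exit),
           axis_position(ax$z, t_exit))
  # snap the exit coordinate exactly onto the crossed face
  pos[k] <- if (side == 2L) ax[[k]]$x2 else ax[[k]]$x1
  nxt <- p$cell
  step <- if (side == 2L) 1L else -1L
  if (k == 1) nxt[3] <- nxt[3] + step          # x axis -> column
  if (k == 2) nxt[2] <- nxt[2] + step          # y axis -> row
  if (k == 3) nxt[1] <- nxt[1] - step          # +z (up) -> shallower layer
  outside <- nxt[1] < 1 || nxt[1] > grid$n_layers ||
    nxt[2] < 1 || nxt[2] > grid$n_rows ||
    nxt[3] < 1 || nxt[3] > grid$n_cols
  if (!outside && !is.null(v$inactive) && v$inactive[nxt[1], nxt[2], nxt[3]]) {
    outside <- TRUE
  }
  list(status = "moved", exit_point = pos, exit_time = t_exit,
       next_cell = if (outside) NULL else nxt)
}

# position after dt days inside the current cell (dt below the exit time)
advance_within_cell <- function(p, v, grid, dt) {
  ax <- cell_axis_data(p, v, grid)
  c(axis_position(ax$x, dt), axis_position(ax$y, dt), axis_position(ax$z, dt))
}

# sink cells (well withdrawal) of a stress period: named vector
# well_id keyed by "l.r.c"
period_sink_cells <- function(period) {
  aw <- period$active_wells
  if (!nrow(aw)) return(character(0))
  net <- rowsum(aw$rate, paste(aw$layer, aw$row, aw$col, sep = "."))
  keys <- rownames(net)[net[, 1] < 0]
  ids <- vapply(keys, function(k) {
    aw$well_id[paste(aw$layer, aw$row, aw$col, sep = ".") == k][1]
  }, character(1))
  setNames(ids, keys)
}

#' Track one particle through a sequence of stress-period velocity fields
#'
#' Advances the particle cell by cell with [pollock_step()], always using
#' the velocity field of the stress period containing the particle's
#' current calendar time. At a period boundary the particle keeps its
#' position and continues under the next field. The track terminates when
#' the particle enters a grid cell holding a net-sink well (capture),
#' leaves the grid or reaches a constant-head cell (both count as domain
#' exits; fixed-head cells stand for far-field boundary water), stagnates,
#' or the time horizon is exhausted.
#'
#' @param p a `particle` from [seed_particles()].
#' @param period_fields list of `list(period = <stress_period>, field =
#'   <velocity_field>)`, contiguous in calendar time and covering the
#'   particle's release year.
#' @param max_years tracking horizon in years from release (default: to the
#'   end of the last period).
#' @return An object of class `particle_track`: `vertices` (data frame
#'   `x`, `y`, `z`, `t_days` with strictly increasing time),
#'   `terminal_status` (`captured_by_well`, `exited_domain`, `stagnant` or
#'   `time_exhausted`), `well_id` (when captured) and `release_year`.
#' @export
track_particle <- function(p, period_fields, max_years = NULL) {
  starts <- vapply(period_fields, function(f) f$period$start_year, numeric(1))
  ends <- vapply(period_fields, function(f) f$period$end_year, numeric(1))
  if (any(abs(ends[-length(ends)] - starts[-1]) > 1e-9)) {
    stop("calendar gap between stress-period velocity fields")
  }
  if (p$release_year < starts[1] - 1e-9) {
    stop("release year precedes the first stress period")
  }
  if (is.null(max_years)) max_years <- ends[length(ends)] - p$release_year
  max_days <- max_years * DAYS_PER_YEAR
  sinks <- lapply(period_fields, function(f) period_sink_cells(f$period))

  verts <- list(c(p$position, p$clock))
  status <- NULL; well <- NA_character_
  g0 <- period_fields[[1]]$field$grid
  max_steps <- 20L * g0$n_layers * g0$n_rows * g0$n_cols + 1000L
  steps <- 0L
  repeat {
    steps <- steps + 1L
    if (steps > max_steps) { status <- "time_exhausted"; break }
    if (p$clock >= max_days - 1e-9) { status <- "time_exhausted"; break }
    t_year <- p$release_year + p$clock / DAYS_PER_YEAR
    k <- which(starts <= t_year + 1e-9 & t_year < ends - 1e-9)
    if (!length(k)) { status <- "time_exhausted"; break }
    k <- k[1]
    fld <- period_fields[[k]]$field
    grid <- fld$grid
    remaining <- min((ends[k] - t_year) * DAYS_PER_YEAR,
                     max_days - p$clock)
    st <- pollock_step(p, fld, grid)
    if (st$status == "stagnant") { status <- "stagnant"; break }
    if (st$exit_time >= remaining) {
      # period (or horizon) boundary: keep position, switch fields
      if (remaining > 1e-9) {
        p$position <- advance_within_cell(p, fld, grid, remaining)
        p$clock <- p$clock + remaining
        verts[[length(verts) + 1]] <- c(p$position, p$clock)
      } else {
        p$clock <- p$clock + 1e-9  # numeric sliver at a period boundary
      }
      next
    }
    p$position <- st$exit_point
    p$clock <- p$clock + st$exit_time
    verts[[length(verts) + 1]] <- c(p$position, p$clock)
    if (is.null(st$next_cell)) { status <- "exited_domain"; break }
    # constant-head cells are far-field boundary water: discharge there
    if (!is.null(fld$fixed) &&
        fld$fixed[st$next_cell[1], st$next_cell[2], st$next_cell[3]]) {
      status <- "exited_domain"
      break
    }
    p$cell <- st$next_cell
    key <- paste(p$cell, collapse = ".")
    if (key %in% names(sinks[[k]])) {
      status <- "captured_by_well"
      well <- sinks[[k]][[key]]
      break
    }
  }
  vm <- do.call(rbind, verts)
  structure(list(
    vertices = data.frame(x = vm[, 1], y = vm[, 2], z = vm[, 3],
                          t_days = vm[, 4]),
    terminal_status = status, well_id = well,
    release_year = p$release_year), class = "particle_track")
}

#' @export
print.particle_track <- function(x, ...) {
  cat(sprintf("<particle_track> %d vertices, %s%s\n",
              nrow(x$vertices), x$terminal_status,
              if (!is.na(x$well_id)) paste0(" (", x$well_id, ")") else ""))
  invisible(x)
}

#' First-arrival calendar years at wells
#'
#' A well is impacted when a particle track ends in the grid cell
#' containing the well; the first impact year is the floor of
#' `release_year + clock / 365.25` over the earliest captured particle.
#' Wells never reached map to `NA`. Arrivals are credited only within the
#' well's operating years.
#'
#' @param tracks list of `particle_track`s computed under one scenario.
#' @param wells well table (rows from [well_spec()]).
#' @param scenario_id label stored with the schedule.
#' @return An object of class `well_impact_schedule`: a data frame with
#'   columns `scenario_id`, `well_id`, `first_impact_year`.
#' @export
detect_arrivals <- function(tracks, wells, scenario_id = "default") {
  wells <- as.data.frame(wells)
  supply <- wells[wells$role == "supply", , drop = FALSE]
  first <- setNames(rep(NA_real_, nrow(supply)), supply$well_id)
  for (tr in tracks) {
    if (!identical(tr$terminal_status, "captured_by_well")) next
    wid <- tr$well_id
    if (!wid %in% names(first)) next
    t_arr <- tr$vertices$t_days[nrow(tr$vertices)]
    yr <- floor(tr$release_year + t_arr / DAYS_PER_YEAR)
    w <- supply[supply$well_id == wid, ]
    if (yr >= w$end_year) next      # no longer operating
    yr <- max(yr, w$start_year)     # cannot be impacted before it exists
    if (is.na(first[wid]) || yr < first[wid]) first[wid] <- yr
  }
  structure(data.frame(scenario_id = scenario_id,
                       well_id = names(first),
                       first_impact_year = as.numeric(first),
                       row.names = NULL, stringsAsFactors = FALSE),
            class = c("well_impact_schedule", "data.frame"))
}

# earliest calendar year a track point passes through each planar cell at
# depth <= depth_criterion below land surface; matrix of years (NA = never).
# Segment midpoints are included so cell crossings between vertices count.
track_cell_arrivals <- function(tracks, grid, depth_criterion = 100) {
  arr <- matrix(NA_real_, grid$n_rows, grid$n_cols)
  surf <- land_surface(grid)
  for (tr in tracks) {
    v <- tr$vertices
    if (nrow(v) == 0) next
    xs <- v$x; ys <- v$y; zs <- v$z; ts <- v$t_days
    if (nrow(v) > 1) {
      mx <- (xs[-1] + xs[-length(xs)]) / 2
      my <- (ys[-1] + ys[-length(ys)]) / 2
      mz <- (zs[-1] + zs[-length(zs)]) / 2
      mt <- (ts[-1] + ts[-length(ts)]) / 2
      xs <- c(xs, mx); ys <- c(ys, my); zs <- c(zs, mz); ts <- c(ts, mt)
    }
    ok <- (surf - zs) <= depth_criterion
    if (!any(ok)) next
    pc <- locate_planar(grid, xs[ok], ys[ok])
    yrs <- floor(tr$release_year + ts[ok] / DAYS_PER_YEAR)
    for (i in seq_len(nrow(pc))) {
      r <- pc[i, 1]; c <- pc[i, 2]
      if (is.na(r) || is.na(c)) next
      if (is.na(arr[r, c]) || yrs[i] < arr[r, c]) arr[r, c] <- yrs[i]
    }
  }
  arr
}

#' Plume impact at a private-well residence
#'
#' A residence on a private well counts as impacted when any effluent
#' track passes through the planar grid cell containing the residence at a
#' depth within `depth_criterion` feet of the land surface (private wells
#' in this kind of aquifer are typically shallower than 100 ft).
#'
#' @param residence_location planar `(x, y)` coordinates (feet).
#' @param tracks list of `particle_track`s for the scenario.
#' @param grid the [grid_spec()].
#' @param depth_criterion screening depth below land surface (feet,
#'   default 100).
#' @return A list with `impacted` (logical) and `first_year` (calendar
#'   year or `NA`).
#' @export
private_well_impact <- function(residence_location, tracks, grid,
                                depth_criterion = 100) {
  pc <- locate_planar(grid, residence_location[1], residence_location[2])
  if (any(is.na(pc))) stop("residence lies outside the model footprint")
  arr <- track_cell_arrivals(tracks, grid, depth_criterion)
  yr <- arr[pc[1, 1], pc[1, 2]]
  list(impacted = !is.na(yr), first_year = yr)
}
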
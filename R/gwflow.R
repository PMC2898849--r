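#' Build the historical stress-period schedule
#'
#' Splits a calendar horizon into piecewise-steady stress periods with
#' breakpoints at every supply-well start (and replacement) year inside the
#' horizon. Each period lists the wells operating throughout it together
#' with their signed volumetric rates: negative for withdrawal (supply),
#' positive for injection (effluent source).
#'
#' @param wells well table (rows from [well_spec()]).
#' @param horizon length-2 integer vector `c(start_year, end_year)`.
#' @param scenario_fraction fraction of rated capacity applied to wells
#'   flagged `scenario_scaled`; other wells pump at
#'   `base_fraction * rated_capacity`.
#' @return A list of `stress_period` objects, contiguous and
#'   non-overlapping, covering the horizon.
#' @examples
#' w <- rbind(
#'   well_spec("a", 1, 1, 1, 1000, 1953, 1993),
#'   well_spec("b", 1, 1, 2, 1000, 1961, 1993))
#' length(build_stress_periods(w, c(1937, 1993)))  # 3 periods
#' @export
build_stress_periods <- function(wells, horizon, scenario_fraction = 1) {
  horizon <- as.integer(horizon)
  if (length(horizon) != 2 || horizon[1] >= horizon[2]) {
    stop("horizon must be c(start_year, end_year) with start < end")
  }
  wells <- if (is.null(wells)) {
    well_spec("none", 1, 1, 1, 0, horizon[1], horizon[2])[0, ]
  } else {
    as.data.frame(wells)
  }
  supply <- wells[wells$role == "supply", , drop = FALSE]
  outside <- supply$end_year <= horizon[1] | supply$start_year >= horizon[2]
  if (any(outside)) {
    verbose_msg(sprintf(
      "%d well(s) operate entirely outside the horizon and are excluded",
      sum(outside)))
  }
  brk <- c(supply$start_year, supply$end_year)
  brk <- sort(unique(brk[brk > horizon[1] & brk < horizon[2]]))
  bounds <- c(horizon[1], brk, horizon[2])
  rate <- wells$rated_capacity *
    ifelse(wells$scenario_scaled, scenario_fraction, wells$base_fraction)
  rate <- ifelse(wells$role == "supply", -rate, rate)
  lapply(seq_len(length(bounds) - 1), function(k) {
    s <- bounds[k]; e <- bounds[k + 1]
    # a well is active in the period iff its [start, end) covers [s, e)
    act <- wells$start_year <= s & wells$end_year >= e &
      wells$rated_capacity > 0
    aw <- wells[act, c("well_id", "layer", "row", "col"), drop = FALSE]
    aw$rate <- rate[act]
    structure(list(start_year = s, end_year = e,
                   active_wells = aw),
              class = "stress_period")
  })
}

#' @export
print.stress_period <- function(x, ...) {
  cat(sprintf("<stress_period> %d-%d, %d active well(s)\n",
              x$start_year, x$end_year, nrow(x$active_wells)))
  invisible(x)
}

# interblock conductances (ft^2/day): harmonic-mean conductivity times face
# area over center distance; zero across impermeable or inactive contacts
interblock_conductances <- function(grid, props, inactive = NULL) {
  nl <- grid$n_layers; nr <- grid$n_rows; nc <- grid$n_cols
  K <- props$K
  if (!is.null(inactive)) K[inactive] <- 0
  dz <- layer_thickness(grid)
  DX <- aperm(array(grid$dx, dim = c(nc, nl, nr)), c(2, 3, 1))
  DY <- aperm(array(grid$dy, dim = c(nr, nl, nc)), c(2, 1, 3))
  DZ <- array(dz, dim = c(nl, nr, nc))
  harm <- function(K1, K2, L1, L2, A) {
    C <- array(0, dim = dim(K1))
    pos <- K1 > 0 & K2 > 0
    C[pos] <- A[pos] / (L1[pos] / (2 * K1[pos]) + L2[pos] / (2 * K2[pos]))
    C
  }
  cx <- if (nc > 1) {
    i1 <- 1:(nc - 1); i2 <- 2:nc
    harm(K[, , i1, drop = FALSE], K[, , i2, drop = FALSE],
         DX[, , i1, drop = FALSE], DX[, , i2, drop = FALSE],
         DY[, , i1, drop = FALSE] * DZ[, , i1, drop = FALSE])
  } else array(0, dim = c(nl, nr, 0))
  cy <- if (nr > 1) {
    i1 <- 1:(nr - 1); i2 <- 2:nr
    harm(K[, i1, , drop = FALSE], K[, i2, , drop = FALSE],
         DY[, i1, , drop = FALSE], DY[, i2, , drop = FALSE],
         DX[, i1, , drop = FALSE] * DZ[, i1, , drop = FALSE])
  } else array(0, dim = c(nl, 0, nc))
  cz <- if (nl > 1) {
    i1 <- 1:(nl - 1); i2 <- 2:nl
    harm(K[i1, , , drop = FALSE], K[i2, , , drop = FALSE],
         DZ[i1, , , drop = FALSE], DZ[i2, , , drop = FALSE],
         DX[i1, , , drop = FALSE] * DY[i1, , , drop = FALSE])
  } else array(0, dim = c(0, nr, nc))
  list(cx = cx, cy = cy, cz = cz)
}

#' Assemble the steady-state flow system for one stress period
#'
#' Builds the symmetric positive-definite sparse linear system `A h = b`
#' with one equation per active, non-constant-head cell. Inter-cell
#' conductances use the harmonic mean of adjacent cell conductivities times
#' face area over center distance; recharge and well rates enter the
#' right-hand side as fixed volumetric rates (feet^3/day).
#'
#' @param grid a [grid_spec()].
#' @param props an [aquifer_props()].
#' @param bc a [boundary_conditions()].
#' @param period a `stress_period` from [build_stress_periods()].
#' @return An object of class `gw_system`.
#' @export
assemble_system <- function(grid, props, bc, period) {
  nl <- grid$n_layers; nr <- grid$n_rows; nc <- grid$n_cols
  dims <- c(nl, nr, nc)
  ncell <- prod(dims)
  inactive <- if (is.null(bc$inactive)) array(FALSE, dims) else bc$inactive
  lin <- function(l, r, c) l + (r - 1L) * nl + (c - 1L) * nl * nr

  fixed <- array(NA_real_, dims)
  ch <- bc$constant_head
  ch_lin <- lin(ch$layer, ch$row, ch$col)
  if (any(inactive[ch_lin])) stop("constant-head cell marked inactive")
  fixed[ch_lin] <- ch$head
  if (all(is.na(fixed[!inactive]))) {
    stop("no constant-head cell in the active domain: singular steady-state system")
  }

  is_unknown <- !inactive & is.na(fixed)
  idx <- array(NA_integer_, dims)
  idx[is_unknown] <- seq_len(sum(is_unknown))
  nun <- sum(is_unknown)

  con <- interblock_conductances(grid, props, inactive)

  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  diag_acc <- numeric(nun)
  b <- numeric(nun)

  # duplicated unknown indices must accumulate, hence rowsum tabulation
  add_faces <- function(lin1, lin2, C) {
    keep <- C > 0
    lin1 <- lin1[keep]; lin2 <- lin2[keep]; C <- C[keep]
    if (!length(C)) return(invisible())
    u1 <- idx[lin1]; u2 <- idx[lin2]
    f1 <- fixed[lin1]; f2 <- fixed[lin2]
    both <- !is.na(u1) & !is.na(u2)
    if (any(both)) {
      ii <<- c(ii, u1[both], u2[both])
      jj <<- c(jj, u2[both], u1[both])
      xx <<- c(xx, -C[both], -C[both])
    }
    acc <- function(u, w) {
      k <- !is.na(u)
      if (any(k)) {
        s <- rowsum(w[k], u[k])
        diag_acc[as.integer(rownames(s))] <<-
          diag_acc[as.integer(rownames(s))] + s[, 1]
      }
    }
    acc(u1, C); acc(u2, C)
    rhs <- function(u, f, w) {
      k <- !is.na(u) & !is.na(f)
      if (any(k)) {
        s <- rowsum(w[k] * f[k], u[k])
        b[as.integer(rownames(s))] <<- b[as.integer(rownames(s))] + s[, 1]
      }
    }
    rhs(u1, f2, C); rhs(u2, f1, C)
    invisible()
  }

  if (nc > 1) {
    g <- expand.grid(l = 1:nl, r = 1:nr, c = 1:(nc - 1))
    add_faces(lin(g$l, g$r, g$c), lin(g$l, g$r, g$c + 1L), as.vector(con$cx))
  }
  if (nr > 1) {
    g <- expand.grid(l = 1:nl, r = 1:(nr - 1), c = 1:nc)
    add_faces(lin(g$l, g$r, g$c), lin(g$l, g$r + 1L, g$c), as.vector(con$cy))
  }
  if (nl > 1) {
    g <- expand.grid(l = 1:(nl - 1), r = 1:nr, c = 1:nc)
    add_faces(lin(g$l, g$r, g$c), lin(g$l + 1L, g$r, g$c), as.vector(con$cz))
  }

  # recharge enters the shallowest active layer of each planar cell
  rch <- bc$recharge
  if (length(rch) == 1) rch <- matrix(rch, nr, nc)
  plan_area <- outer(grid$dy, grid$dx)
  top_layer <- apply(!inactive, c(2, 3), function(a) {
    w <- which(a); if (length(w)) w[1] else NA_integer_
  })
  gg <- expand.grid(r = 1:nr, c = 1:nc)
  tl <- top_layer[cbind(gg$r, gg$c)]
  okr <- !is.na(tl)
  rlin <- lin(tl[okr], gg$r[okr], gg$c[okr])
  ru <- idx[rlin]
  q <- (rch * plan_area)[cbind(gg$r, gg$c)][okr]
  kk <- !is.na(ru)
  if (any(kk)) {
    s <- rowsum(q[kk], ru[kk])
    b[as.integer(rownames(s))] <- b[as.integer(rownames(s))] + s[, 1]
  }

  # wells: fixed volumetric rates at their cells
  aw <- period$active_wells
  if (nrow(aw)) {
    wl <- lin(aw$layer, aw$row, aw$col)
    if (any(!is.na(fixed[wl]))) {
      stop("well occupies a constant-head cell: rejected as a config error")
    }
    if (any(inactive[wl])) stop("well occupies an inactive cell")
    wu <- idx[wl]
    s <- rowsum(aw$rate, wu)
    b[as.integer(rownames(s))] <- b[as.integer(rownames(s))] + s[, 1]
  }

  A <- Matrix::sparseMatrix(
    i = c(ii, seq_len(nun)), j = c(jj, seq_len(nun)),
    x = c(xx, diag_acc), dims = c(nun, nun))
  if (any(diag_acc <= 0)) {
    stop("isolated active cell with no conductance: check conductivity/inactive masks")
  }
  structure(list(A = A, b = b, idx = idx, fixed = fixed,
                 inactive = inactive, grid = grid, props = props, bc = bc,
                 period = period, top_layer = top_layer),
            class = "gw_system")
}

#' Solve a steady-state flow system
#'
#' Solves the assembled sparse SPD system by a direct sparse Cholesky
#' factorisation and verifies the per-cell mass balance residual against
#' the tolerance.
#'
#' @param system a `gw_system` from [assemble_system()].
#' @param tol maximum allowed per-cell net flux imbalance (feet^3/day);
#'   default `1e-8 * max(|stress|)` with a floor of 1e-8.
#' @return An object of class `head_field` with elements `head` (array,
#'   `NA` in inactive cells), `mass_balance_residual`, and the defining
#'   `system`.
#' @export
solve_steady_state <- function(system, tol = NULL) {
  A <- system$A; b <- system$b
  h <- as.numeric(Matrix::solve(A, b))
  resid <- max(abs(as.numeric(A %*% h - b)), 0)
  if (is.null(tol)) tol <- max(1e-8 * max(abs(b), 1), 1e-8)
  if (!is.finite(resid) || resid > tol) {
    stop(sprintf(
      "steady-state solve failed: mass balance residual %.3g > tolerance %.3g ft^3/day",
      resid, tol))
  }
  head <- system$fixed
  head[!is.na(system$idx)] <- h[system$idx[!is.na(system$idx)]]
  head[system$inactive] <- NA_real_
  structure(list(head = head, mass_balance_residual = resid,
                 system = system),
            class = "head_field")
}

#' @export
print.head_field <- function(x, ...) {
  cat(sprintf("<head_field> range %.2f-%.2f ft, residual %.3g ft^3/day\n",
              min(x$head, na.rm = TRUE), max(x$head, na.rm = TRUE),
              x$mass_balance_residual))
  invisible(x)
}

#' Cell-face Darcy fluxes and seepage velocities
#'
#' Computes the Darcy flux (specific discharge, feet/day) across every cell
#' face from the interblock conductances and head differences. Each
#' interior face stores a single shared value; fluxes are positive in the
#' +x (increasing column), +y (increasing row) and +z (upward) directions.
#' Recharge enters through the top face of the shallowest active layer.
#' Seepage (particle) velocity in a cell is the face flux divided by that
#' cell's porosity.
#'
#' @param heads a `head_field` from [solve_steady_state()].
#' @param grid,props the grid and properties used to solve it (defaults to
#'   those stored in the head field).
#' @return An object of class `velocity_field` with face-flux arrays
#'   `fx` (`nl x nr x (nc+1)`), `fy` (`nl x (nr+1) x nc`) and `fz`
#'   (`(nl+1) x nr x nc`, element `[k,,]` is the top face of layer `k`).
#' @export
cell_velocities <- function(heads, grid = heads$system$grid,
                            props = heads$system$props) {
  sys <- heads$system
  nl <- grid$n_layers; nr <- grid$n_rows; nc <- grid$n_cols
  if (any(props$porosity <= 0)) stop("porosity must be positive")
  con <- interblock_conductances(grid, props, sys$inactive)
  h <- heads$head
  h0 <- h; h0[is.na(h0)] <- 0  # inactive: conductance already zero
  dz <- layer_thickness(grid)
  DX <- aperm(array(grid$dx, dim = c(nc, nl, nr)), c(2, 3, 1))
  DY <- aperm(array(grid$dy, dim = c(nr, nl, nc)), c(2, 1, 3))
  DZ <- array(dz, dim = c(nl, nr, nc))

  fx <- array(0, dim = c(nl, nr, nc + 1))
  if (nc > 1) {
    i1 <- 1:(nc - 1); i2 <- 2:nc
    A <- DY[, , i1, drop = FALSE] * DZ[, , i1, drop = FALSE]
    fx[, , 2:nc] <- con$cx *
      (h0[, , i1, drop = FALSE] - h0[, , i2, drop = FALSE]) / A
  }
  fy <- array(0, dim = c(nl, nr + 1, nc))
  if (nr > 1) {
    i1 <- 1:(nr - 1); i2 <- 2:nr
    A <- DX[, i1, , drop = FALSE] * DZ[, i1, , drop = FALSE]
    fy[, 2:nr, ] <- con$cy *
      (h0[, i1, , drop = FALSE] - h0[, i2, , drop = FALSE]) / A
  }
  fz <- array(0, dim = c(nl + 1, nr, nc))
  if (nl > 1) {
    i1 <- 1:(nl - 1); i2 <- 2:nl
    A <- DX[i1, , , drop = FALSE] * DY[i1, , , drop = FALSE]
    # upward positive: flux across the top face of layer i2
    fz[2:nl, , ] <- con$cz *
      (h0[i2, , , drop = FALSE] - h0[i1, , , drop = FALSE]) / A
  }
  # recharge crosses the top face of the shallowest active layer, downward
  rch <- sys$bc$recharge
  if (length(rch) == 1) rch <- matrix(rch, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    tl <- sys$top_layer[r, c]
    if (!is.na(tl)) fz[tl, r, c] <- -rch[r, c]
  }
  structure(list(fx = fx, fy = fy, fz = fz,
                 porosity = props$porosity, grid = grid,
                 inactive = sys$inactive,
                 fixed = !is.na(sys$fixed)),
            class = "velocity_field")
}

#' Volumetric water budget of a solved stress period
#'
#' Sums inflows and outflows across constant-head cells, recharge, and
#' wells. In a converged steady state total in equals total out to within
#' the solver residual.
#'
#' @param heads a `head_field`.
#' @return A list with components `inflow`, `outflow` (feet^3/day, both
#'   positive) and `imbalance` (= inflow - outflow).
#' @export
water_budget <- function(heads) {
  sys <- heads$system
  grid <- sys$grid
  con <- interblock_conductances(grid, sys$props, sys$inactive)
  h <- heads$head; h[is.na(h)] <- 0
  nl <- grid$n_layers; nr <- grid$n_rows; nc <- grid$n_cols
  fixed <- !is.na(sys$fixed)
  inn <- 0; out <- 0
  lin <- function(l, r, c) l + (r - 1L) * nl + (c - 1L) * nl * nr
  pairs <- list()
  if (nc > 1) {
    g <- expand.grid(l = 1:nl, r = 1:nr, c = 1:(nc - 1))
    pairs[[length(pairs) + 1]] <-
      cbind(lin(g$l, g$r, g$c), lin(g$l, g$r, g$c + 1L), as.vector(con$cx))
  }
  if (nr > 1) {
    g <- expand.grid(l = 1:nl, r = 1:(nr - 1), c = 1:nc)
    pairs[[length(pairs) + 1]] <-
      cbind(lin(g$l, g$r, g$c), lin(g$l, g$r + 1L, g$c), as.vector(con$cy))
  }
  if (nl > 1) {
    g <- expand.grid(l = 1:(nl - 1), r = 1:nr, c = 1:nc)
    pairs[[length(pairs) + 1]] <-
      cbind(lin(g$l, g$r, g$c), lin(g$l + 1L, g$r, g$c), as.vector(con$cz))
  }
  for (p in pairs) {
    l1 <- p[, 1]; l2 <- p[, 2]; C <- p[, 3]
    q <- C * (h[l1] - h[l2])  # flow from cell1 into cell2
    # count only faces between a fixed cell and a non-fixed cell
    k1 <- fixed[l1] & !fixed[l2]
    k2 <- fixed[l2] & !fixed[l1]
    ch_out <- sum(q[k1][q[k1] > 0]) + sum(-q[k2][q[k2] < 0])
    ch_in <- sum(-q[k1][q[k1] < 0]) + sum(q[k2][q[k2] > 0])
    inn <- inn + ch_out   # water leaving CH cells enters the domain
    out <- out + ch_in
  }
  rch <- sys$bc$recharge
  if (length(rch) == 1) rch <- matrix(rch, nr, nc)
  plan_area <- outer(grid$dy, grid$dx)
  # recharge enters the budget only where the receiving top active cell
  # is not constant-head (fixed cells absorb it outside the system)
  recv <- matrix(FALSE, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    tl <- sys$top_layer[r, c]
    recv[r, c] <- !is.na(tl) && is.na(sys$fixed[tl, r, c])
  }
  rq <- (rch * plan_area)[recv]
  inn <- inn + sum(rq[rq > 0]); out <- out - sum(rq[rq < 0])
  aw <- sys$period$active_wells
  if (nrow(aw)) {
    inn <- inn + sum(aw$rate[aw$rate > 0])
    out <- out + sum(-aw$rate[aw$rate < 0])
  }
  list(inflow = inn, outflow = out, imbalance = inn - out)
}
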
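#' Define a block-centered finite-difference grid
#'
#' The model domain is a rectilinear grid of `n_layers` x `n_rows` x
#' `n_cols` cells. Cells are addressed `(layer, row, col)` with 1-based
#' indices; layer 1 is the shallowest layer and row 1 lies along the origin
#' edge. The planar x coordinate increases with column index and y with row
#' index. All lengths are in feet, elevations positive upward.
#'
#' @param n_rows,n_cols,n_layers grid dimensions (positive integers).
#' @param dx cell widths along x, one per column (feet); a scalar is
#'   recycled.
#' @param dy cell widths along y, one per row (feet); a scalar is recycled.
#' @param layer_top,layer_bottom elevations of the top and bottom of each
#'   layer (feet, positive up), length `n_layers`, ordered top-down.
#'   Layers must be vertically contiguous (`layer_bottom[l] ==
#'   layer_top[l + 1]`).
#' @param origin planar `(x, y)` coordinates of the corner of cell
#'   `(row 1, col 1)` (feet).
#' @return An object of class `grid_spec`.
#' @examples
#' g <- grid_spec(n_rows = 10, n_cols = 20, dx = 100, dy = 100,
#'                layer_top = 20, layer_bottom = -80)
#' @export
grid_spec <- function(n_rows, n_cols, n_layers = 1L, dx, dy,
                      layer_top, layer_bottom, origin = c(0, 0)) {
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  n_layers <- as.integer(n_layers)
  stopifnot(n_rows >= 1, n_cols >= 1, n_layers >= 1)
  dx <- rep_len(as.numeric(dx), n_cols)
  dy <- rep_len(as.numeric(dy), n_rows)
  layer_top <- rep_len(as.numeric(layer_top), n_layers)
  layer_bottom <- rep_len(as.numeric(layer_bottom), n_layers)
  if (any(dx <= 0) || any(dy <= 0)) {
    stop("cell widths must be positive")
  }
  if (any(layer_top <= layer_bottom)) {
    stop("layer_top must exceed layer_bottom for every layer")
  }
  if (n_layers > 1) {
    gap <- abs(layer_bottom[-n_layers] - layer_top[-1])
    if (any(gap > 1e-9 * max(abs(layer_top - layer_bottom)))) {
      stop("layers must be vertically contiguous and ordered top-down")
    }
  }
  structure(list(
    n_rows = n_rows, n_cols = n_cols, n_layers = n_layers,
    dx = dx, dy = dy,
    layer_top = layer_top, layer_bottom = layer_bottom,
    origin = as.numeric(origin)[1:2]
  ), class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d layer(s) x %d rows x %d cols, %.0f x %.0f ft\n",
              x$n_layers, x$n_rows, x$n_cols, sum(x$dx), sum(x$dy)))
  invisible(x)
}

# face coordinates along each axis
x_edges <- function(grid) grid$origin[1] + cumsum(c(0, grid$dx))
y_edges <- function(grid) grid$origin[2] + cumsum(c(0, grid$dy))
layer_thickness <- function(grid) grid$layer_top - grid$layer_bottom
land_surface <- function(grid) grid$layer_top[1]

# planar cell containing a point; NA outside the footprint
locate_planar <- function(grid, x, y) {
  xe <- x_edges(grid); ye <- y_edges(grid)
  col <- findInterval(x, xe, rightmost.closed = TRUE)
  row <- findInterval(y, ye, rightmost.closed = TRUE)
  col[col < 1 | col > grid$n_cols] <- NA_integer_
  row[row < 1 | row > grid$n_rows] <- NA_integer_
  cbind(row = row, col = col)
}

# layer containing elevation z (layer 1 shallowest); NA outside
locate_layer <- function(grid, z) {
  edges <- c(grid$layer_top[1], grid$layer_bottom)  # descending
  l <- findInterval(-z, -edges, rightmost.closed = TRUE)
  l[l < 1 | l > grid$n_layers] <- NA_integer_
  l
}

#' Define per-cell aquifer properties
#'
#' @param grid a [grid_spec()].
#' @param hydraulic_conductivity isotropic hydraulic conductivity per cell
#'   (feet/day); a scalar or an array of dim
#'   `(n_layers, n_rows, n_cols)`. Zero marks impermeable cells.
#' @param porosity effective porosity per cell, in (0, 1]; scalar or array.
#' @return An object of class `aquifer_props`.
#' @export
aquifer_props <- function(grid, hydraulic_conductivity, porosity) {
  dims <- c(grid$n_layers, grid$n_rows, grid$n_cols)
  expand <- function(v, what) {
    if (length(v) == 1) v <- array(v, dim = dims)
    v <- as.array(v)
    if (!identical(dim(v), as.integer(dims))) {
      stop(sprintf("%s must be scalar or an array of dim (%s)",
                   what, paste(dims, collapse = ", ")))
    }
    v
  }
  K <- expand(hydraulic_conductivity, "hydraulic_conductivity")
  n <- expand(porosity, "porosity")
  if (any(K < 0)) stop("hydraulic conductivity must be >= 0")
  if (any(n <= 0 | n > 1)) stop("porosity must lie in (0, 1]")
  structure(list(K = K, porosity = n), class = "aquifer_props")
}

#' Define boundary conditions
#'
#' @param constant_head data frame with columns `layer`, `row`, `col`,
#'   `head` (feet): cells whose head is held fixed. At least one is
#'   required, otherwise the steady-state system is singular.
#' @param recharge areal recharge flux (feet/day) applied to the top active
#'   layer of each planar cell; scalar or an `n_rows` x `n_cols` matrix.
#' @param inactive optional logical array (`n_layers` x `n_rows` x
#'   `n_cols`) marking no-flow cells.
#' @return An object of class `boundary_conditions`.
#' @export
boundary_conditions <- function(constant_head, recharge = 0,
                                inactive = NULL) {
  ch <- as.data.frame(constant_head)
  need <- c("layer", "row", "col", "head")
  if (!all(need %in% names(ch))) {
    stop("constant_head needs columns layer, row, col, head")
  }
  if (nrow(ch) == 0) {
    stop("at least one constant-head cell is required (singular system otherwise)")
  }
  if (any(!is.finite(ch$head))) stop("constant heads must be finite")
  if (any(!is.finite(recharge))) stop("recharge must be finite")
  structure(list(constant_head = ch, recharge = recharge,
                 inactive = inactive),
            class = "boundary_conditions")
}

#' Describe a well
#'
#' A well occupies one grid cell and is characterised by its rated capacity
#' and operating interval. Supply wells withdraw water; effluent-source
#' wells inject treated wastewater. The operating interval is
#' `[start_year, end_year)`: a well replaced in 1984 has `end_year = 1984`
#' and its replacement `start_year = 1984`.
#'
#' @param well_id label.
#' @param layer,row,col cell indices (1-based).
#' @param rated_capacity maximum volumetric rate (feet^3/day, >= 0).
#' @param start_year,end_year calendar years of operation.
#' @param role `"supply"` (sink) or `"effluent_source"` (source).
#' @param base_fraction fraction of rated capacity pumped in ordinary
#'   operation (default 1).
#' @param scenario_scaled logical; if `TRUE` the well's rate is scaled by
#'   the pumping-scenario fraction instead of `base_fraction`.
#' @return A one-row data frame; rows from several calls can be `rbind`-ed
#'   into a well table.
#' @export
well_spec <- function(well_id, layer, row, col, rated_capacity,
                      start_year, end_year,
                      role = c("supply", "effluent_source"),
                      base_fraction = 1, scenario_scaled = FALSE) {
  role <- match.arg(role)
  if (rated_capacity < 0) stop("rated_capacity must be >= 0")
  if (start_year > end_year) stop("start_year must be <= end_year")
  data.frame(well_id = well_id, layer = as.integer(layer),
             row = as.integer(row), col = as.integer(col),
             rated_capacity = as.numeric(rated_capacity),
             start_year = as.integer(start_year),
             end_year = as.integer(end_year),
             role = role, base_fraction = as.numeric(base_fraction),
             scenario_scaled = scenario_scaled,
             stringsAsFactors = FALSE)
}
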
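#' Write a planar array as an ESRI ASCII grid
#'
#' One layer per file; requires square cells of uniform size (the format
#' has a single CELLSIZE). Row 1 of the matrix is written last so that
#' the file's south-to-north convention round-trips with the grid's
#' origin corner.
#'
#' @param m numeric matrix (`n_rows` x `n_cols`); `NA` becomes the nodata
#'   value.
#' @param path output file.
#' @param xllcorner,yllcorner planar coordinates of the lower-left corner.
#' @param cellsize cell width (feet).
#' @param nodata nodata sentinel (default -9999).
#' @export
write_esri_ascii <- function(m, path, xllcorner = 0, yllcorner = 0,
                             cellsize = 1, nodata = -9999) {
  m[is.na(m)] <- nodata
  hdr <- c(
    sprintf("NCOLS %d", ncol(m)),
    sprintf("NROWS %d", nrow(m)),
    sprintf("XLLCORNER %.10g", xllcorner),
    sprintf("YLLCORNER %.10g", yllcorner),
    sprintf("CELLSIZE %.10g", cellsize),
    sprintf("NODATA_value %.10g", nodata))
  rows <- apply(m[rev(seq_len(nrow(m))), , drop = FALSE], 1,
                function(r) paste(sprintf("%.10g", r), collapse = " "))
  writeLines(c(hdr, rows), path)
}

#' Read an ESRI ASCII grid
#'
#' @param path file written by [write_esri_ascii()] or any conforming
#'   tool.
#' @return A list with `data` (matrix, row 1 northmost), `xllcorner`,
#'   `yllcorner`, `cellsize`, `nodata`.
#' @export
read_esri_ascii <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z_]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr))) {
    stop("not an ESRI ASCII grid: missing ",
         paste(setdiff(need, names(hdr)), collapse = ", "))
  }
  vals <- scan(text = paste(lines[i:length(lines)], collapse = " "),
               quiet = TRUE)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  m[m == nodata] <- NA
  list(data = m,
       xllcorner = if (is.null(hdr$xllcorner)) 0 else hdr$xllcorner,
       yllcorner = if (is.null(hdr$yllcorner)) 0 else hdr$yllcorner,
       cellsize = hdr$cellsize, nodata = nodata)
}

#' Export a head or velocity array as a flat CSV
#'
#' @param arr array of dim `(n_layers, n_rows, n_cols)`.
#' @param path output file.
#' @param value_name name of the value column.
#' @export
write_field_csv <- function(arr, path, value_name = "head") {
  d <- dim(arr)
  g <- expand.grid(layer = seq_len(d[1]), row = seq_len(d[2]),
                   col = seq_len(d[3]))
  g[[value_name]] <- as.vector(arr)
  write.csv(g, path, row.names = FALSE)
}

#' Export particle tracks as CSV
#'
#' @param tracks list of `particle_track`s.
#' @param path output file.
#' @return Invisibly, the exported data frame (`track_id`,
#'   `vertex_index`, `x`, `y`, `z`, `t_days`, `calendar_year`,
#'   `terminal_status`).
#' @export
write_tracks_csv <- function(tracks, path) {
  out <- do.call(rbind, lapply(seq_along(tracks), function(i) {
    tr <- tracks[[i]]
    v <- tr$vertices
    data.frame(track_id = i, vertex_index = seq_len(nrow(v)),
               x = v$x, y = v$y, z = v$z, t_days = v$t_days,
               calendar_year = tr$release_year + v$t_days / DAYS_PER_YEAR,
               terminal_status = tr$terminal_status,
               stringsAsFactors = FALSE)
  }))
  write.csv(out, path, row.names = FALSE)
  invisible(out)
}

#' Read or build an aquifer model description from a config file
#'
#' The config is a YAML or JSON document with a `units` block (must
#' declare feet/days), a `grid` block, `properties` (scalars, inline
#' arrays, or ESRI ASCII file references resolved relative to the config
#' file), `boundaries` (constant-head list and recharge) and a `wells`
#' table.
#'
#' @param path config file (`.yaml`/`.yml`/`.json`).
#' @return A list with `grid`, `props`, `bc`, `wells`.
#' @export
read_aquifer_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(cfg$units) || tolower(cfg$units$length) != "feet" ||
      tolower(cfg$units$time) != "days") {
    stop("config must declare units: length feet, time days")
  }
  g <- cfg$grid
  grid <- grid_spec(n_rows = g$n_rows, n_cols = g$n_cols,
                    n_layers = if (is.null(g$n_layers)) 1 else g$n_layers,
                    dx = g$dx, dy = g$dy,
                    layer_top = g$layer_top, layer_bottom = g$layer_bottom,
                    origin = if (is.null(g$origin)) c(0, 0) else g$origin)
  getprop <- function(p) {
    if (is.character(p)) {
      f <- file.path(dirname(path), p)
      arr <- read_esri_ascii(f)$data
      array(arr, dim = c(1, nrow(arr), ncol(arr)))
    } else if (is.list(p) || length(p) > 1) {
      array(unlist(p), dim = c(grid$n_layers, grid$n_rows, grid$n_cols))
    } else {
      p
    }
  }
  props <- aquifer_props(grid, getprop(cfg$properties$hydraulic_conductivity),
                         getprop(cfg$properties$porosity))
  ch <- as.data.frame(cfg$boundaries$constant_head)
  bc <- boundary_conditions(
    constant_head = ch,
    recharge = if (is.null(cfg$boundaries$recharge)) 0 else
      cfg$boundaries$recharge)
  wells <- do.call(rbind, lapply(cfg$wells, function(w) {
    well_spec(w$well_id, w$layer, w$row, w$col, w$rated_capacity,
              w$start_year, w$end_year,
              role = if (is.null(w$role)) "supply" else w$role,
              base_fraction = if (is.null(w$base_fraction)) 1 else
                w$base_fraction,
              scenario_scaled = isTRUE(w$scenario_scaled))
  }))
  list(grid = grid, props = props, bc = bc, wells = wells)
}
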
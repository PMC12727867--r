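#' Lightweight geographic raster grid
#'
#' An `env_grid` is a regular longitude/latitude grid of real values with an
#' `NA` nodata mask: a numeric matrix whose rows run north to south plus the
#' geotransform (west edge, north edge, square cell size in decimal degrees).
#' It is the in-memory currency for every raster operation in the package
#' (anomalies, focal gap-filling, point extraction, probability maps).
#'
#' @param values Numeric matrix; row 1 is the northernmost row of cells.
#' @param xmin West edge of the grid (decimal degrees).
#' @param ymax North edge of the grid (decimal degrees).
#' @param cellsize Cell size in decimal degrees (cells are square).
#' @param name Layer name.
#' @param units Free-text units note.
#' @return An object of class `env_grid`.
#' @export
env_grid <- function(values, xmin, ymax, cellsize, name = "layer", units = "") {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop_tropirep("`values` must be a numeric matrix", "grid_error")
  }
  if (cellsize <= 0) stop_tropirep("`cellsize` must be positive", "grid_error")
  structure(
    list(values = values, xmin = xmin, ymax = ymax, cellsize = cellsize,
         name = name, units = units),
    class = "env_grid"
  )
}

#' @export
print.env_grid <- function(x, ...) {
  cat(sprintf(
    "<env_grid> %s [%s]: %d x %d cells of %g deg, west %g, north %g, %d nodata\n",
    x$name, x$units, nrow(x$values), ncol(x$values), x$cellsize,
    x$xmin, x$ymax, sum(is.na(x$values))
  ))
  invisible(x)
}

grid_dim <- function(grid) dim(grid$values)

grid_xmax <- function(grid) grid$xmin + ncol(grid$values) * grid$cellsize
grid_ymin <- function(grid) grid$ymax - nrow(grid$values) * grid$cellsize

# cell-center coordinate vectors
grid_lon_centers <- function(grid) {
  grid$xmin + (seq_len(ncol(grid$values)) - 0.5) * grid$cellsize
}
grid_lat_centers <- function(grid) {
  grid$ymax - (seq_len(nrow(grid$values)) - 0.5) * grid$cellsize
}

# row/col of the cell containing each point; 0 marks out-of-extent
grid_rowcol <- function(grid, lon, lat) {
  col <- floor((lon - grid$xmin) / grid$cellsize) + 1
  row <- floor((grid$ymax - lat) / grid$cellsize) + 1
  # points exactly on the east/south edge belong to the last cell
  col[lon == grid_xmax(grid)] <- ncol(grid$values)
  row[lat == grid_ymin(grid)] <- nrow(grid$values)
  bad <- !is.finite(lon) | !is.finite(lat) |
    col < 1 | col > ncol(grid$values) | row < 1 | row > nrow(grid$values)
  col[bad] <- 0L
  row[bad] <- 0L
  list(row = as.integer(row), col = as.integer(col))
}

same_geometry <- function(a, b, tol = 1e-9) {
  all(grid_dim(a) == grid_dim(b)) &&
    abs(a$xmin - b$xmin) < tol && abs(a$ymax - b$ymax) < tol &&
    abs(a$cellsize - b$cellsize) < tol
}

#' Spherical cell areas of a grid
#'
#' Area of every cell on the authalic sphere (radius 6371 km), from the
#' latitude-band closed form \eqn{R^2 \Delta\lambda (\sin\phi_2 - \sin\phi_1)}:
#' constant along a row, decreasing toward the poles.
#'
#' @param grid An [env_grid()].
#' @param radius_km Sphere radius in km.
#' @return An `env_grid` of cell areas in km^2 (no nodata).
#' @export
cell_areas <- function(grid, radius_km = EARTH_RADIUS_KM) {
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  to_rad <- pi / 180
  lat_top <- (grid$ymax - (seq_len(nr) - 1) * grid$cellsize) * to_rad
  lat_bot <- (grid$ymax - seq_len(nr) * grid$cellsize) * to_rad
  dlon <- grid$cellsize * to_rad
  band <- radius_km^2 * dlon * (sin(lat_top) - sin(lat_bot))
  env_grid(matrix(band, nr, nc), grid$xmin, grid$ymax, grid$cellsize,
           name = "cell_area", units = "km^2")
}

# total spherical area (km^2) of the TRUE cells of a logical matrix on grid
mask_area_km2 <- function(mask, grid, radius_km = EARTH_RADIUS_KM) {
  stopifnot(all(dim(mask) == grid_dim(grid)))
  sum(cell_areas(grid, radius_km)$values[mask])
}

#' Convert a grid to a tibble of cell centers
#'
#' @param x An [env_grid()].
#' @param ... Unused.
#' @param drop_na Drop nodata cells.
#' @return A tibble with `longitude`, `latitude`, `value`.
#' @method as_tibble env_grid
#' @export
as_tibble.env_grid <- function(x, ..., drop_na = FALSE) {
  lon <- grid_lon_centers(x)
  lat <- grid_lat_centers(x)
  out <- tibble(
    longitude = rep(lon, each = nrow(x$values)),
    latitude = rep(lat, times = ncol(x$values)),
    value = as.vector(x$values)
  )
  if (drop_na) out <- filter(out, !is.na(.data$value))
  out
}

#' Plot a grid as a filled-tile map
#'
#' @param object An [env_grid()].
#' @param ... Unused.
#' @method autoplot env_grid
#' @export
autoplot.env_grid <- function(object, ...) {
  ggplot(as_tibble(object, drop_na = TRUE),
         aes(.data$longitude, .data$latitude, fill = .data$value)) +
    geom_tile(width = object$cellsize, height = object$cellsize) +
    scale_fill_viridis_c(name = object$name) +
    coord_equal() +
    labs(x = "Longitude", y = "Latitude") +
    theme_minimal()
}

#' Aligned stack of environmental covariate grids
#'
#' A named set of co-registered [env_grid()] layers plus a logical domain
#' mask. Construction validates co-registration: a misaligned layer is
#' rejected rather than resampled.
#'
#' @param layers Named list of `env_grid` objects sharing one geometry.
#' @param domain_mask Logical matrix marking analysis-domain cells; defaults
#'   to cells that are valid (non-nodata) in every layer except `LAI`, whose
#'   gaps are expected and handled by [focal_fill()].
#' @return An object of class `env_stack`.
#' @export
env_stack <- function(layers, domain_mask = NULL) {
  if (length(layers) == 0) stop_tropirep("empty layer list", "stack_error")
  if (is.null(names(layers)) || any(names(layers) == "")) {
    stop_tropirep("layers must be named", "stack_error")
  }
  ref <- layers[[1]]
  ok <- map_lgl(layers, same_geometry, b = ref)
  if (!all(ok)) {
    stop_tropirep(
      paste0("misaligned layers (geometry differs from '", names(layers)[1],
             "'): ", paste(names(layers)[!ok], collapse = ", ")),
      "stack_error"
    )
  }
  if (is.null(domain_mask)) {
    non_lai <- setdiff(names(layers), "LAI")
    domain_mask <- Reduce(`&`, lapply(layers[non_lai],
                                      function(g) !is.na(g$values)))
    if (is.null(domain_mask)) domain_mask <- !is.na(ref$values)
  }
  stopifnot(is.logical(domain_mask), all(dim(domain_mask) == grid_dim(ref)))
  structure(list(layers = layers, domain_mask = domain_mask),
            class = "env_stack")
}

#' @export
print.env_stack <- function(x, ...) {
  ref <- x$layers[[1]]
  cat(sprintf("<env_stack> %d layers on %d x %d grid (%g deg): %s\n",
              length(x$layers), nrow(ref$values), ncol(ref$values),
              ref$cellsize, paste(names(x$layers), collapse = ", ")))
  cat(sprintf("  domain: %d of %d cells\n", sum(x$domain_mask),
              length(x$domain_mask)))
  invisible(x)
}

stack_geometry <- function(stack) stack$layers[[1]]

#' Read and write grids as ESRI ASCII rasters
#'
#' Plain-text raster exchange format: a six-line header (`ncols`, `nrows`,
#' `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`) followed by rows of
#' values, north first.
#'
#' @param path File path.
#' @param name,units Layer metadata attached on read.
#' @return `read_ascii_grid()` returns an [env_grid()];
#'   `write_ascii_grid()` returns `path` invisibly.
#' @export
read_ascii_grid <- function(path, name = basename(path), units = "") {
  if (!file.exists(path)) stop_tropirep(paste("no such file:", path), "io_error")
  lines <- readLines(path)
  hdr <- list()
  for (i in 1:6) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
  }
  vals <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m[m == hdr$nodata_value] <- NA_real_
  env_grid(m, xmin = hdr$xllcorner,
           ymax = hdr$yllcorner + hdr$nrows * hdr$cellsize,
           cellsize = hdr$cellsize, name = name, units = units)
}

#' @rdname read_ascii_grid
#' @param grid An [env_grid()] to write.
#' @param nodata Sentinel written for `NA` cells.
#' @export
write_ascii_grid <- function(grid, path, nodata = -9999) {
  m <- grid$values
  m[is.na(m)] <- nodata
  hdr <- c(
    sprintf("ncols %d", ncol(m)),
    sprintf("nrows %d", nrow(m)),
    sprintf("xllcorner %.10g", grid$xmin),
    sprintf("yllcorner %.10g", grid_ymin(grid)),
    sprintf("cellsize %.10g", grid$cellsize),
    sprintf("NODATA_value %g", nodata)
  )
  body <- apply(m, 1, function(r) paste(format(r, trim = TRUE, digits = 10),
                                        collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write or read a covariate stack as ASCII grids plus a JSON manifest
#'
#' The manifest maps layer names to raster files and units, so a stack round
#' trips through plain text.
#'
#' @param stack An [env_stack()].
#' @param dir Directory for the rasters and `manifest.json`.
#' @return `write_stack()` the manifest path, `read_stack()` an `env_stack`.
#' @export
write_stack <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  entries <- imap(stack$layers, function(g, nm) {
    f <- paste0(nm, ".asc")
    write_ascii_grid(g, file.path(dir, f))
    list(file = f, units = g$units)
  })
  mask_grid <- stack_geometry(stack)
  mask <- env_grid(ifelse(stack$domain_mask, 1, 0) * 1,
                   mask_grid$xmin, mask_grid$ymax, mask_grid$cellsize,
                   name = "domain_mask")
  write_ascii_grid(mask, file.path(dir, "domain_mask.asc"))
  manifest <- list(layers = entries, domain_mask = "domain_mask.asc")
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  layers <- imap(manifest$layers, function(e, nm) {
    read_ascii_grid(file.path(dir, e$file), name = nm,
                    units = e$units %||% "")
  })
  mask <- read_ascii_grid(file.path(dir, manifest$domain_mask))
  env_stack(layers, domain_mask = !is.na(mask$values) & mask$values > 0.5)
}
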
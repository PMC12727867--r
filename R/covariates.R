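#' Climate anomaly layer (future minus baseline)
#'
#' Cellwise difference between a future-period climate layer (2081-2100
#' style) and its baseline (1970-2000 style). Nodata in either input
#' propagates to the output.
#'
#' @param future,baseline Co-registered [env_grid()]s.
#' @param name Output layer name.
#' @return An [env_grid()] of differences.
#' @export
climate_anomaly <- function(future, baseline,
                            name = paste0("d", baseline$name)) {
  if (!same_geometry(future, baseline)) {
    stop_tropirep("future and baseline grids are not co-registered",
                  "grid_error")
  }
  env_grid(future$values - baseline$values, future$xmin, future$ymax,
           future$cellsize, name = name, units = baseline$units)
}

#' Fill raster gaps with a focal moving-window mean
#'
#' Nodata cells are replaced by the mean of the valid cells in the centered
#' `window` x `window` neighborhood; valid cells are never altered. The fill
#' is single-pass: freshly filled values never feed later fills within the
#' same call, so the result is order-independent. Gap cells with no valid
#' neighbor remain nodata. `passes > 1` repeats the (single-pass) fill on
#' the previous result.
#'
#' @param grid An [env_grid()].
#' @param window Odd window size in cells (>= 3); default 19.
#' @param passes Number of repeated single-pass fills.
#' @return The filled [env_grid()].
#' @export
focal_fill <- function(grid, window = 19, passes = 1) {
  if (window %% 2 != 1 || window < 3) {
    stop_tropirep("`window` must be an odd integer >= 3", "validation_error")
  }
  half <- (window - 1) / 2
  v <- grid$values
  for (p in seq_len(passes)) {
    gaps <- which(is.na(v), arr.ind = TRUE)
    if (nrow(gaps) == 0) break
    filled <- v
    nr <- nrow(v); nc <- ncol(v)
    for (k in seq_len(nrow(gaps))) {
      i <- gaps[k, 1]; j <- gaps[k, 2]
      block <- v[max(1, i - half):min(nr, i + half),
                 max(1, j - half):min(nc, j + half)]
      m <- mean(block, na.rm = TRUE)
      if (is.finite(m)) filled[i, j] <- m
    }
    v <- filled
  }
  env_grid(v, grid$xmin, grid$ymax, grid$cellsize, grid$name, grid$units)
}

#' Extract covariate values at point locations
#'
#' Nearest-cell (containing-cell) extraction by coordinate colocation: each
#' point receives the value of the grid cell containing it, for every layer
#' of the stack. Points outside the grid extent get an all-missing row;
#' per-layer nodata shows up as `NA`. Output rows are in input order.
#'
#' @param stack An [env_stack()].
#' @param points A data frame with `longitude` and `latitude` (extra columns
#'   are carried through).
#' @return A tibble: the input columns, one column per layer, and a logical
#'   `outside` flag for out-of-extent points.
#' @export
extract_at_points <- function(stack, points) {
  if (length(stack$layers) == 0) stop_tropirep("empty stack", "stack_error")
  g <- stack_geometry(stack)
  rc <- grid_rowcol(g, points$longitude, points$latitude)
  out <- as_tibble(points)
  idx <- cbind(pmax(rc$row, 1L), pmax(rc$col, 1L))
  inside <- rc$row > 0L
  for (nm in names(stack$layers)) {
    vals <- stack$layers[[nm]]$values[idx]
    vals[!inside] <- NA_real_
    out[[nm]] <- vals
  }
  out$outside <- !inside
  out
}

#' Random background sample of domain pixels
#'
#' Draws `n` distinct cells uniformly without replacement from the stack's
#' domain mask and attaches all covariates at the cell centers. The draw is
#' reproducible under a fixed seed. If the domain has fewer than `n` valid
#' cells, all cells are returned with a warning. `replace = TRUE` switches
#' to sampling with replacement.
#'
#' @param stack An [env_stack()].
#' @param n Number of background pixels (default 100000).
#' @param seed Integer seed.
#' @param replace Sample cells with replacement.
#' @return A covariate tibble with `longitude`, `latitude`, cell indices and
#'   one column per layer.
#' @export
sample_background <- function(stack, n = 100000, seed = 1, replace = FALSE) {
  if (n <= 0) stop_tropirep("`n` must be positive", "validation_error")
  g <- stack_geometry(stack)
  cells <- which(stack$domain_mask)
  if (!replace && length(cells) < n) {
    warn(sprintf("domain has %d valid cells < n = %d: returning all cells",
                 length(cells), n))
    picked <- cells
  } else {
    picked <- withr::with_seed(seed,
                               sample(cells, size = n, replace = replace))
  }
  nr <- nrow(g$values)
  row <- ((picked - 1) %% nr) + 1
  col <- ((picked - 1) %/% nr) + 1
  pts <- tibble(
    longitude = grid_lon_centers(g)[col],
    latitude = grid_lat_centers(g)[row],
    cell_row = row, cell_col = col
  )
  extract_at_points(stack, pts) |> select(-"outside")
}
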
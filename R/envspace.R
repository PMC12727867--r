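#' Weighted 2D histogram over environmental space
#'
#' Bins weighted points over a pair of environmental axes. Bins are
#' right-open `[e_i, e_{i+1})` with the last bin right-closed, so every
#' in-range point lands in exactly one bin. Rows with a missing or
#' out-of-range coordinate are dropped and counted (`n_dropped`,
#' `dropped_weight`); binned mass plus dropped mass equals the input mass.
#'
#' @param x,y Coordinate vectors of equal length.
#' @param w Non-negative weights (default unit weights).
#' @param x_edges,y_edges Strictly increasing bin boundary vectors.
#' @param x_name,y_name Axis names.
#' @return An `env_hist2d`: edges, a `length(x_edges)-1` by
#'   `length(y_edges)-1` weight matrix (x indexes rows), totals and drop
#'   counts.
#' @export
bin2d <- function(x, y, w = NULL, x_edges, y_edges,
                  x_name = "x", y_name = "y") {
  n <- length(x)
  stopifnot(length(y) == n)
  if (is.null(w)) w <- rep(1, n)
  stopifnot(length(w) == n)
  if (any(diff(x_edges) <= 0) || any(diff(y_edges) <= 0)) {
    stop_tropirep("bin edges must be strictly increasing", "validation_error")
  }
  if (any(w < 0, na.rm = TRUE)) {
    stop_tropirep("negative weights", "validation_error")
  }
  ix <- findInterval(x, x_edges, rightmost.closed = TRUE)
  iy <- findInterval(y, y_edges, rightmost.closed = TRUE)
  ok <- !is.na(ix) & !is.na(iy) & !is.na(w) &
    ix >= 1 & ix <= length(x_edges) - 1 & iy >= 1 & iy <= length(y_edges) - 1
  weights <- matrix(0, length(x_edges) - 1, length(y_edges) - 1)
  for (k in which(ok)) {
    weights[ix[k], iy[k]] <- weights[ix[k], iy[k]] + w[k]
  }
  structure(
    list(x_name = x_name, y_name = y_name,
         x_edges = x_edges, y_edges = y_edges, weights = weights,
         total_weight = sum(w[ok]),
         n_dropped = sum(!ok),
         dropped_weight = sum(w[!ok], na.rm = TRUE) + 0),
    class = "env_hist2d"
  )
}

#' @export
print.env_hist2d <- function(x, ...) {
  cat(sprintf(
    "<env_hist2d> %s x %s: %d x %d bins, total weight %.6g (%d rows dropped)\n",
    x$x_name, x$y_name, nrow(x$weights), ncol(x$weights), x$total_weight,
    x$n_dropped))
  invisible(x)
}

#' @method tidy env_hist2d
#' @export
tidy.env_hist2d <- function(x, ...) {
  nx <- nrow(x$weights); ny <- ncol(x$weights)
  tibble(
    x_bin = rep(seq_len(nx), times = ny),
    y_bin = rep(seq_len(ny), each = nx),
    x_mid = rep((x$x_edges[-1] + x$x_edges[-(nx + 1)]) / 2, times = ny),
    y_mid = rep((x$y_edges[-1] + x$y_edges[-(ny + 1)]) / 2, each = nx),
    weight = as.vector(x$weights)
  )
}

#' @method autoplot env_hist2d
#' @export
autoplot.env_hist2d <- function(object, trans = "sqrt", ...) {
  d <- tidy(object)
  ggplot(filter(d, .data$weight > 0),
         aes(.data$x_mid, .data$y_mid, fill = .data$weight)) +
    geom_tile(width = diff(object$x_edges)[1],
              height = diff(object$y_edges)[1]) +
    scale_fill_viridis_c(name = "weight", trans = trans) +
    labs(x = object$x_name, y = object$y_name) +
    theme_minimal()
}

#' Occurrence / sampling / citation frequency comparison in 2D space
#'
#' For each covariate pair, builds three histograms on shared bin edges: the
#' background occurrence of conditions (unit weights on background pixels),
#' the sampling-location frequency (unit weights on locations), and the
#' citation weight (allocated citations as weights). Edges span the pooled
#' background-and-locations range for that pair, expanded by 0.1% so the
#' extremes fall inside the outer bins; a representative sample would show
#' sampling and citation surfaces proportional to occurrence.
#'
#' @param background Covariate tibble of background pixels (see
#'   [sample_background()]).
#' @param locations Covariate tibble of sampling locations carrying
#'   `allocated_citations`.
#' @param pairs List of `c(x_name, y_name)` covariate pairs; defaults to
#'   (MAT, MAP), (dMAT, dMAP), (LAI, SOC), (plant_rich, animal_rich).
#' @param n_bins Number of bins per axis (default 50).
#' @return A named list (one element per pair) of lists with `occurrence`,
#'   `sampling`, `citations` histograms.
#' @export
env_space_comparison <- function(background, locations,
                                 pairs = list(c("MAT", "MAP"),
                                              c("dMAT", "dMAP"),
                                              c("LAI", "SOC"),
                                              c("plant_rich", "animal_rich")),
                                 n_bins = 50) {
  out <- list()
  for (pr in pairs) {
    xn <- pr[1]; yn <- pr[2]
    for (nm in c(xn, yn)) {
      if (!(nm %in% names(background)) || !(nm %in% names(locations))) {
        stop_tropirep(paste("unknown covariate in pairs:", nm),
                      "validation_error")
      }
    }
    pool_x <- c(background[[xn]], locations[[xn]])
    pool_y <- c(background[[yn]], locations[[yn]])
    rng <- function(v) {
      r <- range(v, na.rm = TRUE)
      pad <- 0.001 * (r[2] - r[1])
      if (pad == 0) pad <- 0.001 * max(1, abs(r[1]))
      c(r[1] - pad, r[2] + pad)
    }
    rx <- rng(pool_x); ry <- rng(pool_y)
    xe <- seq(rx[1], rx[2], length.out = n_bins + 1)
    ye <- seq(ry[1], ry[2], length.out = n_bins + 1)
    out[[paste(xn, yn, sep = "_x_")]] <- list(
      occurrence = bin2d(background[[xn]], background[[yn]], NULL, xe, ye,
                         xn, yn),
      sampling = bin2d(locations[[xn]], locations[[yn]], NULL, xe, ye,
                       xn, yn),
      citations = bin2d(locations[[xn]], locations[[yn]],
                        locations$allocated_citations, xe, ye, xn, yn)
    )
  }
  out
}

#' Serialize a 2D histogram to JSON (edges plus weight grid)
#'
#' @param hist An `env_hist2d` (or a nested list of them).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hist2d_json <- function(hist, path) {
  strip <- function(h) {
    if (inherits(h, "env_hist2d")) {
      list(x_name = h$x_name, y_name = h$y_name,
           x_edges = h$x_edges, y_edges = h$y_edges,
           weights = unclass(h$weights),
           total_weight = h$total_weight, n_dropped = h$n_dropped)
    } else {
      map(h, strip)
    }
  }
  jsonlite::write_json(strip(hist), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
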
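#' Biome/ecoregion polygon layer
#'
#' A tibble with one row per spatial unit: `ecoregion_name`, `biome_name`,
#' and a `geometry` list-column. Each geometry is a list of rings; a ring is
#' a two-column (longitude, latitude) matrix, not necessarily closed.
#' Even-odd semantics: a point is inside a unit when it falls in an odd
#' number of its rings, so interior rings act as holes.
#'
#' @param ecoregion_name,biome_name Character vectors.
#' @param geometry List of ring lists.
#' @return A `biome_layer` tibble.
#' @export
biome_layer <- function(ecoregion_name, biome_name, geometry) {
  stopifnot(length(ecoregion_name) == length(biome_name),
            length(biome_name) == length(geometry))
  if (any(!nzchar(biome_name))) {
    stop_tropirep("biome_name must be non-empty", "validation_error")
  }
  geometry <- map(geometry, function(rings) {
    if (is.matrix(rings)) rings <- list(rings)
    map(rings, function(r) {
      r <- as.matrix(r)
      if (ncol(r) != 2 || nrow(r) < 3) {
        stop_tropirep("each ring needs >= 3 vertices and 2 columns",
                      "validation_error")
      }
      # drop a closing vertex; ring closure is implicit
      if (all(r[1, ] == r[nrow(r), ])) r <- r[-nrow(r), , drop = FALSE]
      unname(r)
    })
  })
  out <- tibble(ecoregion_name = as.character(ecoregion_name),
                biome_name = as.character(biome_name),
                geometry = geometry)
  class(out) <- c("biome_layer", class(out))
  out
}

# Even-odd point-in-rings test, vectorized over points, looping over edges.
# Points lying on a ring edge (within eps degrees) count as inside.
points_in_rings <- function(lon, lat, rings, eps = 1e-9) {
  inside <- rep(FALSE, length(lon))
  on_edge <- rep(FALSE, length(lon))
  for (ring in rings) {
    n <- nrow(ring)
    xs <- ring[, 1]; ys <- ring[, 2]
    xe <- xs[c(2:n, 1)]; ye <- ys[c(2:n, 1)]
    for (k in seq_len(n)) {
      x1 <- xs[k]; y1 <- ys[k]; x2 <- xe[k]; y2 <- ye[k]
      # ray casting: horizontal ray to +x, half-open in y to avoid double counts
      crosses <- ((y1 > lat) != (y2 > lat)) &
        (lon < (x2 - x1) * (lat - y1) / (y2 - y1) + x1)
      inside <- xor(inside, crosses)
      # point-on-segment check
      dx <- x2 - x1; dy <- y2 - y1
      len2 <- dx * dx + dy * dy
      if (len2 > 0) {
        t <- pmin(1, pmax(0, ((lon - x1) * dx + (lat - y1) * dy) / len2))
        d2 <- (lon - (x1 + t * dx))^2 + (lat - (y1 + t * dy))^2
        on_edge <- on_edge | d2 <= eps^2
      } else {
        on_edge <- on_edge | ((lon - x1)^2 + (lat - y1)^2 <= eps^2)
      }
    }
  }
  inside | on_edge
}

#' Spherical area of a polygon in km^2
#'
#' Ring areas on the authalic sphere (radius `radius_km`), even-odd: the
#' largest ring is the outer boundary and rings nested inside an odd number
#' of other rings are subtracted as holes. Empty geometry returns 0 with a
#' warning.
#'
#' @param rings A ring list (or single two-column matrix).
#' @param radius_km Sphere radius in km.
#' @return Area in km^2.
#' @export
polygon_area_km2 <- function(rings, radius_km = EARTH_RADIUS_KM) {
  if (is.matrix(rings)) rings <- list(rings)
  if (length(rings) == 0 || all(map_int(rings, nrow) < 3)) {
    warn("empty geometry: area 0")
    return(0)
  }
  areas <- map_dbl(rings, function(r) {
    abs(geosphere::areaPolygon(r, a = radius_km * 1000, f = 0)) / 1e6
  })
  depth <- map_int(seq_along(rings), function(i) {
    p <- rings[[i]][1, ]
    sum(map_lgl(seq_along(rings), function(j) {
      j != i && points_in_rings(p[1], p[2], rings[j], eps = 0)
    }))
  })
  sum(ifelse(depth %% 2 == 0, areas, -areas))
}

#' Build the buffered tropical study domain
#'
#' The core is every grid cell whose center lies in any unit of the biome
#' layer; the buffered domain adds cells whose centers are within
#' `buffer_km` (great-circle, sphere radius 6371 km) of a core boundary
#' cell, so the buffer is measured in kilometers at all latitudes. The
#' buffer-only region is the "extra-tropical other" zone of the summaries.
#'
#' @param biomes A [biome_layer()].
#' @param grid An [env_grid()] or [env_stack()] defining the analysis grid.
#' @param buffer_km Buffer distance in km (0 keeps the core only).
#' @param land_mask Optional logical matrix of land/valid cells; the domain
#'   is intersected with it.
#' @return A `study_domain`: core and buffered masks plus total area.
#' @export
build_domain <- function(biomes, grid, buffer_km = 100, land_mask = NULL) {
  if (inherits(grid, "env_stack")) {
    if (is.null(land_mask)) land_mask <- grid$domain_mask
    grid <- stack_geometry(grid)
  }
  if (nrow(biomes) == 0) stop_tropirep("empty biome layer", "validation_error")
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  lon <- rep(grid_lon_centers(grid), each = nr)
  lat <- rep(grid_lat_centers(grid), times = nc)
  core <- matrix(FALSE, nr, nc)
  for (i in seq_len(nrow(biomes))) {
    todo <- !core
    hit <- points_in_rings(lon[todo], lat[todo], biomes$geometry[[i]], eps = 0)
    core[todo] <- hit
  }
  if (buffer_km > 0 && any(core) && any(!core)) {
    # boundary cells of the core (4-neighborhood, grid edge counts)
    pad <- function(m, side) {
      switch(side,
             n = rbind(FALSE, m[-nr, , drop = FALSE]),
             s = rbind(m[-1, , drop = FALSE], FALSE),
             w = cbind(FALSE, m[, -nc, drop = FALSE]),
             e = cbind(m[, -1, drop = FALSE], FALSE))
    }
    boundary <- core & !(pad(core, "n") & pad(core, "s") &
                           pad(core, "w") & pad(core, "e"))
    bidx <- which(boundary)
    blon <- lon[bidx]; blat <- lat[bidx]
    out_idx <- which(!core)
    near <- rep(FALSE, length(out_idx))
    olon <- lon[out_idx]; olat <- lat[out_idx]
    # prune by a latitude window before exact haversine
    dlat_max <- buffer_km / 111 * 1.05
    for (b in seq_along(bidx)) {
      cand <- which(!near & abs(olat - blat[b]) <= dlat_max)
      if (length(cand) == 0) next
      d <- haversine_km(olon[cand], olat[cand], blon[b], blat[b])
      near[cand[d <= buffer_km]] <- TRUE
    }
    buffered <- core
    buffered[out_idx[near]] <- TRUE
  } else {
    buffered <- core
  }
  if (!is.null(land_mask)) {
    stopifnot(all(dim(land_mask) == dim(core)))
    core <- core & land_mask
    buffered <- buffered & land_mask
  }
  structure(
    list(core_mask = core, buffered_mask = buffered, buffer_km = buffer_km,
         grid = env_grid(matrix(NA_real_, nr, nc), grid$xmin, grid$ymax,
                         grid$cellsize, name = "domain"),
         total_area_km2 = mask_area_km2(buffered, grid)),
    class = "study_domain"
  )
}

#' @export
print.study_domain <- function(x, ...) {
  cat(sprintf(
    "<study_domain> buffer %g km; core %d cells, buffered %d cells, %.4g km^2\n",
    x$buffer_km, sum(x$core_mask), sum(x$buffered_mask), x$total_area_km2))
  invisible(x)
}

#' Label sampling locations with biome and ecoregion, clipping to the domain
#'
#' Each location is assigned the first unit (layer order) whose geometry
#' contains it, with points on a boundary counting as inside. Locations
#' inside the buffered domain but in no unit are labeled
#' `"extra-tropical other"`; locations outside the buffered domain are
#' dropped and counted in the clip report attribute.
#'
#' @param table A [lit_table()].
#' @param biomes A [biome_layer()].
#' @param domain A [build_domain()] result.
#' @return The labeled, clipped table with `biome` and `ecoregion` columns
#'   and a `clip_report` attribute (`n_input`, `n_kept`, `n_dropped`).
#' @export
assign_locations <- function(table, biomes, domain) {
  n_input <- nrow(table)
  rc <- grid_rowcol(domain$grid, table$longitude, table$latitude)
  in_dom <- rc$row > 0 &
    domain$buffered_mask[cbind(pmax(rc$row, 1), pmax(rc$col, 1))]
  in_dom[rc$row == 0] <- FALSE
  out <- table[in_dom, , drop = FALSE]
  biome <- rep("extra-tropical other", nrow(out))
  ecoregion <- rep("extra-tropical other", nrow(out))
  unassigned <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(biomes))) {
    if (!any(unassigned)) break
    hit <- points_in_rings(out$longitude[unassigned], out$latitude[unassigned],
                           biomes$geometry[[i]])
    idx <- which(unassigned)[hit]
    biome[idx] <- biomes$biome_name[i]
    ecoregion[idx] <- biomes$ecoregion_name[i]
    unassigned[idx] <- FALSE
  }
  out$biome <- biome
  out$ecoregion <- ecoregion
  class(out) <- class(table)
  if (nrow(out) == 0) warn("no locations fall inside the study domain")
  attr(out, "clip_report") <- list(n_input = n_input, n_kept = nrow(out),
                                   n_dropped = n_input - nrow(out))
  out
}

#' @rdname assign_locations
#' @export
clip_report <- function(table) attr(table, "clip_report")

#' Per-biome areas of a study domain
#'
#' Rasterizes the biome layer onto the domain grid (first-unit-wins, as in
#' [assign_locations()]) and sums spherical cell areas inside the buffered
#' domain; buffer-only cells are "extra-tropical other".
#'
#' @param biomes A [biome_layer()].
#' @param domain A [build_domain()] result.
#' @return Tibble with `biome`, `area_km2`.
#' @export
biome_areas <- function(biomes, domain) {
  g <- domain$grid
  nr <- nrow(g$values); nc <- ncol(g$values)
  lon <- rep(grid_lon_centers(g), each = nr)
  lat <- rep(grid_lat_centers(g), times = nc)
  label <- matrix(NA_character_, nr, nc)
  for (i in seq_len(nrow(biomes))) {
    todo <- is.na(label) & domain$buffered_mask
    if (!any(todo)) break
    hit <- points_in_rings(lon[todo], lat[todo], biomes$geometry[[i]], eps = 0)
    label[which(todo)[hit]] <- biomes$biome_name[i]
  }
  label[is.na(label) & domain$buffered_mask] <- "extra-tropical other"
  areas <- cell_areas(g)$values
  tibble(biome = label[domain$buffered_mask],
         area = areas[domain$buffered_mask]) |>
    group_by(.data$biome) |>
    summarise(area_km2 = sum(.data$area), .groups = "drop") |>
    rename(biome = "biome")
}

#' Per-biome sampling and citation summary
#'
#' For each biome: area and its percentage share of the domain, location and
#' citation counts with percentage shares, densities per 10^5 km^2, and the
#' citation:sampling ratio (percent citations divided by percent locations,
#' computed on unrounded percentages and reported rounded half-away-from-zero
#' to 1 decimal).
#'
#' @param table A labeled [lit_table()] (see [assign_locations()]) carrying
#'   `allocated_citations`.
#' @param areas Tibble with `biome`, `area_km2` covering every biome present.
#' @return A `biome_summary` tibble, one row per biome, ordered by
#'   decreasing area share.
#' @export
biome_summary <- function(table, areas) {
  if (!("allocated_citations" %in% names(table))) {
    table <- allocate_citations(table)
  }
  missing_b <- setdiff(unique(table$biome), areas$biome)
  if (length(missing_b) > 0) {
    stop_tropirep(paste("biome(s) present in table but absent in areas:",
                        paste(missing_b, collapse = ", ")), "validation_error")
  }
  if (any(areas$area_km2 <= 0)) {
    stop_tropirep("areas must be positive", "validation_error")
  }
  counts <- table |>
    group_by(.data$biome) |>
    summarise(n_locations = dplyr::n(),
              citations = sum(.data$allocated_citations), .groups = "drop")
  out <- areas |>
    left_join(counts, by = "biome") |>
    mutate(
      n_locations = dplyr::coalesce(.data$n_locations, 0L),
      citations = dplyr::coalesce(.data$citations, 0),
      pct_area = 100 * .data$area_km2 / sum(.data$area_km2),
      pct_locations = 100 * .data$n_locations / sum(.data$n_locations),
      pct_citations = 100 * .data$citations / sum(.data$citations),
      loc_density = 1e5 * .data$n_locations / .data$area_km2,
      cit_density = 1e5 * .data$citations / .data$area_km2,
      ratio = round_half_up(.data$pct_citations / .data$pct_locations, 1)
    ) |>
    select("biome", "area_km2", "pct_area", "n_locations", "pct_locations",
           "loc_density", "citations", "pct_citations", "cit_density",
           "ratio") |>
    arrange(dplyr::desc(.data$pct_area))
  class(out) <- c("biome_summary", class(out))
  out
}

#' Coarse location/citation density grids
#'
#' Aggregates the labeled table onto a coarse grid (default 3 degrees): per
#' cell, the summed weight (location count or allocated citations) divided by
#' the cell's land area inside the study domain, in units per 10^5 km^2.
#' Cells with no domain land are nodata. Duplicated coordinates accumulate
#' (multiset semantics).
#'
#' @param table A clipped [lit_table()].
#' @param domain A [build_domain()] result.
#' @param cell_deg Cell size in degrees; must divide 360.
#' @param weight `"locations"` or `"citations"`.
#' @return An [env_grid()] of densities, with attribute `counts` (the
#'   pre-division weight grid).
#' @export
grid_density <- function(table, domain, cell_deg = 3,
                         weight = c("locations", "citations")) {
  weight <- match.arg(weight)
  if (abs(360 %% cell_deg) > 1e-9) {
    stop_tropirep("`cell_deg` must divide 360", "validation_error")
  }
  if (weight == "citations" && !("allocated_citations" %in% names(table))) {
    table <- allocate_citations(table)
  }
  g <- domain$grid
  # coarse grid aligned to the fine grid origin, covering its extent
  nc_coarse <- ceiling(ncol(g$values) * g$cellsize / cell_deg)
  nr_coarse <- ceiling(nrow(g$values) * g$cellsize / cell_deg)
  coarse <- env_grid(matrix(NA_real_, nr_coarse, nc_coarse), g$xmin, g$ymax,
                     cell_deg, name = paste0(weight, "_density"),
                     units = "per 1e5 km^2")
  w <- if (weight == "locations") rep(1, nrow(table)) else
    table$allocated_citations
  rc <- grid_rowcol(coarse, table$longitude, table$latitude)
  counts <- matrix(0, nr_coarse, nc_coarse)
  keep <- rc$row > 0
  for (i in which(keep)) {
    counts[rc$row[i], rc$col[i]] <- counts[rc$row[i], rc$col[i]] + w[i]
  }
  # land area of the domain within each coarse cell
  fine_area <- cell_areas(g)$values
  fine_area[!domain$buffered_mask] <- 0
  ratio <- cell_deg / g$cellsize
  land <- matrix(0, nr_coarse, nc_coarse)
  fr <- ceiling(seq_len(nrow(g$values)) / ratio)
  fc <- ceiling(seq_len(ncol(g$values)) / ratio)
  for (i in seq_len(nr_coarse)) {
    rows <- fr == i
    if (!any(rows)) next
    sub <- fine_area[rows, , drop = FALSE]
    land[i, ] <- vapply(seq_len(nc_coarse),
                        function(j) sum(sub[, fc == j, drop = FALSE]), 0)
  }
  dens <- ifelse(land > 0, 1e5 * counts / land, NA_real_)
  coarse$values <- dens
  attr(coarse, "counts") <- counts
  coarse
}

#' Read and write biome layers as GeoJSON
#'
#' A FeatureCollection of Polygon/MultiPolygon features with `ECO_NAME` and
#' `BIOME_NAME` properties, mirroring the ecoregions dataset fields.
#'
#' @param path GeoJSON file path.
#' @return `read_biomes_geojson()` a [biome_layer()];
#'   `write_biomes_geojson()` the path, invisibly.
#' @export
read_biomes_geojson <- function(path) {
  if (!file.exists(path)) stop_tropirep(paste("no such file:", path), "io_error")
  gj <- jsonlite::read_json(path)
  feats <- gj$features
  ring_mat <- function(coords) {
    do.call(rbind, map(coords, function(p) c(p[[1]], p[[2]])))
  }
  geoms <- map(feats, function(f) {
    g <- f$geometry
    if (g$type == "Polygon") {
      map(g$coordinates, ring_mat)
    } else if (g$type == "MultiPolygon") {
      unlist(map(g$coordinates, function(poly) map(poly, ring_mat)),
             recursive = FALSE)
    } else {
      stop_tropirep(paste("unsupported geometry type:", g$type), "io_error")
    }
  })
  biome_layer(
    ecoregion_name = map_chr(feats, function(f)
      f$properties$ECO_NAME %||% f$properties$ecoregion_name %||% ""),
    biome_name = map_chr(feats, function(f)
      f$properties$BIOME_NAME %||% f$properties$biome_name %||% ""),
    geometry = geoms
  )
}

#' @rdname read_biomes_geojson
#' @param biomes A [biome_layer()] to write.
#' @export
write_biomes_geojson <- function(biomes, path) {
  feats <- map(seq_len(nrow(biomes)), function(i) {
    rings <- map(biomes$geometry[[i]], function(r) {
      r <- rbind(r, r[1, ])  # GeoJSON rings are closed
      map(seq_len(nrow(r)), function(k) c(r[k, 1], r[k, 2]))
    })
    list(
      type = "Feature",
      properties = list(ECO_NAME = biomes$ecoregion_name[i],
                        BIOME_NAME = biomes$biome_name[i]),
      geometry = list(type = "Polygon", coordinates = rings)
    )
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = 10)
  invisible(path)
}

#' @importFrom purrr map_chr
NULL
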
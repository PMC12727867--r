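test_that("spherical cell areas match the closed form globally and geosphere locally", {
  # full sphere: a global 1-degree grid sums to 4 pi R^2
  glob <- env_grid(matrix(0, 180, 360), -180, 90, 1)
  expect_equal(mask_area_km2(matrix(TRUE, 180, 360), glob),
               4 * pi * 6371^2, tolerance = 1e-9)
  # hemisphere is exactly half
  north <- matrix(FALSE, 180, 360)
  north[1:90, ] <- TRUE
  expect_equal(mask_area_km2(north, glob), 2 * pi * 6371^2, tolerance = 1e-9)

  # individual 1x1-degree cells against an independent spherical-polygon
  # computation (edges densified so parallels are followed closely)
  areas <- cell_areas(glob)$values
  withr::with_seed(42, {
    for (k in 1:10) {
      i <- sample(180, 1); j <- sample(360, 1)
      lat_top <- 90 - (i - 1); lon_w <- -180 + (j - 1)
      xs <- seq(lon_w, lon_w + 1, by = 0.05)
      ring <- rbind(
        cbind(xs, lat_top - 1), cbind(rev(xs), lat_top)
      )
      oracle <- abs(geosphere::areaPolygon(ring, a = 6371000, f = 0)) / 1e6
      expect_equal(areas[i, j], oracle, tolerance = 1e-4)
    }
  })
})

test_that("polygon areas on the sphere handle holes and degenerate input", {
  outer <- square_ring(0, 10, 0, 10)
  hole <- square_ring(4, 6, 4, 6)
  a_outer <- polygon_area_km2(outer)
  a_hole <- polygon_area_km2(hole)
  expect_equal(polygon_area_km2(list(outer, hole)), a_outer - a_hole,
               tolerance = 1e-9)
  expect_warning(a0 <- polygon_area_km2(list()), "empty")
  expect_equal(a0, 0)
})

test_that("point-in-polygon agrees with mgcv::in.out and is boundary-inclusive", {
  withr::with_seed(7, {
    th <- seq(0, 2 * pi, length.out = 13)[-13]
    r <- 3 + runif(12)
    blob <- cbind(10 + r * cos(th), -5 + r * sin(th))
    pts_lon <- runif(400, 4, 16)
    pts_lat <- runif(400, -11, 1)
    mine <- points_in_rings(pts_lon, pts_lat, list(blob), eps = 0)
    oracle <- mgcv::in.out(rbind(blob, blob[1, ]), cbind(pts_lon, pts_lat))
    expect_equal(mine, as.logical(oracle))
  })
  # a vertex and an edge midpoint count as inside
  sq <- square_ring(0, 2, 0, 2)
  expect_true(points_in_rings(0, 0, list(sq)))
  expect_true(points_in_rings(1, 0, list(sq)))
  expect_true(points_in_rings(1, 1, list(sq)))
  expect_false(points_in_rings(3, 1, list(sq)))
})

test_that("overlapping units resolve to the earliest layer, verified exhaustively", {
  two <- biome_layer(
    ecoregion_name = c("e1", "e2"),
    biome_name = c("Tropical A", "Tropical B"),
    geometry = list(square_ring(0, 4, 0, 4), square_ring(2, 6, 0, 4))
  )
  g <- env_grid(matrix(0, 8, 10), -1, 5, 1)
  stack <- env_stack(list(z = g))
  dom <- build_domain(two, stack, buffer_km = 0)
  pts <- tibble::tibble(
    article_id = c("a", "a", "a"), total_citations = rep(3, 3),
    longitude = c(1, 3, 5), latitude = c(2, 2, 2),
    habitats = list("forest", "forest", "forest")
  )
  lab <- assign_locations(lit_table(pts), two, dom)
  # overlap point (3, 2) is inside both; exhaustive check then layer order
  expect_true(points_in_rings(3, 2, two$geometry[[1]]))
  expect_true(points_in_rings(3, 2, two$geometry[[2]]))
  expect_equal(lab$biome, c("Tropical A", "Tropical A", "Tropical B"))
})

test_that("buffered domain contains the core and respects kilometre distances", {
  core_poly <- biome_layer("eco", "Tropical core",
                           list(square_ring(0, 10, -5, 5)))
  g <- env_grid(matrix(0, 60, 80), -20, 15, 0.5)
  stack <- env_stack(list(z = g))

  d0 <- build_domain(core_poly, stack, buffer_km = 0)
  expect_identical(d0$core_mask, d0$buffered_mask)
  expect_equal(mask_area_km2(d0$buffered_mask, g), d0$total_area_km2)

  d100 <- build_domain(core_poly, stack, buffer_km = 100)
  expect_true(all(d100$buffered_mask[d0$core_mask]))
  expect_gte(d100$total_area_km2, d0$total_area_km2)

  # a point ~50 km east of the core boundary sits inside the 100 km buffer
  rc <- grid_rowcol(g, 10.45, 0)  # 0.45 deg ~ 50 km at the equator
  expect_true(d100$buffered_mask[rc$row, rc$col])
  # and a point ~300 km out does not
  rc_far <- grid_rowcol(g, 12.7, 0)
  expect_false(d100$buffered_mask[rc_far$row, rc_far$col])

  # monotone growth with buffer distance
  d200 <- build_domain(core_poly, stack, buffer_km = 200)
  expect_true(all(d200$buffered_mask[d100$buffered_mask]))
})

test_that("locations are clipped and labeled; clip counts add up", {
  cfg <- small_syncfg()
  stack <- gen_stack(cfg)
  biomes <- gen_biomes(stack, cfg)
  lit <- gen_literature(stack, cfg)
  dom <- build_domain(biomes, stack, buffer_km = 100)
  lab <- assign_locations(lit, biomes, dom)
  rep <- clip_report(lab)
  expect_equal(rep$n_kept + rep$n_dropped, rep$n_input)
  expect_equal(rep$n_input, nrow(lit))
  expect_true(all(c("biome", "ecoregion") %in% names(lab)))
  expect_true(all(nzchar(lab$biome)))
  # every kept location is inside the buffered mask
  rc <- grid_rowcol(dom$grid, lab$longitude, lab$latitude)
  expect_true(all(dom$buffered_mask[cbind(rc$row, rc$col)]))
})

test_that("per-biome areas tile the domain (additivity within 0.1%)", {
  cfg <- small_syncfg()
  stack <- gen_stack(cfg)
  biomes <- gen_biomes(stack, cfg)
  # buffer wider than one grid cell so an extra-tropical fringe exists
  dom <- build_domain(biomes, stack, buffer_km = 250)
  areas <- biome_areas(biomes, dom)
  expect_equal(sum(areas$area_km2), dom$total_area_km2,
               tolerance = 1e-3)
  expect_true("extra-tropical other" %in% areas$biome)
})

test_that("biome summary reproduces share and ratio identities", {
  # 10 locations in a biome of 2e5 km^2 -> density 5 per 1e5 km^2
  tab <- lit_table(tibble::tibble(
    article_id = rep("a", 10), total_citations = rep(20, 10),
    longitude = 1:10, latitude = rep(0, 10),
    habitats = rep(list("forest"), 10)
  ))
  tab$biome <- "only"
  s1 <- biome_summary(tab, tibble::tibble(biome = "only", area_km2 = 2e5))
  expect_equal(s1$loc_density, 5.0)
  # single-biome degenerate case
  expect_equal(s1$pct_locations, 100)
  expect_equal(s1$pct_citations, 100)
  expect_equal(s1$ratio, 1.0)

  # multi-biome: percentage sums and the 1-dp ratio identity
  cfg <- small_syncfg()
  stack <- gen_stack(cfg)
  biomes <- gen_biomes(stack, cfg)
  dom <- build_domain(biomes, stack, buffer_km = 100)
  lab <- assign_locations(allocate_citations(gen_literature(stack, cfg)),
                          biomes, dom)
  s <- biome_summary(lab, biome_areas(biomes, dom))
  expect_equal(sum(s$pct_area), 100, tolerance = 0.5 / 100)
  expect_equal(sum(s$pct_locations), 100, tolerance = 0.5 / 100)
  expect_equal(sum(s$pct_citations), 100, tolerance = 0.5 / 100)
  expect_true(all(abs(s$ratio - s$pct_citations / s$pct_locations) <= 0.05 +
                    1e-12))
  expect_true(all(s$loc_density >= 0 & s$cit_density >= 0))

  expect_error(
    biome_summary(tab, tibble::tibble(biome = "elsewhere", area_km2 = 1)),
    "absent", class = "validation_error"
  )
})

test_that("density grids conserve weight and keep duplicates", {
  tab <- lit_table(tibble::tibble(
    article_id = c("a", "a", "b"), total_citations = c(4, 4, 9),
    longitude = c(1.2, 1.2, 7.9), latitude = c(0.4, 0.4, 2.1),
    habitats = rep(list("forest"), 3)
  ))
  core_poly <- biome_layer("eco", "Tropical core",
                           list(square_ring(0, 9, -3, 3)))
  g <- env_grid(matrix(0, 12, 24), -3, 3, 0.5)
  dom <- build_domain(core_poly, env_stack(list(z = g)), buffer_km = 0)
  tab$biome <- "Tropical core"
  d <- grid_density(tab, dom, cell_deg = 3, weight = "locations")
  counts <- attr(d, "counts")
  # total weight conserved before area division
  expect_equal(sum(counts), nrow(tab))
  # duplicated coordinates accumulate in one cell
  expect_true(2 %in% counts)
  # cells without domain land are nodata
  expect_true(anyNA(d$values))
  # occupied cell density = count / land area * 1e5
  expect_error(grid_density(tab, dom, cell_deg = 7), "divide",
               class = "validation_error")
})

test_that("biome layers round-trip through GeoJSON", {
  bl <- biome_layer(
    c("e1", "e2"), c("Tropical A", "Tropical B"),
    list(list(square_ring(0, 4, 0, 4), square_ring(1, 2, 1, 2)),
         square_ring(5, 8, -2, 2))
  )
  path <- withr::local_tempfile(fileext = ".geojson")
  write_biomes_geojson(bl, path)
  back <- read_biomes_geojson(path)
  expect_equal(back$ecoregion_name, bl$ecoregion_name)
  expect_equal(back$biome_name, bl$biome_name)
  expect_equal(back$geometry, bl$geometry)
})
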
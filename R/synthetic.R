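#' Default cross-correlation targets for synthetic covariates
#'
#' Moderate, positive-definite correlation structure among the eight
#' covariates: wetter cells carry more leaf area, carbon and diversity;
#' plant and animal richness covary; projected warming and drying are
#' weakly negatively related.
#'
#' @return An 8 x 8 correlation matrix (layer order: MAT, MAP, dMAT, dMAP,
#'   LAI, SOC, plant_rich, animal_rich).
#' @export
default_cor_matrix <- function() {
  nm <- c("MAT", "MAP", "dMAT", "dMAP", "LAI", "SOC",
          "plant_rich", "animal_rich")
  C <- diag(8)
  dimnames(C) <- list(nm, nm)
  set_pair <- function(a, b, r) {
    C[a, b] <<- r
    C[b, a] <<- r
  }
  set_pair("MAP", "LAI", 0.6)
  set_pair("MAT", "LAI", 0.3)
  set_pair("MAP", "SOC", 0.3)
  set_pair("LAI", "SOC", 0.3)
  set_pair("plant_rich", "animal_rich", 0.5)
  set_pair("LAI", "plant_rich", 0.4)
  set_pair("LAI", "animal_rich", 0.4)
  set_pair("MAP", "plant_rich", 0.3)
  set_pair("dMAT", "dMAP", -0.2)
  set_pair("MAT", "dMAT", 0.2)
  C
}

#' Configuration of the synthetic study system
#'
#' Defines the emulated study conditions: the grid, the smooth random-field
#' covariates with a deterministic equator-to-margin gradient, gaps in the
#' LAI layer, and a literature-generating process with preferential
#' sampling, skewed article citations and a configurable share of
#' urban/agricultural locations (default 0.36, matching the share of
#' human-modified habitats among sampling locations that motivates the
#' natural-habitat filter).
#'
#' @param lon_range,lat_range Grid extent in degrees.
#' @param cellsize Cell size in degrees.
#' @param smoothness_cells Gaussian smoothing length of the random fields,
#'   in cells.
#' @param cor_matrix Target correlation matrix of the stochastic field
#'   components (entries in (-1, 1), positive definite).
#' @param base,gradient,scale Named per-layer constants: cell value =
#'   `base - gradient * |latitude| + scale * field`.
#' @param lai_gap_fraction Fraction of LAI cells blanked to nodata.
#' @param n_articles Number of articles to simulate.
#' @param loc_range Integer range of sampling locations per article.
#' @param citation_meanlog,citation_sdlog Log-normal citation parameters
#'   (discretized with `ceiling`, so every article has >= 1 citation).
#' @param beta Named sampling-bias coefficients: location intensity is
#'   proportional to `exp(sum(beta * z))` over standardized covariates.
#' @param urban_agri_fraction Probability a location is urban/agricultural.
#' @param lat_core Latitude bound of the tropical core used by
#'   [gen_biomes()].
#' @param n_biomes Number of biome classes.
#' @param seed Master seed; all stage seeds derive from it.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(lon_range = c(-30, 30), lat_range = c(-32, 32),
                             cellsize = 0.5, smoothness_cells = 6,
                             cor_matrix = default_cor_matrix(),
                             base = c(MAT = 27, MAP = 2100, dMAT = 3.2,
                                      dMAP = 40, LAI = 4.6, SOC = 130,
                                      plant_rich = 170, animal_rich = 480),
                             gradient = c(MAT = 0.22, MAP = 38, dMAT = -0.015,
                                          dMAP = 1.2, LAI = 0.08, SOC = 1.2,
                                          plant_rich = 2.4, animal_rich = 7),
                             scale = c(MAT = 1.8, MAP = 450, dMAT = 0.5,
                                       dMAP = 60, LAI = 1.0, SOC = 35,
                                       plant_rich = 45, animal_rich = 110),
                             lai_gap_fraction = 0.05,
                             n_articles = 400, loc_range = c(1, 4),
                             citation_meanlog = 2.6, citation_sdlog = 1.2,
                             beta = c(LAI = 0.8, MAT = 0.3),
                             urban_agri_fraction = 0.36,
                             lat_core = 23.4, n_biomes = 4, seed = 1) {
  if (lai_gap_fraction < 0 || lai_gap_fraction >= 1) {
    stop_tropirep("`lai_gap_fraction` must be in [0, 1)", "validation_error")
  }
  if (n_articles < 1) stop_tropirep("`n_articles` must be >= 1",
                                    "validation_error")
  off <- cor_matrix[upper.tri(cor_matrix)]
  if (any(off <= -1 | off >= 1)) {
    stop_tropirep("correlation targets must lie in (-1, 1)",
                  "validation_error")
  }
  structure(
    list(lon_range = lon_range, lat_range = lat_range, cellsize = cellsize,
         smoothness_cells = smoothness_cells, cor_matrix = cor_matrix,
         base = base, gradient = gradient, scale = scale,
         lai_gap_fraction = lai_gap_fraction, n_articles = n_articles,
         loc_range = loc_range, citation_meanlog = citation_meanlog,
         citation_sdlog = citation_sdlog, beta = beta,
         urban_agri_fraction = urban_agri_fraction, lat_core = lat_core,
         n_biomes = n_biomes, seed = seed),
    class = "synthetic_config"
  )
}

# Gaussian-smoothed standardized white-noise field (separable convolution
# with edge renormalization)
smooth_field <- function(nr, nc, sigma) {
  z <- matrix(rnorm(nr * nc), nr, nc)
  if (sigma > 0) {
    half <- max(1, ceiling(3 * sigma))
    kern <- exp(-(seq(-half, half))^2 / (2 * sigma^2))
    conv1 <- function(m, k) {
      # convolve each column with k, renormalizing at the edges
      n <- nrow(m)
      out <- matrix(0, n, ncol(m))
      wsum <- numeric(n)
      for (o in seq_along(k)) {
        shift <- o - half - 1
        src <- seq_len(n) + shift
        okk <- src >= 1 & src <= n
        out[okk, ] <- out[okk, ] + k[o] * m[src[okk], ]
        wsum[okk] <- wsum[okk] + k[o]
      }
      out / wsum
    }
    z <- conv1(z, kern)
    z <- t(conv1(t(z), kern))
  }
  (z - mean(z)) / stats::sd(z)
}

#' Generate a synthetic covariate stack
#'
#' Builds the eight covariate layers as correlated smooth random fields plus
#' a deterministic latitudinal gradient (values peak at the equator and
#' decline toward the grid margins). The stochastic components are mixed
#' with the Cholesky factor of the target correlation matrix, so requested
#' pairwise correlations are achieved; the LAI layer receives the configured
#' fraction of nodata gaps. Identical seeds yield bit-identical stacks.
#'
#' @param config A [synthetic_config()].
#' @param seed Optional override of `config$seed`.
#' @return An [env_stack()] with a full domain mask.
#' @export
gen_stack <- function(config, seed = config$seed) {
  nm <- colnames(config$cor_matrix)
  ch <- tryCatch(chol(config$cor_matrix), error = function(e) {
    stop_tropirep("correlation target matrix is not positive definite",
                  "validation_error")
  })
  nc <- round(diff(config$lon_range) / config$cellsize)
  nr <- round(diff(config$lat_range) / config$cellsize)
  fields <- withr::with_seed(
    derive_seed(seed, "fields"),
    vapply(seq_along(nm),
           function(i) as.vector(smooth_field(nr, nc,
                                              config$smoothness_cells)),
           numeric(nr * nc))
  )
  mixed <- fields %*% ch
  colnames(mixed) <- nm
  lat <- rep(config$lat_range[2] - (seq_len(nr) - 0.5) * config$cellsize,
             times = nc)
  layers <- list()
  units <- c(MAT = "degC", MAP = "mm", dMAT = "degC", dMAP = "mm",
             LAI = "m2 m-2", SOC = "t ha-1 (0-2 m)",
             plant_rich = "species / 1000 m2",
             animal_rich = "bird + mammal species")
  for (l in nm) {
    v <- config$base[[l]] - config$gradient[[l]] * abs(lat) +
      config$scale[[l]] * mixed[, l]
    layers[[l]] <- env_grid(matrix(v, nr, nc), config$lon_range[1],
                            config$lat_range[2], config$cellsize,
                            name = l, units = units[[l]])
  }
  if (config$lai_gap_fraction > 0) {
    n_gap <- round(config$lai_gap_fraction * nr * nc)
    gaps <- withr::with_seed(derive_seed(seed, "lai_gaps"),
                             sample(nr * nc, n_gap))
    layers$LAI$values[gaps] <- NA_real_
  }
  env_stack(layers)
}

# connected components (4-neighborhood) of a logical matrix, by flood fill
connected_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  comp <- matrix(0L, nr, nc)
  nxt <- 0L
  for (start in which(mask & comp == 0L)) {
    nxt <- nxt + 1L
    queue <- start
    comp[start] <- nxt
    while (length(queue) > 0) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      i <- ((cur - 1L) %% nr) + 1L
      j <- ((cur - 1L) %/% nr) + 1L
      for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        ii <- i + d[1]; jj <- j + d[2]
        if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc) {
          k <- (jj - 1L) * nr + ii
          if (mask[k] && comp[k] == 0L) {
            comp[k] <- nxt
            queue <- c(queue, k)
          }
        }
      }
    }
  }
  comp
}

# trace the boundary of a cell set into closed rings (corner-grid walk;
# at pinch vertices the walk prefers the rightmost turn, deterministically)
trace_rings <- function(mask, grid) {
  nr <- nrow(mask); nc <- ncol(mask)
  # directed edges (from-corner, to-corner), region kept on the left walking
  # corner id = r * (nc + 1) + c + 1, corner (c, r), c in 0..nc, r in 0..nr
  cid <- function(c, r) r * (nc + 1) + c + 1
  from <- integer(0); to <- integer(0)
  idx <- which(mask, arr.ind = TRUE)
  for (k in seq_len(nrow(idx))) {
    i <- idx[k, 1]; j <- idx[k, 2]
    if (i == 1 || !mask[i - 1, j]) {       # north side: walk west -> east
      from <- c(from, cid(j - 1, i - 1)); to <- c(to, cid(j, i - 1))
    }
    if (i == nr || !mask[i + 1, j]) {      # south side: east -> west
      from <- c(from, cid(j, i)); to <- c(to, cid(j - 1, i))
    }
    if (j == 1 || !mask[i, j - 1]) {       # west side: south -> north
      from <- c(from, cid(j - 1, i)); to <- c(to, cid(j - 1, i - 1))
    }
    if (j == nc || !mask[i, j + 1]) {      # east side: north -> south
      from <- c(from, cid(j, i - 1)); to <- c(to, cid(j, i))
    }
  }
  used <- rep(FALSE, length(from))
  ord <- order(from)
  # adjacency: for each corner, the outgoing edge indices
  out_edges <- split(ord, from[ord])
  corner_xy <- function(id) {
    c0 <- (id - 1) %% (nc + 1)
    r0 <- (id - 1) %/% (nc + 1)
    c(grid$xmin + c0 * grid$cellsize, grid$ymax - r0 * grid$cellsize)
  }
  heading <- function(e) {
    d <- c((to[e] - 1) %% (nc + 1) - (from[e] - 1) %% (nc + 1),
           (to[e] - 1) %/% (nc + 1) - (from[e] - 1) %/% (nc + 1))
    # 0 = E, 1 = S, 2 = W, 3 = N in corner coordinates (r grows southward)
    if (d[1] == 1) 0L else if (d[2] == 1) 1L else if (d[1] == -1) 2L else 3L
  }
  rings <- list()
  for (e0 in seq_along(from)) {
    if (used[e0]) next
    ring_ids <- from[e0]
    e <- e0
    repeat {
      used[e] <- TRUE
      v <- to[e]
      if (v == ring_ids[1]) break
      ring_ids <- c(ring_ids, v)
      cand <- out_edges[[as.character(v)]]
      cand <- cand[!used[cand]]
      if (length(cand) == 0) break  # should not happen on a valid boundary
      if (length(cand) > 1) {
        h <- heading(e)
        pref <- match((c(h + 1, h, h + 3) %% 4),
                      vapply(cand, heading, 0L))
        cand <- cand[pref[!is.na(pref)][1]]
      }
      e <- cand[1]
    }
    coords <- t(vapply(ring_ids, corner_xy, numeric(2)))
    rings[[length(rings) + 1]] <- coords
  }
  rings
}

#' Partition the synthetic tropics into labeled biome polygons
#'
#' Thresholds a smooth latent field into `n_biomes` quantile classes over
#' the tropical core (cells with |latitude| below `lat_core`), splits each
#' class into connected components, and polygonizes every component along
#' cell boundaries. Every core cell belongs to exactly one unit; units carry
#' "Tropical ..." biome names so the layer behaves like the ecoregions
#' dataset the pipeline expects.
#'
#' @param stack An [env_stack()] from [gen_stack()].
#' @param config A [synthetic_config()].
#' @param seed Optional override of `config$seed`.
#' @return A [biome_layer()].
#' @export
gen_biomes <- function(stack, config, seed = config$seed) {
  g <- stack_geometry(stack)
  nr <- nrow(g$values); nc <- ncol(g$values)
  n_biomes <- config$n_biomes
  if (n_biomes < 2) stop_tropirep("`n_biomes` must be >= 2",
                                  "validation_error")
  latent <- withr::with_seed(
    derive_seed(seed, "biome_latent"),
    smooth_field(nr, nc, 2 * config$smoothness_cells)
  )
  lat <- matrix(rep(grid_lat_centers(g), times = nc), nr, nc)
  core <- abs(lat) <= config$lat_core & stack$domain_mask
  vals <- latent[core]
  if (length(unique(vals)) < n_biomes) {
    stop_tropirep("latent field has fewer distinct values than `n_biomes`",
                  "validation_error")
  }
  qs <- quantile(vals, probs = seq(0, 1, length.out = n_biomes + 1),
                 names = FALSE)
  cls <- matrix(0L, nr, nc)
  cls[core] <- pmin(findInterval(vals, qs, rightmost.closed = TRUE), n_biomes)
  biome_names <- paste("Tropical",
                       c("Moist Broadleaf Forests", "Dry Broadleaf Forests",
                         "Grasslands, Savannas & Shrublands",
                         "Deserts & Xeric Shrublands",
                         "Montane Grasslands & Shrublands",
                         "Flooded Grasslands & Savannas",
                         "Coniferous Forests", "Mangroves"))
  eco <- character(0); bio <- character(0); geoms <- list()
  for (b in seq_len(n_biomes)) {
    comp <- connected_components(cls == b)
    for (cc in seq_len(max(comp))) {
      rings <- trace_rings(comp == cc, g)
      eco <- c(eco, sprintf("%s ecoregion %d", biome_names[b], cc))
      bio <- c(bio, biome_names[b])
      geoms[[length(geoms) + 1]] <- rings
    }
  }
  biome_layer(eco, bio, geoms)
}

#' Generate a preferentially sampled synthetic literature table
#'
#' Draws article sampling locations from a point process over domain cells
#' with intensity proportional to `exp(sum(beta * z))` (standardized
#' covariates), mimicking the attraction of field research to particular
#' environments. Locations per article are uniform on `loc_range`; article
#' citations are discretized log-normal (heavy-tailed, minimum 1); each
#' location is urban/agricultural with the configured probability and
#' otherwise carries 1-3 natural habitat labels.
#'
#' @param stack An [env_stack()] from [gen_stack()].
#' @param config A [synthetic_config()].
#' @param seed Optional override of `config$seed`.
#' @return A [lit_table()] with a `truth` attribute recording the bias
#'   coefficients, the intensity summary and all stage seeds.
#' @export
gen_literature <- function(stack, config, seed = config$seed) {
  g <- stack_geometry(stack)
  nr <- nrow(g$values); nc <- ncol(g$values)
  cells <- which(stack$domain_mask)
  log_int <- rep(0, length(cells))
  beta <- config$beta
  for (l in names(beta)) {
    if (!(l %in% names(stack$layers))) {
      stop_tropirep(paste("beta names an unknown layer:", l),
                    "validation_error")
    }
    v <- stack$layers[[l]]$values[cells]
    z <- (v - mean(v, na.rm = TRUE)) / stats::sd(v, na.rm = TRUE)
    log_int <- log_int + beta[[l]] * z
  }
  intensity <- exp(log_int)
  intensity[!is.finite(intensity)] <- 0  # cells missing a bias covariate
  if (all(intensity == 0)) {
    stop_tropirep("all-zero sampling intensity", "validation_error")
  }
  n_loc <- withr::with_seed(
    derive_seed(seed, "n_loc"),
    sample(config$loc_range[1]:config$loc_range[2], config$n_articles,
           replace = TRUE)
  )
  n_total <- sum(n_loc)
  picked <- withr::with_seed(
    derive_seed(seed, "cells"),
    sample(seq_along(cells), n_total, replace = TRUE,
           prob = intensity / sum(intensity))
  )
  jit <- withr::with_seed(derive_seed(seed, "jitter"),
                          matrix(runif(2 * n_total, -0.5, 0.5), ncol = 2))
  idx <- cells[picked]
  row <- ((idx - 1) %% nr) + 1
  col <- ((idx - 1) %/% nr) + 1
  lon <- grid_lon_centers(g)[col] + jit[, 1] * g$cellsize
  lat <- grid_lat_centers(g)[row] + jit[, 2] * g$cellsize
  citations <- withr::with_seed(
    derive_seed(seed, "citations"),
    ceiling(rlnorm(config$n_articles, config$citation_meanlog,
                   config$citation_sdlog))
  )
  natural <- c("forest", "grassland", "wetland", "desert", "rocky",
               "lake", "river")
  habitats <- withr::with_seed(derive_seed(seed, "habitats"), {
    is_mod <- runif(n_total) < config$urban_agri_fraction
    map(seq_len(n_total), function(i) {
      if (is_mod[i]) {
        sample(c("urban", "agricultural"), 1)
      } else {
        k <- sample(1:3, 1, prob = c(0.7, 0.2, 0.1))
        sample(natural, k, prob = c(0.35, 0.2, 0.12, 0.08, 0.05, 0.08, 0.12))
      }
    })
  })
  article_id <- rep(sprintf("A%04d", seq_len(config$n_articles)), times = n_loc)
  tab <- lit_table(tibble(
    article_id = article_id,
    total_citations = rep(citations, times = n_loc),
    longitude = lon, latitude = lat,
    habitats = habitats
  ))
  tab <- allocate_citations(tab)
  attr(tab, "truth") <- list(
    beta = as.list(beta),
    seed = seed,
    stage_seeds = list(
      n_loc = derive_seed(seed, "n_loc"), cells = derive_seed(seed, "cells"),
      jitter = derive_seed(seed, "jitter"),
      citations = derive_seed(seed, "citations"),
      habitats = derive_seed(seed, "habitats")
    ),
    intensity_summary = list(mean = mean(intensity), max = max(intensity),
                             n_cells = length(cells)),
    urban_agri_fraction = config$urban_agri_fraction,
    n_articles = config$n_articles, n_locations = n_total
  )
  tab
}
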